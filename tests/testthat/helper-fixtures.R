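# Shared fixtures. Expensive objects (the full-scale colony and the annual
# gull year) are generated once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

# Study-scale ant colony: 20 animals, 10,000 steps (the generator defaults).
default_ant_fixture <- function() {
  if (is.null(.fixtures$ant)) {
    .fixtures$ant <- generate_ant_colony(seed = 101)
  }
  .fixtures$ant
}

# Small colony for fast structural tests.
small_ant_fixture <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_ant_colony(n_animals = 6, steps = 1800,
                                           seed = 8)
  }
  .fixtures$small
}

# One full synthetic gull bird-year at 25-minute sampling.
default_gull_fixture <- function() {
  if (is.null(.fixtures$gull)) {
    .fixtures$gull <- generate_gull_year(seed = 2)
  }
  .fixtures$gull
}

# Small fitted framework model shared by the framework, simulation and
# composition tests.
fit_small_framework <- function() {
  if (is.null(.fixtures$framework)) {
    sim <- small_ant_fixture()
    geom <- nest_geometry()
    lab <- label_ant_states(sim$track, geom)
    .fixtures$framework <- list(
      sim = sim, geom = geom, lab = lab,
      model = fit_framework(sim$track, lab, geom,
                            state_learner = learner_rf(num_trees = 30),
                            velocity_learner = learner_rf(num_trees = 30),
                            seed = 1)
    )
  }
  .fixtures$framework
}

empty_box <- function(side = 10) {
  nest_geometry(side, side, n_chambers = 1, with_barriers = FALSE)
}

# Build a colony track from per-animal position lists:
# make_track(list(a = cbind(x, y), b = ...))
make_track <- function(positions, dt = 1) {
  rows <- lapply(names(positions), function(id) {
    p <- positions[[id]]
    tibble::tibble(id = id, t = seq_len(nrow(p)), x = p[, 1], y = p[, 2])
  })
  colony_track(dplyr::bind_rows(rows), dt = dt)
}

# Brute-force split oracle: enumerates every (predictor, midpoint threshold)
# pair and recomputes child impurities from scratch, with the same
# tolerance/tie rules as the contract (strict improvement beyond 1e-10;
# ties keep the earlier candidate, i.e. lowest predictor then threshold).
oracle_best_split <- function(x, y, task) {
  x <- as.matrix(x)
  n <- nrow(x)
  imp <- function(rows) {
    yy <- as.matrix(y)[rows, , drop = FALSE]
    if (task %in% c("class", "mvclass")) multioutput_gini(yy) else
      mse_impurity(yy)
  }
  best <- NULL
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (tm in (v[-length(v)] + v[-1]) / 2) {
      l <- x[, j] <= tm
      G <- (sum(l) * imp(l) + sum(!l) * imp(!l)) / n
      if (is.null(best) || G < best$G - 1e-10) {
        best <- list(predictor = j, threshold = tm, G = G)
      }
    }
  }
  best
}

random_split_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(5:50, 1)
  p <- sample(1:4, 1)
  task <- sample(c("class", "reg", "mvclass", "mvreg"), 1)
  x <- matrix(sample(0:6, n * p, TRUE) +
                if (stats::runif(1) < 0.5) 0 else stats::rnorm(n * p, 0, 0.01),
              n, p)
  y <- switch(task,
    class = matrix(sample(0:2, n, TRUE)),
    mvclass = matrix(sample(0:2, n * 3, TRUE), n),
    reg = matrix(stats::rnorm(n)),
    mvreg = matrix(stats::rnorm(2 * n), n)
  )
  list(x = x, y = y, task = task)
}
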