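# Evaluation: one-step mean squared prediction error, the simulation metric
# suite (individual behaviour, space use, interaction), moving-window
# reference bands, the temporal train/test split and grouped CV folds.

#' Mean squared prediction error between paired positions
#'
#' `MSPE = (1/n) sum [(x - x_hat)^2 + (y - y_hat)^2]`. When a geometry is
#' supplied, predictions are first projected onto the nest boundary, the
#' treatment applied before scoring one-step predictions.
#'
#' @param predicted,actual Data frames with columns `x`, `y`, paired row by
#'   row.
#' @param geom Optional [nest_geometry()] used to project predictions.
#' @return A single numeric value.
#' @export
mspe <- function(predicted, actual, geom = NULL) {
  if (nrow(predicted) != nrow(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (nrow(predicted) == 0) stop("empty position lists", call. = FALSE)
  px <- predicted$x; py <- predicted$y
  if (!is.null(geom)) {
    proj <- project_to_boundary(px, py, geom)
    px <- proj$x; py <- proj$y
  }
  mean((actual$x - px)^2 + (actual$y - py)^2)
}

# Per-time colony aggregates shared by simulation_metrics() and
# moving_window_bands(). Positions with NA coordinates are out-of-nest.
colony_time_aggregates <- function(track, states, geom, radius = 12) {
  tr <- dplyr::arrange(tibble::as_tibble(track), .data$id, .data$t)
  ids <- sort(unique(tr$id))
  times <- sort(unique(tr$t))
  N <- length(ids); T <- length(times)
  X <- matrix(tr$x, T, N)
  Y <- matrix(tr$y, T, N)
  present <- !(is.na(X) | is.na(Y))

  st <- dplyr::arrange(tibble::as_tibble(states), .data$id, .data$t)
  S <- matrix(NA_integer_, T, N)
  S[cbind(match(st$t, times), match(st$id, ids))] <- st$state

  # displacement of present -> present steps, summed over animals
  dx <- X[-1, , drop = FALSE] - X[-T, , drop = FALSE]
  dy <- Y[-1, , drop = FALSE] - Y[-T, , drop = FALSE]
  stepd <- sqrt(dx^2 + dy^2)
  stepd[!(present[-1, , drop = FALSE] & present[-T, , drop = FALSE])] <- 0
  disp <- c(0, rowSums(stepd))

  n0 <- rowSums(S == 0, na.rm = TRUE)
  n1 <- rowSums(S == 1, na.rm = TRUE)
  n2 <- rowSums(S == 2, na.rm = TRUE)
  n_state <- n0 + n1 + n2

  n_sub <- nrow(geom$sub_chambers)
  cham <- matrix(0, T, n_sub)
  nb <- numeric(T)
  npres <- rowSums(present)
  for (tt in seq_len(T)) {
    idx <- present[tt, ]
    if (!any(idx)) next
    sc <- sub_chamber_of(X[tt, idx], Y[tt, idx], geom)
    cham[tt, ] <- tabulate(sc, n_sub)
    if (sum(idx) > 1) {
      px <- X[tt, idx]; py <- Y[tt, idx]
      Dm <- sqrt(outer(px, px, "-")^2 + outer(py, py, "-")^2)
      diag(Dm) <- Inf
      nb[tt] <- sum(Dm <= radius)
    }
  }
  list(times = times, disp = disp, n0 = n0, n1 = n1, n2 = n2,
       n_state = n_state, cham = cham, npres = npres, nb = nb)
}

#' Simulation metric suite for one (simulated or observed) track
#'
#' Metrics describing individual behaviour (total distance travelled by all
#' animals; percentage of animal-time records stationary and out of the
#' nest), space use (percentage of in-nest records in each sub-chamber) and
#' interaction (average number of other in-nest animals within `radius` mm).
#'
#' @param track Tibble `id`, `t`, `x`, `y` (NA coordinates = out of nest).
#' @param states Tibble `id`, `t`, `state` for the same records.
#' @param geom A [nest_geometry()].
#' @param radius Interaction radius in mm (closed ball).
#' @return A one-row tibble: `total_distance`, `pct_stationary`, `pct_out`,
#'   `occ_1` ... `occ_<n>`, `avg_neighbors`.
#' @export
simulation_metrics <- function(track, states, geom, radius = 12) {
  if (nrow(tibble::as_tibble(track)) == 0) {
    stop("empty track", call. = FALSE)
  }
  ag <- colony_time_aggregates(track, states, geom, radius)
  occ <- colSums(ag$cham) / max(sum(ag$npres), 1) * 100
  out <- tibble::tibble(
    total_distance = sum(ag$disp),
    pct_stationary = 100 * sum(ag$n0) / max(sum(ag$n_state), 1),
    pct_out = 100 * sum(ag$n1) / max(sum(ag$n_state), 1),
  )
  for (j in seq_along(occ)) out[[paste0("occ_", j)]] <- occ[j]
  out$avg_neighbors <- sum(ag$nb) / max(sum(ag$npres), 1)
  out
}

#' Moving-window reference bands for the simulation metrics
#'
#' Computes the metric suite on every `window`-length window of the observed
#' track (stride 1) and returns per-metric empirical percentiles — the
#' reference bands against which simulated metrics are judged.
#'
#' @inheritParams simulation_metrics
#' @param window Window length in time steps.
#' @param probs Percentile pair (default 25th and 75th).
#' @return A tibble `metric`, `lower`, `upper` with an `n_windows`
#'   attribute.
#' @export
moving_window_bands <- function(track, states, geom, window = 1000,
                                probs = c(0.25, 0.75), radius = 12) {
  ag <- colony_time_aggregates(track, states, geom, radius)
  T <- length(ag$times)
  if (T < window) stop("track shorter than the window", call. = FALSE)
  n_win <- T - window + 1
  csum <- function(v) cumsum(c(0, v))
  win_sum <- function(v, from_offset = 0) {
    # sum of v over window positions a+from_offset .. a+window-1
    cs <- csum(v)
    cs[(window + 1):(T + 1)] - cs[(1 + from_offset):(T - window + 1 + from_offset)]
  }
  # distance: steps strictly inside the window (offset 1 skips the step
  # entering from before the window)
  dist_w <- win_sum(ag$disp, from_offset = 1)
  n0_w <- win_sum(ag$n0); n1_w <- win_sum(ag$n1); ns_w <- win_sum(ag$n_state)
  pres_w <- win_sum(ag$npres); nb_w <- win_sum(ag$nb)
  occ_w <- apply(ag$cham, 2, win_sum)
  if (is.null(dim(occ_w))) occ_w <- matrix(occ_w, nrow = n_win)

  metrics <- tibble::tibble(
    total_distance = dist_w,
    pct_stationary = 100 * n0_w / pmax(ns_w, 1),
    pct_out = 100 * n1_w / pmax(ns_w, 1)
  )
  for (j in seq_len(ncol(occ_w))) {
    metrics[[paste0("occ_", j)]] <- 100 * occ_w[, j] / pmax(pres_w, 1)
  }
  metrics$avg_neighbors <- nb_w / pmax(pres_w, 1)

  out <- tibble::tibble(
    metric = names(metrics),
    lower = unname(vapply(metrics, function(v) {
      unname(stats::quantile(v, probs = probs[1]))
    }, numeric(1))),
    upper = unname(vapply(metrics, function(v) {
      unname(stats::quantile(v, probs = probs[2]))
    }, numeric(1)))
  )
  attr(out, "n_windows") <- as.integer(n_win)
  out
}

#' Contiguous temporal train/test split
#'
#' Splits the track at `floor(fraction * T)` time points: the first part is
#' training data, the remainder test data. No shuffling — the split respects
#' time order.
#'
#' @param track A [colony_track()] or any tibble with a `t` column.
#' @param fraction Fraction of time points assigned to training, in (0, 1).
#' @return A list with elements `train` and `test`.
#' @export
temporal_split <- function(track, fraction = 0.8) {
  times <- sort(unique(track$t))
  n_train <- floor(fraction * length(times))
  if (n_train < 1 || n_train >= length(times)) {
    stop("fraction leaves an empty training or test side", call. = FALSE)
  }
  cut_t <- times[n_train]
  dt <- attr(track, "dt")
  wrap <- function(df) {
    if (inherits(track, "colony_track")) {
      attr(df, "dt") <- dt
      class(df) <- class(track)
    }
    df
  }
  list(
    train = wrap(dplyr::filter(tibble::as_tibble(track), .data$t <= cut_t)),
    test = wrap(dplyr::filter(tibble::as_tibble(track), .data$t > cut_t))
  )
}

#' Assign whole groups to cross-validation folds
#'
#' Seeded random partition of groups (e.g. bird-years) into `k` folds of
#' near-equal size; no group is split across folds.
#'
#' @param groups Vector of group identifiers (one entry per group).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A tibble `group`, `fold`.
#' @export
cv_folds_by_group <- function(groups, k = 5, seed = 1) {
  groups <- unique(groups)
  if (k > length(groups)) {
    stop("more folds than groups", call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(groups)
  tibble::tibble(
    group = shuffled,
    fold = rep_len(seq_len(k), length(shuffled))
  ) |>
    dplyr::arrange(.data$group)
}
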