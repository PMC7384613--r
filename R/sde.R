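# Parametric comparator: a stochastic differential equation with spatially
# varying motility and potential surfaces, discretised by Euler-Maruyama to
# an order-2 autoregression,
#
#   p_{t+2} = beta * m(p_t) * [-grad h(p_t)] + (2 - beta) p_{t+1}
#             - (1 - beta) p_t + m(p_t) eps_t,   eps_t ~ N(0, I),
#
# coupled with a multinomial behavioural-state regression. Surfaces live on
# a regular grid of square cells with indicator-spline bases; the potential
# gradient is a finite difference between adjacent cells. Motility is
# estimated first (penalised Gaussian likelihood of the AR(2) residual scale,
# drift omitted), then the potential by penalised weighted least squares with
# the motility plugged in.

#' Motility/potential surfaces on a regular grid
#'
#' @param geom A [nest_geometry()]; the grid covers the outer rectangle.
#' @param cell_size Cell side length (mm).
#' @param m Initial motility value(s) (scalar or length-J vector, must be
#'   positive).
#' @param h Initial potential value(s).
#' @return An object of class `grid_surfaces` with `nx`, `ny`, `cell_size`
#'   and per-cell vectors `m` and `h` (cell `j = (iy - 1) * nx + ix`).
#' @export
grid_surfaces <- function(geom, cell_size = 1, m = 1, h = 0) {
  nx <- max(1L, ceiling(geom$width / cell_size))
  ny <- max(1L, ceiling(geom$height / cell_size))
  J <- nx * ny
  stopifnot(all(m > 0))
  structure(
    list(nx = nx, ny = ny, cell_size = cell_size, J = J,
         width = geom$width, height = geom$height,
         m = rep_len(m, J), h = rep_len(h, J)),
    class = "grid_surfaces"
  )
}

#' @export
print.grid_surfaces <- function(x, ...) {
  cat(sprintf("<grid_surfaces> %d x %d cells of %g mm (J = %d)\n",
              x$nx, x$ny, x$cell_size, x$J))
  invisible(x)
}

# Cell index of positions; points outside the grid are assigned the nearest
# cell (with a warning unless quiet).
cell_of <- function(s, x, y, quiet = FALSE) {
  ix <- floor(x / s$cell_size) + 1
  iy <- floor(y / s$cell_size) + 1
  # outer edges are closed: a point exactly on the right/top boundary
  # belongs to the last cell
  ix[x >= s$nx * s$cell_size & x <= s$nx * s$cell_size + 1e-9] <- s$nx
  iy[y >= s$ny * s$cell_size & y <= s$ny * s$cell_size + 1e-9] <- s$ny
  outside <- ix < 1 | ix > s$nx | iy < 1 | iy > s$ny
  if (any(outside) && !quiet) {
    warning(sum(outside), " position(s) outside the grid assigned to the ",
            "nearest cell", call. = FALSE)
  }
  ix <- pmin(pmax(ix, 1), s$nx)
  iy <- pmin(pmax(iy, 1), s$ny)
  as.integer((iy - 1) * s$nx + ix)
}

cell_centres <- function(s) {
  ix <- rep(seq_len(s$nx), times = s$ny)
  iy <- rep(seq_len(s$ny), each = s$nx)
  tibble::tibble(cell = seq_len(s$J), ix = ix, iy = iy,
                 x = (ix - 0.5) * s$cell_size, y = (iy - 0.5) * s$cell_size)
}

#' Grid-cell table of a surface object
#'
#' One row per cell with its indices, centre coordinates and current
#' motility/potential values.
#'
#' @param surfaces A [grid_surfaces()].
#' @return A tibble `cell`, `ix`, `iy`, `x`, `y`, `m`, `h`.
#' @export
surface_cells <- function(surfaces) {
  cc <- cell_centres(surfaces)
  cc$m <- surfaces$m
  cc$h <- surfaces$h
  cc
}

#' Evaluate the motility and potential surfaces at positions
#'
#' Indicator-spline evaluation: each position takes the value of its
#' containing cell (half-open cell edges; the grid's outer edges are closed).
#'
#' @param surfaces A [grid_surfaces()].
#' @param x,y Positions.
#' @return A tibble with columns `m` and `h`.
#' @export
surface_eval <- function(surfaces, x, y) {
  j <- cell_of(surfaces, x, y)
  tibble::tibble(m = surfaces$m[j], h = surfaces$h[j])
}

#' Finite-difference gradient of the potential surface
#'
#' Central differences over adjacent cells, one-sided at grid edges, zero
#' where a cell has no neighbour along an axis.
#'
#' @inheritParams surface_eval
#' @return A tibble with columns `gx`, `gy` (potential units per mm).
#' @export
potential_gradient <- function(surfaces, x, y) {
  s <- surfaces
  j <- cell_of(s, x, y)
  ix <- (j - 1) %% s$nx + 1
  iy <- (j - 1) %/% s$nx + 1
  cs <- s$cell_size
  grad_axis <- function(i, n, stride) {
    lo <- i > 1; hi <- i < n
    g <- numeric(length(j))
    both <- lo & hi
    g[both] <- (s$h[j[both] + stride] - s$h[j[both] - stride]) / (2 * cs)
    left <- !lo & hi
    g[left] <- (s$h[j[left] + stride] - s$h[j[left]]) / cs
    right <- lo & !hi
    g[right] <- (s$h[j[right]] - s$h[j[right] - stride]) / cs
    g
  }
  tibble::tibble(gx = grad_axis(ix, s$nx, 1L),
                 gy = grad_axis(iy, s$ny, s$nx))
}

# Per-cell finite-difference gradient field (same stencil as
# potential_gradient, evaluated once for all cells).
gradient_field <- function(s) {
  cc <- seq_len(s$J)
  ix <- (cc - 1) %% s$nx + 1
  iy <- (cc - 1) %/% s$nx + 1
  cs <- s$cell_size
  g_axis <- function(i, n, stride) {
    g <- numeric(s$J)
    both <- i > 1 & i < n
    g[both] <- (s$h[cc[both] + stride] - s$h[cc[both] - stride]) / (2 * cs)
    left <- i == 1 & n > 1
    g[left] <- (s$h[cc[left] + stride] - s$h[cc[left]]) / cs
    right <- i == n & n > 1
    g[right] <- (s$h[cc[right]] - s$h[cc[right] - stride]) / cs
    g
  }
  list(gx = g_axis(ix, s$nx, 1L), gy = g_axis(iy, s$ny, s$nx))
}

# Fast vectorised AR(2) transition without tibble wrapping.
ar2_core <- function(s, gf, beta, x0, y0, x1, y1, sample = FALSE) {
  j <- cell_of(s, x0, y0, quiet = TRUE)
  m <- s$m[j]
  mx <- beta * m * (-gf$gx[j]) + (2 - beta) * x1 - (1 - beta) * x0
  my <- beta * m * (-gf$gy[j]) + (2 - beta) * y1 - (1 - beta) * y0
  if (!sample) return(list(mx = mx, my = my))
  n <- length(mx)
  list(mx = mx, my = my,
       x = mx + m * stats::rnorm(n), y = my + m * stats::rnorm(n))
}

#' Simulate a long AR(2) trajectory
#'
#' Rolls the AR(2) movement model forward `steps` steps from two initial
#' positions, optionally clamping each step to the nest rectangle.
#'
#' @param surfaces A [grid_surfaces()].
#' @param beta Friction coefficient.
#' @param steps Number of steps to simulate.
#' @param init Numeric vector `c(x0, y0, x1, y1)` (defaults to the grid
#'   centre, at rest).
#' @param geom Optional [nest_geometry()]; positions are projected onto its
#'   boundary after each step.
#' @param seed Optional RNG seed.
#' @return A tibble `t`, `x`, `y` of length `steps + 2` (including the two
#'   initial positions).
#' @export
ar2_simulate <- function(surfaces, beta, steps, init = NULL, geom = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- surfaces
  gf <- gradient_field(s)
  if (is.null(init)) {
    cx <- s$nx * s$cell_size / 2
    cy <- s$ny * s$cell_size / 2
    init <- c(cx, cy, cx, cy)
  }
  n <- steps + 2
  x <- numeric(n); y <- numeric(n)
  x[1:2] <- init[c(1, 3)]; y[1:2] <- init[c(2, 4)]
  xmax <- if (is.null(geom)) s$nx * s$cell_size else geom$width
  ymax <- if (is.null(geom)) s$ny * s$cell_size else geom$height
  clamp <- !is.null(geom)
  for (t in 3:n) {
    stp <- ar2_core(s, gf, beta, x[t - 2], y[t - 2], x[t - 1], y[t - 1],
                    sample = TRUE)
    xt <- stp$x; yt <- stp$y
    if (clamp) {
      xt <- min(max(xt, 0), xmax)
      yt <- min(max(yt, 0), ymax)
    }
    x[t] <- xt; y[t] <- yt
  }
  tibble::tibble(t = seq_len(n), x = x, y = y)
}

#' One step of the AR(2) movement model
#'
#' Given positions at two consecutive times, returns the conditional mean of
#' the next position and (optionally) a stochastic draw,
#' `mean = beta * m(p_t) * [-grad h(p_t)] + (2 - beta) p_{t+1} - (1 - beta) p_t`
#' and `sample = mean + m(p_t) * eps`, `eps ~ N(0, I)`.
#'
#' @param x0,y0 Position at time `t`.
#' @param x1,y1 Position at time `t + 1`.
#' @param beta Friction coefficient in `(0, 1]`.
#' @param surfaces A [grid_surfaces()].
#' @param sample Draw the stochastic step (uses the current RNG state)?
#' @return A tibble `mean_x`, `mean_y` and, when `sample = TRUE`, `x`, `y`.
#' @export
ar2_step <- function(x0, y0, x1, y1, beta, surfaces, sample = FALSE) {
  gf <- gradient_field(surfaces)
  stp <- ar2_core(surfaces, gf, beta, x0, y0, x1, y1, sample = sample)
  out <- tibble::tibble(mean_x = stp$mx, mean_y = stp$my)
  if (sample) {
    out$x <- stp$x
    out$y <- stp$y
  }
  out
}

# Extract (p_t, p_{t+1}, p_{t+2}) triples where the two steps ending at
# t+1 and t+2 are both within-nest movements (state 2) and all three
# positions are observed.
moving_triples <- function(track, states, geom) {
  tr <- dplyr::arrange(tibble::as_tibble(track), .data$id, .data$t)
  st <- dplyr::arrange(tibble::as_tibble(states), .data$id, .data$t)
  tr <- dplyr::left_join(tr, st, by = c("id", "t"))
  tr |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(
      x1 = dplyr::lead(.data$x), y1 = dplyr::lead(.data$y),
      x2 = dplyr::lead(.data$x, 2), y2 = dplyr::lead(.data$y, 2),
      s1 = dplyr::lead(.data$state), s2 = dplyr::lead(.data$state, 2)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(
      !.data$out, !is.na(.data$x1), !is.na(.data$x2),
      .data$s1 == 2, .data$s2 == 2
    ) |>
    dplyr::transmute(
      id = .data$id, t = .data$t,
      x0 = .data$x, y0 = .data$y,
      x1 = .data$x1, y1 = .data$y1,
      x2 = .data$x2, y2 = .data$y2
    )
}

ar2_residuals <- function(triples, beta) {
  cbind(
    triples$x2 - (2 - beta) * triples$x1 + (1 - beta) * triples$x0,
    triples$y2 - (2 - beta) * triples$y1 + (1 - beta) * triples$y0
  )
}

#' Estimate the friction coefficient from moving segments
#'
#' Under the AR(2) model with a flat potential, the velocity process is
#' `v_{t+1} = (1 - beta) v_t + m eps`, so the lag-1 autocorrelation of the
#' velocity components identifies `beta`. Pools x and y velocity components
#' over all runs of consecutive within-nest movements.
#'
#' @param track A [colony_track()].
#' @param states Output of [label_ant_states()].
#' @return `beta` estimate clipped to `(0, 1]`.
#' @export
estimate_beta <- function(track, states) {
  tr <- dplyr::arrange(tibble::as_tibble(track), .data$id, .data$t)
  st <- dplyr::arrange(tibble::as_tibble(states), .data$id, .data$t)
  tr <- dplyr::left_join(tr, st, by = c("id", "t"))
  tr <- tr |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(
      vx = .data$x - dplyr::lag(.data$x),
      vy = .data$y - dplyr::lag(.data$y),
      vx1 = dplyr::lead(.data$vx), vy1 = dplyr::lead(.data$vy),
      s1 = dplyr::lead(.data$state)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$state == 2, .data$s1 == 2,
                  !is.na(.data$vx), !is.na(.data$vx1))
  if (nrow(tr) < 10) {
    stop("need at least 10 consecutive moving steps to estimate beta",
         call. = FALSE)
  }
  rho <- stats::cor(c(tr$vx, tr$vy), c(tr$vx1, tr$vy1))
  min(max(1 - rho, 1e-6), 1)
}

surface_adjacency <- function(s) {
  # index pairs of 4-neighbour adjacent cells (each pair once)
  ix <- (seq_len(s$J) - 1) %% s$nx + 1
  iy <- (seq_len(s$J) - 1) %/% s$nx + 1
  right <- which(ix < s$nx)
  up <- which(iy < s$ny)
  cbind(c(right, up), c(right + 1L, up + s$nx))
}

#' Estimate the motility surface by penalised likelihood
#'
#' Maximises the Gaussian likelihood of the AR(2) residuals (drift omitted at
#' this stage) with a per-cell scale, minus `lambda` times the sum of squared
#' differences of log-motility over adjacent cells. Cells without data shrink
#' towards their neighbours through the penalty.
#'
#' @param triples Moving-step triples (from the internal extractor used by
#'   [fit_sde()]), or a data frame with columns `x0, y0, x1, y1, x2, y2`.
#' @param beta Friction coefficient.
#' @param surfaces A [grid_surfaces()] defining the grid.
#' @param lambda Penalty weight; `NULL` selects it by blocked 5-fold
#'   cross-validation over a log-spaced grid.
#' @return `surfaces` with the fitted `m`, plus attributes `lambda` and
#'   `n_cell` (per-cell step counts).
#' @export
estimate_motility <- function(triples, beta, surfaces, lambda = NULL) {
  if (nrow(triples) == 0) stop("no moving steps to fit", call. = FALSE)
  if (is.null(lambda)) {
    lambda <- cv_lambda(
      triples,
      function(tr, l) estimate_motility(tr, beta, surfaces, lambda = l),
      function(fit, tr) {
        r <- ar2_residuals(tr, beta)
        j <- cell_of(fit, tr$x0, tr$y0, quiet = TRUE)
        m <- fit$m[j]
        sum(2 * log(m) + rowSums(r^2) / (2 * m^2))
      }
    )
  }
  r <- ar2_residuals(triples, beta)
  j <- cell_of(surfaces, triples$x0, triples$y0, quiet = TRUE)
  J <- surfaces$J
  n_cell <- tabulate(j, J)
  ucells <- sort(unique(j))
  ss <- numeric(J)
  ss[ucells] <- rowsum(rowSums(r^2), factor(j, levels = ucells))[, 1]
  adj <- surface_adjacency(surfaces)

  pooled <- sqrt(sum(ss) / (2 * max(sum(n_cell), 1)))
  l0 <- rep(log(max(pooled, 1e-6)), J)
  has <- n_cell > 0
  l0[has] <- log(pmax(sqrt(ss[has] / (2 * n_cell[has])), 1e-6))

  obj <- function(l) {
    sum(2 * n_cell * l + ss * exp(-2 * l) / 2) +
      lambda * sum((l[adj[, 1]] - l[adj[, 2]])^2)
  }
  grad <- function(l) {
    g <- 2 * n_cell - ss * exp(-2 * l)
    d <- l[adj[, 1]] - l[adj[, 2]]
    pen <- numeric(J)
    tab1 <- rowsum(d, adj[, 1])
    pen[as.integer(rownames(tab1))] <- pen[as.integer(rownames(tab1))] +
      2 * lambda * tab1[, 1]
    tab2 <- rowsum(-d, adj[, 2])
    pen[as.integer(rownames(tab2))] <- pen[as.integer(rownames(tab2))] +
      2 * lambda * tab2[, 1]
    g + pen
  }
  fit <- stats::optim(l0, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 500))
  out <- surfaces
  out$m <- exp(fit$par)
  attr(out, "lambda") <- lambda
  attr(out, "n_cell") <- n_cell
  attr(out, "convergence") <- fit$convergence
  out
}

#' Estimate the potential surface by penalised weighted least squares
#'
#' With the motility surface plugged in, minimises
#' `sum_t || r_t - beta * m(p_t) * [-grad h](p_t) ||^2 / m(p_t)^2` plus
#' `lambda` times the squared-difference roughness penalty on `h` over
#' adjacent cells. The potential is identified up to an additive constant and
#' is anchored to mean zero.
#'
#' @inheritParams estimate_motility
#' @param surfaces A [grid_surfaces()] carrying the fitted motility in `$m`.
#' @return `surfaces` with the fitted `h` (mean zero) and attribute `lambda`.
#' @export
estimate_potential <- function(triples, beta, surfaces, lambda = NULL) {
  if (nrow(triples) == 0) stop("no moving steps to fit", call. = FALSE)
  if (is.null(lambda)) {
    lambda <- cv_lambda(
      triples,
      function(tr, l) estimate_potential(tr, beta, surfaces, lambda = l),
      function(fit, tr) {
        r <- ar2_residuals(tr, beta)
        sv <- surface_eval(fit, tr$x0, tr$y0)
        g <- potential_gradient(fit, tr$x0, tr$y0)
        sum(((r[, 1] - beta * sv$m * (-g$gx))^2 +
               (r[, 2] - beta * sv$m * (-g$gy))^2) / sv$m^2)
      }
    )
  }
  s <- surfaces
  J <- s$J
  r <- ar2_residuals(triples, beta)
  j <- cell_of(s, triples$x0, triples$y0, quiet = TRUE)
  n_cell <- tabulate(j, J)
  ucells <- sort(unique(j))
  sum_rx <- numeric(J); sum_ry <- numeric(J)
  sum_rx[ucells] <- rowsum(r[, 1], factor(j, levels = ucells))[, 1]
  sum_ry[ucells] <- rowsum(r[, 2], factor(j, levels = ucells))[, 1]

  D <- gradient_operators(s)
  N <- Matrix::Diagonal(x = n_cell)
  adj <- surface_adjacency(s)
  L <- Matrix::sparseMatrix(
    i = c(adj[, 1], adj[, 2], adj[, 1], adj[, 2]),
    j = c(adj[, 1], adj[, 2], adj[, 2], adj[, 1]),
    x = c(rep(1, 2 * nrow(adj)), rep(-1, 2 * nrow(adj))),
    dims = c(J, J)
  )
  A <- beta^2 * (Matrix::t(D$x) %*% N %*% D$x +
                   Matrix::t(D$y) %*% N %*% D$y) + lambda * L
  # grad h enters the model with a negative sign: r ~ beta * m * (-D h)
  b <- -beta * (Matrix::t(D$x) %*% sum_rx + Matrix::t(D$y) %*% sum_ry)
  A <- A + Matrix::Diagonal(J, x = 1e-8 * max(1, mean(Matrix::diag(A))))
  h <- as.vector(Matrix::solve(A, b))
  s$h <- h - mean(h)
  attr(s, "lambda") <- lambda
  attr(s, "n_cell") <- n_cell
  s
}

# Sparse finite-difference operators: row j of D$x (D$y) maps h to the x (y)
# gradient at cell j.
gradient_operators <- function(s) {
  J <- s$J; cs <- s$cell_size
  ix <- (seq_len(J) - 1) %% s$nx + 1
  iy <- (seq_len(J) - 1) %/% s$nx + 1
  build <- function(i, n, stride) {
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    both <- which(i > 1 & i < n)
    rows <- c(rows, both, both)
    cols <- c(cols, both + stride, both - stride)
    vals <- c(vals, rep(1 / (2 * cs), length(both)),
              rep(-1 / (2 * cs), length(both)))
    left <- which(i == 1 & n > 1)
    rows <- c(rows, left, left)
    cols <- c(cols, left + stride, left)
    vals <- c(vals, rep(1 / cs, length(left)), rep(-1 / cs, length(left)))
    right <- which(i == n & n > 1)
    rows <- c(rows, right, right)
    cols <- c(cols, right, right - stride)
    vals <- c(vals, rep(1 / cs, length(right)), rep(-1 / cs, length(right)))
    Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(J, J))
  }
  list(x = build(ix, s$nx, 1L), y = build(iy, s$ny, s$nx))
}

# Blocked k-fold cross-validation over contiguous row blocks of the triples.
cv_lambda <- function(triples, fit_fun, score_fun, k = 5,
                      grid = 10^seq(-2, 2, length.out = 5)) {
  n <- nrow(triples)
  fold <- cut(seq_len(n), breaks = k, labels = FALSE)
  scores <- vapply(grid, function(l) {
    sum(vapply(seq_len(k), function(f) {
      fit <- fit_fun(triples[fold != f, , drop = FALSE], l)
      score_fun(fit, triples[fold == f, , drop = FALSE])
    }, numeric(1)))
  }, numeric(1))
  grid[which.min(scores)]
}

#' Multinomial behavioural-state regression with backward selection
#'
#' Fits a multinomial logistic regression of the state on the derived
#' variables, then removes predictors one at a time, at each round dropping
#' the predictor whose removal most improves the criterion, until no removal
#' improves it.
#'
#' @param x Data frame or matrix of predictors.
#' @param y State labels (>= 2 classes).
#' @param criterion `"AIC"` or `"BIC"`.
#' @param trace Print elimination progress?
#' @return An object of class `multinomial_state_model` with elements `fit`
#'   (the final [nnet::multinom()] model), `retained`, `criterion_value`.
#' @export
fit_multinomial_backward <- function(x, y, criterion = c("AIC", "BIC"),
                                     trace = FALSE) {
  criterion <- match.arg(criterion)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 state classes", call. = FALSE)
  x <- as.data.frame(x)
  crit <- function(fit) {
    if (criterion == "AIC") stats::AIC(fit) else stats::BIC(fit)
  }
  fit_with <- function(vars) {
    df <- cbind(x[, vars, drop = FALSE], .state = y)
    nnet::multinom(.state ~ ., data = df, trace = FALSE, maxit = 300,
                   MaxNWts = 5000)
  }
  retained <- names(x)
  current <- fit_with(retained)
  best <- crit(current)
  repeat {
    if (length(retained) <= 1) break
    cand <- vapply(retained, function(v) {
      crit(fit_with(setdiff(retained, v)))
    }, numeric(1))
    if (min(cand) >= best) break
    drop_var <- retained[which.min(cand)]
    retained <- setdiff(retained, drop_var)
    current <- fit_with(retained)
    best <- crit(current)
    if (trace) message("dropped ", drop_var, " (", criterion, " ",
                       round(best, 2), ")")
  }
  structure(
    list(fit = current, retained = retained, criterion = criterion,
         criterion_value = best, levels = levels(y)),
    class = "multinomial_state_model"
  )
}

#' @export
predict.multinomial_state_model <- function(object, newdata, ...) {
  p <- predict(object$fit, newdata = as.data.frame(newdata), type = "probs")
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  p
}

#' Fit the full SDE movement model to an ant colony
#'
#' Estimates the friction coefficient from moving-run velocity
#' autocorrelation, then the motility surface, then the potential surface,
#' on the subset of the data where the animals were moving within the nest.
#' Optionally fits the multinomial state regression on the derived variables.
#'
#' @param track A [colony_track()].
#' @param states Output of [label_ant_states()].
#' @param geom A [nest_geometry()].
#' @param cell_size Grid cell side (mm).
#' @param beta Friction coefficient; `NULL` estimates it via
#'   [estimate_beta()].
#' @param lambda_m,lambda_h Penalty weights (`NULL` = blocked 5-fold CV).
#' @param fit_states Fit the multinomial state model (backward-selected on
#'   the derived variables)? Requires feature computation; can be slow.
#' @param queen_id,lags,eps_move Feature settings when `fit_states = TRUE`.
#' @return An object of class `sde_model`.
#' @export
fit_sde <- function(track, states, geom, cell_size = 1, beta = NULL,
                    lambda_m = 1, lambda_h = 1, fit_states = FALSE,
                    queen_id = "Que", lags = 5, eps_move = 0) {
  if (is.null(beta)) beta <- estimate_beta(track, states)
  triples <- moving_triples(track, states, geom)
  surf <- grid_surfaces(geom, cell_size)
  surf <- estimate_motility(triples, beta, surf, lambda = lambda_m)
  surf <- estimate_potential(triples, beta, surf, lambda = lambda_h)
  state_model <- NULL
  if (fit_states) {
    feats <- derive_ant_features(track, geom, queen_id, lags, eps_move)
    st <- dplyr::left_join(dplyr::select(feats, "id", "t"), states,
                           by = c("id", "t"))
    fdf <- dplyr::select(feats, -dplyr::any_of(c("id", "t", "out_prev")))
    state_model <- fit_multinomial_backward(fdf, st$state)
  }
  structure(
    list(beta = beta, surfaces = surf, state_model = state_model,
         geom = geom, exit = geom$exit, n_triples = nrow(triples),
         cfg = feature_config(lags = lags, eps_move = eps_move),
         queen_id = queen_id, dt = track_dt(track)),
    class = "sde_model"
  )
}

#' @export
print.sde_model <- function(x, ...) {
  cat(sprintf(
    "<sde_model> beta %.3f, %d x %d grid, fitted on %d moving triples\n",
    x$beta, x$surfaces$nx, x$surfaces$ny, x$n_triples))
  invisible(x)
}

#' One-step-ahead prediction from a fitted SDE model
#'
#' The multinomial state model predicts the behavioural state; stationary
#' animals keep their position, exiting animals move to the exit point, and
#' moving animals follow the AR(2) conditional mean (`mode = "expected"`) or
#' a stochastic draw (`mode = "sampled"`), projected onto the nest.
#'
#' @param model A fitted [fit_sde()] model with `fit_states = TRUE` (or an
#'   externally supplied state model in `model$state_model`).
#' @param track A [colony_track()] providing history.
#' @param times Times at which to predict (default all with history).
#' @param mode `"expected"` or `"sampled"`.
#' @param seed Optional RNG seed for the sampled path.
#' @return A tibble `id`, `t`, `state`, `x`, `y`.
#' @export
sde_predict_one_step <- function(model, track, times = NULL,
                                 mode = c("expected", "sampled"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model$state_model)) {
    stop("model carries no state model; fit with fit_states = TRUE",
         call. = FALSE)
  }
  geom <- model$geom
  feats <- derive_ant_features(track, geom, model$queen_id, model$cfg$lags,
                               model$cfg$eps_move)
  if (!is.null(times)) feats <- dplyr::filter(feats, .data$t %in% times)
  A <- build_track_arrays(track, geom, model$cfg, model$queen_id)
  idx_t <- match(feats$t, A$times)
  idx_i <- match(feats$id, A$ids)
  x1 <- A$X[cbind(idx_t - 1, idx_i)]
  y1 <- A$Y[cbind(idx_t - 1, idx_i)]
  x0 <- A$X[cbind(idx_t - 2, idx_i)]
  y0 <- A$Y[cbind(idx_t - 2, idx_i)]
  fdf <- dplyr::select(feats, -dplyr::any_of(c("id", "t", "out_prev")))
  probs <- predict(model$state_model, fdf)
  lv <- as.integer(colnames(probs))
  state <- if (mode == "expected") {
    lv[max.col(probs, ties.method = "first")]
  } else {
    draw_states(probs, lv)
  }
  step <- ar2_step(x0, y0, x1, y1, model$beta, model$surfaces,
                   sample = (mode == "sampled"))
  x_new <- if (mode == "sampled") step$x else step$mean_x
  y_new <- if (mode == "sampled") step$y else step$mean_y
  pos <- compose_ant_positions(x1, y1, state,
                               (x_new - x1) / model$dt,
                               (y_new - y1) / model$dt,
                               model$dt, geom)
  tibble::tibble(id = feats$id, t = feats$t, state = state,
                 x = pos$x, y = pos$y)
}
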