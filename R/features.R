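# Derived-variable computation for ant colonies and migratory birds.
#
# The single source of truth for ant features is `features_for_time()`, which
# computes the full feature block for every animal at one prediction time
# from history arrays. Batch derivation and simulation rollouts both call it,
# so features seen during training and during rollout are identical by
# construction.

ant_feature_names <- function(lags = 5) {
  c(paste0("x_l", seq_len(lags)), paste0("y_l", seq_len(lags)),
    paste0("vx_l", seq_len(lags)), paste0("vy_l", seq_len(lags)),
    "stationary_time", "d_prev", "sub_chamber",
    "wall_n", "wall_s", "wall_e", "wall_w",
    "nn_dist", "nn_x", "nn_y", "nn_vx", "nn_vy",
    "q1", "q2", "q3", "q4", "n_still", "n_moving", "dist_queen")
}

feature_config <- function(lags = 5, eps_move = 0, r_still = 10, r_moving = 12,
                           quadrant_side = 8) {
  list(lags = lags, eps_move = eps_move, r_still = r_still,
       r_moving = r_moving, quadrant_side = quadrant_side)
}

# History arrays for a colony track. Out-of-arena records are filled with the
# exit point and zero velocity; `OUT` keeps the flag so out animals can be
# excluded from neighbour pools.
build_track_arrays <- function(track, geom, cfg = feature_config(),
                               queen_id = NULL) {
  tr <- tibble::as_tibble(track)
  ids <- sort(unique(tr$id))
  times <- sort(unique(tr$t))
  N <- length(ids); T <- length(times)
  dt <- track_dt(track)
  tr <- dplyr::arrange(tr, .data$id, .data$t)
  X <- matrix(tr$x, nrow = T, ncol = N)
  Y <- matrix(tr$y, nrow = T, ncol = N)
  OUT <- matrix(tr$out, nrow = T, ncol = N)
  X[OUT] <- geom$exit[1]
  Y[OUT] <- geom$exit[2]

  A <- list(ids = ids, times = times, N = N, T = T, dt = dt,
            X = X, Y = Y, OUT = OUT,
            VX = matrix(0, T, N), VY = matrix(0, T, N),
            D = matrix(NA_real_, T, N), RUN = matrix(0L, T, N),
            qidx = if (!is.null(queen_id)) match(queen_id, ids) else NA_integer_,
            cfg = cfg, geom = geom)
  for (s in 2:T) A <- update_arrays_step(A, s)
  A
}

# Fill velocity/displacement/stationary-run entries for step `s` (the step
# from time s-1 to s) from the already-filled position rows.
update_arrays_step <- function(A, s) {
  dt <- A$dt
  vx <- (A$X[s, ] - A$X[s - 1, ]) / dt
  vy <- (A$Y[s, ] - A$Y[s - 1, ]) / dt
  vx[A$OUT[s, ]] <- 0
  vy[A$OUT[s, ]] <- 0
  A$VX[s, ] <- vx
  A$VY[s, ] <- vy
  d <- sqrt(vx^2 + vy^2) * dt
  A$D[s, ] <- d
  still <- d <= A$cfg$eps_move
  A$RUN[s, ] <- ifelse(still, A$RUN[s - 1, ] + 1L, 0L)
  A
}

# Feature block (N x 39 matrix) for prediction time index `t` (>= lags + 2).
features_for_time <- function(A, t) {
  cfg <- A$cfg
  L <- cfg$lags
  geom <- A$geom
  N <- A$N
  stopifnot(t >= L + 2)
  lag_rows <- t - seq_len(L)
  xl <- t(A$X[lag_rows, , drop = FALSE])
  yl <- t(A$Y[lag_rows, , drop = FALSE])
  vxl <- t(A$VX[lag_rows, , drop = FALSE])
  vyl <- t(A$VY[lag_rows, , drop = FALSE])

  s <- t - 1
  px <- A$X[s, ]; py <- A$Y[s, ]
  innest <- !A$OUT[s, ]
  still_s <- A$D[s, ] <= cfg$eps_move

  DXm <- matrix(px, N, N, byrow = TRUE) - px # [i, j] = x_j - x_i
  DYm <- matrix(py, N, N, byrow = TRUE) - py
  DIST <- sqrt(DXm^2 + DYm^2)
  valid <- matrix(innest, N, N, byrow = TRUE)
  diag(valid) <- FALSE
  DISTv <- DIST
  DISTv[!valid] <- Inf

  nn_j <- max.col(-DISTv, ties.method = "first")
  nn_dist <- DISTv[cbind(seq_len(N), nn_j)]
  none <- !is.finite(nn_dist)
  sentinel <- sqrt(geom$width^2 + geom$height^2)
  nn_x <- A$X[s, nn_j]; nn_y <- A$Y[s, nn_j]
  nn_vx <- A$VX[s, nn_j]; nn_vy <- A$VY[s, nn_j]
  nn_dist[none] <- sentinel
  nn_x[none] <- px[none]; nn_y[none] <- py[none]
  nn_vx[none] <- 0; nn_vy[none] <- 0

  qs <- cfg$quadrant_side
  q1 <- rowSums(valid & DXm >= 0 & DXm <= qs & DYm >= 0 & DYm <= qs)
  q2 <- rowSums(valid & DXm >= -qs & DXm < 0 & DYm >= 0 & DYm <= qs)
  q3 <- rowSums(valid & DXm >= -qs & DXm < 0 & DYm >= -qs & DYm < 0)
  q4 <- rowSums(valid & DXm >= 0 & DXm <= qs & DYm >= -qs & DYm < 0)

  stillm <- matrix(still_s, N, N, byrow = TRUE)
  n_still <- rowSums(valid & stillm & DIST <= cfg$r_still)
  n_moving <- rowSums(valid & !stillm & DIST <= cfg$r_moving)

  dist_queen <- if (is.na(A$qidx)) rep(NA_real_, N) else DIST[, A$qidx]
  if (!is.na(A$qidx)) dist_queen[A$qidx] <- 0

  wd <- wall_distances(px, py, geom)
  sc <- sub_chamber_of(px, py, geom)

  out <- cbind(xl, yl, vxl, vyl,
               A$RUN[s, ], A$D[s, ], sc,
               wd$wall_n, wd$wall_s, wd$wall_e, wd$wall_w,
               nn_dist, nn_x, nn_y, nn_vx, nn_vy,
               q1, q2, q3, q4, n_still, n_moving, dist_queen)
  colnames(out) <- ant_feature_names(L)
  out
}

#' Stationary time ending before a prediction time
#'
#' Length of the maximal run of consecutive zero-displacement steps ending at
#' step `t - 1` for a single-animal trajectory.
#'
#' @param track Single-animal tibble with columns `t`, `x`, `y` in time
#'   order.
#' @param t Prediction time index (position in the time sequence, `>= 2`).
#' @param eps_move Displacements `<= eps_move` count as stationary.
#' @return Integer count of consecutive stationary steps.
#' @export
stationary_time <- function(track, t, eps_move = 0) {
  track <- dplyr::arrange(tibble::as_tibble(track), .data$t)
  if (t < 2 || t > nrow(track)) {
    stop("t must index a time with at least one preceding step", call. = FALSE)
  }
  d <- sqrt(diff(track$x)^2 + diff(track$y)^2) # d[s] = step ending at s + 1
  run <- 0L
  s <- t - 1
  while (s >= 2 && d[s - 1] <= eps_move) {
    run <- run + 1L
    s <- s - 1
  }
  run
}

#' Derived variables for every ant at every usable time
#'
#' Computes the 39-variable feature vector (lagged positions and velocities,
#' stationary time, penultimate-step distance, sub-chamber, wall distances,
#' nearest-neighbour fields, quadrant counts, radius counts and distance to
#' the queen) for each animal at each prediction time with sufficient
#' history. Out-of-arena animals are represented at the exit point with zero
#' velocity and are excluded from neighbour pools.
#'
#' @param track A [colony_track()] with a complete (animal x time) grid.
#' @param geom A [nest_geometry()].
#' @param queen_id Identifier of the queen (for the distance-to-queen
#'   variable); `NULL` drops that column's information (filled `NA`).
#' @param lags Number of position/velocity lags (default 5).
#' @param eps_move Stationarity tolerance on step displacement.
#' @param r_still,r_moving Radii (mm) for the still/moving neighbour counts.
#' @param quadrant_side Side length (mm) of the four quadrant squares.
#' @return A tibble with `id`, `t`, the 39 feature columns and an `out_prev`
#'   flag marking rows whose focal animal was outside the arena at `t - 1`.
#' @export
derive_ant_features <- function(track, geom, queen_id = "Que", lags = 5,
                                eps_move = 0, r_still = 10, r_moving = 12,
                                quadrant_side = 8) {
  cfg <- feature_config(lags, eps_move, r_still, r_moving, quadrant_side)
  A <- build_track_arrays(track, geom, cfg, queen_id)
  T0 <- lags + 2
  if (A$T < T0) stop("track too short for ", lags, " lags", call. = FALSE)
  ts <- T0:A$T
  blocks <- vector("list", length(ts))
  for (k in seq_along(ts)) blocks[[k]] <- features_for_time(A, ts[k])
  feat <- do.call(rbind, blocks)
  # blocks are stacked time-major (all animals at t1, then t2, ...)
  out <- tibble::tibble(
    id = rep(A$ids, times = length(ts)),
    t = rep(A$times[ts], each = A$N)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(feat))
  out$out_prev <- as.vector(t(A$OUT[ts - 1, , drop = FALSE]))
  dplyr::arrange(out, .data$id, .data$t)
}

#' Neighbour-derived variables for one animal at one time
#'
#' Convenience wrapper returning the neighbourhood block of the feature
#' vector (nearest-neighbour distance/position/velocity, quadrant counts,
#' still/moving radius counts and distance to the queen) for a single focal
#' animal at one prediction time.
#'
#' @inheritParams derive_ant_features
#' @param animal Focal animal identifier.
#' @param t Prediction time (uses neighbour information at `t - 1`; must be
#'   at least the third time point so that stillness at `t - 1` is defined).
#' @return A one-row tibble of the neighbour features.
#' @export
neighbor_features <- function(track, animal, t, geom, queen_id = "Que",
                              eps_move = 0, r_still = 10, r_moving = 12,
                              quadrant_side = 8) {
  cfg <- feature_config(1, eps_move, r_still, r_moving, quadrant_side)
  A <- build_track_arrays(track, geom, cfg, queen_id)
  ti <- match(t, A$times)
  if (is.na(ti) || ti < 3) {
    stop("t must be at least the third time point of the track",
         call. = FALSE)
  }
  fm <- features_for_time(A, ti)
  i <- match(animal, A$ids)
  cols <- c("nn_dist", "nn_x", "nn_y", "nn_vx", "nn_vy",
            "q1", "q2", "q3", "q4", "n_still", "n_moving", "dist_queen")
  tibble::as_tibble(as.list(fm[i, cols]))
}

gull_feature_names <- function(lags) {
  c(paste0("x_l", seq_len(lags)), paste0("y_l", seq_len(lags)),
    paste0("vx_l", seq_len(lags)), paste0("vy_l", seq_len(lags)),
    "day_number", "time_of_day", "d_prev")
}

#' Days since 1 June of the bird-year and fractional time of day
#'
#' The bird-year epoch is the most recent 1 June (00:00 UTC) at or before the
#' timestamp.
#'
#' @param time POSIXct timestamps.
#' @return A tibble with integer `day_number` and `time_of_day` in `[0, 1)`.
#' @export
bird_year_clock <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  yr <- lt$year + 1900
  epoch_yr <- ifelse(lt$mon + 1 > 6 | (lt$mon + 1 == 6), yr, yr - 1)
  epoch <- as.POSIXct(paste0(epoch_yr, "-06-01 00:00:00"), tz = "UTC")
  dd <- as.numeric(difftime(time, epoch, units = "days"))
  tibble::tibble(
    day_number = floor(dd),
    time_of_day = dd - floor(dd)
  )
}

#' Derived variables for a migratory bird track
#'
#' Lagged planar positions and velocities up to `lags` lags, the bird-year
#' day number, fractional time of day and the penultimate-step distance.
#'
#' @param track Tibble for one bird-year with columns `id`, `t` (POSIXct,
#'   regular sampling), `x`, `y` (planar coordinates).
#' @param lags Number of lags (candidate values in the tuning study: 30, 40,
#'   50).
#' @return A tibble with `id`, `t` and the feature columns; rows with
#'   insufficient history are excluded.
#' @export
derive_gull_features <- function(track, lags = 50) {
  track <- dplyr::arrange(tibble::as_tibble(track), .data$id, .data$t)
  one_bird <- function(df) {
    T <- nrow(df)
    if (T < lags + 2) return(NULL)
    dt_s <- median(diff(as.numeric(df$t)))
    vx <- c(NA, diff(df$x) / dt_s)
    vy <- c(NA, diff(df$y) / dt_s)
    ts <- (lags + 2):T
    lag_mat <- function(v) {
      sapply(seq_len(lags), function(k) v[ts - k])
    }
    feat <- cbind(lag_mat(df$x), lag_mat(df$y), lag_mat(vx), lag_mat(vy))
    clock <- bird_year_clock(df$t[ts])
    d_prev <- sqrt((df$x[ts - 1] - df$x[ts - 2])^2 +
                     (df$y[ts - 1] - df$y[ts - 2])^2)
    feat <- cbind(feat, clock$day_number, clock$time_of_day, d_prev)
    colnames(feat) <- gull_feature_names(lags)
    dplyr::bind_cols(tibble::tibble(id = df$id[ts], t = df$t[ts]),
                     tibble::as_tibble(feat))
  }
  track |>
    dplyr::group_split(.data$id) |>
    purrr::map(one_bird) |>
    purrr::compact() |>
    dplyr::bind_rows()
}
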