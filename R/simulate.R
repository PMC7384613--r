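# Long-range stochastic rollout: each sampled step is fed back into feature
# computation, so simulations never touch held-out truth. Every raw sampled
# position is projected onto the nest boundary before it enters the next
# feature row, and replicate r uses a seed derived deterministically from
# (seed, r).

#' Simulate movement forward from an initial history
#'
#' Autoregressive rollout of a fitted model: at each step, features are
#' computed from the simulated history, the behavioural state is drawn from
#' the classifier's categorical output, and the velocity is drawn via the
#' learner's stochastic sampling rule (a sampled ensemble member or a Monte
#' Carlo dropout pass) or, for the SDE model, from the AR(2) transition.
#' Stationary animals keep their position exactly; animals leaving the nest
#' sit at the exit point.
#'
#' @param model A `framework_model` (ant or gull) or `sde_model`.
#' @param init Initial history: a [colony_track()] (ants) or an
#'   `id`/`t`/`x`/`y` tibble (gulls) at least as long as the model's lag
#'   depth plus one.
#' @param steps Number of steps to simulate ahead.
#' @param reps Number of independent replicates.
#' @param seed Integer seed; replicate sub-seeds are derived from it.
#' @return A `simulation_result` tibble with columns `rep`, `id`, `t`, `x`,
#'   `y`, `state` (`x`/`y` are `NA` while an ant is outside the nest).
#' @export
simulate_movement <- function(model, init, steps = 1000, reps = 100,
                              seed = 1) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  runs <- vector("list", reps)
  for (r in seq_len(reps)) {
    runs[[r]] <- dplyr::mutate(
      simulate_once(model, init, steps, sub_seeds[r]),
      rep = r, .before = 1
    )
  }
  out <- dplyr::bind_rows(runs)
  attr(out, "seed") <- seed
  attr(out, "sub_seeds") <- sub_seeds
  attr(out, "steps") <- steps
  attr(out, "model_class") <- class(model)[1]
  class(out) <- c("simulation_result", class(out))
  out
}

simulate_once <- function(model, init, steps, seed) {
  set.seed(seed)
  if (inherits(model, "sde_model")) {
    simulate_once_ant(model, init, steps, sde = TRUE)
  } else if (model$species == "ant") {
    simulate_once_ant(model, init, steps, sde = FALSE)
  } else {
    simulate_once_gull(model, init, steps)
  }
}

simulate_once_ant <- function(model, init, steps, sde = FALSE) {
  geom <- model$geom
  cfg <- model$cfg
  A <- build_track_arrays(init, geom, cfg, model$queen_id)
  T0 <- A$T
  if (T0 < cfg$lags + 2) {
    stop("initial history shorter than the model lag depth", call. = FALSE)
  }
  N <- A$N
  Ttot <- T0 + steps
  grow <- function(mat, fill) rbind(mat, matrix(fill, steps, N))
  A$X <- grow(A$X, NA_real_); A$Y <- grow(A$Y, NA_real_)
  A$OUT <- grow(A$OUT, FALSE)
  A$VX <- grow(A$VX, 0); A$VY <- grow(A$VY, 0)
  A$D <- grow(A$D, NA_real_); A$RUN <- grow(A$RUN, 0L)
  A$T <- Ttot
  dt_step <- A$times[2] - A$times[1]
  A$times <- c(A$times, A$times[T0] + dt_step * seq_len(steps))
  state_out <- matrix(NA_integer_, steps, N)
  lv <- if (sde) c(0L, 1L, 2L) else model$state_levels
  gf <- if (sde) gradient_field(model$surfaces) else NULL

  for (k in seq_len(steps)) {
    t <- T0 + k
    fmat <- features_for_time(A, t)
    if (sde) {
      probs <- predict(model$state_model, as.data.frame(fmat))
      probs <- align_prob_cols(probs, lv)
      state <- draw_states(probs, lv)
      stp <- ar2_core(model$surfaces, gf, model$beta,
                      A$X[t - 2, ], A$Y[t - 2, ], A$X[t - 1, ], A$Y[t - 1, ],
                      sample = TRUE)
      vx <- (stp$x - A$X[t - 1, ]) / A$dt
      vy <- (stp$y - A$Y[t - 1, ]) / A$dt
    } else if (model$level == "individual") {
      probs <- ml_sample(model$state_model, fmat)
      probs <- align_prob_cols(probs, lv)
      state <- draw_states(probs, lv)
      if (is.null(model$velocity_model)) {
        if (any(state == 2)) {
          stop("no velocity model available for state 2", call. = FALSE)
        }
        vx <- numeric(N); vy <- numeric(N)
      } else {
        vel <- ml_sample(model$velocity_model, fmat)
        vx <- vel[, 1]; vy <- vel[, 2]
      }
    } else {
      feats <- dplyr::bind_cols(
        tibble::tibble(id = A$ids, t = A$times[t]),
        tibble::as_tibble(fmat)
      )
      res <- colony_joint_predict(model, feats, fmat, mode = "sampled")
      state <- res$state; vx <- res$vx; vy <- res$vy
    }
    vx[state != 2] <- 0
    vy[state != 2] <- 0
    pos <- compose_ant_positions(A$X[t - 1, ], A$Y[t - 1, ], state, vx, vy,
                                 A$dt, geom)
    A$X[t, ] <- pos$x
    A$Y[t, ] <- pos$y
    A$OUT[t, ] <- state == 1
    A <- update_arrays_step(A, t)
    state_out[k, ] <- state
  }

  ts <- (T0 + 1):Ttot
  x <- A$X[ts, , drop = FALSE]; y <- A$Y[ts, , drop = FALSE]
  x[A$OUT[ts, , drop = FALSE]] <- NA_real_
  y[A$OUT[ts, , drop = FALSE]] <- NA_real_
  tibble::tibble(
    id = rep(A$ids, each = steps),
    t = rep(A$times[ts], times = N),
    x = as.vector(x), y = as.vector(y),
    state = as.vector(state_out)
  )
}

simulate_once_gull <- function(model, init, steps) {
  lags <- model$lags
  buf <- dplyr::arrange(tibble::as_tibble(init), .data$t)
  if (nrow(buf) < lags + 2) {
    stop("initial history shorter than the model lag depth", call. = FALSE)
  }
  dt_s <- model$dt
  lv <- model$state_levels
  out <- vector("list", steps)
  for (k in seq_len(steps)) {
    tail_buf <- utils::tail(buf, lags + 2)
    t_new <- tail_buf$t[nrow(tail_buf)] + dt_s
    probe <- dplyr::bind_rows(
      tail_buf,
      tibble::tibble(id = tail_buf$id[1], t = t_new, x = NA_real_,
                     y = NA_real_)
    )
    feats <- derive_gull_features(probe, lags)
    feats <- feats[nrow(feats), , drop = FALSE]
    fmat <- as.matrix(dplyr::select(feats, -dplyr::any_of(c("id", "t"))))
    probs <- align_prob_cols(ml_sample(model$state_model, fmat), lv)
    state <- draw_states(probs, lv)
    vm <- model$velocity_models[[as.character(state)]]
    if (is.null(vm)) stop("no velocity model for state ", state, call. = FALSE)
    vel <- ml_sample(vm, fmat)
    new_row <- tibble::tibble(
      id = tail_buf$id[1], t = t_new,
      x = tail_buf$x[nrow(tail_buf)] + vel[1, 1] * dt_s,
      y = tail_buf$y[nrow(tail_buf)] + vel[1, 2] * dt_s
    )
    out[[k]] <- dplyr::mutate(new_row, state = state)
    buf <- dplyr::bind_rows(buf, new_row)
  }
  dplyr::bind_rows(out)
}
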