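# The two-step movement framework: a behavioural-state classifier plus
# per-state velocity models, composed into next-position predictions.
#
# Ants (states 0 stationary / 1 out of nest / 2 moving) have two special
# states with deterministic kinematics: state 0 forces zero displacement and
# state 1 forces the position to the nest exit with velocity
# (exit_x - x_{t-1}, exit_y - y_{t-1}). Only state-2 movement is learned.
# Gulls (states 1-4) carry one learned velocity model per state.
#
# At the colony level a single joint model emits states for all animals from
# the concatenated feature vector U_{t-1}, a single joint velocity model
# emits a 2N-dimensional velocity vector, and the state output zeroes or
# overrides velocities of animals classified as stationary or outside.

#' Deterministic exit velocity
#'
#' Velocity assigned to an animal that leaves the arena: the displacement
#' taking it from its last observed position to the exit point in one step.
#'
#' @param x_prev,y_prev Previous position.
#' @param exit Exit point `c(x, y)`.
#' @return A tibble with columns `vx`, `vy`.
#' @export
exit_velocity <- function(x_prev, y_prev, exit) {
  tibble::tibble(vx = exit[1] - x_prev, vy = exit[2] - y_prev)
}

# Velocity responses (filled-position first differences, so stationary rows
# are zero and exit rows equal the deterministic exit velocity).
response_velocities <- function(A, ts) {
  dt <- A$dt
  rvx <- (A$X[ts, , drop = FALSE] - A$X[ts - 1, , drop = FALSE]) / dt
  rvy <- (A$Y[ts, , drop = FALSE] - A$Y[ts - 1, , drop = FALSE]) / dt
  list(vx = rvx, vy = rvy)
}

#' Fit the two-step framework to an ant colony
#'
#' Fits a state classifier on the derived features at `t - 1` (target: the
#' state at `t`) and a bivariate velocity model. At the individual level with
#' non-recurrent learners the velocity model is trained only on movements
#' that resulted in the animal moving (state 2); recurrent and colony-level
#' velocity models are trained on all rows, with the state output used to
#' zero out velocities at prediction time.
#'
#' @param track A [colony_track()].
#' @param states Output of [label_ant_states()] (or ground-truth states).
#' @param geom A [nest_geometry()].
#' @param level `"individual"` (one model applied to each animal) or
#'   `"colony"` (one joint model over all animals).
#' @param state_learner,velocity_learner Learner specifications
#'   ([learner_rf()], [learner_mvrf()], [learner_mlp()]).
#' @param queen_id Queen identifier for the distance-to-queen feature.
#' @param lags,eps_move Feature settings (see [derive_ant_features()]).
#' @param pca_components Number of principal components for colony-level
#'   network inputs (`NULL` = no reduction; ignored for tree learners).
#' @param seed Integer seed controlling all fitting randomness.
#' @return A `framework_model`.
#' @export
fit_framework <- function(track, states, geom,
                          level = c("individual", "colony"),
                          state_learner = learner_rf(),
                          velocity_learner = learner_rf(),
                          queen_id = "Que", lags = 5, eps_move = 0,
                          pca_components = NULL, seed = 1) {
  level <- match.arg(level)
  cfg <- feature_config(lags = lags, eps_move = eps_move)
  A <- build_track_arrays(track, geom, cfg, queen_id)
  T0 <- lags + 2
  ts <- T0:A$T
  feats <- derive_ant_features(track, geom, queen_id, lags, eps_move)
  st <- dplyr::arrange(states, .data$id, .data$t)

  # align states with feature rows (feature at time t predicts state at t)
  key <- dplyr::left_join(
    dplyr::select(feats, "id", "t"),
    st, by = c("id", "t")
  )
  if (anyNA(key$state)) stop("states missing for some feature rows",
                             call. = FALSE)
  fmat <- as.matrix(dplyr::select(feats, -dplyr::any_of(c("id", "t", "out_prev"))))
  rv <- response_velocities(A, ts)

  recurrent <- inherits(velocity_learner, "learner_mlp") &&
    isTRUE(velocity_learner$recurrent)

  if (level == "individual") {
    state_model <- ml_fit(state_learner, fmat, factor(key$state),
                          task = "class", seed = seed,
                          seq_id = key$id)
    # velocity responses in feature-row order (id-major)
    v_resp <- cbind(as.vector(rv$vx), as.vector(rv$vy))
    if (recurrent) {
      vel_rows <- rep(TRUE, nrow(fmat))
    } else {
      vel_rows <- key$state == 2
    }
    velocity_model <- if (any(vel_rows)) {
      ml_fit(velocity_learner, fmat[vel_rows, , drop = FALSE],
             v_resp[vel_rows, , drop = FALSE],
             task = "mvreg", seed = seed + 1,
             seq_id = key$id[vel_rows])
    } else {
      NULL # no moving steps observed; prediction into state 2 will error
    }
    pca <- NULL
  } else {
    # colony: one row per time, concatenating animals in roster order
    N <- A$N
    n_t <- length(ts)
    U <- matrix(0, n_t, N * ncol(fmat))
    for (i in seq_len(N)) {
      rows <- ((i - 1) * n_t + 1):(i * n_t)
      U[, ((i - 1) * ncol(fmat) + 1):(i * ncol(fmat))] <- fmat[rows, ]
    }
    colnames(U) <- paste0(rep(A$ids, each = ncol(fmat)), ".",
                          rep(colnames(fmat), times = N))
    Mt <- matrix(key$state, nrow = n_t) # columns = animals (id-major stack)
    Vt <- matrix(0, n_t, 2 * N)
    Vt[, seq(1, 2 * N, by = 2)] <- rv$vx
    Vt[, seq(2, 2 * N, by = 2)] <- rv$vy

    use_pca <- inherits(state_learner, "learner_mlp") ||
      inherits(velocity_learner, "learner_mlp")
    pca <- NULL
    Ux <- U
    if (use_pca) {
      k <- pca_components %||% min(1000, ncol(U), nrow(U) - 1)
      pca <- pca_reduce(U, k)
      Ux <- predict(pca, U)
      colnames(Ux) <- paste0("PC", seq_len(ncol(Ux)))
    }
    Ustate <- if (inherits(state_learner, "learner_mlp")) Ux else U
    Uvel <- if (inherits(velocity_learner, "learner_mlp")) Ux else U
    state_model <- ml_fit(state_learner, Ustate, Mt, task = "mvclass",
                          seed = seed)
    velocity_model <- ml_fit(velocity_learner, Uvel, Vt, task = "mvreg",
                             seed = seed + 1)
  }

  structure(
    list(species = "ant", level = level, state_model = state_model,
         velocity_model = velocity_model, pca = pca, geom = geom,
         exit = geom$exit, ids = A$ids, queen_id = queen_id,
         cfg = cfg, dt = A$dt, seed = seed,
         state_levels = c(0L, 1L, 2L)),
    class = "framework_model"
  )
}

#' Fit the two-step framework to migratory bird tracks
#'
#' One 4-state classifier plus four per-state velocity models, each trained
#' on the rows whose target state is the modelled state.
#'
#' @param track Tibble of one or more bird-years: `id`, `t` (POSIXct,
#'   regular), `x`, `y` (planar coordinates, e.g. UTM km).
#' @param states Tibble `id`, `t`, `state` with states 1-4.
#' @param lags Number of feature lags.
#' @param state_learner,velocity_learner Learner specifications
#'   (non-recurrent).
#' @param seed Integer seed.
#' @return A `framework_model` (species `"gull"`).
#' @export
fit_gull_framework <- function(track, states, lags = 50,
                               state_learner = learner_rf(),
                               velocity_learner = learner_rf(), seed = 1) {
  recurrent <- function(sp) inherits(sp, "learner_mlp") && isTRUE(sp$recurrent)
  if (recurrent(state_learner) || recurrent(velocity_learner)) {
    stop("recurrent learners are not supported for per-state bird models; ",
         "use a dense or forest learner", call. = FALSE)
  }
  feats <- derive_gull_features(track, lags)
  st <- dplyr::left_join(dplyr::select(feats, "id", "t"), states,
                         by = c("id", "t"))
  if (anyNA(st$state)) stop("states missing for some feature rows",
                            call. = FALSE)
  fmat <- as.matrix(dplyr::select(feats, -dplyr::any_of(c("id", "t"))))
  track <- dplyr::arrange(tibble::as_tibble(track), .data$id, .data$t)
  pos <- dplyr::left_join(
    dplyr::select(feats, "id", "t"),
    track, by = c("id", "t")
  )
  prev <- dplyr::left_join(
    dplyr::mutate(dplyr::select(feats, "id", "t"), t = .data$t),
    dplyr::transmute(track, id = .data$id,
                     t = dplyr::lead(.data$t), x_prev = .data$x,
                     y_prev = .data$y),
    by = c("id", "t")
  )
  dt_s <- median(diff(as.numeric(track$t[track$id == track$id[1]])))
  v_resp <- cbind((pos$x - prev$x_prev) / dt_s, (pos$y - prev$y_prev) / dt_s)

  state_model <- ml_fit(state_learner, fmat, factor(st$state), task = "class",
                        seed = seed)
  vel_models <- lapply(sort(unique(st$state)), function(k) {
    rows <- st$state == k
    if (!any(rows)) return(NULL)
    ml_fit(velocity_learner, fmat[rows, , drop = FALSE],
           v_resp[rows, , drop = FALSE], task = "mvreg", seed = seed + k)
  })
  names(vel_models) <- as.character(sort(unique(st$state)))

  structure(
    list(species = "gull", level = "individual", state_model = state_model,
         velocity_models = vel_models, lags = lags, dt = dt_s, seed = seed,
         state_levels = sort(unique(st$state))),
    class = "framework_model"
  )
}

#' @export
print.framework_model <- function(x, ...) {
  cat(sprintf("<framework_model> species %s, level %s, states {%s}\n",
              x$species, x$level,
              paste(x$state_levels, collapse = ", ")))
  invisible(x)
}

# Compose next positions from previous positions, state draws and velocities
# (ant rules: 0 freeze, 1 exit, 2 move + boundary projection).
compose_ant_positions <- function(x_prev, y_prev, state, vx, vy, dt, geom) {
  x_new <- x_prev + vx * dt
  y_new <- y_prev + vy * dt
  proj <- project_to_boundary(pmin(pmax(x_new, -geom$width), 2 * geom$width),
                              pmin(pmax(y_new, -geom$height), 2 * geom$height),
                              geom)
  x_new <- proj$x; y_new <- proj$y
  x_new[state == 0] <- x_prev[state == 0]
  y_new[state == 0] <- y_prev[state == 0]
  x_new[state == 1] <- geom$exit[1]
  y_new[state == 1] <- geom$exit[2]
  tibble::tibble(x = x_new, y = y_new)
}

draw_states <- function(probs, levels) {
  # probs: n x K matrix; one categorical draw per row
  u <- stats::runif(nrow(probs))
  cum <- t(apply(probs, 1, cumsum))
  idx <- rowSums(u > cum) + 1
  idx <- pmin(idx, length(levels))
  levels[idx]
}

#' One-step-ahead prediction from a fitted framework model
#'
#' Computes derived features at `t - 1` and predicts states and positions at
#' `t`. `mode = "expected"` (the evaluation path) uses the most probable
#' state and the mean velocity; `mode = "sampled"` (the simulation path)
#' draws the state from the classifier's categorical output and the velocity
#' from the learner's stochastic sampling rule. Ant rules: state 0 keeps the
#' previous position exactly, state 1 places the animal at the exit point,
#' state 2 adds the (projected) velocity displacement.
#'
#' @param model A `framework_model`.
#' @param track Track providing the observed history (a [colony_track()] for
#'   ants; an `id`/`t`/`x`/`y` tibble for gulls).
#' @param times Time values at which to predict (default: every time with
#'   sufficient history).
#' @param mode `"expected"` or `"sampled"`.
#' @param seed Optional seed for the sampled path.
#' @return A tibble `id`, `t`, per-state probability columns `p_<state>`,
#'   `state`, `vx`, `vy`, `x`, `y`.
#' @export
predict_one_step <- function(model, track, times = NULL,
                             mode = c("expected", "sampled"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (model$species == "ant") {
    predict_one_step_ant(model, track, times, mode)
  } else {
    predict_one_step_gull(model, track, times, mode)
  }
}

predict_one_step_ant <- function(model, track, times, mode) {
  geom <- model$geom
  feats <- derive_ant_features(track, geom, model$queen_id,
                               model$cfg$lags, model$cfg$eps_move)
  if (!is.null(times)) feats <- dplyr::filter(feats, .data$t %in% times)
  A <- build_track_arrays(track, geom, model$cfg, model$queen_id)
  idx_t <- match(feats$t, A$times)
  idx_i <- match(feats$id, A$ids)
  x_prev <- A$X[cbind(idx_t - 1, idx_i)]
  y_prev <- A$Y[cbind(idx_t - 1, idx_i)]
  fmat <- as.matrix(dplyr::select(feats, -dplyr::any_of(c("id", "t", "out_prev"))))
  dt <- model$dt
  lv <- model$state_levels

  if (model$level == "individual") {
    probs <- if (mode == "expected") ml_predict(model$state_model, fmat) else
      ml_sample(model$state_model, fmat)
    probs <- align_prob_cols(probs, lv)
    state <- if (mode == "expected") {
      lv[max.col(probs, ties.method = "first")]
    } else {
      draw_states(probs, lv)
    }
    if (is.null(model$velocity_model)) {
      if (any(state == 2)) {
        stop("no velocity model available for state 2", call. = FALSE)
      }
      vx <- numeric(length(state)); vy <- numeric(length(state))
    } else {
      vel <- if (mode == "expected") {
        ml_predict(model$velocity_model, fmat)
      } else {
        ml_sample(model$velocity_model, fmat)
      }
      vx <- vel[, 1]; vy <- vel[, 2]
    }
  } else {
    # colony: rebuild U rows (time-major) then scatter back to feature rows
    res <- colony_joint_predict(model, feats, fmat, mode)
    probs <- res$probs; state <- res$state; vx <- res$vx; vy <- res$vy
  }
  vx[state != 2] <- 0
  vy[state != 2] <- 0
  ev <- exit_velocity(x_prev, y_prev, model$exit)
  vx[state == 1] <- ev$vx[state == 1] / dt
  vy[state == 1] <- ev$vy[state == 1] / dt
  pos <- compose_ant_positions(x_prev, y_prev, state, vx, vy, dt, geom)
  out <- tibble::tibble(id = feats$id, t = feats$t)
  for (k in seq_along(lv)) out[[paste0("p_", lv[k])]] <- probs[, k]
  out$state <- state
  out$vx <- vx; out$vy <- vy
  out$x <- pos$x; out$y <- pos$y
  out
}

align_prob_cols <- function(probs, levels) {
  want <- as.character(levels)
  have <- colnames(probs)
  out <- matrix(0, nrow(probs), length(want), dimnames = list(NULL, want))
  for (k in want) if (k %in% have) out[, k] <- probs[, k]
  out
}

colony_joint_predict <- function(model, feats, fmat, mode) {
  ids <- model$ids
  N <- length(ids)
  lv <- model$state_levels
  t_vals <- sort(unique(feats$t))
  n_t <- length(t_vals)
  p <- ncol(fmat)
  U <- matrix(0, n_t, N * p)
  # feats rows are (id-major); place each into U
  for (r in seq_len(nrow(fmat))) {
    i <- match(feats$id[r], ids)
    tt <- match(feats$t[r], t_vals)
    U[tt, ((i - 1) * p + 1):(i * p)] <- fmat[r, ]
  }
  Ustate <- if (inherits(model$state_model$spec, "learner_mlp") &&
                !is.null(model$pca)) {
    z <- predict(model$pca, U); colnames(z) <- paste0("PC", seq_len(ncol(z))); z
  } else U
  Uvel <- if (inherits(model$velocity_model$spec, "learner_mlp") &&
              !is.null(model$pca)) {
    z <- predict(model$pca, U); colnames(z) <- paste0("PC", seq_len(ncol(z))); z
  } else U
  colnames(Ustate) <- model$state_model$feature_names
  colnames(Uvel) <- model$velocity_model$feature_names

  parr <- if (mode == "expected") ml_predict(model$state_model, Ustate) else
    ml_sample(model$state_model, Ustate) # n_t x N x K
  vmat <- if (mode == "expected") ml_predict(model$velocity_model, Uvel) else
    ml_sample(model$velocity_model, Uvel) # n_t x 2N

  # scatter back to feature-row order
  n_rows <- nrow(fmat)
  probs <- matrix(0, n_rows, length(lv), dimnames = list(NULL, lv))
  state <- integer(n_rows)
  vx <- numeric(n_rows); vy <- numeric(n_rows)
  for (r in seq_len(n_rows)) {
    i <- match(feats$id[r], ids)
    tt <- match(feats$t[r], t_vals)
    pk <- parr[tt, i, ]
    pk <- pk[as.character(lv)]
    pk[is.na(pk)] <- 0
    probs[r, ] <- pk
    state[r] <- if (mode == "expected") {
      lv[which.max(pk)]
    } else {
      draw_states(matrix(pk, 1), lv)
    }
    vx[r] <- vmat[tt, 2 * i - 1]
    vy[r] <- vmat[tt, 2 * i]
  }
  list(probs = probs, state = state, vx = vx, vy = vy)
}

predict_one_step_gull <- function(model, track, times, mode) {
  feats <- derive_gull_features(track, model$lags)
  if (!is.null(times)) feats <- dplyr::filter(feats, .data$t %in% times)
  fmat <- as.matrix(dplyr::select(feats, -dplyr::any_of(c("id", "t"))))
  lv <- model$state_levels
  probs <- if (mode == "expected") ml_predict(model$state_model, fmat) else
    ml_sample(model$state_model, fmat)
  probs <- align_prob_cols(probs, lv)
  state <- if (mode == "expected") {
    lv[max.col(probs, ties.method = "first")]
  } else {
    draw_states(probs, lv)
  }
  vx <- numeric(nrow(fmat)); vy <- numeric(nrow(fmat))
  for (k in lv) {
    rows <- state == k
    if (!any(rows)) next
    vm <- model$velocity_models[[as.character(k)]]
    if (is.null(vm)) {
      stop("no velocity model available for state ", k, call. = FALSE)
    }
    vel <- if (mode == "expected") {
      ml_predict(vm, fmat[rows, , drop = FALSE])
    } else {
      ml_sample(vm, fmat[rows, , drop = FALSE])
    }
    vx[rows] <- vel[, 1]; vy[rows] <- vel[, 2]
  }
  x_prev <- feats$x_l1
  y_prev <- feats$y_l1
  out <- tibble::tibble(id = feats$id, t = feats$t)
  for (k in seq_along(lv)) out[[paste0("p_", lv[k])]] <- probs[, k]
  out$state <- state
  out$vx <- vx; out$vy <- vy
  out$x <- x_prev + vx * model$dt
  out$y <- y_prev + vy * model$dt
  out
}
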