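# Seeded fixture generators. The ant generator produces a colony whose
# statistical structure matches what the framework assumes: a sticky 3-state
# behavioural chain whose occupancy matches the 76% stationary / 22% moving /
# 2% out decomposition observed in real carpenter-ant colonies, with
# within-nest movement driven by a known AR(2) (SDE) truth. The gull
# generator produces an annual track cycling through the four migratory
# states with drifts strong enough that the threshold labelling rules can
# recover the true states.

#' Behavioural-state transition matrix with a prescribed occupancy
#'
#' Builds a 3-state Markov transition matrix (states 0 stationary, 1 out of
#' nest, 2 moving) whose stationary distribution equals `occupancy`, given
#' chosen self-transition (dwell) probabilities for the stationary and
#' out-of-nest states; the remaining rates follow from the balance
#' equations.
#'
#' @param occupancy Target long-run fractions (stationary, out, moving).
#' @param stay_stationary,stay_out Self-transition probabilities.
#' @param stationary_to_out,out_to_stationary Small cross rates.
#' @return A 3x3 row-stochastic matrix.
#' @export
ant_transition_matrix <- function(occupancy = c(0.76, 0.02, 0.22),
                                  stay_stationary = 0.96, stay_out = 0.98,
                                  stationary_to_out = 4e-4,
                                  out_to_stationary = 0.01) {
  stopifnot(abs(sum(occupancy) - 1) < 1e-9)
  p <- occupancy
  a01 <- stationary_to_out
  a02 <- 1 - stay_stationary - a01
  a10 <- out_to_stationary
  a12 <- 1 - stay_out - a10
  a21 <- (p[2] * (1 - stay_out) - p[1] * a01) / p[3]
  a20 <- (p[1] * (1 - stay_stationary) - p[2] * a10) / p[3]
  a22 <- 1 - a20 - a21
  P <- matrix(c(stay_stationary, a01, a02,
                a10, stay_out, a12,
                a20, a21, a22), 3, 3, byrow = TRUE,
              dimnames = list(0:2, 0:2))
  if (any(P < 0)) stop("infeasible transition construction", call. = FALSE)
  P
}

#' Generate a synthetic ant colony
#'
#' States evolve per animal as a Markov chain; moving steps follow the AR(2)
#' movement model under the configured motility/potential truth with
#' boundary projection, stationary steps freeze the position, and
#' out-of-nest steps hold the animal at the exit (recorded as missing
#' coordinates). Re-entry resumes just inside the exit.
#'
#' @param n_animals Number of animals (the first is the queen, id `"Que"`).
#' @param steps Number of time steps (1 Hz).
#' @param geom A [nest_geometry()].
#' @param transition 3x3 state transition matrix.
#' @param beta Friction coefficient of the movement truth.
#' @param motility Constant motility (mm), or a [grid_surfaces()] carrying
#'   `m` (and `h`).
#' @param potential_scale Height of the quadratic potential bowl centred on
#'   the nest (0 = flat potential).
#' @param seed Integer seed.
#' @return A list of class `ant_sim`: `track` (a [colony_track()] with `NA`
#'   coordinates while out of the nest), `states` (truth states for `t >=
#'   2`), and `truth` (generator parameters, including the surfaces).
#' @export
generate_ant_colony <- function(n_animals = 20, steps = 10000,
                                geom = nest_geometry(),
                                transition = ant_transition_matrix(),
                                beta = 0.5, motility = 0.8,
                                potential_scale = 1, seed = 1) {
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-9), beta > 0, beta <= 1)
  set.seed(seed)
  N <- n_animals
  T <- steps
  ids <- c("Que", sprintf("A%02d", seq_len(max(N - 1, 0))))[seq_len(N)]

  if (inherits(motility, "grid_surfaces")) {
    surf <- motility
  } else {
    surf <- grid_surfaces(geom, cell_size = 5, m = motility)
    if (potential_scale > 0) {
      cc <- cell_centres(surf)
      r2 <- (cc$x - geom$width / 2)^2 + (cc$y - geom$height / 2)^2
      surf$h <- potential_scale * r2 / max(r2)
    }
  }

  occupancy <- Re(eigen(t(transition))$vectors[, 1])
  occupancy <- occupancy / sum(occupancy)
  gf <- gradient_field(surf)

  X <- matrix(NA_real_, T, N)
  Y <- matrix(NA_real_, T, N)
  S <- matrix(NA_integer_, T, N) # truth state of the step ending at t
  x_int <- matrix(NA_real_, T, N) # internal positions (exit while out)
  y_int <- matrix(NA_real_, T, N)

  x_int[1, ] <- stats::runif(N, 0.05 * geom$width, 0.95 * geom$width)
  y_int[1, ] <- stats::runif(N, 0.05 * geom$height, 0.95 * geom$height)
  x_int[2, ] <- x_int[1, ]
  y_int[2, ] <- y_int[1, ]
  s_prev <- apply(stats::rmultinom(N, 1, occupancy), 2, which.max) - 1L
  S[2, ] <- s_prev
  out_now <- s_prev == 1L
  x_int[1, out_now] <- geom$exit[1]; y_int[1, out_now] <- geom$exit[2]
  x_int[2, out_now] <- geom$exit[1]; y_int[2, out_now] <- geom$exit[2]

  for (t in 3:T) {
    u <- stats::runif(N)
    cum <- transition[s_prev + 1L, , drop = FALSE]
    cum <- t(apply(cum, 1, cumsum))
    s_new <- rowSums(u > cum) + 0L
    s_new <- pmin(s_new, 2L)

    x_new <- x_int[t - 1, ]
    y_new <- y_int[t - 1, ]
    move <- s_new == 2L
    if (any(move)) {
      reenter <- move & (s_prev == 1L)
      roam <- move & !reenter
      if (any(roam)) {
        stp <- ar2_core(surf, gf, beta,
                        x_int[t - 2, roam], y_int[t - 2, roam],
                        x_int[t - 1, roam], y_int[t - 1, roam],
                        sample = TRUE)
        x_new[roam] <- pmin(pmax(stp$x, 0), geom$width)
        y_new[roam] <- pmin(pmax(stp$y, 0), geom$height)
      }
      if (any(reenter)) {
        k <- sum(reenter)
        x_new[reenter] <- geom$exit[1] -
          stats::runif(k, 0.5, 3)
        y_new[reenter] <- geom$exit[2] + stats::runif(k, 0.5, 3)
        proj <- project_to_boundary(x_new[reenter], y_new[reenter], geom)
        x_new[reenter] <- proj$x; y_new[reenter] <- proj$y
      }
    }
    x_new[s_new == 1L] <- geom$exit[1]
    y_new[s_new == 1L] <- geom$exit[2]
    x_int[t, ] <- x_new
    y_int[t, ] <- y_new
    S[t, ] <- s_new
    s_prev <- s_new
  }

  X <- x_int; Y <- y_int
  out_mask <- S == 1L
  out_mask[1, ] <- out_mask[2, ] # t = 1 inherits the initial state
  X[out_mask] <- NA_real_
  Y[out_mask] <- NA_real_

  track <- colony_track(tibble::tibble(
    id = rep(ids, each = T),
    t = rep(seq_len(T), times = N),
    x = as.vector(X), y = as.vector(Y)
  ), dt = 1)
  states <- tibble::tibble(
    id = rep(ids, each = T - 1),
    t = rep(2:T, times = N),
    state = as.integer(S[-1, ][cbind(rep(seq_len(T - 1), times = N),
                                     rep(seq_len(N), each = T - 1))])
  )
  structure(
    list(track = track, states = states,
         truth = list(transition = transition, occupancy = occupancy,
                      beta = beta, surfaces = surf, seed = seed)),
    class = "ant_sim"
  )
}

#' Generate a synthetic gull bird-year
#'
#' One annual track starting in the Northern range on 1 June, migrating
#' south after `dwell_north` days at `drift_south` degrees latitude per 10
#' hours for `dwell_south_leg` days, residing in the Southern range, then
#' returning north, with small within-state positional noise.
#'
#' @param id Bird-year identifier.
#' @param start Start date (1 June of the bird-year).
#' @param interval_min Sampling interval in minutes.
#' @param dwell_north,dwell_south_leg,dwell_south,dwell_north_leg Phase
#'   durations in days (any remaining days of the year are Northern range).
#' @param drift_south,drift_north Migration drifts in degrees latitude per
#'   10 hours (southbound negative).
#' @param noise_lat,noise_lon Within-state noise standard deviations
#'   (degrees).
#' @param start_lat,start_lon Northern-range centre.
#' @param seed Integer seed.
#' @return A list of class `gull_sim`: `track` (`id`, `t`, `lat`, `lon`) and
#'   `states` (truth states 1-4 per record).
#' @export
generate_gull_year <- function(id = "gull1", start = "2010-06-01",
                               interval_min = 25, dwell_north = 120,
                               dwell_south_leg = 8, dwell_south = 180,
                               dwell_north_leg = 8, drift_south = -1.2,
                               drift_north = 1.2, noise_lat = 0.02,
                               noise_lon = 0.05, start_lat = 60,
                               start_lon = 5, seed = 1) {
  stopifnot(drift_south < 0, drift_north > 0)
  set.seed(seed)
  per_day <- 24 * 60 / interval_min
  n_phase <- round(per_day * c(dwell_north, dwell_south_leg, dwell_south,
                               dwell_north_leg))
  n_rest <- max(0, round(per_day * 365) - sum(n_phase))
  states <- rep(c(1L, 2L, 3L, 4L, 1L), c(n_phase, n_rest))
  T <- length(states)
  step_h <- interval_min / 60
  drift_per_step <- c(0, drift_south * step_h / 10, 0,
                      drift_north * step_h / 10)
  dlat <- drift_per_step[states]
  lat <- start_lat + cumsum(dlat) + stats::rnorm(T, 0, noise_lat)
  lon <- start_lon + cumsum(stats::rnorm(T, 0, noise_lon / 10)) +
    stats::rnorm(T, 0, noise_lon)
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  tt <- t0 + (seq_len(T) - 1) * interval_min * 60
  structure(
    list(
      track = tibble::tibble(id = id, t = tt, lat = lat, lon = lon),
      states = tibble::tibble(id = id, t = tt, state = states),
      truth = list(drift_south = drift_south, drift_north = drift_north,
                   interval_min = interval_min, seed = seed)
    ),
    class = "gull_sim"
  )
}
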