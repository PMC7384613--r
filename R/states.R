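# Behavioural-state labelling.
#
# States are assumed observable from the position data: at high temporal
# resolution an ant is visibly stationary, moving, or absent from the nest,
# and a migrating bird's range residency versus directed migration is evident
# from latitude displacement. No hidden-state inference is attempted.

#' Label ant behavioural states from a colony track
#'
#' State alphabet: `0` stationary within the nest, `1` outside the nest, `2`
#' moving within the nest. A record flagged absent is state 1 (including the
#' step in which the ant leaves); a present record whose step displacement is
#' at most `eps_move` is state 0; anything else is state 2. The first time
#' point has no preceding step and receives no state.
#'
#' @param track A [colony_track()].
#' @param geom A [nest_geometry()] (supplies the exit point used as the
#'   position of absent animals when computing re-entry displacements).
#' @param eps_move Stationarity tolerance on step displacement (default 0:
#'   repeated identical coordinates count as stationary).
#' @return A tibble `id`, `t`, `state` for all time points after the first.
#' @export
label_ant_states <- function(track, geom, eps_move = 0) {
  A <- build_track_arrays(track, geom, feature_config(eps_move = eps_move))
  ts <- 2:A$T
  state <- matrix(2L, length(ts), A$N)
  still <- A$D[ts, , drop = FALSE] <= eps_move
  state[still] <- 0L
  state[A$OUT[ts, , drop = FALSE]] <- 1L
  tibble::tibble(
    id = rep(A$ids, each = length(ts)),
    t = rep(A$times[ts], times = A$N),
    state = as.integer(state[cbind(
      rep(seq_along(ts), times = A$N),
      rep(seq_len(A$N), each = length(ts))
    )])
  )
}

#' Configuration for the gull migratory-state rule
#'
#' @param south_threshold Degrees latitude that must be covered southbound
#'   within the window to enter (and sustain) Southbound migration.
#' @param north_threshold Degrees latitude northbound for Northbound
#'   migration.
#' @param window_hours Trailing window length in hours.
#' @param stopover_hours Minimum duration of a failing run inside a migration
#'   leg to count as a stopover (reassigned to a range state) rather than a
#'   momentary lull.
#' @return A list of class `gull_state_rules`.
#' @export
gull_state_rules <- function(south_threshold = 0.91, north_threshold = 1.0,
                             window_hours = 10, stopover_hours = 12) {
  stopifnot(south_threshold > 0, north_threshold > 0, window_hours > 0)
  structure(list(south_threshold = south_threshold,
                 north_threshold = north_threshold,
                 window_hours = window_hours,
                 stopover_hours = stopover_hours),
            class = "gull_state_rules")
}

# Merge TRUE-runs of `cond` separated by gaps shorter than `gap_max` samples.
# Returns a list of (start, end) index pairs for the merged legs.
merge_legs <- function(cond, gap_max) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  legs <- cbind(starts[r$values], ends[r$values])
  if (nrow(legs) == 0) return(legs)
  merged <- legs[1, , drop = FALSE]
  if (nrow(legs) > 1) {
    for (k in 2:nrow(legs)) {
      gap <- legs[k, 1] - merged[nrow(merged), 2] - 1
      if (gap < gap_max) {
        merged[nrow(merged), 2] <- legs[k, 2]
      } else {
        merged <- rbind(merged, legs[k, ])
      }
    }
  }
  merged
}

#' Label migratory states for one bird-year
#'
#' State alphabet: `1` Northern range, `2` Southbound migration, `3` Southern
#' range, `4` Northbound migration. A bird enters Southbound migration when
#' its track covers more than `south_threshold` degrees latitude southward
#' over the trailing window, and stays there while the condition holds;
#' symmetrically for Northbound migration with `north_threshold`. Failing
#' runs shorter than `stopover_hours` inside a migration leg stay in the
#' migration state; longer interruptions (stopovers) and all residency
#' periods are assigned to the Northern or Southern range by whichever of the
#' year's farthest-North / farthest-South observed latitudes is closer.
#'
#' @param track Tibble for one bird-year: columns `t` (POSIXct, regular
#'   sampling after interpolation), `lat`, `lon`.
#' @param rules A [gull_state_rules()].
#' @return A tibble `t`, `state`.
#' @export
label_gull_states <- function(track, rules = gull_state_rules()) {
  track <- dplyr::arrange(tibble::as_tibble(track), .data$t)
  T <- nrow(track)
  dt_h <- median(diff(as.numeric(track$t))) / 3600
  w <- max(1L, round(rules$window_hours / dt_h))
  state <- rep(1L, T)
  if (T <= w) {
    warning("track shorter than one rule window; labelling everything ",
            "Northern range", call. = FALSE)
    return(tibble::tibble(t = track$t, state = state))
  }
  lat <- track$lat
  idx <- (w + 1):T
  net <- lat[idx] - lat[idx - w] # trailing net latitude displacement
  cond_s <- c(rep(FALSE, w), net < -rules$south_threshold)
  cond_n <- c(rep(FALSE, w), net > rules$north_threshold)

  gap_max <- max(1L, round(rules$stopover_hours / dt_h))
  legs_s <- merge_legs(cond_s, gap_max)
  legs_n <- merge_legs(cond_n, gap_max)
  legs <- rbind(
    if (nrow(legs_s)) cbind(legs_s, 2L),
    if (nrow(legs_n)) cbind(legs_n, 4L)
  )
  if (is.null(legs) || nrow(legs) == 0) {
    return(tibble::tibble(t = track$t, state = state))
  }
  legs <- legs[order(legs[, 1]), , drop = FALSE]
  for (k in seq_len(nrow(legs))) {
    state[legs[k, 1]:legs[k, 2]] <- as.integer(legs[k, 3])
  }

  # Residency periods between/around legs: Northern or Southern range by
  # proximity of the period's latitude to the year's extreme latitudes.
  lat_n <- max(lat); lat_s <- min(lat)
  bounds <- c(0, as.vector(t(legs[, 1:2, drop = FALSE])), T + 1)
  n_seg <- length(bounds) / 2
  for (k in seq_len(n_seg)) {
    a <- bounds[2 * k - 1] + 1
    b <- bounds[2 * k] - 1
    if (a > b) next
    if (k == 1) {
      state[a:b] <- 1L # all birds begin in the Northern range
      next
    }
    seg_lat <- mean(lat[a:b])
    state[a:b] <- if (abs(seg_lat - lat_n) <= abs(seg_lat - lat_s)) 1L else 3L
  }
  tibble::tibble(t = track$t, state = state)
}

#' One-hot encode a state
#'
#' @param m State value(s).
#' @param alphabet Vector of allowed states, in output order.
#' @return A matrix with one row per element of `m`; each row is the
#'   indicator vector of its state.
#' @export
one_hot <- function(m, alphabet) {
  j <- match(m, alphabet)
  if (anyNA(j)) stop("state not in alphabet", call. = FALSE)
  out <- matrix(0L, length(m), length(alphabet))
  out[cbind(seq_along(m), j)] <- 1L
  colnames(out) <- as.character(alphabet)
  out
}
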