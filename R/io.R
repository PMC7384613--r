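#' Build a colony track from a tidy tracking table
#'
#' A colony track is a tibble with one record per (animal, time) pair and
#' columns `id`, `t`, `x`, `y`, `out`. Missing coordinates mark records where
#' the animal was outside the arena (its position is unobserved); these are
#' kept as explicit rows with `out = TRUE`. Times must be strictly increasing
#' within each animal and shared across animals (every animal has a record at
#' every time index).
#'
#' @param data Data frame with columns `id`, `t`, `x`, `y`.
#' @param dt Time-step duration (seconds per index step).
#' @return A `colony_track` tibble (`id`, `t`, `x`, `y`, `out`) with a `dt`
#'   attribute.
#' @export
colony_track <- function(data, dt = 1) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("id", "t", "x", "y") %in% names(data)))
  data$id <- as.character(data$id)
  data$t <- as.numeric(data$t)
  dup <- duplicated(data[c("id", "t")])
  if (any(dup)) {
    stop("duplicate (id, t) record at row ", which(dup)[1], call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$id, .data$t)
  times <- sort(unique(data$t))
  n_per <- table(data$id)
  if (length(unique(n_per)) != 1 || unique(n_per) != length(times)) {
    stop("every animal must have exactly one record per time index",
         call. = FALSE)
  }
  data$out <- is.na(data$x) | is.na(data$y)
  out <- dplyr::select(data, "id", "t", "x", "y", "out")
  attr(out, "dt") <- dt
  class(out) <- c("colony_track", class(out))
  out
}

track_dt <- function(track) {
  dt <- attr(track, "dt")
  if (is.null(dt)) 1 else dt
}

#' Read a tracking CSV into a colony track
#'
#' Expects a header row and columns `id, t, x, y`; empty `x`/`y` cells encode
#' out-of-arena records.
#'
#' @param path File path.
#' @param dt Time-step duration in seconds.
#' @return A [colony_track()].
#' @export
read_tracking_csv <- function(path, dt = 1) {
  # base strtod parsing is correctly rounded, so written coordinates
  # round-trip bit-exactly
  raw <- utils::read.csv(path, colClasses = c(id = "character",
                                              t = "numeric", x = "numeric",
                                              y = "numeric"))
  colony_track(tibble::as_tibble(raw), dt = dt)
}

#' Write a colony track to CSV
#'
#' Out-of-arena records are written with empty coordinate cells, the format
#' [read_tracking_csv()] expects.
#'
#' @param track A [colony_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(track, path) {
  out <- dplyr::select(tibble::as_tibble(track), "id", "t", "x", "y")
  # %.17g survives the text round trip bit-exactly
  num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out$x <- num(out$x)
  out$y <- num(out$y)
  out$t <- num(out$t)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# WGS84 ellipsoid constants for the transverse Mercator projection.
.wgs84 <- list(a = 6378137.0, f = 1 / 298.257223563, k0 = 0.9996)

utm_zone_of <- function(lon) pmin(pmax(floor((lon + 180) / 6) + 1, 1), 60)

#' Convert latitude/longitude to UTM coordinates
#'
#' Projects WGS84 geographic coordinates to Universal Transverse Mercator
#' eastings/northings (metres) using the standard series expansion of the
#' transverse Mercator projection. By default all points are projected into
#' one zone — the modal zone of the input — so that a whole track lives in a
#' single planar frame.
#'
#' @param lat,lon Coordinates in decimal degrees (vectorised).
#' @param zone UTM zone to project into; default is the modal zone of `lon`.
#' @return A tibble with columns `x` (easting), `y` (northing), `zone`.
#' @export
latlon_to_utm <- function(lat, lon, zone = NULL) {
  if (any(lat < -90 | lat > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (is.null(zone)) {
    zs <- utm_zone_of(lon[!is.na(lon)])
    zone <- as.integer(names(sort(table(zs), decreasing = TRUE))[1])
  }
  a <- .wgs84$a; f <- .wgs84$f; k0 <- .wgs84$k0
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  lam0 <- (-183 + 6 * zone) * pi / 180
  dlam <- (lon * pi / 180) - lam0

  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- dlam * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
              (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
              (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
              (35 * e2^3 / 3072) * sin(6 * phi))
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                   (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 5e5
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
                                   (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                                   (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  y <- ifelse(lat < 0, y + 1e7, y)
  tibble::tibble(x = x, y = y, zone = zone)
}

#' Convert UTM coordinates back to latitude/longitude
#'
#' Inverse of [latlon_to_utm()] (WGS84).
#'
#' @param x,y Easting and northing in metres.
#' @param zone UTM zone of the coordinates.
#' @param south Logical; was the point in the southern hemisphere?
#' @return A tibble with columns `lat`, `lon` in decimal degrees.
#' @export
utm_to_latlon <- function(x, y, zone, south = FALSE) {
  a <- .wgs84$a; f <- .wgs84$f; k0 <- .wgs84$k0
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  xm <- x - 5e5
  ym <- ifelse(rep(south, length.out = length(y)), y - 1e7, y)
  M <- ym / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  T1 <- tan(phi1)^2
  C1 <- ep2 * cos(phi1)^2
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  D <- xm / (N1 * k0)
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
       (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- (D - (1 + 2 * T1 + C1) * D^3 / 6 +
            (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) /
    cos(phi1)
  lam0 <- (-183 + 6 * zone) * pi / 180
  tibble::tibble(lat = phi * 180 / pi, lon = (lam0 + lam) * 180 / pi)
}

#' Read a gull-style tracking CSV
#'
#' Expects columns `id` (bird-year identifier), `timestamp` (ISO-8601, UTC),
#' `lat`, `lon`.
#'
#' @param path File path.
#' @return A tibble with columns `id`, `t` (POSIXct), `lat`, `lon`.
#' @export
read_gull_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      timestamp = readr::col_datetime(format = ""),
      lat = readr::col_double(), lon = readr::col_double()
    )
  ) |>
    dplyr::rename(t = "timestamp")
}

#' Fill gaps in a trajectory by linear interpolation
#'
#' Missing coordinate records are interpolated linearly in time within each
#' animal's track. Runs of missingness longer than `max_gap` consecutive
#' records are left missing and flagged. Leading or trailing missing records
#' cannot be interpolated and are dropped with a warning.
#'
#' @param track Tibble with columns `id`, `t` and two coordinate columns
#'   (`x`/`y` or `lat`/`lon`).
#' @param max_gap Longest run of consecutive missing records to fill.
#' @return The track with interpolated coordinates and a logical
#'   `interpolated` column.
#' @export
interpolate_gaps <- function(track, max_gap = Inf) {
  coord <- intersect(c("x", "y", "lat", "lon"), names(track))
  stopifnot(length(coord) == 2)
  fill_one <- function(df) {
    df <- dplyr::arrange(df, .data$t)
    miss <- is.na(df[[coord[1]]]) | is.na(df[[coord[2]]])
    if (!any(miss)) {
      df$interpolated <- FALSE
      return(df)
    }
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    fillable <- rep(FALSE, nrow(df))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      interior <- starts[k] > 1 && ends[k] < nrow(df)
      if (interior && r$lengths[k] <= max_gap) {
        fillable[starts[k]:ends[k]] <- TRUE
      }
    }
    tt <- as.numeric(df$t)
    for (cc in coord) {
      ok <- !miss
      if (sum(ok) >= 2) {
        df[[cc]][fillable] <- stats::approx(tt[ok], df[[cc]][ok],
                                            xout = tt[fillable])$y
      }
    }
    lead_trail <- miss & !fillable &
      (seq_len(nrow(df)) < which(!miss)[1] |
         seq_len(nrow(df)) > max(which(!miss)))
    if (any(lead_trail)) {
      warning("dropping ", sum(lead_trail),
              " leading/trailing missing records", call. = FALSE)
      keep <- !lead_trail
      df <- df[keep, ]
      fillable <- fillable[keep]
    }
    df$interpolated <- fillable
    df
  }
  track |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(~ fill_one(.x)) |>
    dplyr::ungroup()
}
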