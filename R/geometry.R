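#' Axis-aligned nest geometry
#'
#' Builds the arena geometry used throughout the package: an outer rectangle
#' divided into `n_chambers` equal chambers by interior walls, each chamber
#' optionally split into two halves by a mid-chamber barrier. Walls carry
#' narrow gaps (doorways between chambers, passageways through barriers) so
#' that the accessible interior is connected. Sub-chambers (half-chambers)
#' are numbered left to right.
#'
#' All coordinates follow the convention that x increases rightward (chamber
#' 1 towards chamber `n_chambers`), y increases upward ("North"), with the
#' origin at the bottom-left corner of the outer rectangle.
#'
#' @param width,height Outer rectangle extent (mm for ant nests).
#' @param n_chambers Number of equal-width chambers along x.
#' @param with_barriers Add a mid-chamber barrier to each chamber?
#' @param doorway_width Width of the gap in each interior wall.
#' @param gap_centre y-coordinate of the centre of every interior gap;
#'   defaults to mid-height.
#' @param exit Exit point on the outer boundary (where animals leave the
#'   arena); defaults to the bottom-right corner.
#' @param extra_walls Optional data frame of additional axis-aligned wall
#'   segments with columns `x1, y1, x2, y2`.
#' @return An object of class `nest_geometry`: a list with the outer extent,
#'   a tibble of wall segments, a tibble of sub-chamber rectangles and the
#'   exit point.
#' @examples
#' geom <- nest_geometry()          # 4-chamber 160 x 65 mm nest
#' box  <- nest_geometry(10, 10, n_chambers = 1, with_barriers = FALSE)
#' @export
nest_geometry <- function(width = 160, height = 65, n_chambers = 4,
                          with_barriers = TRUE, doorway_width = 6,
                          gap_centre = height / 2,
                          exit = c(width, 0), extra_walls = NULL) {
  if (width <= 0 || height <= 0) {
    stop("degenerate geometry: nest must have positive area", call. = FALSE)
  }
  outer <- tibble::tibble(
    x1 = c(0, 0, width, 0), y1 = c(0, height, 0, 0),
    x2 = c(width, width, width, 0), y2 = c(0, height, height, height)
  )
  gap <- c(gap_centre - doorway_width / 2, gap_centre + doorway_width / 2)
  gap[1] <- max(gap[1], 0)
  gap[2] <- min(gap[2], height)

  vertical_wall <- function(x) {
    tibble::tibble(
      x1 = x, y1 = c(0, gap[2]),
      x2 = x, y2 = c(gap[1], height)
    )
  }
  chamber_w <- width / n_chambers
  chamber_xs <- if (n_chambers > 1) chamber_w * seq_len(n_chambers - 1) else numeric()
  barrier_xs <- if (with_barriers) chamber_w * (seq_len(n_chambers) - 0.5) else numeric()
  interior <- dplyr::bind_rows(lapply(c(chamber_xs, barrier_xs), vertical_wall))
  if (nrow(interior) > 0) {
    interior <- dplyr::filter(interior, .data$y2 > .data$y1)
  }
  walls <- dplyr::bind_rows(outer, interior)
  if (!is.null(extra_walls)) {
    walls <- dplyr::bind_rows(walls, tibble::as_tibble(extra_walls))
  }

  cuts <- sort(unique(c(0, chamber_xs, barrier_xs, width)))
  sub_chambers <- tibble::tibble(
    sub_chamber = seq_len(length(cuts) - 1),
    xmin = cuts[-length(cuts)], xmax = cuts[-1],
    ymin = 0, ymax = height
  )

  structure(
    list(width = width, height = height, walls = walls,
         sub_chambers = sub_chambers, exit = as.numeric(exit),
         doorway_width = doorway_width),
    class = "nest_geometry"
  )
}

#' @export
print.nest_geometry <- function(x, ...) {
  cat(sprintf(
    "<nest_geometry> %g x %g mm, %d sub-chambers, %d wall segments, exit (%g, %g)\n",
    x$width, x$height, nrow(x$sub_chambers), nrow(x$walls), x$exit[1], x$exit[2]
  ))
  invisible(x)
}

in_nest <- function(x, y, geom, tol = 0) {
  x >= -tol & x <= geom$width + tol & y >= -tol & y <= geom$height + tol
}

#' Sub-chamber containing a position
#'
#' Assigns positions to sub-chamber rectangles (numbered left to right).
#' Containment is half-open: a point on the shared edge of two cells belongs
#' to the right-hand (higher-index) cell; the outer right edge belongs to the
#' last cell.
#'
#' @param x,y Position coordinates (vectorised).
#' @param geom A [nest_geometry()].
#' @return Integer vector of sub-chamber indices.
#' @export
sub_chamber_of <- function(x, y, geom) {
  if (any(!in_nest(x, y, geom))) {
    stop("position outside the nest rectangle", call. = FALSE)
  }
  cuts <- c(geom$sub_chambers$xmin, geom$width)
  idx <- findInterval(x, cuts, left.open = FALSE, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), nrow(geom$sub_chambers))
}

#' Distances to the nearest wall in the four cardinal directions
#'
#' Casts axis-aligned rays from each position and reports the distance to the
#' first wall segment hit in the North (+y), South (-y), East (+x) and West
#' (-x) directions. Interior walls and barriers count as walls.
#'
#' @inheritParams sub_chamber_of
#' @return A tibble with columns `wall_n`, `wall_s`, `wall_e`, `wall_w`.
#' @export
wall_distances <- function(x, y, geom) {
  if (any(!in_nest(x, y, geom))) {
    stop("position outside the nest rectangle", call. = FALSE)
  }
  n <- length(x)
  dn <- geom$height - y; ds <- y; de <- geom$width - x; dw <- x
  w <- geom$walls
  for (k in seq_len(nrow(w))) {
    if (w$y1[k] == w$y2[k]) { # horizontal segment blocks N/S rays
      x1 <- min(w$x1[k], w$x2[k]); x2 <- max(w$x1[k], w$x2[k]); wy <- w$y1[k]
      m <- x >= x1 & x <= x2
      up <- m & wy >= y
      dn[up] <- pmin(dn[up], wy - y[up])
      lo <- m & wy <= y
      ds[lo] <- pmin(ds[lo], y[lo] - wy)
    } else { # vertical segment blocks E/W rays
      y1 <- min(w$y1[k], w$y2[k]); y2 <- max(w$y1[k], w$y2[k]); wx <- w$x1[k]
      m <- y >= y1 & y <= y2
      rt <- m & wx >= x
      de[rt] <- pmin(de[rt], wx - x[rt])
      lf <- m & wx <= x
      dw[lf] <- pmin(dw[lf], x[lf] - wx)
    }
  }
  tibble::tibble(wall_n = dn, wall_s = ds, wall_e = de, wall_w = dw)
}

#' Project positions onto the nest boundary
#'
#' Positions inside the outer rectangle are returned unchanged; positions
#' outside are replaced by the closest (Euclidean) point on the rectangle
#' border. Used to keep predicted and simulated locations inside the arena.
#'
#' @inheritParams sub_chamber_of
#' @return A tibble with columns `x` and `y`.
#' @export
project_to_boundary <- function(x, y, geom) {
  if (geom$width <= 0 || geom$height <= 0) {
    stop("degenerate geometry: nest must have positive area", call. = FALSE)
  }
  tibble::tibble(
    x = pmin(pmax(x, 0), geom$width),
    y = pmin(pmax(y, 0), geom$height)
  )
}
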