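# Lattice geometry: cells are 0-based (x, y) integer pairs, x rightward,
# y downward.  The lattice metric is Chebyshev ("Distance"): orthogonal and
# diagonal neighbours are both 1 Distance away.

#' Axis-aligned cell rectangle
#'
#' A rectangle of lattice cells with inclusive bounds. Used for ditches
#' (bars), the nest region, and feeding-spot footprints.
#'
#' @param x_min,x_max,y_min,y_max Inclusive cell-index bounds.
#' @return An object of class `"rect"`.
#' @export
rect <- function(x_min, x_max, y_min, y_max) {
  x_min <- as.integer(x_min); x_max <- as.integer(x_max)
  y_min <- as.integer(y_min); y_max <- as.integer(y_max)
  if (x_min > x_max || y_min > y_max)
    stop("invalid rect: require x_min <= x_max and y_min <= y_max")
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "rect")
}

#' @export
print.rect <- function(x, ...) {
  cat(sprintf("<rect x:[%d,%d] y:[%d,%d]>\n", x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

rect_cells <- function(r) {
  as.matrix(expand.grid(x = r$x_min:r$x_max, y = r$y_min:r$y_max))
}

rect_area <- function(r) (r$x_max - r$x_min + 1L) * (r$y_max - r$y_min + 1L)

in_rect <- function(px, py, r) {
  px >= r$x_min & px <= r$x_max & py >= r$y_min & py <= r$y_max
}

rects_overlap <- function(a, b) {
  a$x_min <= b$x_max && b$x_min <= a$x_max && a$y_min <= b$y_max && b$y_min <= a$y_max
}

# Chebyshev distance from a point to a rect (0 inside).
dist_to_rect <- function(px, py, r) {
  dx <- pmax(0L, r$x_min - px, px - r$x_max)
  dy <- pmax(0L, r$y_min - py, py - r$y_max)
  pmax(dx, dy)
}

#' Chebyshev distance between cells
#'
#' The simulation's lattice metric: orthogonal and diagonal neighbours are
#' both 1 Distance away, so the distance is `max(|dx|, |dy|)`.
#'
#' @param p,q Cells as length-2 `c(x, y)` vectors, or two-column matrices of
#'   cells (recycled row-wise).
#' @return Integer distance(s).
#' @examples
#' chebyshev_distance(c(0, 0), c(1, 1))  # diagonal neighbour: 1
#' @export
chebyshev_distance <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  as.integer(pmax(abs(p[, 1] - q[, 1]), abs(p[, 2] - q[, 2])))
}

# Moore-neighbourhood offsets at radius 1 (8 cells) and radius <= 2 (24 cells),
# excluding the centre.
.offsets <- function(radius) {
  g <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  g <- g[!(g$dx == 0L & g$dy == 0L), , drop = FALSE]
  as.matrix(g)
}
OFF1 <- .offsets(1L)
OFF2 <- .offsets(2L)

#' Cells within a Chebyshev radius
#'
#' All in-bounds cells `q != pos` with `chebyshev_distance(pos, q) <= radius`.
#'
#' @param env A `grid_environment` (or anything with `width`/`height`).
#' @param pos Cell `c(x, y)`, 0-based.
#' @param radius Radius in Distances (>= 1).
#' @return Integer matrix with columns `x`, `y`.
#' @export
neighborhood <- function(env, pos, radius = 1L) {
  stopifnot(radius >= 1L)
  off <- if (radius == 1L) OFF1 else if (radius == 2L) OFF2 else .offsets(as.integer(radius))
  xs <- pos[1L] + off[, 1L]
  ys <- pos[2L] + off[, 2L]
  keep <- xs >= 0L & xs < env$width & ys >= 0L & ys < env$height
  cbind(x = as.integer(xs[keep]), y = as.integer(ys[keep]))
}
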