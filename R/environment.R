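# The lattice world: ditches (bars), nest, feeding spots.
#
# Cell classes are coded in an integer matrix indexed [x + 1, y + 1]:
#   0 OPEN, 1 DITCH, 2 NEST.  FOOD is dynamic: a cell belonging to a feeding
# spot whose remaining food is positive classifies as FOOD.

.CLS_OPEN  <- 0L
.CLS_DITCH <- 1L
.CLS_NEST  <- 2L
.CLS_WALL  <- 9L  # padding sentinel used by the engine, never inside the grid

#' Feeding spot
#'
#' A labelled rectangular food patch holding an integer number of food units.
#' Any cell of the footprint yields food while `remaining_food > 0`.
#'
#' @param label Spot label, e.g. `"A"`.
#' @param footprint A [rect()] of cells.
#' @param food Initial food units (non-negative integer).
#' @return An object of class `"feeding_spot"`.
#' @export
feeding_spot <- function(label, footprint, food) {
  stopifnot(inherits(footprint, "rect"), food >= 0)
  structure(list(label = as.character(label), footprint = footprint,
                 initial_food = as.integer(food), remaining_food = as.integer(food)),
            class = "feeding_spot")
}

#' Construct a lattice world
#'
#' Builds a bounded `width` x `height` grid with rectangular ditches (bars),
#' an optional nest region and feeding spots.  World edges are impassable
#' walls (no torus).  Validates that the nest and every spot are disjoint
#' from the ditches and that spots avoid the nest.
#'
#' @param width,height Grid dimensions in cells.
#' @param bars Named or unnamed list of [rect()] ditches.
#' @param nest A [rect()] nest region, or `NULL`.
#' @param spots List of [feeding_spot()] objects.
#' @return An object of class `"grid_environment"`.
#' @export
grid_environment <- function(width, height, bars = list(), nest = NULL, spots = list()) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 1L, height >= 1L)
  full <- rect(0L, width - 1L, 0L, height - 1L)
  chk_in <- function(r, what) {
    if (r$x_min < 0L || r$x_max >= width || r$y_min < 0L || r$y_max >= height)
      stop(sprintf("%s extends outside the %dx%d grid", what, width, height))
  }
  cls <- matrix(.CLS_OPEN, nrow = width, ncol = height)
  for (i in seq_along(bars)) {
    b <- bars[[i]]
    chk_in(b, sprintf("bar %d", i))
    cls[(b$x_min:b$x_max) + 1L, (b$y_min:b$y_max) + 1L] <- .CLS_DITCH
  }
  if (!is.null(nest)) {
    chk_in(nest, "nest")
    nc <- cls[(nest$x_min:nest$x_max) + 1L, (nest$y_min:nest$y_max) + 1L]
    if (any(nc == .CLS_DITCH)) stop("nest overlaps a ditch")
    cls[(nest$x_min:nest$x_max) + 1L, (nest$y_min:nest$y_max) + 1L] <- .CLS_NEST
  }
  spot_id <- matrix(0L, nrow = width, ncol = height)
  for (i in seq_along(spots)) {
    s <- spots[[i]]
    stopifnot(inherits(s, "feeding_spot"))
    f <- s$footprint
    chk_in(f, sprintf("feeding spot '%s'", s$label))
    sc <- cls[(f$x_min:f$x_max) + 1L, (f$y_min:f$y_max) + 1L]
    if (any(sc == .CLS_DITCH))
      stop(sprintf("feeding spot '%s' overlaps a ditch", s$label))
    if (any(sc == .CLS_NEST))
      stop(sprintf("feeding spot '%s' overlaps the nest", s$label))
    if (any(spot_id[(f$x_min:f$x_max) + 1L, (f$y_min:f$y_max) + 1L] != 0L))
      stop(sprintf("feeding spot '%s' overlaps another spot", s$label))
    spot_id[(f$x_min:f$x_max) + 1L, (f$y_min:f$y_max) + 1L] <- i
  }
  structure(list(width = width, height = height, bars = bars, nest = nest,
                 spots = spots, cls = cls, spot_id = spot_id),
            class = "grid_environment")
}

#' @export
print.grid_environment <- function(x, ...) {
  cat(sprintf("<grid_environment %dx%d: %d bar(s), %d spot(s)%s>\n",
              x$width, x$height, length(x$bars), length(x$spots),
              if (is.null(x$nest)) "" else ", nest"))
  for (s in x$spots)
    cat(sprintf("  spot %s: x[%d,%d] y[%d,%d], food %d/%d\n", s$label,
                s$footprint$x_min, s$footprint$x_max, s$footprint$y_min,
                s$footprint$y_max, s$remaining_food, s$initial_food))
  invisible(x)
}

#' Default feeding-spot layout
#'
#' Three spots around the walled nest: B beyond the left ditch, C beyond the
#' right ditch, A below the centre ditch.  Positions are a package convention
#' (config-overridable); only the nest/bar geometry is fixed by the default
#' world.
#'
#' @param food Named vector of food units, e.g. `c(A = 200, B = 100, C = 100)`.
#' @return List of [feeding_spot()] objects in label order A, B, C.
#' @export
default_spot_layout <- function(food = c(A = 100L, B = 100L, C = 100L)) {
  stopifnot(all(c("A", "B", "C") %in% names(food)))
  list(feeding_spot("A", rect(48L, 53L, 80L, 85L), food[["A"]]),
       feeding_spot("B", rect(10L, 15L, 45L, 50L), food[["B"]]),
       feeding_spot("C", rect(84L, 89L, 45L, 50L), food[["C"]]))
}

#' Build the default 100 x 100 world
#'
#' The standard arena: a 100 x 100 lattice whose central nest is fenced on
#' the left, right and bottom by three 3-cell-wide ditches (leftbar,
#' rightbar, centerbar).  Bar corner coordinates follow a half-open
#' convention on the max edge so that each ditch blocks exactly 3 cell
#' widths: leftbar blocks x in \{30,31,32\} and rightbar x in \{70,71,72\},
#' both over y in \[30,69\]; centerbar blocks y in \{70,71,72\} over
#' x in \[30,72\].  The strip above the bars (y < 30) stays open, so an ant
#' can reach any feeding area by a long detour around a ditch end -- a
#' living bridge across a ditch is the short cut, not the only route.
#' Within the side-barred rows (y in 30..69) the direct line is fully
#' blocked: restricted to those rows the arena falls into exactly three
#' parts (left of leftbar, the nest side, right of rightbar), and
#' restricted to the centerbar rows (y in 70..72) into exactly two.
#'
#' @param spot_layout List of [feeding_spot()]s; see [default_spot_layout()].
#' @return A `"grid_environment"`.
#' @examples
#' env <- build_default_environment()
#' classify_cell(env, c(31, 50))  # "DITCH"
#' @export
build_default_environment <- function(spot_layout = default_spot_layout()) {
  bars <- list(leftbar   = rect(30L, 32L, 30L, 69L),
               rightbar  = rect(70L, 72L, 30L, 69L),
               centerbar = rect(30L, 72L, 70L, 72L))
  nest <- rect(33L, 69L, 30L, 69L)
  grid_environment(100L, 100L, bars = bars, nest = nest, spots = spot_layout)
}

#' Occupancy areas of the default world
#'
#' The three sub-regions the ditches separate from the nest side, used as
#' the per-tick occupancy areas of the standard scenarios: `A` is the
#' bottom region beyond the centre ditch, `B` the region left of the left
#' ditch, `C` the region right of the right ditch.  Each area includes the
#' ditch band between it and the nest, so agents assembled into a chain or
#' bridge on that ditch count as occupying the area they bridge toward.
#' Where the rectangles overlap (the ditch corners), `A` takes precedence,
#' then `B`, then `C`.  The open strip above the bars and the nest side
#' itself belong to no area.
#'
#' @return Named list of [rect()]s (`A`, `B`, `C`).
#' @examples
#' default_areas()$B
#' @export
default_areas <- function() {
  list(A = rect(30L, 72L, 70L, 99L),
       B = rect(0L, 32L, 30L, 99L),
       C = rect(70L, 99L, 30L, 99L))
}

#' Classify one cell
#'
#' @param env A `"grid_environment"` or `"sim_state"`.
#' @param pos Cell `c(x, y)`, 0-based.
#' @return One of `"OPEN"`, `"DITCH"`, `"NEST"`, `"FOOD"`.
#' @export
classify_cell <- function(env, pos) {
  if (inherits(env, "sim_state")) env <- sim_environment(env)
  x <- as.integer(pos[1L]); y <- as.integer(pos[2L])
  if (x < 0L || x >= env$width || y < 0L || y >= env$height)
    stop(sprintf("cell (%d, %d) is outside the %dx%d grid", x, y, env$width, env$height))
  cl <- env$cls[x + 1L, y + 1L]
  if (cl == .CLS_DITCH) return("DITCH")
  if (cl == .CLS_NEST)  return("NEST")
  sid <- env$spot_id[x + 1L, y + 1L]
  if (sid > 0L && env$spots[[sid]]$remaining_food > 0L) return("FOOD")
  "OPEN"
}

#' Counts of cell classes over the whole grid
#'
#' @param env A `"grid_environment"`.
#' @return Named integer vector over OPEN/DITCH/NEST/FOOD summing to
#'   `width * height`.
#' @export
cell_class_counts <- function(env) {
  cl <- env$cls
  food <- matrix(FALSE, env$width, env$height)
  for (i in seq_along(env$spots)) {
    s <- env$spots[[i]]
    if (s$remaining_food > 0L) {
      f <- s$footprint
      food[(f$x_min:f$x_max) + 1L, (f$y_min:f$y_max) + 1L] <- TRUE
    }
  }
  c(OPEN  = sum(cl == .CLS_OPEN & !food),
    DITCH = sum(cl == .CLS_DITCH),
    NEST  = sum(cl == .CLS_NEST),
    FOOD  = sum(food))
}

#' Flood-fill reachability over non-ditch cells
#'
#' The set of cells reachable from `from` by 1-Distance moves over
#' OPEN/NEST/FOOD cells (agents ignored).  Used to verify that the default
#' ditches block the direct line while leaving the detour above the bars
#' open.
#'
#' @param env A `"grid_environment"`.
#' @param from Starting cell `c(x, y)`.
#' @return Logical matrix (`width` x `height`) of reachable cells.
#' @export
reachable_cells <- function(env, from) {
  w <- env$width; h <- env$height
  open <- env$cls != .CLS_DITCH
  seen <- matrix(FALSE, w, h)
  if (!open[from[1L] + 1L, from[2L] + 1L])
    stop("starting cell is a ditch")
  seen[from[1L] + 1L, from[2L] + 1L] <- TRUE
  frontier <- matrix(as.integer(from), ncol = 2L)
  while (nrow(frontier) > 0L) {
    nxt <- NULL
    for (k in seq_len(8L)) {
      xs <- frontier[, 1L] + OFF1[k, 1L]
      ys <- frontier[, 2L] + OFF1[k, 2L]
      ok <- xs >= 0L & xs < w & ys >= 0L & ys < h
      xs <- xs[ok]; ys <- ys[ok]
      if (!length(xs)) next
      idx <- cbind(xs + 1L, ys + 1L)
      new <- open[idx] & !seen[idx]
      if (any(new)) {
        seen[idx[new, , drop = FALSE]] <- TRUE
        nxt <- rbind(nxt, cbind(xs[new], ys[new]))
      }
    }
    frontier <- if (is.null(nxt)) matrix(integer(), ncol = 2L) else unique(nxt)
  }
  seen
}
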