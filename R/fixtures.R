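# Miniature deterministic worlds for fast tests and manual inspection.

#' Corridor world
#'
#' A 5 x `length` strip: nest band at the top end, one food spot at the far
#' end, and optionally a full-width 3-cell ditch midway.  A single ant can
#' never cross the ditch; a colony can bridge it.
#'
#' @param length Strip length in cells (>= 8).
#' @param ditch Include the 3-cell ditch?
#' @param n_minor,n_major Agent counts, placed on random nest cells.
#' @param food Food units at the spot.
#' @param seed RNG seed.
#' @param max_ticks Default run length.
#' @param pheromone A [pheromone_params()].
#' @param behavior A [behavior_params()].
#' @param engine `"cpp"` or `"r"` stepper (see [make_scenario()]).
#' @return A `"sim_state"`.
#' @examples
#' st <- corridor_world(12, ditch = TRUE, n_minor = 3, seed = 1)
#' @export
corridor_world <- function(length = 24L, ditch = TRUE, n_minor = 5L,
                           n_major = 0L, food = 3L, seed = 1L,
                           max_ticks = 10L * length,
                           pheromone = pheromone_params(),
                           behavior = behavior_params(),
                           engine = c("cpp", "r")) {
  length <- as.integer(length)
  stopifnot(length >= 8L)
  mid <- length %/% 2L
  bars <- if (ditch) list(ditch = rect(0L, 4L, mid, mid + 2L)) else list()
  nest <- rect(0L, 4L, 0L, mid - 2L)
  spot_y0 <- max(mid + 3L, length - 2L)
  spot <- feeding_spot("A", rect(1L, 3L, spot_y0, length - 1L), food)
  env <- grid_environment(5L, length, bars = bars, nest = nest, spots = list(spot))
  set.seed(seed)
  n <- n_major + n_minor
  nc <- rect_cells(nest)
  if (n > nrow(nc)) stop("more ants than nest cells; use a longer corridor")
  pick <- nc[sample.int(nrow(nc), n), , drop = FALSE]
  ants <- data.frame(x = pick[, 1L], y = pick[, 2L],
                     caste = rep(c("MAJOR", "MINOR"), c(n_major, n_minor)),
                     state = "SEARCH")
  new_sim_state(env, ants, pheromone = pheromone, behavior = behavior,
                seed = seed, name = sprintf("corridor-%d%s", length,
                                            if (ditch) "-ditch" else ""),
                max_ticks = max_ticks, area_dilation = 2L,
                engine = match.arg(engine))
}

#' Field with a single point mass
#'
#' @param width,height Grid dimensions.
#' @param pos Cell `c(x, y)`, 0-based.
#' @param amount Non-negative amount.
#' @param layer `"ground"` or `"space"`.
#' @return A `"pheromone_field"`.
#' @export
point_mass_field <- function(width, height, pos, amount,
                             layer = c("ground", "space")) {
  layer <- match.arg(layer)
  stopifnot(amount >= 0, pos[1L] >= 0L, pos[1L] < width, pos[2L] >= 0L, pos[2L] < height)
  f <- pheromone_field(width, height)
  f[[layer]][pos[1L] + 1L, pos[2L] + 1L] <- amount
  f
}

#' Chain fixture: k members planted in a ditch
#'
#' Places `k` Altruism-state Minor ants contiguously across a ditch's short
#' dimension, starting from the wall nearer the ditch's min edge, at the
#' middle of the ditch's long dimension.  Exercises chain bookkeeping,
#' leave probabilities and bridge detection.
#'
#' @param env A `"grid_environment"` with at least one bar.
#' @param ditch Bar index or name.
#' @param k Number of members (1 <= k <= ditch short width).
#' @param seed RNG seed.
#' @param pheromone A [pheromone_params()].
#' @param behavior A [behavior_params()].
#' @return A `"sim_state"`.
#' @export
chain_fixture <- function(env, ditch = 1L, k = 3L, seed = 1L,
                          pheromone = pheromone_params(),
                          behavior = behavior_params()) {
  stopifnot(inherits(env, "grid_environment"), length(env$bars) >= 1L, k >= 1L)
  b <- env$bars[[ditch]]
  short_x <- (b$x_max - b$x_min) <= (b$y_max - b$y_min)
  cap <- if (short_x) b$x_max - b$x_min + 1L else b$y_max - b$y_min + 1L
  if (k > cap) stop(sprintf("k = %d exceeds ditch capacity %d", k, cap))
  long_mid <- if (short_x) (b$y_min + b$y_max) %/% 2L else (b$x_min + b$x_max) %/% 2L
  cells <- if (short_x)
    cbind(b$x_min + 0L:(k - 1L), long_mid)
  else
    cbind(long_mid, b$y_min + 0L:(k - 1L))
  set.seed(seed)
  ants <- data.frame(x = cells[, 1L], y = cells[, 2L],
                     caste = "MINOR", state = "ALTRUISM")
  new_sim_state(env, ants, pheromone = pheromone, behavior = behavior,
                seed = seed, name = sprintf("chain-%d", k),
                max_ticks = 1000L, area_dilation = 2L)
}
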