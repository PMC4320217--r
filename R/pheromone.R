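# Two-layer pheromone field.  Agents deposit on the ground layer; each tick
# the ground layer evaporates a fixed fraction r_e into the space layer,
# which diffuses and decays.  Only the space layer is perceived by agents.

#' Pheromone parameters
#'
#' @param r_A Decay ratio of the space layer per tick.
#' @param r_B Diffusion rate to the four orthogonal neighbours.
#' @param r_C Diffusion rate to the four diagonal neighbours.
#' @param r_e Evaporation rate: fraction of ground pheromone transferred to
#'   the space layer per tick.
#' @param deposit_ground Ground units laid per depositing agent per tick.
#' @param diagonal_deposit_factor Multiplier applied to a deposit made after
#'   a diagonal move (scattered pheromone diminishes on diagonals).
#' @param kernel `"laplacian"` applies the update in its literal discrete
#'   Laplacian form (with `-4 s` terms); `"conservative"` redistributes the
#'   same rates without the `-4 s` terms, which is exactly mass-conserving in
#'   the interior when `r_A + 4 r_B + 4 r_C = 1` (true of the defaults).
#' @param floor Concentrations below this value are flushed to exact zero at
#'   the end of each exchange step.  Exponential decay otherwise leaves
#'   physically meaningless residues (eventually subnormal doubles) on every
#'   cell ever touched, which both poisons floating-point performance and
#'   makes agents "perceive" pheromone forever.  With the default decay
#'   rate a unit deposit falls below the default floor in about 115 ticks.
#' @return An object of class `"pheromone_params"`.
#' @export
pheromone_params <- function(r_A = 0.788, r_B = 0.043, r_C = 0.010, r_e = 0.05,
                             deposit_ground = 1.0, diagonal_deposit_factor = 0.5,
                             kernel = c("laplacian", "conservative"),
                             floor = 1e-12) {
  kernel <- match.arg(kernel)
  for (v in c(r_A = r_A, r_B = r_B, r_C = r_C, r_e = r_e))
    if (v < 0 || v > 1) stop("pheromone rates must lie in [0, 1]")
  if (deposit_ground < 0) stop("deposit_ground must be non-negative")
  if (diagonal_deposit_factor <= 0 || diagonal_deposit_factor > 1)
    stop("diagonal_deposit_factor must lie in (0, 1]")
  if (floor < 0) stop("floor must be non-negative")
  structure(list(r_A = r_A, r_B = r_B, r_C = r_C, r_e = r_e,
                 deposit_ground = deposit_ground,
                 diagonal_deposit_factor = diagonal_deposit_factor,
                 kernel = kernel, floor = floor),
            class = "pheromone_params")
}

#' Two-layer pheromone field
#'
#' @param width,height Grid dimensions, or pass an existing matrix via
#'   `space` / `ground`.
#' @param space,ground Optional initial matrices (non-negative).
#' @return An object of class `"pheromone_field"` with `space` and `ground`
#'   matrices indexed `[x + 1, y + 1]`.
#' @export
pheromone_field <- function(width, height, space = NULL, ground = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.null(space)) space <- matrix(0, width, height)
  if (is.null(ground)) ground <- matrix(0, width, height)
  stopifnot(identical(dim(space), c(width, height)),
            identical(dim(ground), c(width, height)))
  if (any(space < 0) || any(ground < 0))
    stop("pheromone concentrations must be non-negative")
  structure(list(space = space, ground = ground), class = "pheromone_field")
}

# Zero-padded matrix shift: value of the neighbour at (x + dx, y + dy),
# out-of-grid neighbours contributing 0 (absorbing edge).
.shift <- function(m, dx, dy) {
  w <- nrow(m); h <- ncol(m)
  out <- matrix(0, w, h)
  xs <- max(1L, 1L + dx):min(w, w + dx)
  ys <- max(1L, 1L + dy):min(h, h + dy)
  out[xs, ys] <- m[xs - dx, ys - dy]
  out
}

#' One diffusion--decay step of the space layer
#'
#' Synchronous update of every cell from the time-t snapshot:
#' `space' = r_A s + r_B (sum of 4 orthogonal neighbours - 4 s)
#'             + r_C (sum of 4 diagonal neighbours - 4 s)`
#' with out-of-grid neighbours contributing 0.  Any negative result (possible
#' at edges under the literal form) is clipped to 0; the number of clipped
#' cells is returned in attribute `"clipped"`.
#'
#' @param field A `"pheromone_field"`.
#' @param params A [pheromone_params()].
#' @return The field with the updated space layer.
#' @export
space_diffusion_step <- function(field, params = pheromone_params()) {
  s <- field$space
  if (any(s < 0)) stop("space layer contains negative values")
  orth <- .shift(s, 1, 0) + .shift(s, -1, 0) + .shift(s, 0, 1) + .shift(s, 0, -1)
  diag <- .shift(s, 1, 1) + .shift(s, 1, -1) + .shift(s, -1, 1) + .shift(s, -1, -1)
  s2 <- if (params$kernel == "laplacian")
    params$r_A * s + params$r_B * (orth - 4 * s) + params$r_C * (diag - 4 * s)
  else
    params$r_A * s + params$r_B * orth + params$r_C * diag
  clipped <- sum(s2 < 0)
  if (clipped > 0) s2[s2 < 0] <- 0
  field$space <- s2
  attr(field, "clipped") <- clipped
  field
}

#' Ground-to-space evaporation exchange
#'
#' Applied cellwise after the diffusion step of the same tick:
#' `space(t+1) = space'(t) + r_e ground(t)`;
#' `ground(t+1) = (1 - r_e) ground(t)`.
#' Afterwards both layers are flushed: values below `params$floor` become
#' exact zeros (see [pheromone_params()]).
#'
#' @inheritParams space_diffusion_step
#' @return The field with both layers updated.
#' @export
ground_space_exchange <- function(field, params = pheromone_params()) {
  g <- field$ground
  if (any(g < 0)) stop("ground layer contains negative values")
  s <- field$space + params$r_e * g
  g2 <- g - params$r_e * g
  s[s < params$floor] <- 0
  g2[g2 < params$floor] <- 0
  field$space <- s
  field$ground <- g2
  field
}

#' Deposit ground pheromone at a cell
#'
#' Adds `deposit_ground` units (scaled by `diagonal_deposit_factor` if the
#' depositing agent moved diagonally) to the ground layer at `pos`.
#'
#' @inheritParams space_diffusion_step
#' @param pos Cell `c(x, y)`, 0-based.
#' @param moved_diagonally Whether the agent's move this tick was diagonal.
#' @return The field with the updated ground layer.
#' @export
deposit <- function(field, pos, params = pheromone_params(), moved_diagonally = FALSE) {
  x <- as.integer(pos[1L]) + 1L; y <- as.integer(pos[2L]) + 1L
  stopifnot(x >= 1L, x <= nrow(field$ground), y >= 1L, y <= ncol(field$ground))
  amt <- params$deposit_ground * if (moved_diagonally) params$diagonal_deposit_factor else 1
  field$ground[x, y] <- field$ground[x, y] + amt
  field
}

#' Layer totals
#'
#' @param field A `"pheromone_field"`.
#' @return Named numeric vector `c(space = ..., ground = ...)`.
#' @export
total_pheromone <- function(field) {
  c(space = sum(field$space), ground = sum(field$ground))
}
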