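# Simulation state.
#
# A `sim_state` is an R environment (reference semantics: the stepping
# functions update it in place and return it invisibly).  Geometry,
# occupancy and pheromone layers are stored as matrices padded with a
# 2-cell border so that every radius-1/radius-2 perception check is a plain
# vector lookup without bounds tests:
#   cls   padded cell classes (border = wall sentinel, impassable)
#   occ   walker occupancy (ant id or 0; border -1)
#   mem   chain-member occupancy on ditch cells (ant id or 0)
#   space, ground  pheromone layers (border 0)
# Cell (x, y) maps to linear padded index (x + 3) + W * (y + 2) with
# W = width + 4.

.SEARCH <- 1L; .RETURN <- 2L; .ALTRUISM <- 3L
.MAJOR <- 1L; .MINOR <- 2L
.STATE_NAMES <- c("SEARCH", "RETURN", "ALTRUISM")
.CASTE_NAMES <- c("MAJOR", "MINOR")

.pad <- function(m, border, P = 2L) {
  W <- nrow(m) + 2L * P; H <- ncol(m) + 2L * P
  M <- matrix(border, W, H)
  M[(P + 1L):(W - P), (P + 1L):(H - P)] <- m
  M
}

.li <- function(x, y, W) (x + 3L) + W * (y + 2L)

# Internal constructor shared by make_scenario() and the fixtures.
# `ants` is a data.frame with columns x, y, caste ("MAJOR"/"MINOR"),
# state ("SEARCH"/"RETURN"/"ALTRUISM").
new_sim_state <- function(env, ants, pheromone = pheromone_params(),
                          behavior = behavior_params(), seed = NA_integer_,
                          name = "custom", max_ticks = 10000L,
                          area_dilation = 5L, areas = NULL,
                          engine = c("cpp", "r")) {
  stopifnot(inherits(env, "grid_environment"))
  engine <- match.arg(engine)
  w <- env$width; h <- env$height
  st <- new.env(parent = emptyenv())
  st$env <- env
  st$engine <- engine
  st$name <- name
  st$seed <- as.integer(seed)
  st$max_ticks <- as.integer(max_ticks)
  st$w <- w; st$h <- h
  st$W <- w + 4L; st$H <- h + 4L
  st$cls <- .pad(env$cls, .CLS_WALL)
  st$spot <- .pad(env$spot_id, 0L)
  st$occ <- .pad(matrix(0L, w, h), -1L)
  st$mem <- .pad(matrix(0L, w, h), 0L)
  st$space <- .pad(matrix(0, w, h), 0)
  st$ground <- .pad(matrix(0, w, h), 0)
  st$d1 <- OFF1[, 1L] + st$W * OFF1[, 2L]
  st$d2 <- OFF2[, 1L] + st$W * OFF2[, 2L]
  st$pheromone <- pheromone
  st$behavior <- behavior
  st$nest_rect <- env$nest
  st$remaining <- vapply(env$spots, function(s) s$remaining_food, integer(1))
  st$initial_food <- vapply(env$spots, function(s) s$initial_food, integer(1))
  st$spot_labels <- vapply(env$spots, function(s) s$label, character(1))
  names(st$remaining) <- names(st$initial_food) <- st$spot_labels
  st$delivered <- stats::setNames(integer(length(env$spots)), st$spot_labels)
  # occupancy areas: explicit rects if given, else spot footprints dilated
  # and clipped to the grid
  if (is.null(areas)) {
    st$areas <- lapply(env$spots, function(s) {
      f <- s$footprint
      rect(max(0L, f$x_min - area_dilation), min(w - 1L, f$x_max + area_dilation),
           max(0L, f$y_min - area_dilation), min(h - 1L, f$y_max + area_dilation))
    })
    names(st$areas) <- st$spot_labels
  } else {
    stopifnot(is.list(areas), !is.null(names(areas)),
              all(vapply(areas, inherits, logical(1), "rect")))
    st$areas <- areas
  }

  n <- nrow(ants)
  st$n_ants <- n
  st$ant_x <- as.integer(ants$x); st$ant_y <- as.integer(ants$y)
  st$ant_caste <- match(ants$caste, .CASTE_NAMES)
  st$ant_state <- match(ants$state, .STATE_NAMES)
  if (anyNA(st$ant_caste) || anyNA(st$ant_state))
    stop("ant caste must be MAJOR/MINOR and state SEARCH/RETURN/ALTRUISM")
  st$ant_carrying <- rep(FALSE, n)
  st$ant_cargo <- rep(NA_integer_, n)
  st$ant_hx <- integer(n); st$ant_hy <- integer(n)
  st$ant_chain <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    x <- st$ant_x[i]; y <- st$ant_y[i]
    if (x < 0L || x >= w || y < 0L || y >= h)
      stop(sprintf("ant %d placed outside the grid", i))
    li <- .li(x, y, st$W)
    on_ditch <- st$cls[li] == .CLS_DITCH
    if (st$ant_state[i] == .ALTRUISM) {
      if (!on_ditch) stop(sprintf("ant %d: ALTRUISM state requires a ditch cell", i))
      if (st$mem[li] != 0L) stop(sprintf("ant %d: ditch cell already holds a chain member", i))
      st$mem[li] <- i
    } else {
      if (on_ditch && st$mem[li] == 0L)
        stop(sprintf("ant %d: walker placed on an unbridged ditch cell", i))
      if (st$occ[li] != 0L) stop(sprintf("ant %d: cell already occupied", i))
      st$occ[li] <- i
    }
  }
  st$tick <- 0L
  st$clip_events <- 0L
  st$metrics <- list()
  st$ev <- list()
  class(st) <- "sim_state"
  .rebuild_chains_internal(st)
  .record_metrics(st)
  st
}

#' Deep-copy a simulation state
#'
#' `sim_state` objects have reference semantics; use this to snapshot one.
#' The copy is fully independent: the compiled engine mutates vectors in
#' place, so each value is duplicated rather than rebound.
#'
#' @param state A `"sim_state"`.
#' @return An independent copy.
#' @export
clone_state <- function(state) {
  st <- new.env(parent = emptyenv())
  for (nm in ls(state, all.names = TRUE))
    assign(nm, unserialize(serialize(get(nm, envir = state), NULL)), envir = st)
  class(st) <- "sim_state"
  st
}

#' Current environment of a simulation
#'
#' Returns the `grid_environment` with each spot's `remaining_food` updated
#' to the simulation's current value.
#'
#' @param state A `"sim_state"`.
#' @return A `"grid_environment"`.
#' @export
sim_environment <- function(state) {
  env <- state$env
  for (i in seq_along(env$spots)) env$spots[[i]]$remaining_food <- state$remaining[i]
  env
}

#' Ants as a data frame
#'
#' @param state A `"sim_state"`.
#' @return A data.frame with one row per ant: id, x, y, caste, state,
#'   carrying, chain id (NA outside the Altruism state).
#' @export
sim_ants <- function(state) {
  data.frame(id = seq_len(state$n_ants), x = state$ant_x, y = state$ant_y,
             caste = .CASTE_NAMES[state$ant_caste],
             state = .STATE_NAMES[state$ant_state],
             carrying = state$ant_carrying,
             chain = ifelse(is.na(state$ant_chain), NA_integer_,
                            state$chain_ids[state$ant_chain]))
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state '%s' tick %d: %d ants (%d Major/%d Minor)>\n",
              x$name, x$tick, x$n_ants, sum(x$ant_caste == .MAJOR),
              sum(x$ant_caste == .MINOR)))
  cat(sprintf("  states: %d SEARCH, %d RETURN, %d ALTRUISM in %d chain(s)\n",
              sum(x$ant_state == .SEARCH), sum(x$ant_state == .RETURN),
              sum(x$ant_state == .ALTRUISM), length(x$chain_sizes)))
  if (length(x$remaining))
    cat("  food remaining:", paste(sprintf("%s=%d", names(x$remaining), x$remaining),
                                   collapse = ", "),
        sprintf("| delivered %d\n", sum(x$delivered)))
  invisible(x)
}

#' Check all state invariants
#'
#' Verifies occupancy consistency (one walker per free cell, at most one
#' chain member plus one walker per ditch cell), state/caste coherence
#' (carrying implies Return; Altruism only on a ditch cell; a walker on a
#' ditch cell only over a chain member), and food
#' conservation (delivered + remaining + carried equals the initial stock).
#' Errors on the first violation.
#'
#' @param state A `"sim_state"`.
#' @return `TRUE` invisibly.
#' @export
validate_state <- function(state) {
  n <- state$n_ants
  occ_seen <- state$occ; occ_seen[occ_seen == -1L] <- 0L
  mem_seen <- state$mem
  occ_ids <- occ_seen[occ_seen > 0L]; mem_ids <- mem_seen[mem_seen > 0L]
  if (anyDuplicated(occ_ids) || anyDuplicated(mem_ids))
    stop("duplicate ant id in an occupancy layer")
  if (!setequal(c(occ_ids, mem_ids), seq_len(n)))
    stop("occupancy layers do not account for every ant exactly once")
  for (i in seq_len(n)) {
    li <- .li(state$ant_x[i], state$ant_y[i], state$W)
    alt <- state$ant_state[i] == .ALTRUISM
    if (alt && state$mem[li] != i) stop(sprintf("ant %d not registered as chain member", i))
    if (!alt && state$occ[li] != i) stop(sprintf("ant %d not registered as walker", i))
    on_ditch <- state$cls[li] == .CLS_DITCH
    if (alt && !on_ditch)
      stop(sprintf("ant %d: Altruism state requires a ditch cell", i))
    if (!alt && on_ditch && state$mem[li] == 0L)
      stop(sprintf("ant %d: walker on an unbridged ditch cell", i))
    if (state$ant_carrying[i] && state$ant_state[i] != .RETURN)
      stop(sprintf("ant %d carries food outside the Return state", i))
    if (alt != !is.na(state$ant_chain[i]))
      stop(sprintf("ant %d: chain membership must coincide with the Altruism state", i))
  }
  if (length(state$initial_food)) {
    total <- sum(state$delivered) + sum(state$remaining) + sum(state$ant_carrying)
    if (total != sum(state$initial_food))
      stop(sprintf("food not conserved: %d accounted vs %d initial",
                   total, sum(state$initial_food)))
  }
  invisible(TRUE)
}
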