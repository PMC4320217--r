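# Observation of runs: occupancy by area, bridge detection, group
# statistics and depletion order, plus the file outputs.

#' Count agents by occupancy area
#'
#' Areas default to each feeding spot's footprint dilated by 5 cells (set
#' at scenario construction).  Every ant is counted exactly once: nest
#' first, then the first matching area in label order, otherwise "other".
#'
#' @param state A `"sim_state"`.
#' @param areas Named list of [rect()]s; defaults to the state's.
#' @return Named integer vector: one count per area, then `nest`, `other`;
#'   sums to the total number of ants.
#' @export
agents_by_area <- function(state, areas = state$areas) {
  xs <- state$ant_x; ys <- state$ant_y
  lab <- rep("other", state$n_ants)
  for (a in rev(seq_along(areas))) lab[in_rect(xs, ys, areas[[a]])] <- names(areas)[a]
  if (!is.null(state$nest_rect)) lab[in_rect(xs, ys, state$nest_rect)] <- "nest"
  out <- vapply(c(names(areas), "nest", "other"), function(a) sum(lab == a), integer(1))
  out
}

#' Is a ditch actively bridged?
#'
#' TRUE when connected Altruism-state agents occupy ditch cells forming a
#' 1-Distance path whose endpoints are adjacent to non-ditch cells on the
#' two opposite sides of the ditch's short dimension (so a walker can cross).
#'
#' @param state A `"sim_state"`.
#' @param ditch One of the environment's bars: a [rect()], a bar name, or a
#'   bar index.
#' @return Logical flag.
#' @export
bridge_active <- function(state, ditch) {
  if (!inherits(ditch, "rect")) ditch <- state$env$bars[[ditch]]
  alt <- which(state$ant_state == .ALTRUISM)
  if (!length(alt)) return(FALSE)
  xs <- state$ant_x[alt]; ys <- state$ant_y[alt]
  inside <- in_rect(xs, ys, ditch)
  if (!any(inside)) return(FALSE)
  xs <- xs[inside]; ys <- ys[inside]
  short_x <- (ditch$x_max - ditch$x_min) <= (ditch$y_max - ditch$y_min)
  s <- if (short_x) xs else ys
  t <- if (short_x) ys else xs
  smin <- if (short_x) ditch$x_min else ditch$y_min
  smax <- if (short_x) ditch$x_max else ditch$y_max
  # cheap prefilter: a spanning path must touch both extreme lanes
  if (!any(s == smin) || !any(s == smax)) return(FALSE)
  # member adjacent (Chebyshev 1) to an in-bounds non-ditch cell beyond a side
  open_beyond <- function(k, side) {
    sv <- if (side == 1L) smin - 1L else smax + 1L
    for (dt in -1L:1L) {
      x <- if (short_x) sv else xs[k] + dt
      y <- if (short_x) ys[k] + dt else sv
      if (x >= 0L && x < state$w && y >= 0L && y < state$h &&
          state$cls[.li(x, y, state$W)] != .CLS_DITCH)
        return(TRUE)
    }
    FALSE
  }
  k <- length(s)
  start <- which(s == smin & vapply(seq_len(k), open_beyond, logical(1), side = 1L))
  goal <- which(s == smax & vapply(seq_len(k), open_beyond, logical(1), side = 2L))
  if (!length(start) || !length(goal)) return(FALSE)
  adj <- pmax(abs(outer(xs, xs, "-")), abs(outer(ys, ys, "-"))) <= 1L
  seen <- logical(k)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nb <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  any(seen[goal])
}

#' Spatial group statistics
#'
#' Groups are the connected components (Chebyshev adjacency at `radius`) of
#' agents currently outside the nest region, keeping components with at
#' least `min_size` members.
#'
#' @param state A `"sim_state"`.
#' @param radius Adjacency radius in Distances (>= 1).
#' @param min_size Minimum component size to count as a group (>= 2).
#' @return A list: `n_agent` (total ants), `n_group`, `n_agent_of_group`
#'   (mean group size, NA when no group), `n_others` (non-nest ants in no
#'   group), `sizes` (all component sizes).
#' @export
detect_groups <- function(state, radius = 2L, min_size = 10L) {
  stopifnot(radius >= 1L, min_size >= 2L)
  out_nest <- if (is.null(state$nest_rect)) rep(TRUE, state$n_ants)
  else !in_rect(state$ant_x, state$ant_y, state$nest_rect)
  idx <- which(out_nest)
  k <- length(idx)
  if (k == 0L)
    return(list(n_agent = state$n_ants, n_group = 0L, n_agent_of_group = NA_real_,
                n_others = 0L, sizes = integer(0)))
  xs <- state$ant_x[idx]; ys <- state$ant_y[idx]
  adj <- pmax(abs(outer(xs, xs, "-")), abs(outer(ys, ys, "-"))) <= radius
  comp <- integer(k); nc <- 0L
  for (a in seq_len(k)) if (comp[a] == 0L) {
    nc <- nc + 1L
    frontier <- a
    comp[a] <- nc
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & comp == 0L)
      comp[nb] <- nc
      frontier <- nb
    }
  }
  sizes <- tabulate(comp, nc)
  grp <- sizes >= min_size
  list(n_agent = state$n_ants,
       n_group = sum(grp),
       n_agent_of_group = if (any(grp)) mean(sizes[grp]) else NA_real_,
       n_others = sum(sizes[!grp]),
       sizes = sizes)
}

#' Order in which feeding spots were exhausted
#'
#' @param run A `"sim_run"` or its per-tick metrics data.frame.
#' @return Character vector of spot labels sorted by the tick at which
#'   `remaining_food` first reached 0; never-exhausted spots come last
#'   (tick sentinel `Inf`); ties break by label order.  The ticks are
#'   attached as attribute `"tick"`.
#' @export
depletion_order <- function(run) {
  metrics <- if (inherits(run, "sim_run")) run$metrics else run
  cols <- grep("^food_", names(metrics), value = TRUE)
  labels <- sub("^food_", "", cols)
  ticks <- vapply(cols, function(cc) {
    hit <- which(metrics[[cc]] == 0L)
    if (length(hit)) metrics$tick[hit[1L]] else Inf
  }, numeric(1))
  ord <- order(ticks, labels)
  structure(labels[ord], tick = unname(ticks[ord]))
}

#' Write run outputs to a directory
#'
#' Writes `metrics.csv` (one row per tick), `events.ndjson` (one state
#' transition per line) and `summary.json`.
#'
#' @param run A `"sim_run"`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(run, dir) {
  stopifnot(inherits(run, "sim_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(metrics = file.path(dir, "metrics.csv"),
             events = file.path(dir, "events.ndjson"),
             summary = file.path(dir, "summary.json"))
  utils::write.csv(run$metrics, paths[["metrics"]], row.names = FALSE)
  con <- file(paths[["events"]], open = "w")
  on.exit(close(con))
  if (nrow(run$events) > 0L)
    jsonlite::stream_out(run$events, con, verbose = FALSE)
  jsonlite::write_json(run$summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
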