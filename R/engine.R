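# Scenario construction and run orchestration.

.PRESETS <- local({
  ratios <- list(`1` = c(2L, 1L, 1L), `2` = c(1L, 2L, 1L),
                 `3` = c(1L, 1L, 2L), `4` = c(4L, 2L, 1L))
  out <- list()
  for (series in 1:2) for (v in 1:4)
    out[[sprintf("Env %d-%d", series, v)]] <-
      list(n_major = 3L, n_minor = if (series == 1L) 100L else 50L,
           ratio = ratios[[v]])
  out
})

#' Scenario presets
#'
#' The eight standard scenarios: series 1 uses 3 Major + 100 Minor ants,
#' series 2 uses 3 Major + 50 Minor ants; the A:B:C feeding-spot ratios are
#' 2:1:1, 1:2:1, 1:1:2 and 4:2:1.
#'
#' @return A data.frame with columns `name`, `n_major`, `n_minor`, `ratio`.
#' @export
scenario_presets <- function() {
  data.frame(name = names(.PRESETS),
             n_major = vapply(.PRESETS, `[[`, integer(1), "n_major"),
             n_minor = vapply(.PRESETS, `[[`, integer(1), "n_minor"),
             ratio = vapply(.PRESETS, function(p) paste(p$ratio, collapse = ":"),
                            character(1)),
             row.names = NULL)
}

#' Explicit scenario specification
#'
#' @param name Scenario label.
#' @param n_major,n_minor Agent counts (> 0 in total).
#' @param ratio Integer triple of A:B:C food proportions.
#' @param base_food_units Food units per ratio unit.
#' @param max_ticks Default run length.
#' @param seed RNG seed.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(name = "custom", n_major = 3L, n_minor = 50L,
                          ratio = c(2L, 1L, 1L), base_food_units = 100L,
                          max_ticks = 10000L, seed = 1L) {
  stopifnot(n_major >= 0L, n_minor >= 0L, n_major + n_minor > 0L,
            length(ratio) == 3L, all(ratio > 0L), base_food_units > 0L)
  structure(list(name = name, n_major = as.integer(n_major),
                 n_minor = as.integer(n_minor), ratio = as.integer(ratio),
                 base_food_units = as.integer(base_food_units),
                 max_ticks = as.integer(max_ticks), seed = as.integer(seed)),
            class = "scenario_spec")
}

.normalize_preset <- function(name) {
  key <- sub("^Env\\s*", "Env ", name)
  if (!grepl("^Env ", key)) key <- paste("Env", key)
  if (!key %in% names(.PRESETS))
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(names(.PRESETS), collapse = ", ")))
  key
}

#' Build a seeded initial simulation state
#'
#' Constructs the default 100 x 100 world, sizes each feeding spot as
#' `base_food_units` times its ratio component, places all ants in the
#' Search state on distinct random nest cells, and zeroes the pheromone
#' field.  The RNG is seeded here, so the same preset and seed always give
#' the same initial state and (absent outside RNG use) the same run.
#'
#' @param preset A preset name (see [scenario_presets()]) or a
#'   [scenario_spec()].
#' @param seed RNG seed (overrides the spec's).
#' @param base_food_units Food units per ratio unit.
#' @param max_ticks Default run length for [sim_run()].
#' @param pheromone A [pheromone_params()].
#' @param behavior A [behavior_params()].
#' @param engine `"cpp"` (compiled stepper, the default) or `"r"` (the pure-R
#'   reference stepper).  Both consume the random-number stream draw for
#'   draw, so a given preset and seed yield the identical trajectory under
#'   either engine.
#' @return A `"sim_state"`.
#' @examples
#' st <- make_scenario("Env 2-1", seed = 1, base_food_units = 10)
#' st
#' @export
make_scenario <- function(preset = "Env 1-1", seed = 1L,
                          base_food_units = 100L, max_ticks = 10000L,
                          pheromone = pheromone_params(),
                          behavior = behavior_params(),
                          engine = c("cpp", "r")) {
  if (inherits(preset, "scenario_spec")) {
    spec <- preset
    if (!missing(seed)) spec$seed <- as.integer(seed)
    if (!missing(base_food_units)) spec$base_food_units <- as.integer(base_food_units)
    if (!missing(max_ticks)) spec$max_ticks <- as.integer(max_ticks)
  } else {
    key <- .normalize_preset(preset)
    p <- .PRESETS[[key]]
    spec <- scenario_spec(name = key, n_major = p$n_major, n_minor = p$n_minor,
                          ratio = p$ratio, base_food_units = base_food_units,
                          max_ticks = max_ticks, seed = seed)
  }
  set.seed(spec$seed)
  food <- spec$base_food_units * spec$ratio
  env <- build_default_environment(default_spot_layout(
    c(A = food[1L], B = food[2L], C = food[3L])))
  n <- spec$n_major + spec$n_minor
  nest_cells <- rect_cells(env$nest)
  if (n > nrow(nest_cells)) stop("more ants than free nest cells")
  pick <- nest_cells[sample.int(nrow(nest_cells), n), , drop = FALSE]
  ants <- data.frame(x = pick[, 1L], y = pick[, 2L],
                     caste = rep(c("MAJOR", "MINOR"), c(spec$n_major, spec$n_minor)),
                     state = "SEARCH")
  new_sim_state(env, ants, pheromone = pheromone, behavior = behavior,
                seed = spec$seed, name = spec$name, max_ticks = spec$max_ticks,
                areas = default_areas(), engine = match.arg(engine))
}

.record_metrics <- function(state) {
  n <- state$n_ants
  xs <- state$ant_x; ys <- state$ant_y
  lab <- rep("other", n)
  for (a in rev(seq_along(state$areas))) {
    r <- state$areas[[a]]
    lab[in_rect(xs, ys, r)] <- names(state$areas)[a]
  }
  if (!is.null(state$nest_rect)) lab[in_rect(xs, ys, state$nest_rect)] <- "nest"
  area_counts <- vapply(names(state$areas), function(a) sum(lab == a), integer(1))
  bridges <- vapply(state$env$bars, function(b) bridge_active(state, b), logical(1))
  nm_pfx <- function(v, prefix, nms) {
    # paste0(prefix, NULL) has length 1, so guard the empty case
    stats::setNames(v, if (length(v)) paste0(prefix, nms) else character(0))
  }
  bar_names <- if (is.null(names(state$env$bars))) seq_along(state$env$bars)
  else names(state$env$bars)
  row <- c(tick = state$tick,
           nm_pfx(area_counts, "n_", names(state$areas)),
           n_nest = sum(lab == "nest"), n_other = sum(lab == "other"),
           nm_pfx(state$remaining, "food_", state$spot_labels),
           carried = sum(state$ant_carrying),
           delivered = sum(state$delivered),
           n_chains = length(state$chain_sizes),
           chain_max = if (length(state$chain_sizes)) max(state$chain_sizes) else 0L,
           ants_in_chains = sum(state$chain_sizes),
           nm_pfx(as.integer(bridges), "bridge_", bar_names))
  state$metrics[[length(state$metrics) + 1L]] <- row
  invisible(NULL)
}

#' Advance the simulation by one tick
#'
#' Agents act once each in a freshly shuffled order (deposits applied
#' immediately); chains are rebuilt; then the space layer diffuses and the
#' ground layer evaporates into it; finally a metrics row is recorded.
#' The state is modified in place.
#'
#' @param state A `"sim_state"`.
#' @return The state at tick + 1, invisibly.
#' @export
sim_step <- function(state) {
  state$tick <- state$tick + 1L
  n <- state$n_ants
  cpp <- identical(state$engine, "cpp")
  if (n > 0L) {
    if (cpp) {
      evm <- cpp_agents_tick(state)
      if (nrow(evm)) {
        base <- length(state$ev)
        for (r in seq_len(nrow(evm))) state$ev[[base + r]] <- evm[r, ]
      }
    } else {
      for (i in .shuffle(n)) {
        st <- state$ant_state[i]
        if (st == .SEARCH) search_step(state, i)
        else if (st == .RETURN) return_step(state, i)
        else altruism_step(state, i)
      }
    }
  }
  .rebuild_chains_internal(state)
  if (cpp) {
    state$clip_events <- state$clip_events + cpp_field_tick(state)
  } else {
    rows <- 3L:(state$w + 2L); cols <- 3L:(state$h + 2L)
    f <- structure(list(space = state$space[rows, cols],
                        ground = state$ground[rows, cols]),
                   class = "pheromone_field")
    f <- space_diffusion_step(f, state$pheromone)
    state$clip_events <- state$clip_events + attr(f, "clipped")
    f <- ground_space_exchange(f, state$pheromone)
    state$space[rows, cols] <- f$space
    state$ground[rows, cols] <- f$ground
  }
  .record_metrics(state)
  invisible(state)
}

.metrics_df <- function(state) {
  as.data.frame(do.call(rbind, state$metrics))
}

.events_df <- function(state) {
  if (!length(state$ev)) {
    return(data.frame(tick = integer(0), ant = integer(0), from = character(0),
                      to = character(0), x = integer(0), y = integer(0)))
  }
  m <- do.call(rbind, state$ev)
  data.frame(tick = m[, 1L], ant = m[, 2L], from = .STATE_NAMES[m[, 3L]],
             to = .STATE_NAMES[m[, 4L]], x = m[, 5L], y = m[, 6L])
}

#' Run a simulation to completion
#'
#' Iterates [sim_step()] until `max_ticks` is reached or (by default) every
#' feeding spot is exhausted and all cargo delivered.
#'
#' @param state A `"sim_state"` (modified in place).
#' @param max_ticks Tick budget; defaults to the scenario's.
#' @param stop_when_done Stop early once all food is delivered.
#' @param until Optional predicate `function(state)`; the run stops as soon
#'   as it returns `TRUE`.
#' @param observer Optional `function(state)` returning a numeric vector,
#'   called every `observe_every` ticks; rows are collected in
#'   `$observations`.
#' @param observe_every Observation interval in ticks.
#' @param snapshot_every,snapshot_dir Optionally dump both pheromone layers
#'   as plain-text matrices every so many ticks.
#' @return An object of class `"sim_run"`: list with `state`, `metrics`
#'   (one row per tick incl. tick 0), `events` (state transitions),
#'   `observations` and `summary`.
#' @export
sim_run <- function(state, max_ticks = NULL, stop_when_done = TRUE,
                    until = NULL, observer = NULL, observe_every = 25L,
                    snapshot_every = NULL, snapshot_dir = NULL) {
  if (is.null(max_ticks)) max_ticks <- state$max_ticks
  obs <- list()
  stopped <- "max_ticks"
  while (state$tick < max_ticks) {
    sim_step(state)
    if (!is.null(observer) && state$tick %% observe_every == 0L) {
      o <- observer(state)
      if (!is.null(o)) obs[[length(obs) + 1L]] <- o
    }
    if (!is.null(snapshot_every) && state$tick %% snapshot_every == 0L)
      .write_snapshot(state, snapshot_dir)
    if (stop_when_done && length(state$remaining) &&
        all(state$remaining == 0L) && !any(state$ant_carrying)) {
      stopped <- "all_food_delivered"
      break
    }
    if (!is.null(until) && isTRUE(until(state))) {
      stopped <- "until_condition"
      break
    }
  }
  metrics <- .metrics_df(state)
  res <- list(state = state, metrics = metrics, events = .events_df(state),
              observations = if (length(obs)) do.call(rbind, obs) else NULL,
              summary = list(name = state$name, seed = state$seed,
                             ticks = state$tick, stopped = stopped,
                             delivered = as.list(state$delivered),
                             remaining = as.list(state$remaining),
                             clip_events = state$clip_events,
                             n_ants = state$n_ants))
  class(res) <- "sim_run"
  res
}

#' @export
print.sim_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sim_run '%s' seed %s: %d ticks (%s), delivered %d/%d units>\n",
              s$name, s$seed, s$ticks, s$stopped,
              sum(unlist(s$delivered)),
              sum(unlist(s$delivered)) + sum(unlist(s$remaining))))
  invisible(x)
}

.write_snapshot <- function(state, dir) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- 3L:(state$w + 2L); cols <- 3L:(state$h + 2L)
  utils::write.table(state$space[rows, cols],
                     file.path(dir, sprintf("space_%06d.txt", state$tick)),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(state$ground[rows, cols],
                     file.path(dir, sprintf("ground_%06d.txt", state$tick)),
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Sweep colony sizes and summarise group formation
#'
#' Runs `trials` seeded simulations per Minor-ant count, observes spatial
#' group statistics every `observe_every` ticks while food remains, and
#' aggregates the modal group count per run into a table keyed by
#' (agents, groups).
#'
#' Trial seeds are derived from the master seed as
#' `master_seed + 1000 * count_index + trial`, so any single trial can be
#' reproduced in isolation.
#'
#' @param agent_counts Integer vector of Minor-ant counts.
#' @param trials Trials per count.
#' @param master_seed Master seed for the counter scheme.
#' @param n_major Major-ant count (default 3).
#' @param ratio A:B:C food ratio used for every run.
#' @param base_food_units Food units per ratio unit.
#' @param max_ticks Tick budget per run.
#' @param radius,min_size Group-detection parameters (see [detect_groups()]).
#' @param observe_every Observation interval in ticks.
#' @return A list with `runs` (one row per run: n_agent, seed, n_group,
#'   n_agent_of_group, n_others, delivered) and `table` (aggregate rows per
#'   observed (n_agent, n_group) combination).
#' @export
sweep_agents <- function(agent_counts, trials = 10L, master_seed = 1L,
                         n_major = 3L, ratio = c(2L, 1L, 1L),
                         base_food_units = 100L, max_ticks = 10000L,
                         radius = 2L, min_size = 10L, observe_every = 25L) {
  stopifnot(trials >= 1L)
  rows <- list()
  for (ci in seq_along(agent_counts)) {
    for (tr in seq_len(trials)) {
      seed <- master_seed + 1000L * ci + tr
      spec <- scenario_spec(name = sprintf("sweep-%d", agent_counts[ci]),
                            n_major = n_major, n_minor = agent_counts[ci],
                            ratio = ratio, base_food_units = base_food_units,
                            max_ticks = max_ticks, seed = seed)
      st <- make_scenario(spec)
      run <- sim_run(st, observer = function(s) {
        if (all(s$remaining == 0L)) return(NULL)
        g <- detect_groups(s, radius = radius, min_size = min_size)
        c(n_group = g$n_group,
          n_agent_of_group = if (is.na(g$n_agent_of_group)) 0 else g$n_agent_of_group,
          n_others = g$n_others)
      }, observe_every = observe_every)
      ob <- run$observations
      if (is.null(ob) || nrow(ob) == 0L) {
        ng <- 0L; nag <- NA_real_; no <- NA_real_
      } else {
        tab <- table(ob[, "n_group"])
        ng <- as.integer(names(tab)[which.max(tab)])
        sel <- ob[, "n_group"] == ng
        nag <- if (ng > 0L) mean(ob[sel, "n_agent_of_group"]) else NA_real_
        no <- mean(ob[sel, "n_others"])
      }
      rows[[length(rows) + 1L]] <-
        data.frame(n_agent = agent_counts[ci], seed = seed, n_group = ng,
                   n_agent_of_group = nag, n_others = no,
                   delivered = sum(st$delivered))
    }
  }
  runs <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(n_agent_of_group, n_others) ~ n_agent + n_group,
                          data = runs, FUN = mean, na.action = stats::na.pass)
  cnt <- stats::aggregate(seed ~ n_agent + n_group, data = runs, FUN = length)
  names(cnt)[3L] <- "trials"
  table <- merge(agg, cnt, by = c("n_agent", "n_group"))
  table <- table[order(table$n_agent, table$n_group), , drop = FALSE]
  rownames(table) <- NULL
  list(runs = runs, table = table)
}
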