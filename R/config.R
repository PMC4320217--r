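# YAML configuration: one file with sections scenario / environment /
# pheromone / behavior / output.  `scenario` may name a preset; an explicit
# `environment` section overrides the default world geometry.

.rect_to_list <- function(r) r[c("x_min", "x_max", "y_min", "y_max")]
.rect_from_list <- function(l) rect(l$x_min, l$x_max, l$y_min, l$y_max)

#' Write a scenario configuration file
#'
#' Emits a complete YAML configuration for a preset, including the default
#' world geometry and all model parameters, ready to edit and feed back to
#' [read_config()].
#'
#' @param preset Preset name (see [scenario_presets()]).
#' @param path Output file; `""` prints to stdout.
#' @param seed,base_food_units,max_ticks Scenario knobs.
#' @return The configuration list, invisibly.
#' @export
make_config <- function(preset = "Env 1-1", path = "", seed = 1L,
                        base_food_units = 100L, max_ticks = 10000L) {
  key <- .normalize_preset(preset)
  p <- .PRESETS[[key]]
  pp <- pheromone_params()
  bp <- behavior_params()
  food <- base_food_units * p$ratio
  env <- build_default_environment(default_spot_layout(
    c(A = food[1L], B = food[2L], C = food[3L])))
  cfg <- list(
    scenario = list(name = key, n_major = p$n_major, n_minor = p$n_minor,
                    ratio = as.integer(p$ratio),
                    base_food_units = as.integer(base_food_units),
                    max_ticks = as.integer(max_ticks), seed = as.integer(seed)),
    environment = list(
      width = env$width, height = env$height,
      bars = lapply(env$bars, .rect_to_list),
      nest = .rect_to_list(env$nest),
      spots = lapply(env$spots, function(s)
        c(list(label = s$label), .rect_to_list(s$footprint),
          list(food = s$initial_food)))),
    pheromone = pp[c("r_A", "r_B", "r_C", "r_e", "deposit_ground",
                     "diagonal_deposit_factor", "kernel", "floor")],
    behavior = c(bp[c("n", "alpha", "entry_mode", "model2_threshold",
                      "leave_rule", "minor_deposit_in_search",
                      "majors_join_chains")],
                 list(leave = unclass(bp$leave), enter = unclass(bp$enter),
                      exit = unclass(bp$exit))),
    output = list(dir = "out", snapshot_every = NULL))
  txt <- yaml::as.yaml(cfg)
  if (identical(path, "")) cat(txt) else writeLines(txt, path)
  invisible(cfg)
}

#' Read a configuration file and build the initial state
#'
#' @param path YAML file written by [make_config()] (possibly edited).
#' @param seed Optional seed override.
#' @return A `"sim_state"`.
#' @export
read_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  sc <- cfg$scenario
  if (is.null(sc)) stop("config lacks a 'scenario' section")
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  pp <- do.call(pheromone_params, cfg$pheromone %||% list())
  bsec <- cfg$behavior %||% list()
  bargs <- bsec[intersect(names(bsec),
                          c("n", "alpha", "entry_mode", "model2_threshold",
                            "leave_rule", "minor_deposit_in_search",
                            "majors_join_chains"))]
  if (!is.null(bsec$leave)) bargs$leave <- do.call(leave_model, bsec$leave)
  if (!is.null(bsec$enter)) bargs$enter <- do.call(chain_entry_model, bsec$enter)
  if (!is.null(bsec$exit)) bargs$exit <- do.call(chain_exit_model, bsec$exit)
  bp <- do.call(behavior_params, bargs)
  set.seed(sc$seed %||% 1L)
  if (!is.null(cfg$environment)) {
    es <- cfg$environment
    spots <- lapply(es$spots, function(s)
      feeding_spot(s$label, rect(s$x_min, s$x_max, s$y_min, s$y_max), s$food))
    env <- grid_environment(es$width, es$height,
                            bars = lapply(es$bars, .rect_from_list),
                            nest = if (is.null(es$nest)) NULL else .rect_from_list(es$nest),
                            spots = spots)
  } else {
    food <- (sc$base_food_units %||% 100L) * unlist(sc$ratio)
    env <- build_default_environment(default_spot_layout(
      c(A = food[1L], B = food[2L], C = food[3L])))
  }
  n <- (sc$n_major %||% 0L) + (sc$n_minor %||% 0L)
  nc <- rect_cells(env$nest)
  if (n > nrow(nc)) stop("more ants than free nest cells")
  pick <- nc[sample.int(nrow(nc), n), , drop = FALSE]
  ants <- data.frame(x = pick[, 1L], y = pick[, 2L],
                     caste = rep(c("MAJOR", "MINOR"),
                                 c(sc$n_major %||% 0L, sc$n_minor %||% 0L)),
                     state = "SEARCH")
  new_sim_state(env, ants, pheromone = pp, behavior = bp,
                seed = sc$seed %||% 1L, name = sc$name %||% "config",
                max_ticks = sc$max_ticks %||% 10000L,
                areas = if (is.null(cfg$environment)) default_areas())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
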