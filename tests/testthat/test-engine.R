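expect_same_trajectory <- function(a, b) {
  for (f in c("tick", "ant_x", "ant_y", "ant_state", "ant_carrying",
              "ant_cargo", "ant_hx", "ant_hy", "ant_chain", "chain_sizes",
              "chain_ids", "remaining", "delivered", "clip_events"))
    expect_identical(a[[f]], b[[f]], label = f, expected.label = f)
  expect_identical(a$occ, b$occ)
  expect_identical(a$mem, b$mem)
  expect_identical(a$space, b$space)
  expect_identical(a$ground, b$ground)
  expect_identical(a$ev, b$ev)
  expect_identical(a$metrics, b$metrics)
}

test_that("scenario presets match the standard table", {
  tab <- scenario_presets()
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$name, sprintf("Env %d-%d", rep(1:2, each = 4), 1:4))
  expect_true(all(tab$n_major == 3L))
  expect_equal(tab$n_minor, rep(c(100L, 50L), each = 4L))
  expect_equal(tab$ratio, rep(c("2:1:1", "1:2:1", "1:1:2", "4:2:1"), 2L))
  expect_error(make_scenario("Env 3-1"), "unknown preset")
})

test_that("make_scenario seeds food by ratio and places ants in the nest", {
  st <- make_scenario("Env 1-4", seed = 2, base_food_units = 10)
  expect_equal(st$n_ants, 103L)
  expect_equal(unname(st$remaining), c(40L, 20L, 10L))
  expect_equal(sum(st$ant_caste == bivouac:::.MAJOR), 3L)
  expect_true(all(bivouac:::in_rect(st$ant_x, st$ant_y, st$nest_rect)))
  expect_true(all(st$ant_state == bivouac:::.SEARCH))
  # distinct cells
  expect_false(anyDuplicated(cbind(st$ant_x, st$ant_y)) > 0)
  validate_state(st)
})

# Scenario construction seeds the global RNG and stepping consumes it, so
# each trajectory must be built *and* run before the next one starts.
run_corridor <- function(seed, engine, ticks = 150L, n_minor = 10L) {
  st <- corridor_world(20, n_minor = n_minor, seed = seed, engine = engine)
  for (i in seq_len(ticks)) sim_step(st)
  st
}

test_that("identical seeds give identical trajectories", {
  a <- run_corridor(7, "cpp", 120L, 6L)
  b <- run_corridor(7, "cpp", 120L, 6L)
  expect_same_trajectory(a, b)
  # and a different seed diverges
  d <- run_corridor(8, "cpp", 120L, 6L)
  expect_false(identical(a$ant_x, d$ant_x) && identical(a$ant_y, d$ant_y))
})

test_that("compiled and reference engines produce identical trajectories", {
  for (seed in c(1, 5)) {
    a <- run_corridor(seed, "cpp")
    b <- run_corridor(seed, "r")
    expect_same_trajectory(a, b)
  }
})

test_that("engines also agree on a full-scale scenario slice", {
  run_env <- function(engine) {
    st <- make_scenario("Env 2-3", seed = 3, base_food_units = 2,
                        engine = engine)
    for (i in 1:60) sim_step(st)
    st
  }
  expect_same_trajectory(run_env("cpp"), run_env("r"))
})

test_that("agents and food are conserved over a 500-tick run", {
  st <- make_scenario("Env 2-2", seed = 9, base_food_units = 2)
  for (i in 1:500) sim_step(st)
  validate_state(st)   # errors if occupancy or the food ledger drifts
  expect_equal(st$n_ants, 53L)
  expect_equal(sum(st$delivered) + sum(st$remaining) + sum(st$ant_carrying),
               sum(st$initial_food))
  # pheromone layers stay non-negative under the full engine too
  expect_true(all(st$space >= 0) && all(st$ground >= 0))
})

test_that("walkers and ditches stay mutually exclusive throughout a run", {
  st <- corridor_world(20, n_minor = 12, seed = 2, max_ticks = 300)
  for (i in 1:300) {
    sim_step(st)
    on_ditch <- st$cls[bivouac:::.li(st$ant_x, st$ant_y, st$W)] == bivouac:::.CLS_DITCH
    walker <- st$ant_state != bivouac:::.ALTRUISM
    bridged <- st$mem[bivouac:::.li(st$ant_x, st$ant_y, st$W)] > 0L
    expect_true(all(!walker | !on_ditch | bridged))
    expect_true(all(!(!walker) | on_ditch))    # members only on ditch cells
  }
})

test_that("sim_run stops when all food is delivered and reports it", {
  st <- corridor_world(12, ditch = FALSE, n_minor = 5, food = 2, seed = 1,
                       max_ticks = 3000)
  run <- sim_run(st)
  expect_s3_class(run, "sim_run")
  expect_equal(run$summary$stopped, "all_food_delivered")
  expect_equal(unname(unlist(run$summary$delivered)), 2L)
  expect_equal(nrow(run$metrics), st$tick + 1L)   # tick 0 row included
  expect_equal(run$metrics$tick, 0:st$tick)
})

test_that("sim_run honours an until-predicate and the observer hook", {
  st <- corridor_world(16, n_minor = 6, seed = 3, max_ticks = 500)
  run <- sim_run(st, stop_when_done = FALSE,
                 until = function(s) s$tick >= 40L,
                 observer = function(s) c(alt = sum(s$ant_state == 3L)),
                 observe_every = 10L)
  expect_equal(run$summary$stopped, "until_condition")
  expect_equal(run$state$tick, 40L)
  expect_equal(nrow(run$observations), 4L)
})

test_that("clone_state yields an independent deep copy", {
  st <- corridor_world(16, n_minor = 6, seed = 1)
  for (i in 1:20) sim_step(st)
  cp <- clone_state(st)
  expect_same_trajectory(st, cp)
  sim_step(st)
  expect_equal(cp$tick, st$tick - 1L)            # copy untouched
  # mutating the copy's matrices must not leak back into the original
  before <- st$occ
  cp$occ[1, 1] <- 99L
  expect_identical(st$occ, before)
})

test_that("sim_ants and sim_environment expose a consistent view", {
  st <- make_scenario("Env 2-1", seed = 4, base_food_units = 1)
  for (i in 1:50) sim_step(st)
  df <- sim_ants(st)
  expect_equal(nrow(df), 53L)
  expect_setequal(unique(df$caste), c("MAJOR", "MINOR"))
  expect_true(all(df$state %in% c("SEARCH", "RETURN", "ALTRUISM")))
  expect_true(all(is.na(df$chain) == (df$state != "ALTRUISM")))
  env <- sim_environment(st)
  expect_equal(vapply(env$spots, function(s) s$remaining_food, integer(1)),
               unname(st$remaining))
})
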