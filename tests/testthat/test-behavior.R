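# A small hand-built world used to exercise individual state-machine edges:
# 9x9, a 3x3 ditch in the middle, the nest in a corner, one food spot in
# the opposite corner.
tiny_world <- function(ants, food = 3L, n = 2L) {
  env <- grid_environment(9, 9, bars = list(d = rect(3, 5, 3, 5)),
                          nest = rect(0, 1, 0, 1),
                          spots = list(feeding_spot("A", rect(7, 7, 7, 7), food)))
  bivouac:::new_sim_state(env, ants, behavior = behavior_params(n = n),
                          seed = 1L, area_dilation = 1L, engine = "r")
}

test_that("pheromone_guided_move follows candidate levels proportionally", {
  set.seed(1)
  lv <- c(1, 0, 3)
  picks <- replicate(4000, pheromone_guided_move(c("a", "b", "c"), lv))
  tab <- table(factor(picks, levels = c("a", "b", "c")))
  expect_equal(unname(tab[["b"]]), 0L)          # zero level never chosen
  expect_equal(unname(tab[["c"]]) / 4000, 0.75, tolerance = 0.05)
  # all-zero levels fall back to uniform
  picks0 <- replicate(3000, pheromone_guided_move(1:3, c(0, 0, 0)))
  expect_gt(min(table(factor(picks0, levels = 1:3))), 800)
  # matrix candidates return the chosen row
  expect_equal(pheromone_guided_move(rbind(c(1, 2), c(3, 4)), c(0, 5)), c(3, 4))
  expect_error(pheromone_guided_move(1:3, c(1, -1, 0)))
})

test_that("a single candidate is chosen without consuming the RNG stream", {
  set.seed(99)
  before <- .Random.seed
  expect_equal(pheromone_guided_move(7, 0), 7)
  expect_identical(.Random.seed, before)
})

test_that("rebuild_chains labels connected components with sizes", {
  env <- build_default_environment()
  st <- chain_fixture(env, "leftbar", k = 3)
  ch <- rebuild_chains(st)
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$size, 3L)
  expect_setequal(ch[[1]]$members, 1:3)
  # diagonal contact still connects (Chebyshev adjacency)
  ants <- data.frame(x = c(3, 4, 5), y = c(3, 4, 5),
                     caste = "MINOR", state = "ALTRUISM")
  st2 <- tiny_world(ants)
  ch2 <- rebuild_chains(st2)
  expect_length(ch2, 1L)
  expect_equal(ch2[[1]]$size, 3L)
  # separated members form distinct singleton chains
  ants3 <- data.frame(x = c(3, 5), y = c(3, 5), caste = "MINOR",
                      state = "ALTRUISM")
  st3 <- tiny_world(ants3)
  ch3 <- rebuild_chains(st3)
  expect_length(ch3, 2L)
  expect_equal(vapply(ch3, `[[`, integer(1), "size"), c(1L, 1L))
})

test_that("Search -> Return on finding food within 1 Distance", {
  ants <- data.frame(x = 7, y = 6, caste = "MINOR", state = "SEARCH")
  st <- tiny_world(ants)
  search_step(st, 1L)
  expect_equal(st$ant_state[1], bivouac:::.RETURN)
  expect_true(st$ant_carrying[1])
  expect_equal(unname(st$remaining["A"]), 2L)
  ev <- bivouac:::.events_df(st)
  expect_equal(ev$from, "SEARCH")
  expect_equal(ev$to, "RETURN")
})

test_that("Majors never pick up food", {
  ants <- data.frame(x = 7, y = 6, caste = "MAJOR", state = "SEARCH")
  st <- tiny_world(ants)
  set.seed(5)
  search_step(st, 1L)
  expect_equal(st$ant_state[1], bivouac:::.SEARCH)
  expect_false(st$ant_carrying[1])
  expect_equal(unname(st$remaining["A"]), 3L)
})

test_that("Search -> Altruism next to a ditch when another walker is near", {
  ants <- data.frame(x = c(2, 2), y = c(4, 6), caste = "MINOR", state = "SEARCH")
  st <- tiny_world(ants)
  set.seed(3)
  search_step(st, 1L)
  expect_equal(st$ant_state[1], bivouac:::.ALTRUISM)
  expect_equal(classify_cell(st$env, c(st$ant_x[1], st$ant_y[1])), "DITCH")
  expect_equal(st$mem[bivouac:::.li(st$ant_x[1], st$ant_y[1], st$W)], 1L)
  expect_equal(st$occ[bivouac:::.li(2, 4, st$W)], 0L)
})

test_that("an isolated walker near a ditch keeps searching (Model 1)", {
  ants <- data.frame(x = 2, y = 4, caste = "MINOR", state = "SEARCH")
  st <- tiny_world(ants)
  set.seed(3)
  search_step(st, 1L)
  expect_equal(st$ant_state[1], bivouac:::.SEARCH)
})

test_that("Return -> Search on delivering at the nest", {
  ants <- data.frame(x = 0, y = 0, caste = "MINOR", state = "RETURN")
  st <- tiny_world(ants)
  st$ant_carrying[1] <- TRUE
  st$ant_cargo[1] <- 1L
  st$remaining["A"] <- st$remaining["A"] - 1L
  return_step(st, 1L)
  expect_equal(st$ant_state[1], bivouac:::.SEARCH)
  expect_false(st$ant_carrying[1])
  expect_equal(unname(st$delivered["A"]), 1L)
  validate_state(st)
})

test_that("a returning carrier on open ground moves strictly closer to the nest", {
  ants <- data.frame(x = 8, y = 0, caste = "MINOR", state = "RETURN")
  st <- tiny_world(ants)
  st$ant_carrying[1] <- TRUE
  st$ant_cargo[1] <- 1L
  st$remaining["A"] <- st$remaining["A"] - 1L
  d0 <- bivouac:::dist_to_rect(8, 0, st$nest_rect)
  set.seed(11)
  return_step(st, 1L)
  d1 <- bivouac:::dist_to_rect(st$ant_x[1], st$ant_y[1], st$nest_rect)
  expect_lt(d1, d0)
  # carriers deposit ground pheromone at the cell they moved to
  expect_equal(st$ground[bivouac:::.li(st$ant_x[1], st$ant_y[1], st$W)] > 0, TRUE)
})

test_that("an under-attended chain member leaves to a non-ditch cell", {
  # on the ditch edge so that open exit cells exist within 1 Distance
  ants <- data.frame(x = 3, y = 4, caste = "MINOR", state = "ALTRUISM")
  st <- tiny_world(ants)                      # others = 0 < n = 2
  set.seed(2)
  altruism_step(st, 1L)
  expect_equal(st$ant_state[1], bivouac:::.SEARCH)
  expect_false(classify_cell(st$env, c(st$ant_x[1], st$ant_y[1])) == "DITCH")
  validate_state(st)
})

test_that("a chain member with a walker on its back never leaves", {
  ants <- data.frame(x = c(3, 3), y = c(4, 4), caste = "MINOR",
                     state = c("ALTRUISM", "SEARCH"))
  st <- tiny_world(ants)
  set.seed(2)
  before <- .Random.seed
  altruism_step(st, 1L)
  expect_equal(st$ant_state[1], bivouac:::.ALTRUISM)
  expect_identical(.Random.seed, before)      # decision short-circuits, no draw
  validate_state(st)
})

test_that("is_traversable encodes walls, occupancy and bridges", {
  ants <- data.frame(x = c(4, 0), y = c(4, 8), caste = "MINOR",
                     state = c("ALTRUISM", "SEARCH"))
  st <- tiny_world(ants)
  expect_false(is_traversable(st, c(-1, 0)))   # out of bounds
  expect_false(is_traversable(st, c(3, 3)))    # unbridged ditch
  expect_true(is_traversable(st, c(4, 4)))     # bridged ditch cell
  expect_false(is_traversable(st, c(0, 8)))    # walker occupies it
  expect_true(is_traversable(st, c(0, 0)))     # free nest cell
})

test_that("every recorded transition is a legal state-machine edge", {
  st <- corridor_world(16, n_minor = 8, seed = 4, max_ticks = 400)
  run <- sim_run(st, stop_when_done = FALSE)
  ev <- run$events
  legal <- c("SEARCH>RETURN", "RETURN>SEARCH", "SEARCH>ALTRUISM",
             "ALTRUISM>SEARCH")
  expect_gt(nrow(ev), 0)
  expect_true(all(paste0(ev$from, ">", ev$to) %in% legal))
})
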