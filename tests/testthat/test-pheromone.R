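# Naive per-cell reimplementation of the diffusion update, used as an
# oracle against the vectorised space_diffusion_step().
naive_diffusion <- function(s, params) {
  w <- nrow(s); h <- ncol(s)
  at <- function(x, y) if (x >= 1 && x <= w && y >= 1 && y <= h) s[x, y] else 0
  out <- matrix(0, w, h)
  for (x in seq_len(w)) for (y in seq_len(h)) {
    orth <- at(x + 1, y) + at(x - 1, y) + at(x, y + 1) + at(x, y - 1)
    diag <- at(x + 1, y + 1) + at(x + 1, y - 1) + at(x - 1, y + 1) + at(x - 1, y - 1)
    v <- if (params$kernel == "laplacian")
      params$r_A * s[x, y] + params$r_B * (orth - 4 * s[x, y]) +
        params$r_C * (diag - 4 * s[x, y])
    else
      params$r_A * s[x, y] + params$r_B * orth + params$r_C * diag
    out[x, y] <- max(v, 0)
  }
  out
}

test_that("diffusion matches the naive per-cell oracle on random 12x12 fields", {
  set.seed(42)
  for (kernel in c("laplacian", "conservative")) {
    pp <- pheromone_params(kernel = kernel)
    for (rep in 1:5) {
      s <- matrix(runif(144, 0, 10), 12, 12)
      f <- pheromone_field(12, 12, space = s)
      f2 <- space_diffusion_step(f, pp)
      expect_equal(f2$space, naive_diffusion(s, pp), tolerance = 1e-12)
    }
  }
})

test_that("uniform interior field contracts by exactly r_A", {
  pp <- pheromone_params()
  s <- matrix(3.7, 10, 10)
  f2 <- space_diffusion_step(pheromone_field(10, 10, space = s), pp)
  interior <- f2$space[3:8, 3:8]
  expect_true(all(interior == pp$r_A * 3.7))
})

test_that("one exchange moves exactly r_e of the ground layer to space", {
  pp <- pheromone_params()
  f <- point_mass_field(8, 8, c(3, 4), 2.0, layer = "ground")
  f2 <- ground_space_exchange(f, pp)
  expect_equal(f2$space[4, 5], pp$r_e * 2.0)
  expect_equal(f2$ground[4, 5], 2.0 - pp$r_e * 2.0)
  expect_equal(sum(f2$space) + sum(f2$ground), 2.0)
})

test_that("ground layer decays geometrically as (1 - r_e)^t", {
  pp <- pheromone_params(floor = 0)
  f <- point_mass_field(6, 6, c(2, 2), 1.0, layer = "ground")
  for (t in 1:40) {
    f <- ground_space_exchange(f, pp)
    expect_equal(f$ground[3, 3], (1 - pp$r_e)^t, tolerance = 1e-12)
  }
})

test_that("both layers stay non-negative through long mixed evolution", {
  set.seed(7)
  for (kernel in c("laplacian", "conservative")) {
    pp <- pheromone_params(kernel = kernel)
    f <- pheromone_field(10, 10, space = matrix(runif(100, 0, 5), 10, 10),
                         ground = matrix(runif(100, 0, 5), 10, 10))
    for (t in 1:200) {
      f <- space_diffusion_step(f, pp)
      f <- ground_space_exchange(f, pp)
      f <- deposit(f, c(sample.int(10, 1) - 1L, sample.int(10, 1) - 1L), pp,
                   moved_diagonally = t %% 2L == 0L)
      expect_true(all(f$space >= 0))
      expect_true(all(f$ground >= 0))
    }
  }
})

test_that("conservative kernel conserves interior mass", {
  # defaults satisfy r_A + 4 r_B + 4 r_C = 1, so a point mass far from the
  # edge diffuses without loss
  pp <- pheromone_params(kernel = "conservative")
  expect_equal(pp$r_A + 4 * pp$r_B + 4 * pp$r_C, 1.0)
  f <- point_mass_field(21, 21, c(10, 10), 5.0, layer = "space")
  for (t in 1:5) f <- space_diffusion_step(f, pp)
  expect_equal(sum(f$space), 5.0, tolerance = 1e-12)
})

test_that("deposit adds to the ground layer, halved on diagonal moves", {
  pp <- pheromone_params()
  f <- pheromone_field(5, 5)
  f <- deposit(f, c(2, 3), pp)
  expect_equal(f$ground[3, 4], 1.0)
  f <- deposit(f, c(2, 3), pp, moved_diagonally = TRUE)
  expect_equal(f$ground[3, 4], 1.5)
  expect_equal(unname(total_pheromone(f)["ground"]), 1.5)
})

test_that("sub-floor residues flush to exact zero", {
  pp <- pheromone_params(floor = 1e-6)
  f <- pheromone_field(4, 4, ground = matrix(1e-7, 4, 4))
  f <- ground_space_exchange(f, pp)
  expect_true(all(f$ground == 0))
  expect_true(all(f$space == 0))
})

test_that("pheromone parameter validation rejects bad rates", {
  expect_error(pheromone_params(r_A = 1.2), "\\[0, 1\\]")
  expect_error(pheromone_params(r_e = -0.1), "\\[0, 1\\]")
  expect_error(pheromone_params(deposit_ground = -1), "non-negative")
  expect_error(pheromone_params(diagonal_deposit_factor = 0), "\\(0, 1\\]")
  expect_error(pheromone_params(floor = -1), "non-negative")
  expect_error(pheromone_field(3, 3, space = matrix(-1, 3, 3)), "non-negative")
})
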