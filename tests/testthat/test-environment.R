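# Component labelling of non-ditch cells over 8-connected adjacency,
# restricted to a band of rows; used to check the ditch partition.
band_components <- function(env, y_min, y_max) {
  open <- env$cls[, (y_min:y_max) + 1L] != bivouac:::.CLS_DITCH
  w <- nrow(open); h <- ncol(open)
  comp <- matrix(0L, w, h)
  nc <- 0L
  for (sx in seq_len(w)) for (sy in seq_len(h)) {
    if (!open[sx, sy] || comp[sx, sy] > 0L) next
    nc <- nc + 1L
    frontier <- matrix(c(sx, sy), 1L)
    comp[sx, sy] <- nc
    while (nrow(frontier) > 0L) {
      nxt <- NULL
      for (k in seq_len(8L)) {
        xs <- frontier[, 1L] + OFF1[k, 1L]
        ys <- frontier[, 2L] + OFF1[k, 2L]
        ok <- xs >= 1L & xs <= w & ys >= 1L & ys <= h
        xs <- xs[ok]; ys <- ys[ok]
        if (!length(xs)) next
        idx <- cbind(xs, ys)
        new <- open[idx] & comp[idx] == 0L
        if (any(new)) {
          comp[idx[new, , drop = FALSE]] <- nc
          nxt <- rbind(nxt, cbind(xs[new], ys[new]))
        }
      }
      frontier <- if (is.null(nxt)) matrix(integer(), ncol = 2L) else unique(nxt)
    }
  }
  nc
}

test_that("default world is 100x100 with three 3-cell-wide ditches", {
  env <- build_default_environment()
  expect_equal(env$width, 100L)
  expect_equal(env$height, 100L)
  expect_equal(length(env$bars), 3L)
  expect_named(env$bars, c("leftbar", "rightbar", "centerbar"))
  widths <- vapply(env$bars, function(b)
    min(b$x_max - b$x_min + 1L, b$y_max - b$y_min + 1L), integer(1))
  expect_true(all(widths == 3L))
})

test_that("ditches partition the side-barred band into three parts", {
  env <- build_default_environment()
  expect_equal(band_components(env, 30L, 69L), 3L)
  expect_equal(band_components(env, 70L, 72L), 2L)
})

test_that("every feeding spot is reachable from the nest by a detour", {
  env <- build_default_environment()
  seen <- reachable_cells(env, c(50, 50))
  for (s in env$spots) {
    f <- s$footprint
    expect_true(seen[f$x_min + 1L, f$y_min + 1L], label = paste("spot", s$label))
  }
  # but no ditch cell is ever reachable
  expect_false(any(seen[env$cls == bivouac:::.CLS_DITCH]))
})

test_that("classify_cell distinguishes all four classes", {
  env <- build_default_environment(default_spot_layout(c(A = 2L, B = 1L, C = 1L)))
  expect_equal(classify_cell(env, c(31, 50)), "DITCH")
  expect_equal(classify_cell(env, c(50, 50)), "NEST")
  expect_equal(classify_cell(env, c(50, 82)), "FOOD")
  expect_equal(classify_cell(env, c(0, 0)), "OPEN")
  expect_error(classify_cell(env, c(-1, 0)), "outside")
  expect_error(classify_cell(env, c(100, 0)), "outside")
})

test_that("a depleted spot stops classifying as FOOD", {
  env <- build_default_environment(default_spot_layout(c(A = 0L, B = 1L, C = 1L)))
  expect_equal(classify_cell(env, c(50, 82)), "OPEN")
})

test_that("cell class counts cover the grid exactly", {
  env <- build_default_environment()
  counts <- cell_class_counts(env)
  expect_equal(sum(counts), 100L * 100L)
  # three bars: 2 * 3*40 + 43*3 cells
  expect_equal(unname(counts["DITCH"]), 2L * 120L + 129L)
  expect_equal(unname(counts["NEST"]), 37L * 40L)
  expect_equal(unname(counts["FOOD"]), 3L * 36L)
})

test_that("grid_environment rejects overlapping or out-of-bounds regions", {
  expect_error(grid_environment(10, 10, bars = list(rect(8, 12, 0, 2))),
               "outside")
  expect_error(grid_environment(10, 10, bars = list(rect(0, 2, 0, 2)),
                                nest = rect(1, 3, 1, 3)),
               "nest overlaps a ditch")
  expect_error(grid_environment(10, 10, bars = list(rect(0, 2, 0, 2)),
                                spots = list(feeding_spot("A", rect(2, 4, 0, 1), 5))),
               "overlaps a ditch")
  expect_error(grid_environment(10, 10, nest = rect(0, 4, 0, 4),
                                spots = list(feeding_spot("A", rect(3, 5, 3, 5), 5))),
               "overlaps the nest")
  expect_error(grid_environment(
    10, 10, spots = list(feeding_spot("A", rect(0, 2, 0, 2), 5),
                         feeding_spot("B", rect(2, 4, 2, 4), 5))),
    "overlaps another spot")
})

test_that("default areas cover each region plus its fronting ditch", {
  areas <- default_areas()
  expect_named(areas, c("A", "B", "C"))
  env <- build_default_environment()
  for (a in areas) expect_false(bivouac:::rects_overlap(a, env$nest))
  # each area contains its own ditch band (chain members on a bridge count
  # as occupying the area they bridge toward)
  expect_true(bivouac:::rects_overlap(areas$A, env$bars$centerbar))
  expect_true(bivouac:::rects_overlap(areas$B, env$bars$leftbar))
  expect_true(bivouac:::rects_overlap(areas$C, env$bars$rightbar))
  # each spot footprint lies inside its area
  for (s in env$spots) {
    a <- areas[[s$label]]
    f <- s$footprint
    expect_true(f$x_min >= a$x_min && f$x_max <= a$x_max &&
                  f$y_min >= a$y_min && f$y_max <= a$y_max)
  }
  # a chain member planted on each bar is attributed to the matching area
  for (pair in list(c("centerbar", "A"), c("leftbar", "B"),
                    c("rightbar", "C"))) {
    st <- chain_fixture(env, pair[1], k = 1)
    counts <- agents_by_area(st, areas)
    expect_equal(unname(counts[pair[2]]), 1L)
  }
})

test_that("feeding_spot validates its arguments", {
  expect_error(feeding_spot("A", rect(0, 1, 0, 1), -1))
  s <- feeding_spot("A", rect(0, 1, 0, 1), 7)
  expect_equal(s$remaining_food, 7L)
  expect_equal(s$initial_food, 7L)
})
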