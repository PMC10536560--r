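test_that("nearest resampling is exact for a constant field", {
  g <- toy_grid(matrix(3.7, 4, 4), dx = 500)
  tgt <- list(nrow = 2L, ncol = 2L, xmin = 0, ymax = 2000,
              dx = 1000, dy = 1000)
  r <- resample_nearest(g, tgt)
  expect_equal(r$values, matrix(3.7, 2, 2))
})

test_that("nearest resampling matches the brute-force nearest-center oracle", {
  g <- toy_grid(matrix(1:16, 4, 4, byrow = TRUE), dx = 500)
  tgt <- list(nrow = 2L, ncol = 2L, xmin = 0, ymax = 2000,
              dx = 1000, dy = 1000)
  expect_equal(resample_nearest(g, tgt)$values, brute_nearest(g, tgt))

  # assorted geometries: upsampling, downsampling, offset sub-windows
  set.seed(11)
  for (case in 1:6) {
    nr <- sample(3:7, 1); nc <- sample(3:7, 1)
    src <- toy_grid(matrix(runif(nr * nc), nr, nc), dx = 300)
    tgt <- list(nrow = sample(2:9, 1), ncol = sample(2:9, 1),
                xmin = runif(1, -200, 400), ymax = nr * 300 - runif(1, -300, 300),
                dx = runif(1, 100, 700), dy = runif(1, 100, 700))
    expect_equal(resample_nearest(src, tgt)$values, brute_nearest(src, tgt),
                 info = paste("case", case))
  }
})

test_that("nearest resampling propagates nodata and never invents values", {
  v <- matrix(runif(36), 6, 6)
  v[sample(36, 10)] <- NA
  g <- toy_grid(v, dx = 500)
  tgt <- list(nrow = 4L, ncol = 4L, xmin = 0, ymax = 3000, dx = 750, dy = 750)
  r <- resample_nearest(g, tgt)
  expect_true(all(r$values %in% c(v, NA)))

  allna <- toy_grid(matrix(NA_real_, 4, 4), dx = 500)
  expect_true(all(is.na(resample_nearest(allna, tgt)$values)))
})

test_that("nearest resampling rejects disjoint extents and crs mismatch", {
  g <- toy_grid(matrix(1, 4, 4), dx = 500)
  far <- list(nrow = 2L, ncol = 2L, xmin = 1e6, ymax = 1e6, dx = 500, dy = 500)
  expect_error(resample_nearest(g, far), "overlap")
  other <- list(nrow = 2L, ncol = 2L, xmin = 0, ymax = 2000,
                dx = 1000, dy = 1000, crs = "EPSG:4326")
  expect_error(resample_nearest(g, other), "crs mismatch")
})

test_that("maximum value composite takes the valid per-pixel maximum", {
  g1 <- toy_grid(matrix(c(1, NA, NA, 5), 2, 2))
  g2 <- toy_grid(matrix(c(3, 0.4, NA, 2), 2, 2))
  g3 <- toy_grid(matrix(c(2, NA, NA, 9), 2, 2))
  st <- grid_stack(list(g1, g2, g3), year = 2016L)
  mvc <- max_value_composite(st)
  expect_equal(mvc$values, matrix(c(3, 0.4, NA, 9), 2, 2))

  one <- grid_stack(list(g2), year = 2016L)
  expect_identical(max_value_composite(one)$values, g2$values)
})

test_that("composite is permutation-invariant and idempotent", {
  set.seed(4)
  slices <- lapply(1:5, function(i) {
    v <- matrix(runif(20), 4, 5)
    v[sample(20, 4)] <- NA
    toy_grid(v)
  })
  a <- max_value_composite(grid_stack(slices))
  b <- max_value_composite(grid_stack(slices[c(3, 1, 5, 2, 4)]))
  expect_identical(a$values, b$values)
  again <- max_value_composite(grid_stack(list(a)))
  expect_identical(again$values, a$values)
})

test_that("stack construction validates geometry and timestamps", {
  g <- toy_grid(matrix(1, 2, 2))
  h <- toy_grid(matrix(1, 3, 2))
  expect_error(grid_stack(list(g, h)), "not aligned")
  expect_error(grid_stack(list(g, g), timestamps = c(2, 1)),
               "strictly increasing")
})

test_that("stack manifests round-trip through YAML + ASCII grids", {
  set.seed(9)
  slices <- lapply(1:3, function(i) toy_grid(matrix(runif(16), 4, 4)))
  st <- grid_stack(slices, timestamps = c(1, 2, 3), year = 2020L)
  d <- withr::local_tempdir()
  mp <- write_stack_manifest(st, d, "fvc_2020")
  st2 <- read_stack_manifest(mp)
  expect_equal(length(st2$slices), 3L)
  expect_identical(st2$year, 2020L)
  for (i in 1:3)
    expect_identical(st2$slices[[i]]$values, st$slices[[i]]$values)
})
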