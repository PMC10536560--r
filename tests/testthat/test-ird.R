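# one zone, one type over a 10 x 10 grid -> a single stratum
one_stratum <- function(values) {
  g <- toy_grid(values)
  st <- build_strata(grid_like(g, matrix(1, nrow(values), ncol(values))),
                     grid_like(g, matrix(1, nrow(values), ncol(values))))
  list(grid = g, strata = st)
}

test_that("reference values are stratum maxima (or percentiles)", {
  s <- one_stratum(matrix(c(0.2, 0.5, 0.9, rep(0.3, 97)), 10, 10))
  refs <- compute_reference(s$grid, s$strata)
  expect_equal(refs$reference, 0.9)

  single <- one_stratum(matrix(0.42, 1, 1))
  expect_equal(compute_reference(single$grid, single$strata)$reference, 0.42)

  # upper percentile against an independent sort-based computation (type 7)
  set.seed(3)
  vals <- runif(100)
  s2 <- one_stratum(matrix(vals, 10, 10))
  refs2 <- compute_reference(s2$grid, s2$strata, method = "percentile",
                             q = 0.95)
  xs <- sort(vals)
  h <- (100 - 1) * 0.95
  manual <- xs[floor(h) + 1] + (h - floor(h)) * (xs[floor(h) + 2] - xs[floor(h) + 1])
  expect_equal(refs2$reference, manual)
})

test_that("non-positive references are an error naming the stratum", {
  s <- one_stratum(matrix(0, 2, 2))
  expect_error(compute_reference(s$grid, s$strata),
               "non-positive reference.*zone, type")
})

test_that("relative density is the ratio to the stratum reference", {
  s <- one_stratum(matrix(c(0.3, 0, 0.6, 0.15), 2, 2))
  refs <- compute_reference(s$grid, s$strata)
  ird <- compute_ird(s$grid, s$strata, refs)
  expect_equal(ird$values, matrix(c(0.5, 0, 1, 0.25), 2, 2))
})

test_that("IRD lies in [0,1], attains 1 per stratum, and is scale-free", {
  set.seed(21)
  z <- matrix(sample(1:3, 400, TRUE), 20, 20)
  t <- matrix(sample(1:2, 400, TRUE), 20, 20)
  st <- build_strata(toy_grid(z), toy_grid(t))
  f <- toy_grid(matrix(runif(400, 0.1, 5), 20, 20))
  refs <- compute_reference(f, st)
  ird <- compute_ird(f, st, refs)
  expect_true(all(ird$values >= 0 & ird$values <= 1, na.rm = TRUE))
  for (code in st$legend$code)
    expect_equal(max(ird$values[st$codes == code]), 1)

  # multiplying an indicator by a positive scalar within a stratum leaves
  # that stratum's IRD unchanged
  f2v <- f$values
  f2v[st$codes == 2L] <- f2v[st$codes == 2L] * 37.5
  f2 <- grid_like(f, f2v)
  ird2 <- compute_ird(f2, st, compute_reference(f2, st))
  expect_equal(ird2$values[st$codes == 2L], ird$values[st$codes == 2L])
})

test_that("a stratum without a reference entry is an error", {
  s <- one_stratum(matrix(runif(9, 0.1, 1), 3, 3))
  refs <- compute_reference(s$grid, s$strata)
  refs2 <- refs[refs$code != 1L, ]
  class(refs2) <- class(refs)
  expect_error(compute_ird(s$grid, s$strata, refs2), "no reference")
})

test_that("z-scores use the population standard deviation", {
  g <- toy_grid(matrix(c(1, 2, 3), 1, 3))
  z <- standardize(g)
  expect_equal(z$grid$values, matrix(c(-1, 0, 1) * sqrt(3 / 2), 1, 3),
               tolerance = 1e-12)
  expect_equal(z$params$sd, sqrt(2 / 3))
})

test_that("re-estimated z-scores have mean 0 and sd 1 to 1e-10", {
  set.seed(13)
  v <- matrix(rexp(500), 20, 25)
  v[sample(500, 40)] <- NA
  z <- standardize(toy_grid(v))$grid$values
  n <- sum(!is.na(z))
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-10)
  expect_lt(abs(sqrt(sum(z^2, na.rm = TRUE) / n) - 1), 1e-10)
})

test_that("stored parameters reapply bit-identically and invert", {
  set.seed(14)
  g <- toy_grid(matrix(rnorm(100, 5, 2), 10, 10))
  first <- standardize(g)
  again <- standardize(g, first$params)
  expect_identical(again$grid$values, first$grid$values)

  # applying one epoch's parameters to different data shifts the mean
  g2 <- toy_grid(matrix(rnorm(100, 7, 2), 10, 10))
  cross <- standardize(g2, first$params)
  expect_gt(abs(mean(cross$grid$values)), 0.1)

  back <- unstandardize(first$grid, first$params)
  expect_equal(back$values, g$values, tolerance = 1e-10)
})

test_that("degenerate standardization inputs are rejected", {
  expect_error(standardize(toy_grid(matrix(5, 3, 3))), "zero variance")
  expect_error(standardize(toy_grid(matrix(c(1, NA, NA, NA), 2, 2))),
               "fewer than 2")
})
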