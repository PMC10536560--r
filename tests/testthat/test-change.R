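test_that("the difference grid is element-wise year2 minus year1", {
  set.seed(3)
  v1 <- matrix(rnorm(100), 10, 10); v1[c(4, 40)] <- NA
  v2 <- matrix(rnorm(100), 10, 10); v2[c(40, 77)] <- NA
  g1 <- toy_grid(v1); g2 <- toy_grid(v2)
  d <- delta_eqi(g1, g2)
  expect_equal(d$values, v2 - v1)                  # subtraction oracle
  expect_identical(is.na(d$values), is.na(v1) | is.na(v2))

  expect_equal(delta_eqi(g1, g1)$values, matrix(0, 10, 10) + v1 * 0)
  shifted <- grid_like(g1, v1 + 0.1)
  expect_equal(delta_eqi(g1, shifted)$values,
               matrix(0.1, 10, 10) + v1 * 0)

  expect_error(delta_eqi(g1, toy_grid(matrix(0, 9, 10))), "not aligned")
})

test_that("change significance uses the printed boundary conventions", {
  d <- toy_grid(matrix(c(0.05, -0.05, 0, 0.0501, -0.0501, 1), 2, 3))
  cls <- classify_change(d)
  lv <- attr(cls, "levels")
  expect_equal(lv[cls$values[1, 1]], "no_change")  # 0.05 -> no change
  expect_equal(lv[cls$values[2, 1]], "decreased")  # -0.05 -> decreased
  expect_equal(lv[cls$values[1, 2]], "no_change")  # center
  expect_equal(lv[cls$values[2, 2]], "increased")
  expect_equal(lv[cls$values[1, 3]], "decreased")
  expect_equal(lv[cls$values[2, 3]], "increased")

  expect_error(classify_change(d, thresholds = c(0.05, -0.05)),
               "lower < upper")
})

test_that("negating the difference swaps increased and decreased exactly", {
  set.seed(19)
  d <- toy_grid(matrix(rnorm(400, 0, 0.1), 20, 20))
  a <- classify_change(d)$values
  b <- classify_change(grid_like(d, -d$values))$values
  expect_equal(sum(a == 3), sum(b == 1))
  expect_equal(sum(a == 1), sum(b == 3))
  expect_equal(sum(a == 2), sum(b == 2))
})

planted_setup <- function() {
  # 10 x 10, one zone/type; planted counts 30 increased, 60 no-change,
  # 10 decreased
  v <- c(rep(0.2, 30), rep(0, 60), rep(-0.2, 10))
  d <- toy_grid(matrix(v, 10, 10))
  st <- build_strata(toy_grid(matrix(1, 10, 10)),
                     toy_grid(matrix(1, 10, 10)))
  list(d = d, st = st)
}

test_that("area shares equal an exhaustive pixel tally", {
  p <- planted_setup()
  tabs <- summarize_classes(classify_change(p$d), p$st)
  tot <- tabs$total
  expect_equal(tot$percent_of_total[match(c("decreased", "no_change", "increased"),
                                          tot$class)],
               c(10, 60, 30))
  expect_equal(sum(tot$percent_of_total), 100, tolerance = 1e-6)
})

test_that("single-class grids give a 100/0/0 share split", {
  st <- planted_setup()$st
  allup <- classify_change(toy_grid(matrix(1, 10, 10)))
  tot <- summarize_classes(allup, st)$total
  expect_equal(tot$percent_of_total[tot$class == "increased"], 100)
  expect_equal(sum(tot$percent_of_total[tot$class != "increased"]), 0)
})

test_that("within-group shares sum to 100 and zones add up to the total", {
  set.seed(29)
  z <- matrix(sample(1:4, 900, TRUE), 30, 30)
  t <- matrix(sample(1:3, 900, TRUE), 30, 30)
  st <- build_strata(toy_grid(z), toy_grid(t))
  d <- toy_grid(matrix(rnorm(900, 0, 0.08), 30, 30))
  tabs <- summarize_classes(classify_change(d), st)

  bz <- tabs$by_zone
  for (zz in unique(bz$zone))
    expect_equal(sum(bz$percent_within[bz$zone == zz]), 100,
                 tolerance = 1e-6)
  # additivity: zone class areas sum to the study-area class totals
  for (cl in CHANGE_CLASSES)
    expect_equal(sum(bz$n_pixels[bz$class == cl]),
                 tabs$total$n_pixels[tabs$total$class == cl])
})

test_that("self-comparison yields 100% no-change end to end", {
  set.seed(37)
  g <- toy_grid(matrix(rnorm(400), 20, 20))
  st <- build_strata(toy_grid(matrix(1, 20, 20)),
                     toy_grid(matrix(1, 20, 20)))
  ch <- change_analysis(g, g, st)
  tot <- ch$tables$total
  expect_equal(tot$percent_of_total[tot$class == "no_change"], 100)
})

test_that("cosine area weighting uses the row-center latitude", {
  # two rows at latitudes 60 and 0 degrees: weights 0.5 and 1
  g <- eqi_grid(matrix(c(1, 1), 2, 1), xmin = 0, ymax = 90, dx = 30, dy = 60,
                crs = "geographic")
  d <- grid_like(g, matrix(c(1, -1), 2, 1))    # increased / decreased
  st <- build_strata(grid_like(g, matrix(1, 2, 1)),
                     grid_like(g, matrix(1, 2, 1)))
  tot <- summarize_classes(classify_change(d), st, weighting = "cosine")$total
  w_north <- cos(60 * pi / 180); w_south <- cos(0)
  expect_equal(tot$percent_of_total[tot$class == "increased"],
               100 * w_north / (w_north + w_south))
})
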