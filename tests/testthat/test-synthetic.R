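test_that("scenarios are bit-identical under a fixed seed", {
  a <- small_scenario(seed = 5L)
  b <- small_scenario(seed = 5L)
  expect_identical(a$indicators$lai[["2016"]]$slices[[2]]$values,
                   b$indicators$lai[["2016"]]$slices[[2]]$values)
  expect_identical(a$indicators$gpp[["2020"]]$slices[[4]]$values,
                   b$indicators$gpp[["2020"]]$slices[[4]]$values)
  expect_identical(a$zones$values, b$zones$values)
  c2 <- small_scenario(seed = 6L)
  expect_false(identical(a$zones$values, c2$zones$values))
})

test_that("generated layers are aligned, nonnegative and fully stratified", {
  scn <- small_scenario(seed = 2L)
  expect_true(assert_aligned(list(scn$zones, scn$lulc[["2016"]])))
  # FVC/GPP are generated at half the cell size, on the same extent
  expect_equal(scn$indicators$fvc[["2016"]]$slices[[1]]$dx, scn$zones$dx / 2)

  for (ind in scn$indicators)
    for (st in ind)
      for (s in st$slices)
        expect_true(all(s$values >= 0, na.rm = TRUE))

  # every stratum that the pipeline will see is non-empty
  eco <- reclassify_lulc(scn$lulc[["2016"]], scn$scheme)
  st <- build_strata(scn$zones, eco)
  expect_gt(nrow(st$legend), 1L)
  expect_true(all(table(st$codes[st$codes > 0]) >= 1))
})

test_that("compositing the sub-annual series recovers the annual field", {
  scn <- small_scenario(seed = 3L)
  st <- scn$indicators$fvc[["2016"]]
  mvc <- max_value_composite(st)
  # the seasonal peak slice is left exact, so the composite equals the
  # per-pixel maximum which equals the annual field; recompositing after
  # shuffling slices changes nothing
  mvc2 <- max_value_composite(grid_stack(st$slices[c(3, 1, 6, 2, 5, 4)],
                                         year = st$year))
  expect_identical(mvc$values, mvc2$values)
})

test_that("the empirical correlation approaches the target within a stratum", {
  tgt <- matrix(c(1, 0.7, 0.7, 0.7, 1, 0.7, 0.7, 0.7, 1), 3, 3)
  scn <- generate_scenario(scenario_config(
    nrow = 200L, ncol = 200L, correlation = tgt, n_fine_slices = 4L,
    nodata_fraction = 0, seed = 8L))
  ann <- lapply(scn$indicators, function(ind) {
    g <- max_value_composite(ind[["2016"]])
    if (!assert_aligned(list(g, scn$zones))) g <- resample_nearest(g, scn$zones)
    g
  })
  eco <- reclassify_lulc(scn$lulc[["2016"]], scn$scheme)
  st <- build_strata(scn$zones, eco)
  biggest <- as.integer(names(which.max(table(st$codes[st$codes > 0]))))
  sel <- st$codes == biggest
  X <- sapply(ann, function(g) g$values[sel])
  R <- correlation_matrix(X)
  expect_lt(max(abs(R[upper.tri(R)] - 0.7)), 0.05)
})

test_that("invalid scenario configurations are rejected", {
  bad <- matrix(c(1, 0.99, -0.9, 0.99, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(scenario_config(correlation = bad), "positive-definite")
  notsym <- matrix(c(1, 0.2, 0.3, 0.4, 1, 0.5, 0.3, 0.5, 1), 3, 3)
  expect_error(scenario_config(correlation = notsym), "symmetric")
})

test_that("planted regions drive the end-to-end change sign", {
  scn <- generate_scenario(scenario_config(
    nrow = 80L, ncol = 80L, n_zones = 4L, n_patches = 50L,
    n_fine_slices = 6L, seed = 9L))
  res <- run_assessment(scn$indicators, scn$zones, scn$lulc, scn$scheme)
  sig <- res$change$sig$values
  for (j in seq_along(scn$change_masks)) {
    m <- scn$change_masks[[j]]
    want <- if (attr(m, "offset") > 0) 3 else 1
    cls <- sig[m]; cls <- cls[!is.na(cls)]
    # the planted class is the modal class of its region
    expect_equal(as.integer(names(which.max(table(cls)))), want)
    expect_gt(mean(cls == want), 0.9)
  }
})
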