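test_that("correlation matrix follows the sum-of-products definition", {
  # 6-observation, 3-indicator fixture; expected R hand-computed from the
  # standardized sum-of-products sum(x_ki x_kj) / (m - 1)
  X <- cbind(a = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2),
             b = c(1.1, 0.9, 1.4, 1.6, 1.4, 2.0),
             c = c(5.0, 4.0, 3.5, 3.0, 2.0, 1.0))
  Z <- scale(X)                 # column-standardized, sample sd
  manual <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    manual[i, j] <- sum(Z[, i] * Z[, j]) / (nrow(X) - 1)
  R <- correlation_matrix(X)
  expect_equal(unname(R), manual, tolerance = 1e-12)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))

  # duplicated column -> perfect correlation
  R2 <- correlation_matrix(cbind(X[, 1], X[, 1]))
  expect_equal(R2[1, 2], 1)

  expect_error(correlation_matrix(cbind(X[, 1], rep(2, 6))), "constant")
})

test_that("independently generated columns are near-uncorrelated", {
  set.seed(1001)
  X <- matrix(rnorm(2e5), ncol = 2)
  expect_lt(abs(correlation_matrix(X)[1, 2]), 0.02)
})

test_that("uncorrelated indicators receive equal weights", {
  w <- pca_weights(diag(3), is_correlation = TRUE)
  expect_equal(unname(w$weights), rep(1 / 3, 3))
  expect_equal(w$p, 3L)
  expect_equal(sum(w$e), 1)
})

test_that("equicorrelated indicators match the closed-form eigenstructure", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  w <- pca_weights(R, is_correlation = TRUE, rho = 0.6)
  expect_equal(w$alpha, c(2, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(w$e, c(2, 0.5, 0.5) / 3, tolerance = 1e-12)
  expect_equal(w$p, 1L)                       # e1 = 2/3 >= 0.6
  # single retained component with symmetric loadings 1/sqrt(3)
  expect_equal(unname(w$weights), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("weights match the characteristic-polynomial oracle to 1e-8", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:3, 1)
    R <- random_corr(n)
    rho <- runif(1, 0.5, 1)
    got <- pca_weights(R, rho = rho, is_correlation = TRUE)
    want <- pca_weights_oracle(R, rho = rho)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-8)
    expect_equal(got$p, want$p)
    expect_equal(unname(got$weights), want$weights, tolerance = 1e-8)
  }
})

test_that("weights are nonnegative, sum to 1, and permute with columns", {
  set.seed(31)
  for (rep in 1:10) {
    X <- matrix(rnorm(600), ncol = 3) %*% matrix(runif(9, -1, 1), 3)
    if (any(apply(X, 2, sd) == 0)) next
    w <- pca_weights(X, rho = runif(1, 0.3, 1))
    expect_true(all(w$weights >= 0))
    expect_equal(sum(w$weights), 1, tolerance = 1e-10)

    perm <- sample(3)
    wp <- pca_weights(X[, perm], rho = w$rho)
    expect_equal(unname(wp$weights), unname(w$weights[perm]),
                 tolerance = 1e-10)
  }
})

test_that("rho outside (0, 1] and non-finite input are rejected", {
  expect_error(pca_weights(diag(3), rho = 0, is_correlation = TRUE), "rho")
  expect_error(pca_weights(diag(3), rho = 1.2, is_correlation = TRUE), "rho")
  R <- diag(3); R[1, 2] <- R[2, 1] <- NaN
  expect_error(pca_weights(R, is_correlation = TRUE), "non-finite")
})

test_that("year averaging is the renormalized arithmetic mean", {
  w1 <- c(lai = 0.2, fvc = 0.3, gpp = 0.5)
  w2 <- c(lai = 0.4, fvc = 0.3, gpp = 0.3)
  avg <- average_weights(list(w1, w2))
  expect_equal(unname(avg$weights), c(0.3, 0.3, 0.4))
  expect_equal(sum(avg$weights), 1)

  same <- average_weights(list(w1, w1))
  expect_equal(same$weights, w1)

  # means of valid weight sets already sum to 1: renormalization is a no-op
  expect_lt(abs(sum((w1 + w2) / 2) - 1), 1e-12)

  expect_error(average_weights(list(w1, c(a = 0.5, b = 0.5, c = 0))),
               "names differ")
})

test_that("the dominant shared-variance indicator receives the top weight", {
  L <- c(0.97, 0.90, 0.88)
  for (s in 1:3) {
    set.seed(s)
    f <- rnorm(2e4)
    X <- sapply(1:3, function(i) L[i] * f + sqrt(1 - L[i]^2) * rnorm(2e4))
    w <- pca_weights(X, rho = 0.85)
    expect_equal(unname(which.max(w$weights)), 1L)
  }
})
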