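# Independent oracles used by the tests. These deliberately share no code
# with the package implementation: brute-force searches, exhaustive
# enumeration, and closed-form eigenstructure.

# Nearest-neighbor oracle: for every output cell center, scan ALL source
# cell centers and take the closest, ties resolved to the smaller row index
# then smaller column index.
brute_nearest <- function(source, target) {
  tg <- if (inherits(target, "eqi_grid"))
    list(nrow = nrow(target$values), ncol = ncol(target$values),
         xmin = target$xmin, ymax = target$ymax,
         dx = target$dx, dy = target$dy)
  else target
  sx <- source$xmin + (seq_len(ncol(source$values)) - 0.5) * source$dx
  sy <- source$ymax - (seq_len(nrow(source$values)) - 0.5) * source$dy
  out <- matrix(NA_real_, tg$nrow, tg$ncol)
  for (i in seq_len(tg$nrow)) {
    y <- tg$ymax - (i - 0.5) * tg$dy
    for (j in seq_len(tg$ncol)) {
      x <- tg$xmin + (j - 0.5) * tg$dx
      # outside the source extent -> nodata
      if (x < source$xmin || x > source$xmin + ncol(source$values) * source$dx ||
          y > source$ymax || y < source$ymax - nrow(source$values) * source$dy)
        next
      best <- Inf; bi <- bj <- NA_integer_
      for (si in seq_len(nrow(source$values)))
        for (sj in seq_len(ncol(source$values))) {
          d <- (x - sx[sj])^2 + (y - sy[si])^2
          if (is.na(bi) || d < best * (1 - 1e-12)) {
            best <- d; bi <- si; bj <- sj
          } else if (d <= best * (1 + 1e-12)) {
            if (si < bi || (si == bi && sj < bj)) { bi <- si; bj <- sj }
          }
        }
      out[i, j] <- source$values[bi, bj]
    }
  }
  out
}

# Exhaustive Fisher-Jenks oracle: enumerate every partition of the sorted
# values into k contiguous nonempty classes (boundaries in lexicographic
# order, first strict improvement kept, so equal-cost ties resolve to the
# smallest first class), and return the class maxima and total cost.
exhaustive_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)   # columns in lexicographic order
  best <- Inf; best_breaks <- NULL
  for (ci in seq_len(ncol(cuts))) {
    b <- cuts[, ci]
    idx <- c(0, b, n)
    cost <- 0
    for (cl in seq_len(k))
      cost <- cost + sse(x[(idx[cl] + 1):idx[cl + 1]])
    if (cost < best - 1e-12) {
      best <- cost
      best_breaks <- x[b]
    }
  }
  list(breaks = best_breaks, cost = best)
}

# Closed-form PCA-weight oracle for n = 2, 3: eigenvalues as roots of the
# characteristic polynomial, eigenvectors from the cross product of rows of
# (R - lambda I); then contribution rates, retention, absolute-loading
# importances and normalized weights computed directly.
pca_weights_oracle <- function(R, rho = 0.85) {
  n <- nrow(R)
  stopifnot(n %in% c(2L, 3L))
  if (n == 2L) {
    a <- R[1, 1]; b <- R[1, 2]; d <- R[2, 2]
    tr <- a + d; det2 <- a * d - b^2
    disc <- sqrt(tr^2 / 4 - det2)
    lam <- c(tr / 2 + disc, tr / 2 - disc)
    vecs <- sapply(lam, function(l) {
      v <- if (abs(b) > 1e-14) c(b, l - a) else if (l == a) c(1, 0) else c(0, 1)
      v / sqrt(sum(v^2))
    })
  } else {
    # characteristic polynomial det(R - lambda I) = -lambda^3 + c2 lambda^2
    # + c1 lambda + c0, roots via polyroot (companion matrix, independent
    # of the symmetric eigensolver under test)
    c2 <- sum(diag(R))
    m12 <- R[1, 1] * R[2, 2] - R[1, 2]^2
    m13 <- R[1, 1] * R[3, 3] - R[1, 3]^2
    m23 <- R[2, 2] * R[3, 3] - R[2, 3]^2
    c1 <- -(m12 + m13 + m23)
    c0 <- det(R)
    lam <- sort(Re(polyroot(c(c0, c1, c2, -1))), decreasing = TRUE)
    vecs <- sapply(lam, function(l) {
      A <- R - diag(l, 3)
      # cross products of row pairs span the null space; take the largest
      cands <- list(cross3(A[1, ], A[2, ]),
                    cross3(A[1, ], A[3, ]),
                    cross3(A[2, ], A[3, ]))
      nr2 <- vapply(cands, function(v) sum(v^2), numeric(1))
      v <- cands[[which.max(nr2)]]
      v / sqrt(sum(v^2))
    })
  }
  e <- lam / sum(lam)
  p <- which(cumsum(e) >= rho - 1e-12)[1]
  gam <- as.numeric(abs(vecs[, seq_len(p), drop = FALSE]) %*% e[seq_len(p)]) /
    sum(e[seq_len(p)])
  list(weights = gam / sum(gam), alpha = lam, e = e, p = p)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Random correlation matrix with (almost surely) distinct eigenvalues.
random_corr <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  S <- crossprod(A) + diag(n) * 0.1
  D <- diag(1 / sqrt(diag(S)))
  D %*% S %*% D
}

# Small, fast scenario for unit tests.
small_scenario <- function(seed = 1L, ...) {
  generate_scenario(scenario_config(
    nrow = 48L, ncol = 48L, n_zones = 3L, n_patches = 25L,
    n_fine_slices = 6L, seed = seed, ...))
}

# Simple aligned grid filled with given values.
toy_grid <- function(values, nrow = NULL, ncol = NULL, dx = 1000) {
  if (!is.matrix(values)) values <- matrix(values, nrow, ncol)
  eqi_grid(values, xmin = 0, ymax = nrow(values) * dx, dx = dx, dy = dx,
           crs = "toy")
}
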