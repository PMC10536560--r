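#' Correlation matrix of an observation matrix
#'
#' Pearson correlation matrix of the columns of `X` (m pixels x n
#' indicators). For columns that are already standardized this coincides
#' with their sample covariance matrix, which is how the weighting procedure
#' defines it. A constant column has no defined correlation and is an error.
#'
#' @param X numeric matrix, m >= n + 1 rows, no missing values.
#' @return symmetric n x n correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(X) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), nrow(X) >= ncol(X) + 1L)
  if (any(!is.finite(X))) stop("non-finite entries in observation matrix")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(which(sds == 0), collapse = ", "))
  R <- stats::cor(X)
  dimnames(R) <- list(colnames(X), colnames(X))
  R
}

#' Indicator weights from principal component analysis
#'
#' Derives objective indicator weights from the correlation structure of the
#' standardized indicator relative densities:
#' eigendecompose the correlation matrix `R` (eigenvalues sorted descending),
#' take contribution rates `e_i = alpha_i / sum(alpha)`, retain the smallest
#' number `p` of components whose cumulative contribution reaches `rho`,
#' score each indicator by its retained loadings weighted by contribution
#' rate, `gamma_i = sum_{j<=p} |c_ij| e_j / sum_{j<=p} e_j`, and normalize
#' `omega_i = gamma_i / sum(gamma)`. Absolute loadings guarantee nonnegative
#' weights summing to 1; the signed variant is available for sensitivity
#' analysis but can produce negative weights.
#'
#' @param X observation matrix (m pixels x n indicators) of standardized
#'   densities, or a precomputed correlation matrix when `is_correlation =
#'   TRUE`.
#' @param rho cumulative contribution-rate threshold in (0, 1]; default 0.85.
#' @param is_correlation set `TRUE` when `X` already is a correlation matrix.
#' @param loading_scale `"unit"` (eigenvectors as loadings, default) or
#'   `"sqrt_eigenvalue"` (eigenvectors scaled by `sqrt(alpha_j)`).
#' @param signed_loadings if `TRUE` use signed loadings in the importance
#'   score (can yield negative weights); default `FALSE`.
#' @return object of class `pca_weights`: list with `weights` (named, sums
#'   to 1), `gamma`, `R`, `alpha` (eigenvalues), `C` (loading matrix, sign
#'   convention: largest-magnitude element of each column positive), `e`
#'   (contribution rates), `p` (retained components), `rho`, `m`
#'   (observations used, NA when a correlation matrix was supplied).
#' @export
pca_weights <- function(X, rho = 0.85, is_correlation = FALSE,
                        loading_scale = c("unit", "sqrt_eigenvalue"),
                        signed_loadings = FALSE) {
  loading_scale <- match.arg(loading_scale)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1)
    stop("rho must lie in (0, 1]")
  if (is_correlation) {
    R <- as.matrix(X)
    if (any(!is.finite(R))) stop("non-finite entries in correlation matrix")
    if (!isSymmetric(unname(R), tol = 1e-8))
      stop("correlation matrix must be symmetric")
    m <- NA_integer_
  } else {
    R <- correlation_matrix(X)
    m <- nrow(X)
  }
  n <- ncol(R)
  nm <- colnames(R)
  if (is.null(nm)) nm <- paste0("V", seq_len(n))

  eig <- eigen(R, symmetric = TRUE)     # eigenvalues already descending
  alpha <- pmax(eig$values, 0)
  C <- eig$vectors
  # sign convention: largest-|.| element of each eigenvector positive
  for (j in seq_len(n)) {
    i0 <- which.max(abs(C[, j]))
    if (C[i0, j] < 0) C[, j] <- -C[, j]
  }
  e <- alpha / sum(alpha)
  p <- which(cumsum(e) >= rho - 1e-12)[1L]
  L <- if (loading_scale == "sqrt_eigenvalue")
    sweep(C, 2L, sqrt(alpha), "*") else C
  Lp <- L[, seq_len(p), drop = FALSE]
  if (!signed_loadings) Lp <- abs(Lp)
  gamma <- as.numeric(Lp %*% e[seq_len(p)]) / sum(e[seq_len(p)])
  omega <- gamma / sum(gamma)
  names(omega) <- names(gamma) <- nm
  dimnames(C) <- list(nm, paste0("PC", seq_len(n)))
  structure(list(weights = omega, gamma = gamma, R = R, alpha = alpha,
                 C = C, e = e, p = p, rho = rho, m = m,
                 loading_scale = loading_scale,
                 signed_loadings = signed_loadings),
            class = "pca_weights")
}

#' @export
print.pca_weights <- function(x, ...) {
  cat(sprintf("<pca_weights> %d indicators, p = %d of %d components (rho = %g)\n",
              length(x$weights), x$p, length(x$alpha), x$rho))
  cat("  weights:",
      paste(sprintf("%s = %.4f", names(x$weights), x$weights),
            collapse = ", "), "\n")
  invisible(x)
}

#' Average per-year weight sets
#'
#' Element-wise arithmetic mean over years, renormalized so the result sums
#' exactly to 1 (for valid inputs the renormalization is a no-op up to
#' floating point). Indicator names must agree across years.
#'
#' @param per_year list of `pca_weights` objects or named weight vectors.
#' @return object of class `weight_set`: `weights` (named, sums to 1),
#'   `per_year` (the inputs), `provenance`.
#' @export
average_weights <- function(per_year) {
  stopifnot(is.list(per_year), length(per_year) >= 1L)
  ws <- lapply(per_year, function(w) {
    if (inherits(w, "pca_weights")) w$weights else w
  })
  nm <- names(ws[[1L]])
  if (is.null(nm)) stop("weights must be named by indicator")
  for (w in ws[-1L])
    if (!identical(names(w), nm))
      stop("indicator names differ across years: ",
           paste(nm, collapse = "/"), " vs ", paste(names(w), collapse = "/"))
  avg <- Reduce(`+`, ws) / length(ws)
  avg <- avg / sum(avg)
  structure(list(weights = avg, per_year = per_year,
                 provenance = list(n_years = length(ws),
                                   indicators = nm)),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set> mean of %d year(s): %s\n",
              x$provenance$n_years,
              paste(sprintf("%s = %.4f", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize a weight set (and its PCA provenance) to JSON
#'
#' @param ws a `weight_set` or `pca_weights`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_weights_json <- function(ws, path) {
  to_list <- function(w) {
    if (inherits(w, "pca_weights"))
      list(weights = as.list(w$weights), alpha = w$alpha, e = w$e, p = w$p,
           rho = w$rho, gamma = as.list(w$gamma), m = w$m,
           R = unname(apply(w$R, 1L, as.list, simplify = FALSE)),
           C = unname(apply(w$C, 1L, as.list, simplify = FALSE)))
    else as.list(w)
  }
  obj <- if (inherits(ws, "weight_set")) {
    list(weights = as.list(ws$weights),
         per_year = lapply(ws$per_year, to_list),
         provenance = ws$provenance)
  } else to_list(ws)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
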