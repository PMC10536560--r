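#' Per-stratum reference values for an indicator
#'
#' The reference value of a stratum is the maximum (default) — or, as an
#' outlier-robust option, an upper percentile — of the indicator over the
#' stratum's valid pixels. References are the denominators of the indicator
#' relative density, so any non-positive reference is an error naming the
#' stratum (the ratio would be undefined or sign-flipping).
#'
#' @param indicator `eqi_grid` of indicator values for one year.
#' @param strata a `stratum_map` aligned with the indicator.
#' @param method `"max"` (default) or `"percentile"`.
#' @param q upper-percentile level used when `method = "percentile"`
#'   (default 0.99); quantile type 7.
#' @return a data frame of class `reference_table` with columns `code`,
#'   `zone`, `type`, `type_name`, `n_pixels`, `reference`, and attributes
#'   `method`/`q`.
#' @export
compute_reference <- function(indicator, strata,
                              method = c("max", "percentile"), q = 0.99) {
  method <- match.arg(method)
  stopifnot(inherits(indicator, "eqi_grid"), inherits(strata, "stratum_map"))
  stop_if_misaligned(list(indicator, strata$geometry),
                     "indicator and stratum map")
  codes <- strata$codes
  vals <- indicator$values
  use <- codes > 0L & !is.na(vals)
  if (!any(use)) stop("no valid pixels in any stratum")
  f <- factor(codes[use], levels = strata$legend$code)
  n <- as.integer(table(f))
  if (any(n == 0L))
    stop("stratum with no valid pixel for this indicator: ",
         paste(strata$legend$code[n == 0L], collapse = ", "))
  ref <- if (method == "max") {
    as.numeric(tapply(vals[use], f, max))
  } else {
    stopifnot(q > 0, q <= 1)
    as.numeric(tapply(vals[use], f, stats::quantile, probs = q, names = FALSE))
  }
  bad <- which(ref <= 0)
  if (length(bad) > 0L) {
    lg <- strata$legend[bad, , drop = FALSE]
    stop("non-positive reference value in stratum (zone, type): ",
         paste(sprintf("(%d, %s)", lg$zone, lg$type_name), collapse = ", "))
  }
  out <- cbind(strata$legend, n_pixels = n, reference = ref)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "q") <- if (method == "percentile") q else NA_real_
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Indicator relative density
#'
#' Divides each pixel's indicator value by its stratum's reference value:
#' `IRD = F / Fmax` where `Fmax` is taken per (year, zone, ecosystem type).
#' Pixels outside the strata (masked, non-vegetation, or nodata) are nodata.
#' With maximum references and nonnegative indicators the result lies in
#' `[0, 1]` and every stratum attains 1 at its reference pixel.
#'
#' @param indicator `eqi_grid` of indicator values.
#' @param strata a `stratum_map`.
#' @param refs a `reference_table` from [compute_reference()] covering every
#'   stratum code present.
#' @return `eqi_grid` of relative densities.
#' @export
compute_ird <- function(indicator, strata, refs) {
  stopifnot(inherits(refs, "reference_table"))
  stop_if_misaligned(list(indicator, strata$geometry),
                     "indicator and stratum map")
  codes <- strata$codes
  present <- unique(codes[codes > 0L])
  missing_ref <- setdiff(present, refs$code)
  if (length(missing_ref) > 0L)
    stop("no reference for stratum code(s): ",
         paste(sort(missing_ref), collapse = ", "))
  denom <- refs$reference[match(codes, refs$code)]
  out <- indicator$values / matrix(denom, nrow(codes), ncol(codes))
  out[codes == 0L] <- NA_real_
  grid_like(indicator, out)
}

#' Z-score standardization of a raster
#'
#' Standardizes all valid pixels to `Z = (x - mean) / sd`. By default the
#' mean and the population standard deviation (divide-by-n) are estimated
#' from the grid itself; passing stored `params` applies them instead of
#' re-estimating, which is how a second epoch can be expressed on a first
#' epoch's baseline. The parameters actually used are always returned so a
#' run is reproducible and invertible.
#'
#' @param x `eqi_grid` (typically an IRD grid).
#' @param params optional list with `mean` and `sd` to apply; `NULL`
#'   (default) re-estimates from `x`.
#' @return list with `grid` (standardized `eqi_grid`) and `params`
#'   (list `mean`, `sd`, `n`, `population`).
#' @export
standardize <- function(x, params = NULL) {
  stopifnot(inherits(x, "eqi_grid"))
  v <- x$values
  ok <- !is.na(v)
  if (is.null(params)) {
    n <- sum(ok)
    if (n < 2L) stop("fewer than 2 valid pixels; cannot standardize")
    mu <- mean(v[ok])
    sigma <- sqrt(sum((v[ok] - mu)^2) / n)  # population sd
    if (sigma == 0) stop("zero variance; cannot standardize")
    params <- list(mean = mu, sd = sigma, n = n, population = "estimated")
  } else {
    stopifnot(is.numeric(params$mean), is.numeric(params$sd), params$sd > 0)
    params$population <- "applied"
  }
  z <- (v - params$mean) / params$sd
  list(grid = grid_like(x, z), params = params)
}

#' Invert a z-score standardization
#'
#' @param z standardized `eqi_grid`.
#' @param params the `params` returned by [standardize()].
#' @return `eqi_grid` on the original scale.
#' @export
unstandardize <- function(z, params) {
  grid_like(z, z$values * params$sd + params$mean)
}

#' Write reference tables / standardization parameters for audit
#'
#' @param refs a `reference_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(refs, path) {
  df <- as.data.frame(refs)
  df$method <- attr(refs, "method")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
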