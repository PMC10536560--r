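#' Ecosystem quality level names, poor to excellent
#'
#' Integer level codes 1..5 follow this order, so a larger code always means
#' a better class.
#' @export
EQI_LEVELS <- c("poor", "low", "moderate", "good", "excellent")

#' Published five-level break presets
#'
#' Named presets of fixed classification breaks. `"brr-2016-2020"` carries
#' the thresholds published for the Belt-and-Road-region 2016/2020
#' assessment (poor <= -0.97 < low <= -0.25 < moderate <= 0.44 < good <=
#' 1.19 < excellent), so level maps from that study can be reproduced from
#' any EQI grid without re-running Jenks.
#' @export
EQI_BREAK_PRESETS <- list("brr-2016-2020" = c(-0.97, -0.25, 0.44, 1.19))

#' Continuous ecosystem quality index
#'
#' Weighted sum of the standardized indicator relative densities:
#' `EQI = sum_i omega_i * Z_i` per pixel. Only complete-case pixels are
#' scored: a pixel missing any input is nodata.
#'
#' @param z_grids named list of standardized `eqi_grid`s, one per indicator.
#' @param weights a `weight_set`, `pca_weights`, or named numeric vector;
#'   names must match `z_grids` when both are named.
#' @return `eqi_grid` of continuous EQI values.
#' @export
compute_eqi <- function(z_grids, weights) {
  stopifnot(is.list(z_grids), length(z_grids) >= 1L)
  w <- if (inherits(weights, c("weight_set", "pca_weights")))
    weights$weights else weights
  if (length(w) != length(z_grids))
    stop("need one weight per grid: ", length(w), " weights, ",
         length(z_grids), " grids")
  if (!is.null(names(w)) && !is.null(names(z_grids))) {
    if (!setequal(names(w), names(z_grids)))
      stop("weight names do not match grid names")
    w <- w[names(z_grids)]
  }
  if (length(z_grids) > 1L) stop_if_misaligned(z_grids, "standardized grids")
  acc <- z_grids[[1L]]$values * w[[1L]]
  for (i in seq_along(z_grids)[-1L])
    acc <- acc + z_grids[[i]]$values * w[[i]]   # NA if any input NA
  grid_like(z_grids[[1L]], acc)
}

#' Jenks natural breaks (exact Fisher-Jenks)
#'
#' Partitions a 1-D distribution into `k` classes minimizing the total
#' within-class sum of squared deviations from class means, by exact dynamic
#' programming over the sorted distinct values with multiplicity — not the
#' heuristic reallocation variant — so the result is deterministic and
#' verifiable against exhaustive search. Among equal-cost optima the
#' partition whose first (lowest) class is smallest wins.
#'
#' @param values finite numeric vector (NAs dropped); must contain at least
#'   `k` distinct values.
#' @param k number of classes, >= 2.
#' @return numeric vector of `k - 1` ordered cut points, the maxima of
#'   classes 1..k-1; class membership is lower-open/upper-closed (a value
#'   equal to a cut point belongs to the lower class).
#' @export
jenks_breaks <- function(values, k) {
  v <- values[!is.na(values)]
  if (any(!is.finite(v))) stop("values must be finite")
  if (k < 2L) stop("k must be >= 2")
  tab <- table(v)
  ux <- as.numeric(names(tab))
  if (length(ux) < k)
    stop("need at least k = ", k, " distinct values, got ", length(ux))
  res <- .jenks_dp(ux, as.numeric(tab), as.integer(k))
  res$breaks
}

#' Subsampled Jenks breaks for large rasters
#'
#' For value counts above `sample_size`, computes breaks on a seeded uniform
#' subsample (without replacement); below it, on all values. The seed and
#' effective sample size are recorded as attributes for provenance.
#'
#' @inheritParams jenks_breaks
#' @param sample_size subsample cap (default `1e5`).
#' @param seed RNG seed for the subsample (default 1).
#' @return as [jenks_breaks()], with attributes `n_used` and `seed`.
#' @export
jenks_breaks_sampled <- function(values, k, sample_size = 1e5, seed = 1L) {
  v <- values[!is.na(values)]
  used_seed <- NA_integer_
  if (length(v) > sample_size) {
    used_seed <- as.integer(seed)
    v <- withr::with_seed(used_seed, sample(v, sample_size))
  }
  br <- jenks_breaks(v, k)
  attr(br, "n_used") <- length(v)
  attr(br, "seed") <- used_seed
  br
}

#' Classify a continuous EQI grid into levels
#'
#' Applies the lower-open, upper-closed interval convention: with breaks
#' `b1 < b2 < b3 < b4`, a pixel is `poor` when `EQI <= b1`, `low` when
#' `b1 < EQI <= b2`, ..., `excellent` when `EQI > b4`. A value equal to a
#' break belongs to the lower class. Works for any number of classes
#' (`length(breaks) + 1`); level names are attached for five classes.
#'
#' @param eqi `eqi_grid` of continuous index values.
#' @param breaks strictly increasing cut points, or the name of a preset in
#'   [EQI_BREAK_PRESETS].
#' @return `eqi_grid` of integer level codes 1 (worst) .. k (best), with a
#'   `levels` attribute naming the codes.
#' @export
classify <- function(eqi, breaks) {
  stopifnot(inherits(eqi, "eqi_grid"))
  if (is.character(breaks)) {
    if (!breaks %in% names(EQI_BREAK_PRESETS))
      stop("unknown break preset: ", breaks)
    breaks <- EQI_BREAK_PRESETS[[breaks]]
  }
  breaks <- as.numeric(breaks)
  if (length(breaks) < 1L || any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing")
  v <- eqi$values
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- findInterval(v[ok], breaks, left.open = TRUE) + 1
  out <- grid_like(eqi, cls)
  attr(out, "levels") <- if (length(breaks) == 4L) EQI_LEVELS
                         else paste0("class", seq_len(length(breaks) + 1L))
  attr(out, "breaks") <- breaks
  out
}

#' Full EQI result: continuous index, breaks, level grid
#'
#' Convenience wrapper that runs [jenks_breaks_sampled()] on the pooled
#' values of one or more EQI grids (pooling epochs gives one comparable
#' level scale across years) and classifies each grid.
#'
#' @param eqi_grids named list of continuous EQI `eqi_grid`s (e.g. one per
#'   year).
#' @param k number of classes (default 5).
#' @param breaks optional fixed breaks or preset name; when supplied Jenks
#'   is skipped and `break_source` is `"fixed"`.
#' @param sample_size,seed passed to [jenks_breaks_sampled()].
#' @return object of class `eqi_result`: list with `eqi` (input grids),
#'   `breaks`, `levels` (classified grids), `break_source`.
#' @export
eqi_result <- function(eqi_grids, k = 5L, breaks = NULL,
                       sample_size = 1e5, seed = 1L) {
  stopifnot(is.list(eqi_grids), length(eqi_grids) >= 1L)
  if (is.null(breaks)) {
    pooled <- unlist(lapply(eqi_grids, function(g) g$values[!is.na(g$values)]))
    breaks <- jenks_breaks_sampled(pooled, k, sample_size = sample_size,
                                   seed = seed)
    src <- "jenks"
  } else {
    if (is.character(breaks)) breaks <- EQI_BREAK_PRESETS[[breaks]]
    src <- "fixed"
  }
  levels <- lapply(eqi_grids, classify, breaks = as.numeric(breaks))
  structure(list(eqi = eqi_grids, breaks = as.numeric(breaks),
                 levels = levels, break_source = src),
            class = "eqi_result")
}

#' @export
print.eqi_result <- function(x, ...) {
  cat(sprintf("<eqi_result> %d epoch(s), %d classes, breaks (%s): %s\n",
              length(x$eqi), length(x$breaks) + 1L, x$break_source,
              paste(sprintf("%.3f", x$breaks), collapse = ", ")))
  invisible(x)
}
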