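#' Change class names
#'
#' Integer codes for the three significance classes of two-epoch EQI change:
#' 1 = decreased, 2 = no_change, 3 = increased.
#' @export
CHANGE_CLASSES <- c("decreased", "no_change", "increased")

#' Two-epoch EQI difference
#'
#' Per-pixel `EQI(year2) - EQI(year1)`; nodata wherever either epoch is
#' nodata.
#'
#' @param eqi1,eqi2 aligned continuous EQI `eqi_grid`s for the earlier and
#'   later epoch.
#' @return `eqi_grid` of differences.
#' @export
delta_eqi <- function(eqi1, eqi2) {
  stop_if_misaligned(list(eqi1, eqi2), "EQI epochs")
  grid_like(eqi1, eqi2$values - eqi1$values)
}

#' Classify an EQI difference into significance classes
#'
#' Applies the adopted evaluation convention with its printed boundary
#' memberships: `delta <= lower` is `decreased`, `lower < delta <= upper` is
#' `no_change`, `delta > upper` is `increased`. Defaults are the standard
#' +-0.05 thresholds.
#'
#' @param delta `eqi_grid` from [delta_eqi()].
#' @param thresholds length-2 numeric `c(lower, upper)` with `lower < upper`
#'   (default `c(-0.05, 0.05)`).
#' @return `eqi_grid` of codes 1..3 (see [CHANGE_CLASSES]), with a `levels`
#'   attribute.
#' @export
classify_change <- function(delta, thresholds = c(-0.05, 0.05)) {
  stopifnot(inherits(delta, "eqi_grid"), length(thresholds) == 2L)
  if (!(thresholds[1L] < thresholds[2L]))
    stop("thresholds must satisfy lower < upper")
  v <- delta$values
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- findInterval(v[ok], thresholds, left.open = TRUE) + 1
  out <- grid_like(delta, cls)
  attr(out, "levels") <- CHANGE_CLASSES
  attr(out, "thresholds") <- thresholds
  out
}

#' Per-zone / per-type area shares of a class grid
#'
#' Tabulates a categorical grid (change classes or EQI levels) against a
#' stratum map and returns area percentages at four groupings: the whole
#' study area, per eco-geographical zone, per ecosystem type, and per
#' (zone, type) stratum. Two denominators are reported for each row:
#' `percent_of_total` (share of the entire valid study area) and
#' `percent_within` (share within the row's group), so both reading
#' conventions of published proportion figures are available. Weighting is
#' by pixel count by default; `"cosine"` weights each pixel by the cosine of
#' its center latitude, the equal-angle approximation of true cell area on a
#' geographic grid (y coordinates are then interpreted as degrees latitude).
#'
#' @param classes `eqi_grid` of integer class codes with a `levels`
#'   attribute (from [classify()] or [classify_change()]).
#' @param strata a `stratum_map` aligned with `classes`.
#' @param weighting `"pixel"` (default) or `"cosine"`.
#' @return object of class `change_tables`: named list of data frames
#'   `total`, `by_zone`, `by_type`, `by_stratum`, each with columns
#'   `class`, `n_pixels` (or weighted area), `percent_of_total`,
#'   `percent_within`.
#' @export
summarize_classes <- function(classes, strata,
                              weighting = c("pixel", "cosine")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(classes, "eqi_grid"), inherits(strata, "stratum_map"))
  stop_if_misaligned(list(classes, strata$geometry), "classes and strata")
  lv <- attr(classes, "levels")
  cls <- classes$values
  codes <- strata$codes
  ok <- !is.na(cls) & codes > 0L
  if (!any(ok)) stop("no valid classified pixels inside strata")
  if (is.null(lv)) lv <- paste0("class", sort(unique(cls[ok])))

  w <- matrix(1, nrow(cls), ncol(cls))
  if (weighting == "cosine") {
    lat <- grid_row_centers(classes)  # row-center latitudes in degrees
    w <- matrix(rep(cos(lat * pi / 180), ncol(cls)), nrow(cls), ncol(cls))
  }

  cl <- factor(lv[cls[ok]], levels = lv)
  zone <- strata$legend$zone[codes[ok]]
  type <- strata$legend$type_name[codes[ok]]
  wt <- w[ok]
  total_area <- sum(wt)

  tab <- function(...) {
    groups <- list(...)
    agg <- stats::aggregate(wt, by = c(groups, list(class = cl)), FUN = sum,
                            drop = FALSE)
    names(agg)[ncol(agg)] <- "area"
    agg$area[is.na(agg$area)] <- 0
    agg$percent_of_total <- 100 * agg$area / total_area
    grp_cols <- setdiff(names(agg), c("class", "area", "percent_of_total"))
    if (length(grp_cols) == 0L) {
      agg$percent_within <- 100 * agg$area / total_area
    } else {
      gkey <- do.call(paste, agg[grp_cols])
      gtot <- tapply(agg$area, gkey, sum)[gkey]
      agg$percent_within <- ifelse(gtot > 0, 100 * agg$area / gtot, 0)
    }
    names(agg)[names(agg) == "area"] <- "n_pixels"
    agg
  }

  structure(list(
    total = tab(),
    by_zone = tab(zone = zone),
    by_type = tab(type = type),
    by_stratum = tab(zone = zone, type = type)),
    class = "change_tables")
}

#' @export
print.change_tables <- function(x, ...) {
  cat("<change_tables> study-area shares:\n")
  print(x$total, row.names = FALSE)
  invisible(x)
}

#' Two-epoch change analysis in one call
#'
#' Runs [delta_eqi()], [classify_change()] and [summarize_classes()].
#'
#' @inheritParams delta_eqi
#' @inheritParams classify_change
#' @inheritParams summarize_classes
#' @return object of class `change_result`: list with `delta`, `sig`
#'   (class grid), `thresholds`, `tables`.
#' @export
change_analysis <- function(eqi1, eqi2, strata, thresholds = c(-0.05, 0.05),
                            weighting = c("pixel", "cosine")) {
  delta <- delta_eqi(eqi1, eqi2)
  sig <- classify_change(delta, thresholds)
  tables <- summarize_classes(sig, strata, weighting = match.arg(weighting))
  structure(list(delta = delta, sig = sig, thresholds = thresholds,
                 tables = tables),
            class = "change_result")
}

#' @export
print.change_result <- function(x, ...) {
  cat(sprintf("<change_result> thresholds (%g, %g]\n",
              x$thresholds[1], x$thresholds[2]))
  print(x$tables)
  invisible(x)
}

#' Write class-share tables as CSV
#'
#' @param tables a `change_tables`.
#' @param dir output directory.
#' @param prefix file-name prefix, e.g. `"change"` or `"levels"`.
#' @return the directory, invisibly.
#' @export
write_change_tables <- function(tables, dir, prefix = "classes") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]],
                     file.path(dir, sprintf("%s_%s.csv", prefix, nm)),
                     row.names = FALSE)
  invisible(dir)
}
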