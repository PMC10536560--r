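#' Vegetation ecosystem-type names
#'
#' The six vegetation ecosystem types used for stratification, plus the
#' non-vegetation mask class. Integer codes 1..6 follow this order; 0 is the
#' mask.
#' @export
ECOSYSTEM_TYPES <- c("cultivated", "forest", "grassland", "shrub",
                     "wetland", "tundra")

#' Define a LULC-to-ecosystem-type reclassification scheme
#'
#' Maps first-level land-use/land-cover class codes onto the six vegetation
#' ecosystem types or the non-vegetation mask. The mapping must be total over
#' every code that can occur in the LULC raster.
#'
#' @param mapping data frame with columns `lulc_code` (integer) and `type`
#'   (one of [ECOSYSTEM_TYPES] or `"non_vegetation"`), or a path to a CSV/YAML
#'   file with those fields.
#' @return an object of class `ecotype_scheme`.
#' @examples
#' sch <- ecotype_scheme(data.frame(
#'   lulc_code = c(10, 20, 30, 90),
#'   type = c("cultivated", "forest", "grassland", "non_vegetation")))
#' @export
ecotype_scheme <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- if (grepl("\\.ya?ml$", mapping)) {
      m <- yaml::read_yaml(mapping)
      data.frame(lulc_code = as.integer(names(m)),
                 type = unlist(m, use.names = FALSE))
    } else {
      utils::read.csv(mapping, stringsAsFactors = FALSE)
    }
  }
  stopifnot(is.data.frame(mapping),
            all(c("lulc_code", "type") %in% names(mapping)))
  ok <- mapping$type %in% c(ECOSYSTEM_TYPES, "non_vegetation")
  if (!all(ok))
    stop("unknown ecosystem type(s): ",
         paste(unique(mapping$type[!ok]), collapse = ", "))
  if (anyDuplicated(mapping$lulc_code))
    stop("duplicate lulc_code in scheme")
  structure(list(mapping = mapping), class = "ecotype_scheme")
}

#' Reclassify a LULC raster to ecosystem-type codes
#'
#' Every valid LULC code is looked up in the scheme; vegetation types get
#' codes 1..6 (order of [ECOSYSTEM_TYPES]), non-vegetation and nodata pixels
#' get the mask code 0. A LULC code absent from the scheme is an error that
#' names the offending codes.
#'
#' @param lulc `eqi_grid` of integer LULC class codes.
#' @param scheme an [ecotype_scheme()].
#' @return `eqi_grid` of ecosystem-type codes (0 = masked).
#' @export
reclassify_lulc <- function(lulc, scheme) {
  stopifnot(inherits(lulc, "eqi_grid"), inherits(scheme, "ecotype_scheme"))
  v <- lulc$values
  codes <- unique(v[!is.na(v)])
  unmapped <- setdiff(codes, scheme$mapping$lulc_code)
  if (length(unmapped) > 0L)
    stop("LULC code(s) not in scheme: ", paste(sort(unmapped), collapse = ", "))
  type_of <- match(scheme$mapping$type, ECOSYSTEM_TYPES)  # NA for non-veg
  type_of[is.na(type_of)] <- 0L
  idx <- match(v, scheme$mapping$lulc_code)
  out <- type_of[idx]
  out[is.na(v)] <- 0L
  grid_like(lulc, matrix(as.numeric(out), nrow(v), ncol(v)))
}

#' Build (zone x ecosystem-type) strata
#'
#' Joins the eco-geographical zone raster with the ecosystem-type raster:
#' each pixel with a valid zone and a vegetation type receives the integer
#' code of its (zone, type) pair; all other pixels get 0 (masked). The legend
#' enumerates only pairs that actually occur, ordered by zone then type.
#' These strata define the reference populations for indicator relative
#' densities.
#'
#' @param zones `eqi_grid` of integer zone identifiers (NA = outside study
#'   area).
#' @param ecotypes `eqi_grid` of ecosystem-type codes from
#'   [reclassify_lulc()] (0 = masked).
#' @return an object of class `stratum_map`: list with `codes` (integer
#'   matrix, 0 = masked), `legend` (data frame `code`, `zone`, `type`,
#'   `type_name`) and `geometry` (an `eqi_grid` template).
#' @export
build_strata <- function(zones, ecotypes) {
  stop_if_misaligned(list(zones, ecotypes), "zone and ecotype grids")
  z <- zones$values
  t <- ecotypes$values
  veg <- !is.na(z) & !is.na(t) & t >= 1
  if (any(z[veg] < 0 | z[veg] != round(z[veg])))
    stop("zone identifiers must be non-negative integers")
  key <- ifelse(veg, z * 100 + t, NA_real_)
  occurring <- sort(unique(key[!is.na(key)]))
  if (length(occurring) == 0L) stop("no vegetated pixels to stratify")
  legend <- data.frame(
    code = seq_along(occurring),
    zone = as.integer(occurring %/% 100),
    type = as.integer(occurring %% 100))
  legend$type_name <- ECOSYSTEM_TYPES[legend$type]
  codes <- matrix(0L, nrow(z), ncol(z))
  codes[veg] <- match(key[veg], occurring)
  structure(list(codes = codes, legend = legend,
                 geometry = grid_like(zones, matrix(0, nrow(z), ncol(z)))),
            class = "stratum_map")
}

#' @export
print.stratum_map <- function(x, ...) {
  cat(sprintf("<stratum_map> %d strata over %d x %d cells (%d masked)\n",
              nrow(x$legend), nrow(x$codes), ncol(x$codes),
              sum(x$codes == 0L)))
  invisible(x)
}

#' Restrict a stratum map to pixels valid in every indicator
#'
#' Applies the complete-case rule: a pixel that is nodata in any indicator is
#' excluded from all stratum statistics (the composite index needs all
#' standardized densities at a pixel). Strata left empty are dropped from the
#' legend and remaining codes are renumbered consecutively.
#'
#' @param strata a `stratum_map`.
#' @param valid logical matrix, `TRUE` where every indicator is observed.
#' @return a `stratum_map` covering only complete-case vegetated pixels.
#' @export
mask_strata <- function(strata, valid) {
  stopifnot(inherits(strata, "stratum_map"),
            identical(dim(valid), dim(strata$codes)))
  codes <- strata$codes
  codes[!valid] <- 0L
  keep <- sort(unique(codes[codes > 0L]))
  if (length(keep) == 0L) stop("complete-case mask removed every stratum")
  legend <- strata$legend[match(keep, strata$legend$code), , drop = FALSE]
  legend$code <- seq_along(keep)
  rownames(legend) <- NULL
  new_codes <- matrix(0L, nrow(codes), ncol(codes))
  pos <- codes > 0L
  new_codes[pos] <- match(codes[pos], keep)
  structure(list(codes = new_codes, legend = legend,
                 geometry = strata$geometry),
            class = "stratum_map")
}

#' Export a stratum legend as CSV
#'
#' @param strata a `stratum_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stratum_legend <- function(strata, path) {
  utils::write.csv(strata$legend, path, row.names = FALSE)
  invisible(path)
}
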