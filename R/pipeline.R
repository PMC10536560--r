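#' Assessment options
#'
#' Collects the tunable parameters of the assessment with their published
#' defaults: maximum stratum references, global per-year z-score
#' standardization, PCA weighting with cumulative contribution threshold
#' `rho = 0.85`, five Jenks classes on the pooled epochs, and +-0.05 change
#' thresholds.
#'
#' @param reference_method `"max"` (default) or `"percentile"`.
#' @param q upper percentile when `reference_method = "percentile"`.
#' @param standardization `"per_year"` (default; each epoch standardized on
#'   its own statistics) or `"shared_baseline"` (the first epoch's
#'   parameters applied to every epoch, removing re-standardization drift
#'   from the change signal).
#' @param rho cumulative contribution-rate threshold for PCA weighting.
#' @param weights_in optional named numeric vector of fixed indicator
#'   weights; when given, PCA estimation is skipped.
#' @param loading_scale,signed_loadings passed to [pca_weights()].
#' @param breaks `"jenks"` (default), a preset name from
#'   [EQI_BREAK_PRESETS], or a numeric vector of fixed cut points.
#' @param k number of EQI classes (default 5).
#' @param jenks_sample_size subsample cap for Jenks on large rasters.
#' @param change_thresholds length-2 `c(lower, upper)` significance
#'   thresholds on the EQI difference.
#' @param weighting `"pixel"` or `"cosine"` area weighting for summary
#'   tables.
#' @param seed RNG seed used for any subsampling.
#' @return list of class `assessment_options`.
#' @export
assessment_options <- function(reference_method = "max", q = 0.99,
                               standardization = "per_year", rho = 0.85,
                               weights_in = NULL,
                               loading_scale = "unit",
                               signed_loadings = FALSE,
                               breaks = "jenks", k = 5L,
                               jenks_sample_size = 1e5,
                               change_thresholds = c(-0.05, 0.05),
                               weighting = "pixel", seed = 1L) {
  stopifnot(reference_method %in% c("max", "percentile"),
            standardization %in% c("per_year", "shared_baseline"),
            weighting %in% c("pixel", "cosine"))
  if (!is.numeric(rho) || rho <= 0 || rho > 1)
    stop("rho must lie in (0, 1]")
  if (length(change_thresholds) != 2L ||
      !(change_thresholds[1] < change_thresholds[2]))
    stop("change_thresholds must be c(lower, upper) with lower < upper")
  if (is.character(breaks) && breaks != "jenks" &&
      !breaks %in% names(EQI_BREAK_PRESETS))
    stop("breaks must be \"jenks\", a preset name, or numeric cut points")
  structure(list(reference_method = reference_method, q = q,
                 standardization = standardization, rho = rho,
                 weights_in = weights_in, loading_scale = loading_scale,
                 signed_loadings = signed_loadings, breaks = breaks,
                 k = as.integer(k), jenks_sample_size = jenks_sample_size,
                 change_thresholds = change_thresholds,
                 weighting = weighting, seed = as.integer(seed)),
            class = "assessment_options")
}

#' Run the full ecosystem-quality assessment in memory
#'
#' Orchestrates the complete method on in-memory objects:
#' composite each indicator's sub-annual stack to an annual grid (maximum
#' value composite), harmonize onto the analysis grid (nearest neighbor),
#' stratify (zones x reclassified ecosystem types, complete-case masked),
#' compute stratified reference values and indicator relative densities,
#' z-score standardize, derive PCA weights per epoch and average them,
#' combine into the continuous EQI, classify into `k` levels (Jenks on the
#' pooled epochs by default), and — with two epochs — difference, classify
#' change, and tabulate area shares.
#'
#' @param indicators named list (one entry per indicator, e.g. `lai`,
#'   `fvc`, `gpp`); each entry a named-by-year list of `grid_stack`s.
#' @param zones `eqi_grid` of eco-geographical zone identifiers; also
#'   defines the analysis grid.
#' @param lulc named-by-year list of LULC `eqi_grid`s on the analysis grid.
#' @param scheme an [ecotype_scheme()].
#' @param options an [assessment_options()].
#' @return object of class `eqi_assessment`: list with `years`, `weights`
#'   (`weight_set`), `pca` (per-year `pca_weights` or `NULL`), `eqi` (an
#'   `eqi_result`), `change` (a `change_result` or `NULL`), `level_tables`
#'   (per-year `change_tables` of level shares), `strata`, `references`,
#'   `standardization` (per year/indicator), `options`.
#' @export
run_assessment <- function(indicators, zones, lulc, scheme,
                           options = assessment_options()) {
  stopifnot(is.list(indicators), length(indicators) >= 1L,
            inherits(zones, "eqi_grid"), inherits(scheme, "ecotype_scheme"),
            inherits(options, "assessment_options"))
  ind_names <- names(indicators)
  if (is.null(ind_names)) stop("indicators must be a named list")
  years <- names(indicators[[1L]])
  for (ind in indicators)
    if (!identical(names(ind), years))
      stop("all indicators must cover the same years")
  if (!identical(sort(names(lulc)), sort(years)))
    stop("lulc must be supplied for the same years as the indicators")

  ## per-year: composite -> harmonize -> stratify -> IRD -> standardize
  annual <- strata_y <- refs_y <- z_y <- params_y <- list()
  for (y in years) {
    ann <- lapply(indicators, function(ind) {
      g <- max_value_composite(ind[[y]])
      if (!assert_aligned(list(g, zones))) g <- resample_nearest(g, zones)
      g
    })
    ecotypes <- reclassify_lulc(lulc[[y]], scheme)
    st <- build_strata(zones, ecotypes)
    valid <- Reduce(`&`, lapply(ann, function(g) !is.na(g$values)))
    st <- mask_strata(st, valid)

    refs <- z <- params <- stats::setNames(vector("list", length(ann)),
                                           ind_names)
    for (nm in ind_names) {
      refs[[nm]] <- compute_reference(ann[[nm]], st,
                                      method = options$reference_method,
                                      q = options$q)
      ird <- compute_ird(ann[[nm]], st, refs[[nm]])
      p_in <- if (options$standardization == "shared_baseline" &&
                  y != years[1L]) params_y[[years[1L]]][[nm]] else NULL
      s <- standardize(ird, p_in)
      z[[nm]] <- s$grid
      params[[nm]] <- s$params
    }
    annual[[y]] <- ann; strata_y[[y]] <- st
    refs_y[[y]] <- refs; z_y[[y]] <- z; params_y[[y]] <- params
  }

  ## weights: PCA per year over complete-case pixels, averaged
  pca_by_year <- NULL
  if (is.null(options$weights_in)) {
    pca_by_year <- stats::setNames(lapply(years, function(y) {
      ok <- Reduce(`&`, lapply(z_y[[y]], function(g) !is.na(g$values)))
      X <- vapply(z_y[[y]], function(g) g$values[ok], numeric(sum(ok)))
      pca_weights(X, rho = options$rho,
                  loading_scale = options$loading_scale,
                  signed_loadings = options$signed_loadings)
    }), years)
    weights <- average_weights(pca_by_year)
  } else {
    w <- options$weights_in
    if (!setequal(names(w), ind_names))
      stop("weights_in names must match the indicators")
    weights <- average_weights(list(w[ind_names]))
  }

  ## EQI, classification, change
  eqi_grids <- stats::setNames(
    lapply(years, function(y) compute_eqi(z_y[[y]], weights)), years)
  fixed <- if (identical(options$breaks, "jenks")) NULL else options$breaks
  eres <- eqi_result(eqi_grids, k = options$k, breaks = fixed,
                     sample_size = options$jenks_sample_size,
                     seed = options$seed)
  level_tables <- stats::setNames(lapply(years, function(y)
    summarize_classes(eres$levels[[y]], strata_y[[y]],
                      weighting = options$weighting)), years)

  change <- NULL
  if (length(years) >= 2L) {
    y1 <- years[1L]; y2 <- years[length(years)]
    both <- !is.na(eqi_grids[[y1]]$values) & !is.na(eqi_grids[[y2]]$values)
    st12 <- mask_strata(strata_y[[y1]], both)
    change <- change_analysis(eqi_grids[[y1]], eqi_grids[[y2]], st12,
                              thresholds = options$change_thresholds,
                              weighting = options$weighting)
  }

  structure(list(years = years, weights = weights, pca = pca_by_year,
                 eqi = eres, change = change, level_tables = level_tables,
                 strata = strata_y, references = refs_y,
                 standardization = params_y, options = options),
            class = "eqi_assessment")
}

#' @export
print.eqi_assessment <- function(x, ...) {
  cat(sprintf("<eqi_assessment> years %s\n", paste(x$years, collapse = ", ")))
  print(x$weights)
  print(x$eqi)
  if (!is.null(x$change)) print(x$change$tables)
  invisible(x)
}

#' Run the pipeline from a configuration file
#'
#' Reads a YAML run configuration (see [write_scenario()] for a generated
#' example), loads every input raster, executes [run_assessment()], and
#' writes the full artifact directory: EQI and level grids per epoch, the
#' difference and change-class grids, reference tables, standardization
#' parameters, weights with PCA provenance, breaks, summary tables, the
#' stratum legend, the resolved configuration, and a machine-readable run
#' log. Reruns with the same configuration are bit-identical.
#'
#' @param config path to a YAML file, or an equivalent named list. Fields:
#'   `years`, `indicators` (per indicator, per year: stack manifest path),
#'   `zones`, `lulc` (per year), `scheme`, optional `options` (see
#'   [assessment_options()]), `output` directory.
#' @param base_dir directory against which relative paths are resolved;
#'   defaults to the config file's directory (or `"."` for a list).
#' @return the `eqi_assessment`, invisibly, with the artifact directory in
#'   attribute `"output"`.
#' @export
run_pipeline <- function(config, base_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  rel <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)

  for (f in c("years", "indicators", "zones", "lulc", "scheme", "output"))
    if (is.null(config[[f]])) stop("config missing field: ", f)
  oin <- as.list(config$options)
  if (!is.null(oin$change_thresholds))
    oin$change_thresholds <- as.numeric(unlist(oin$change_thresholds))
  if (!is.null(oin$weights_in)) oin$weights_in <- unlist(oin$weights_in)
  if (!is.null(oin$breaks) && !is.character(oin$breaks))
    oin$breaks <- as.numeric(unlist(oin$breaks))
  opts <- do.call(assessment_options, oin)
  years <- as.character(config$years)

  indicators <- lapply(config$indicators, function(by_year) {
    stats::setNames(lapply(years, function(y) {
      p <- by_year[[y]]
      if (is.null(p)) stop("missing manifest for year ", y)
      read_stack_manifest(rel(p))
    }), years)
  })
  zones <- read_grid_asc(rel(config$zones))
  lulc <- stats::setNames(lapply(years, function(y)
    read_grid_asc(rel(config$lulc[[y]]))), years)
  scheme <- ecotype_scheme(rel(config$scheme))

  res <- run_assessment(indicators, zones, lulc, scheme, options = opts)

  out <- rel(config$output)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (y in years) {
    write_grid_asc(res$eqi$eqi[[y]], file.path(out, sprintf("eqi_%s.asc", y)))
    write_grid_asc(res$eqi$levels[[y]],
                   file.path(out, sprintf("levels_%s.asc", y)))
    write_stratum_legend(res$strata[[y]],
                         file.path(out, sprintf("strata_legend_%s.csv", y)))
    for (nm in names(res$references[[y]]))
      write_reference_table(res$references[[y]][[nm]],
                            file.path(out, sprintf("reference_%s_%s.csv", nm, y)))
    write_change_tables(res$level_tables[[y]], out,
                        prefix = sprintf("levels_%s", y))
  }
  if (!is.null(res$change)) {
    write_grid_asc(res$change$delta, file.path(out, "delta_eqi.asc"))
    write_grid_asc(res$change$sig, file.path(out, "change_classes.asc"))
    write_change_tables(res$change$tables, out, prefix = "change")
  }
  write_weights_json(res$weights, file.path(out, "weights.json"))
  jsonlite::write_json(
    list(breaks = res$eqi$breaks, break_source = res$eqi$break_source,
         k = opts$k),
    file.path(out, "breaks.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$standardization,
                       file.path(out, "standardization_params.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(config, file.path(out, "config_resolved.yaml"))
  jsonlite::write_json(
    list(package = "eqiscope",
         version = as.character(utils::packageVersion("eqiscope")),
         r_version = R.version.string,
         seed = opts$seed,
         config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
         timestamp_free = TRUE),
    file.path(out, "run_log.json"), auto_unbox = TRUE, digits = NA)
  attr(res, "output") <- out
  invisible(res)
}
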