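#' Configure a synthetic two-epoch assessment scenario
#'
#' Builds the configuration for [generate_scenario()], which fabricates a
#' fully self-contained dataset with the statistical structure the
#' assessment assumes: three positively co-varying vegetation indicators
#' (LAI-like, FVC-like, GPP-like) over contiguous eco-geographical zones and
#' ecosystem-type patches, sub-annual series whose maximum value composite
#' recovers the annual field, a second epoch that is a small temporal
#' perturbation of the first, and rectangular regions with planted EQI
#' change of known sign.
#'
#' Defaults emulate the study conditions of a continental two-epoch
#' assessment at 1 km: a 200 x 200 analysis grid, 10 eco-geographical
#' zones, six vegetation ecosystem types plus non-vegetation, quarterly
#' LAI at analysis resolution, 8-day (46-slice) FVC and GPP at half the
#' cell size (the 500 m analog, exercising the resampling path), strong
#' positive inter-indicator correlation, 2% nodata, and planted change
#' offsets of +-0.5 on the EQI scale.
#'
#' @param nrow,ncol analysis-grid shape (default 200 x 200).
#' @param cell analysis cell size in map units (default 1000).
#' @param n_zones number of Voronoi-contiguous eco-geographical zones
#'   (default 10).
#' @param n_patches number of Voronoi seeds for the LULC mosaic
#'   (default 150).
#' @param correlation 3x3 target correlation of the indicators' stochastic
#'   component (LAI, FVC, GPP order); must be symmetric positive-definite
#'   with unit diagonal.
#' @param sd_frac spread of each indicator around its stratum mean, as a
#'   fraction of the mean (default 0.2).
#' @param spatial_weight share `a` of a smooth shared spatial field mixed
#'   into each indicator's Gaussian driver (default 0.45); the copula
#'   correlation is adjusted so the per-pixel correlation still meets the
#'   target.
#' @param nodata_fraction approximate fraction of the study area covered by
#'   nodata blobs in the indicator rasters (default 0.02).
#' @param temporal_sd year-to-year perturbation of the indicators outside
#'   planted regions, as a fraction of each indicator's spatial spread
#'   (default 0.02; vegetation fields are highly persistent between nearby
#'   years).
#' @param change_regions list of planted-change regions, each a list with
#'   `rows`, `cols` (fractional extents in [0, 1]) and `offset` (EQI-scale
#'   shift applied to all indicators in the second epoch).
#' @param n_lai_slices quarterly LAI slices per year (default 4).
#' @param n_fine_slices 8-day FVC/GPP slices per year (default 46).
#' @param years two epoch labels (default `c(2016, 2020)`).
#' @param seed RNG seed; the whole scenario is a deterministic function of
#'   the configuration.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(nrow = 200L, ncol = 200L, cell = 1000,
                            n_zones = 10L, n_patches = 150L,
                            correlation = matrix(c(1, 0.8, 0.75,
                                                   0.8, 1, 0.7,
                                                   0.75, 0.7, 1), 3, 3),
                            sd_frac = 0.2, spatial_weight = 0.45,
                            nodata_fraction = 0.02, temporal_sd = 0.02,
                            change_regions = list(
                              list(rows = c(0.08, 0.28),
                                   cols = c(0.08, 0.30), offset = 0.5),
                              list(rows = c(0.60, 0.85),
                                   cols = c(0.55, 0.80), offset = -0.5)),
                            n_lai_slices = 4L, n_fine_slices = 46L,
                            years = c(2016L, 2020L), seed = 1L) {
  correlation <- as.matrix(correlation)
  if (!isSymmetric(unname(correlation)) ||
      any(abs(diag(correlation) - 1) > 1e-12))
    stop("target correlation must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("target correlation matrix is not positive-definite")
  stopifnot(nrow >= 20L, ncol >= 20L, n_zones >= 1L, n_patches >= n_zones,
            sd_frac > 0, spatial_weight >= 0, spatial_weight < 1,
            nodata_fraction >= 0, nodata_fraction < 0.5,
            temporal_sd >= 0, length(years) == 2L)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell = cell, n_zones = as.integer(n_zones),
                 n_patches = as.integer(n_patches),
                 correlation = correlation, sd_frac = sd_frac,
                 spatial_weight = spatial_weight,
                 nodata_fraction = nodata_fraction,
                 temporal_sd = temporal_sd,
                 change_regions = change_regions,
                 n_lai_slices = as.integer(n_lai_slices),
                 n_fine_slices = as.integer(n_fine_slices),
                 years = as.integer(years), seed = as.integer(seed),
                 crs = "synthetic-metric"),
            class = "scenario_config")
}

# Stratum mean levels per ecosystem type for (LAI, FVC, GPP): plausible
# physical magnitudes so unit heterogeneity stresses the standardization.
SYNTH_TYPE_MEANS <- rbind(
  cultivated = c(lai = 3.2, fvc = 0.60, gpp = 1500),
  forest     = c(lai = 5.0, fvc = 0.75, gpp = 2200),
  grassland  = c(lai = 1.8, fvc = 0.45, gpp = 900),
  shrub      = c(lai = 1.2, fvc = 0.35, gpp = 700),
  wetland    = c(lai = 2.5, fvc = 0.55, gpp = 1300),
  tundra     = c(lai = 0.6, fvc = 0.20, gpp = 300))

SYNTH_RANGES <- list(lai = c(0, 7), fvc = c(0, 1), gpp = c(0, 3000))

# LULC codes written into the synthetic land-cover raster; the scheme maps
# them back onto the six vegetation types + non-vegetation.
SYNTH_LULC_CODES <- c(cultivated = 10, forest = 20, grassland = 30,
                      shrub = 40, wetland = 50, tundra = 60,
                      water = 80, barren = 90)

#' The LULC reclassification scheme of the synthetic scenario
#'
#' @return an [ecotype_scheme()] mapping the synthetic LULC codes.
#' @export
synthetic_scheme <- function() {
  ecotype_scheme(data.frame(
    lulc_code = as.integer(SYNTH_LULC_CODES),
    type = c(ECOSYSTEM_TYPES, "non_vegetation", "non_vegetation")))
}

# Smooth unit-variance field: coarse iid normals bilinearly interpolated up.
smooth_field <- function(nr, nc, scale = 12L) {
  nrc <- max(2L, ceiling(nr / scale) + 1L)
  ncc <- max(2L, ceiling(nc / scale) + 1L)
  coarse <- matrix(stats::rnorm(nrc * ncc), nrc, ncc)
  ri <- (seq_len(nr) - 1) / (nr - 1) * (nrc - 1) + 1
  ci <- (seq_len(nc) - 1) / (nc - 1) * (ncc - 1) + 1
  r0 <- pmin(floor(ri), nrc - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), ncc - 1L); fc <- ci - c0
  a <- coarse[r0, c0] * outer(1 - fr, 1 - fc) +
       coarse[r0 + 1, c0] * outer(fr, 1 - fc) +
       coarse[r0, c0 + 1] * outer(1 - fr, fc) +
       coarse[r0 + 1, c0 + 1] * outer(fr, fc)
  as.numeric(scale(as.numeric(a))) |> matrix(nr, nc)
}

# Voronoi labels: each cell takes the label of the nearest seed (map coords).
voronoi_labels <- function(xc, yc, seed_x, seed_y, labels) {
  nr <- length(yc); nc <- length(xc)
  best <- matrix(Inf, nr, nc)
  lab <- matrix(labels[1L], nr, nc)
  for (s in seq_along(seed_x)) {
    d <- outer((yc - seed_y[s])^2, (xc - seed_x[s])^2, `+`)
    hit <- d < best
    best[hit] <- d[hit]
    lab[hit] <- labels[s]
  }
  lab
}

# Smooth saturation toward the range ceiling: identity below hi - margin,
# exponential approach to hi above it. Monotone, so stratum ordering (and
# the reference pixel) is preserved, and it leaves no probability atom at
# the ceiling the way a hard clamp would.
squash_high <- function(x, lo, hi, frac = 0.15) {
  m <- frac * (hi - lo)
  knee <- hi - m
  over <- !is.na(x) & x > knee
  x[over] <- knee + m * (1 - exp(-(x[over] - knee) / m))
  pmax(x, lo)
}

region_mask <- function(nr, nc, region) {
  rows <- pmax(1L, pmin(nr, ceiling(region$rows * nr)))
  cols <- pmax(1L, pmin(nc, ceiling(region$cols * nc)))
  m <- matrix(FALSE, nr, nc)
  m[rows[1L]:rows[2L], cols[1L]:cols[2L]] <- TRUE
  m
}

#' Generate a synthetic two-epoch scenario
#'
#' Deterministic in `config$seed`. Indicators are built per fine pixel as
#' `mean(type) * zone_factor + sd * G`, where the Gaussian drivers `G` mix a
#' smooth shared spatial field with a Gaussian copula whose correlation is
#' adjusted so the total per-pixel correlation matches
#' `config$correlation`; values are clamped to plausible physical ranges.
#' The second epoch adds small temporal noise everywhere and shifts all
#' three indicators inside each planted region by `offset` times the
#' indicator's spatial spread, so the sign of the planted EQI change is
#' known by construction. Sub-annual slices are scaled-down copies of the
#' annual field with the seasonal peak left exact, so maximum value
#' compositing recovers the annual field.
#'
#' @param config a [scenario_config()].
#' @return list of class `scenario` with elements `indicators` (named list
#'   `lai`/`fvc`/`gpp`, each a per-year named list of `grid_stack`s; FVC and
#'   GPP at half the analysis cell size), `zones` (`eqi_grid`), `lulc`
#'   (per-year named list of `eqi_grid`s), `scheme`, `change_masks`
#'   (analysis-grid logical matrices, one per planted region, with
#'   `offset` attributes), and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, generate_scenario_impl(config))
}

generate_scenario_impl <- function(cfg) {
  nr <- cfg$nrow; nc <- cfg$ncol; cell <- cfg$cell
  nrf <- 2L * nr; ncf <- 2L * nc; cellf <- cell / 2
  xmin <- 0; ymax <- nr * cell
  crs <- cfg$crs
  template <- eqi_grid(matrix(0, nr, nc), xmin = xmin, ymax = ymax,
                       dx = cell, dy = cell, crs = crs)
  xc <- grid_col_centers(template); yc <- grid_row_centers(template)
  fine_template <- eqi_grid(matrix(0, nrf, ncf), xmin = xmin, ymax = ymax,
                            dx = cellf, dy = cellf, crs = crs)
  xcf <- grid_col_centers(fine_template); ycf <- grid_row_centers(fine_template)

  ## zones: Voronoi over seed points, same seeds at both resolutions
  zx <- stats::runif(cfg$n_zones, xmin, xmin + nc * cell)
  zy <- stats::runif(cfg$n_zones, ymax - nr * cell, ymax)
  zones_c <- voronoi_labels(xc, yc, zx, zy, seq_len(cfg$n_zones))
  zones_f <- voronoi_labels(xcf, ycf, zx, zy, seq_len(cfg$n_zones))

  ## LULC mosaic: patch seeds with type labels; non-vegetation ~15%
  px <- stats::runif(cfg$n_patches, xmin, xmin + nc * cell)
  py <- stats::runif(cfg$n_patches, ymax - nr * cell, ymax)
  pool <- c(names(SYNTH_LULC_CODES)[1:6], "water", "barren")
  pprob <- c(0.17, 0.17, 0.17, 0.12, 0.11, 0.11, 0.075, 0.075)
  ptype <- sample(pool, cfg$n_patches, replace = TRUE, prob = pprob)
  # guarantee every vegetation type at least two patches
  for (t in names(SYNTH_LULC_CODES)[1:6])
    if (sum(ptype == t) < 2L)
      ptype[sample(which(!ptype %in% t), 2L)] <- t
  lulc_c <- voronoi_labels(xc, yc, px, py, SYNTH_LULC_CODES[ptype])
  type_f <- voronoi_labels(xcf, ycf, px, py, ptype)

  ## Gaussian drivers at fine resolution
  a <- cfg$spatial_weight
  Rtot <- cfg$correlation
  Radj <- (Rtot - a^2) / (1 - a^2); diag(Radj) <- 1
  ch <- tryCatch(chol(Radj), error = function(e)
    stop("target correlation too weak for spatial_weight ", a,
         ": adjusted copula not positive-definite"))
  f0 <- smooth_field(nrf, ncf)
  E <- matrix(stats::rnorm(nrf * ncf * 3L), ncol = 3L) %*% ch
  G <- a * as.numeric(f0) + sqrt(1 - a^2) * E   # recycled over 3 columns

  zone_factor <- stats::runif(cfg$n_zones, 0.85, 1.15)
  zf_f <- matrix(zone_factor[zones_f], nrf, ncf)
  veg_idx <- match(type_f, rownames(SYNTH_TYPE_MEANS))   # NA for non-veg

  ## nodata blobs (map-coordinate circles shared by all indicators/epochs)
  nodata_mask_f <- matrix(FALSE, nrf, ncf)
  if (cfg$nodata_fraction > 0) {
    n_blobs <- 3L
    area <- (nc * cell) * (nr * cell) * cfg$nodata_fraction / n_blobs
    rad <- sqrt(area / pi)
    bx <- stats::runif(n_blobs, xmin, xmin + nc * cell)
    by <- stats::runif(n_blobs, ymax - nr * cell, ymax)
    for (b in seq_len(n_blobs)) {
      d <- outer((ycf - by[b])^2, (xcf - bx[b])^2, `+`)
      nodata_mask_f <- nodata_mask_f | (d <= rad^2)
    }
  }

  inds <- c("lai", "fvc", "gpp")
  annual1 <- annual2 <- stats::setNames(vector("list", 3L), inds)
  masks_c <- lapply(cfg$change_regions, function(rg) {
    m <- region_mask(nr, nc, rg)
    attr(m, "offset") <- rg$offset
    m
  })
  # fine-grid masks expand the analysis-grid masks (each coarse cell covers
  # a 2x2 fine block), so planted regions agree exactly across resolutions
  fine_of_coarse <- ceiling(row(matrix(0L, nrf, ncf)) / 2) +
    (ceiling(col(matrix(0L, nrf, ncf)) / 2) - 1L) * nr
  masks_f <- lapply(masks_c, function(m) matrix(m[fine_of_coarse], nrf, ncf))

  for (i in seq_along(inds)) {
    mu_t <- SYNTH_TYPE_MEANS[, i][veg_idx]       # NA on non-veg
    mu <- matrix(mu_t, nrf, ncf) * zf_f
    sdev <- cfg$sd_frac * mu
    v1 <- mu + sdev * matrix(G[, i], nrf, ncf)
    rng <- SYNTH_RANGES[[inds[i]]]
    v1 <- squash_high(v1, rng[1], rng[2])
    v1[is.na(mu_t)] <- stats::runif(sum(is.na(mu_t)), 0, 0.02 * rng[2])

    # Per-pixel shift scale calibrated to the EQI path: a shift of
    # delta * sd(IRD) * Fmax(stratum) in indicator units moves that pixel's
    # standardized density by ~delta, so planted offsets land on the EQI
    # scale regardless of the stratum's physical magnitude.
    strat_key <- ifelse(!is.na(veg_idx), as.numeric(zones_f) * 10 + veg_idx,
                        NA_real_)
    fk <- factor(strat_key)
    fmax_s <- tapply(as.numeric(v1), fk, max)
    denom <- as.numeric(fmax_s[fk])              # NA on non-vegetation
    ird1 <- as.numeric(v1) / denom
    sd_ird <- stats::sd(ird1, na.rm = TRUE)
    px_scale <- matrix(sd_ird * denom, nrf, ncf)
    px_scale[is.na(px_scale)] <- 0               # non-vegetation: no signal

    # Reference state of each stratum as the analysis grid will see it:
    # the analysis grid samples fine pixel (2i-1, 2j-1) for coarse cell
    # (i, j) (nearest-center tie rule), strata come from the coarse zone
    # and LULC rasters, and nodata pixels drop out. Planted improvements
    # are capped at this reference — quality cannot exceed the regional
    # best — so they do not inflate the epoch-2 reference values.
    rs <- 2L * seq_len(nr) - 1L; cs <- 2L * seq_len(nc) - 1L
    tc_idx <- match(lulc_c, SYNTH_LULC_CODES[1:6])
    key_c <- ifelse(!is.na(tc_idx) & !nodata_mask_f[rs, cs],
                    zones_c * 10 + tc_idx, NA_real_)
    samp_v1 <- v1[rs, cs]
    ok_c <- !is.na(key_c)
    fmax_c <- tapply(samp_v1[ok_c], key_c[ok_c], max)
    cap_c <- matrix(NA_real_, nr, nc)
    cap_c[ok_c] <- fmax_c[as.character(key_c[ok_c])]
    cap_f <- cap_c[ceiling(row(matrix(0, nrf, ncf)) / 2) +
                   (ceiling(col(matrix(0, nrf, ncf)) / 2) - 1L) * nr]
    cap_f <- matrix(pmin(denom, cap_f, na.rm = TRUE), nrf, ncf)

    # each stratum's reference pixel (on the analysis grid) keeps its
    # epoch-1 value, so planted decreases cannot deflate the reference
    is_ref_c <- ok_c & samp_v1 == cap_c
    protect <- matrix(FALSE, nrf, ncf)
    protect[rs, cs] <- is_ref_c

    # at the pixels the analysis grid samples, scale shifts by the stratum
    # the analysis will assign (fine and coarse labels can disagree along
    # patch boundaries; the analysis-grid label is the one that counts)
    scale_c <- matrix(0, nr, nc)
    scale_c[ok_c] <- sd_ird * fmax_c[as.character(key_c[ok_c])]
    px_scale[rs, cs] <- scale_c

    v2 <- v1 + cfg$temporal_sd * px_scale * matrix(stats::rnorm(nrf * ncf),
                                                   nrf, ncf)
    for (j in seq_along(masks_f)) {
      m <- masks_f[[j]]
      off <- cfg$change_regions[[j]]$offset
      v2[m] <- v2[m] + off * px_scale[m]
      if (off > 0) v2[m] <- pmin(v2[m], cap_f[m], na.rm = TRUE)
    }
    v2[protect] <- v1[protect]
    v2 <- pmin(pmax(v2, rng[1]), rng[2])   # safety only; v2 <= cap < ceiling

    v1[nodata_mask_f] <- NA_real_
    v2[nodata_mask_f] <- NA_real_
    annual1[[i]] <- grid_like(fine_template, v1)
    annual2[[i]] <- grid_like(fine_template, v2)
  }

  ## seasonal profiles peaking at a zone-dependent period (peak kept exact
  ## so MVC recovers the annual field)
  make_stack <- function(annual_fine, n_slices, at_coarse, year,
                         zones_mat_f, zones_mat_c) {
    annual <- if (at_coarse) resample_nearest(annual_fine, template)
              else annual_fine
    zmat <- if (at_coarse) zones_mat_c else zones_mat_f
    peak <- 1L + (zone_factor * 7919) %% 1 * (n_slices - 1L)  # deterministic
    peak <- as.integer(round(peak))
    slices <- vector("list", n_slices)
    width <- max(2, n_slices / 5)
    for (t in seq_len(n_slices)) {
      s <- exp(-0.5 * ((t - peak[zmat]) / width)^2)
      damp <- matrix(1 - 0.1 * stats::runif(length(s)),
                     nrow(annual$values), ncol(annual$values))
      fac <- matrix(s, nrow(annual$values), ncol(annual$values)) * damp
      fac[matrix(s, nrow(fac), ncol(fac)) >= 1 - 1e-12] <- 1  # exact at peak
      slices[[t]] <- grid_like(annual, annual$values * fac)
    }
    grid_stack(slices, timestamps = seq_len(n_slices), year = year)
  }

  years <- cfg$years
  indicators <- list(
    lai = stats::setNames(list(
      make_stack(annual1$lai, cfg$n_lai_slices, TRUE, years[1], zones_f, zones_c),
      make_stack(annual2$lai, cfg$n_lai_slices, TRUE, years[2], zones_f, zones_c)),
      as.character(years)),
    fvc = stats::setNames(list(
      make_stack(annual1$fvc, cfg$n_fine_slices, FALSE, years[1], zones_f, zones_c),
      make_stack(annual2$fvc, cfg$n_fine_slices, FALSE, years[2], zones_f, zones_c)),
      as.character(years)),
    gpp = stats::setNames(list(
      make_stack(annual1$gpp, cfg$n_fine_slices, FALSE, years[1], zones_f, zones_c),
      make_stack(annual2$gpp, cfg$n_fine_slices, FALSE, years[2], zones_f, zones_c)),
      as.character(years)))

  lulc_grid <- grid_like(template, lulc_c)
  structure(list(
    indicators = indicators,
    zones = grid_like(template, zones_c),
    lulc = stats::setNames(list(lulc_grid, lulc_grid), as.character(years)),
    scheme = synthetic_scheme(),
    change_masks = masks_c,
    config = cfg), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<scenario> %d x %d analysis grid, %d zones, ",
                     "years %s, seed %d\n"),
              cfg$nrow, cfg$ncol, cfg$n_zones,
              paste(cfg$years, collapse = "/"), cfg$seed))
  invisible(x)
}

#' Write a scenario to disk in the pipeline's input layout
#'
#' Writes every indicator stack (ASCII grids + YAML manifests), the zone and
#' LULC rasters, the reclassification scheme CSV, and a ready-to-run
#' pipeline configuration `config.yaml`.
#'
#' @param scenario a `scenario` from [generate_scenario()].
#' @param dir output directory (created).
#' @return path of the written pipeline config, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  years <- as.character(scenario$config$years)
  manifests <- list()
  for (ind in names(scenario$indicators))
    for (y in years) {
      nm <- sprintf("%s_%s", ind, y)
      manifests[[ind]][[y]] <-
        basename(write_stack_manifest(scenario$indicators[[ind]][[y]],
                                      dir, nm))
    }
  write_grid_asc(scenario$zones, file.path(dir, "zones.asc"))
  for (y in years)
    write_grid_asc(scenario$lulc[[y]], file.path(dir, sprintf("lulc_%s.asc", y)))
  utils::write.csv(scenario$scheme$mapping, file.path(dir, "scheme.csv"),
                   row.names = FALSE)
  cfgp <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    years = as.integer(years),
    indicators = manifests,
    zones = "zones.asc",
    lulc = stats::setNames(as.list(sprintf("lulc_%s.asc", years)), years),
    scheme = "scheme.csv",
    options = list(reference_method = "max", rho = 0.85,
                   standardization = "per_year", breaks = "jenks", k = 5,
                   jenks_sample_size = 1e5,
                   change_thresholds = c(-0.05, 0.05), seed = 1),
    output = "results"), cfgp)
  invisible(cfgp)
}
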