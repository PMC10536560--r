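#' Bundle co-registered sub-annual rasters into a stack
#'
#' A `grid_stack` holds the sub-annual slices (quarterly or 8-day) of one
#' indicator for one year. All slices must share one geometry and the
#' timestamps must be strictly increasing.
#'
#' @param slices list of `eqi_grid` sharing one geometry.
#' @param timestamps numeric or integer labels (quarter index, 8-day period
#'   index), strictly increasing, one per slice.
#' @param year integer epoch the stack belongs to.
#' @return an object of class `grid_stack`.
#' @export
grid_stack <- function(slices, timestamps = seq_along(slices), year = NA_integer_) {
  stopifnot(is.list(slices), length(slices) >= 1L)
  lapply(slices, function(s) stopifnot(inherits(s, "eqi_grid")))
  if (length(timestamps) != length(slices))
    stop("one timestamp per slice required")
  if (length(slices) > 1L) {
    stop_if_misaligned(slices, "stack slices")
    if (any(diff(as.numeric(timestamps)) <= 0))
      stop("timestamps must be strictly increasing")
  }
  structure(list(slices = slices, timestamps = timestamps,
                 year = as.integer(year)),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d slices, year %s, %d x %d cells\n",
              length(x$slices), x$year,
              nrow(x$slices[[1]]$values), ncol(x$slices[[1]]$values)))
  invisible(x)
}

#' Maximum value composite of a sub-annual raster stack
#'
#' Per-pixel maximum over all slices with a valid observation, the standard
#' compositing rule for vegetation index time series (it favors the
#' least-atmosphere-contaminated, peak-growth observation). A pixel is nodata
#' only when it is nodata in every slice.
#'
#' @param stack a `grid_stack`.
#' @return an `eqi_grid` with the stack's geometry (the annual composite).
#' @export
max_value_composite <- function(stack) {
  stopifnot(inherits(stack, "grid_stack"))
  if (length(stack$slices) == 0L) stop("empty stack")
  acc <- stack$slices[[1L]]$values
  for (s in stack$slices[-1L]) {
    v <- s$values
    take <- !is.na(v) & (is.na(acc) | v > acc)
    acc[take] <- v[take]
  }
  grid_like(stack$slices[[1L]], acc)
}

#' Nearest-neighbor resampling onto a target geometry
#'
#' Each output cell takes the value of the source cell whose center is
#' nearest the output cell center. Output cells whose center falls outside
#' the source extent, or whose nearest source cell is nodata, are nodata.
#' When an output center is exactly equidistant from two source centers the
#' cell with the smaller row index, then smaller column index, wins
#' (deterministic tie rule). No reprojection is performed: a crs mismatch is
#' an error, not a silent transform.
#'
#' @param source an `eqi_grid`.
#' @param target target geometry: an `eqi_grid` (its values are ignored) or a
#'   list with `nrow`, `ncol`, `xmin`, `ymax`, `dx`, `dy` and optionally `crs`.
#' @return an `eqi_grid` on the target geometry.
#' @export
resample_nearest <- function(source, target) {
  stopifnot(inherits(source, "eqi_grid"))
  tg <- if (inherits(target, "eqi_grid")) grid_geometry(target) else target
  for (k in c("nrow", "ncol", "xmin", "ymax", "dx", "dy"))
    if (is.null(tg[[k]])) stop("target geometry missing field ", k)
  if (!is.null(tg$crs) && !identical(tg$crs, source$crs))
    stop("crs mismatch: source '", source$crs, "' vs target '", tg$crs,
         "' (no implicit reprojection)")
  nr_s <- nrow(source$values); nc_s <- ncol(source$values)

  # Output centers in fractional source-cell units: u in (j-1, j] maps to
  # source column j. An integer u is the tie (center midway between columns
  # u and u+1); ceiling() resolves it to the smaller index. Same for rows,
  # counted from the top so "smaller row index" = northernmost.
  snap <- function(u) {
    r <- round(u)
    u[abs(u - r) < 1e-9] <- r[abs(u - r) < 1e-9]
    u
  }
  xc <- tg$xmin + (seq_len(tg$ncol) - 0.5) * tg$dx
  yc <- tg$ymax - (seq_len(tg$nrow) - 0.5) * tg$dy
  u <- snap((xc - source$xmin) / source$dx)
  v <- snap((source$ymax - yc) / source$dy)
  col_idx <- as.integer(ceiling(u)); col_idx[u == 0] <- 1L
  row_idx <- as.integer(ceiling(v)); row_idx[v == 0] <- 1L
  col_ok <- u >= 0 & u <= nc_s
  row_ok <- v >= 0 & v <= nr_s
  if (!any(col_ok) || !any(row_ok))
    stop("target geometry does not overlap the source extent")

  out <- matrix(NA_real_, tg$nrow, tg$ncol)
  ri <- row_idx[row_ok]; ci <- col_idx[col_ok]
  out[row_ok, col_ok] <- source$values[ri, ci, drop = FALSE]
  eqi_grid(out, xmin = tg$xmin, ymax = tg$ymax, dx = tg$dx, dy = tg$dy,
           crs = source$crs, nodata = source$nodata)
}

#' Read a stack manifest
#'
#' A manifest is a YAML file describing one indicator-year stack:
#' ```yaml
#' year: 2016
#' slices:
#'   - {path: lai_2016_q1.asc, timestamp: 1}
#'   - {path: lai_2016_q2.asc, timestamp: 2}
#' ```
#' Relative slice paths are resolved against the manifest's directory.
#'
#' @param path path to the YAML manifest.
#' @return a `grid_stack`.
#' @export
read_stack_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$slices) || length(m$slices) == 0L)
    stop("manifest has no slices: ", path)
  base <- dirname(path)
  slices <- lapply(m$slices, function(s) {
    p <- s$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    read_grid_asc(p)
  })
  ts <- vapply(m$slices, function(s) as.numeric(s$timestamp), numeric(1))
  grid_stack(slices, timestamps = ts,
             year = if (is.null(m$year)) NA_integer_ else m$year)
}

#' Write a stack and its manifest
#'
#' Writes each slice as an ASCII grid plus a YAML manifest readable by
#' [read_stack_manifest()].
#'
#' @param stack a `grid_stack`.
#' @param dir output directory (created if needed).
#' @param name base name for slice files, e.g. `"lai_2016"`.
#' @return path of the manifest, invisibly.
#' @export
write_stack_manifest <- function(stack, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(stack$slices))
  for (i in seq_along(stack$slices)) {
    f <- sprintf("%s_t%02d.asc", name, i)
    write_grid_asc(stack$slices[[i]], file.path(dir, f))
    entries[[i]] <- list(path = f, timestamp = stack$timestamps[[i]])
  }
  mpath <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(list(year = stack$year, slices = entries), mpath)
  invisible(mpath)
}
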