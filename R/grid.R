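#' Construct a georeferenced raster grid
#'
#' `eqi_grid` is the package's in-memory raster: a numeric matrix with an
#' axis-aligned (north-up) geotransform, a coordinate-reference tag and a
#' nodata sentinel. Missing observations are held as `NA` in `values`; the
#' `nodata` sentinel is used only on disk.
#'
#' @param values numeric (or integer) matrix, row 1 = northernmost row.
#' @param xmin x coordinate of the left edge (west).
#' @param ymax y coordinate of the top edge (north).
#' @param dx,dy cell width and height in map units; both strictly positive.
#' @param crs coordinate reference identifier (opaque string; compared for
#'   exact equality, never reprojected).
#' @param nodata numeric sentinel written to disk for missing cells.
#' @return an object of class `eqi_grid`.
#' @examples
#' g <- eqi_grid(matrix(runif(12), 3, 4), xmin = 0, ymax = 3000,
#'               dx = 1000, dy = 1000)
#' dim(g$values)
#' @export
eqi_grid <- function(values, xmin = 0, ymax = nrow(values) * dy,
                     dx = 1, dy = dx, crs = "local", nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must be at least 1 x 1")
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0)
    stop("cell sizes must be strictly positive")
  if (any(values == nodata, na.rm = TRUE))
    stop("nodata sentinel ", nodata, " appears as a valid observation")
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         dx = as.numeric(dx), dy = as.numeric(dy),
         crs = as.character(crs), nodata = as.numeric(nodata)),
    class = "eqi_grid")
}

#' @export
print.eqi_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<eqi_grid> %d x %d cells (%g x %g map units)\n",
              nrow(v), ncol(v), x$dx, x$dy))
  cat(sprintf("  extent : x [%g, %g]  y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$dx, x$ymax - nrow(v) * x$dy, x$ymax))
  cat(sprintf("  crs    : %s   nodata: %g (%d cells NA)\n",
              x$crs, x$nodata, sum(is.na(v))))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (all(is.finite(rng)))
    cat(sprintf("  values : [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.eqi_grid <- function(x) dim(x$values)

grid_geometry <- function(g) {
  list(nrow = nrow(g$values), ncol = ncol(g$values),
       xmin = g$xmin, ymax = g$ymax, dx = g$dx, dy = g$dy, crs = g$crs)
}

#' Replace the values of a grid, keeping its geometry
#'
#' @param g an `eqi_grid` template.
#' @param values matrix conformable with `g$values`.
#' @return an `eqi_grid` with `g`'s geometry and the new values.
#' @export
grid_like <- function(g, values) {
  stopifnot(inherits(g, "eqi_grid"))
  if (!is.matrix(values)) values <- matrix(values, nrow(g$values), ncol(g$values))
  stopifnot(identical(dim(values), dim(g$values)))
  eqi_grid(values, xmin = g$xmin, ymax = g$ymax, dx = g$dx, dy = g$dy,
           crs = g$crs, nodata = g$nodata)
}

# Map-coordinate centers of all cells, by row (y) and column (x).
grid_col_centers <- function(g) g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$dx
grid_row_centers <- function(g) g$ymax - (seq_len(nrow(g$values)) - 0.5) * g$dy

#' Test that rasters share one analysis geometry
#'
#' Returns `TRUE` iff all grids have identical integer shape and the same crs
#' string, and their origin and cell sizes agree within `tol`. Never raises;
#' pipeline stages raise when this returns `FALSE`.
#'
#' @param grids list of `eqi_grid` (at least two).
#' @param tol absolute tolerance on geotransform terms (default `1e-9`).
#' @return logical scalar.
#' @export
assert_aligned <- function(grids, tol = 1e-9) {
  stopifnot(is.list(grids), length(grids) >= 2L)
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!identical(dim(g$values), dim(ref$values))) return(FALSE)
    if (!identical(g$crs, ref$crs)) return(FALSE)
    if (max(abs(c(g$xmin - ref$xmin, g$ymax - ref$ymax,
                  g$dx - ref$dx, g$dy - ref$dy))) > tol) return(FALSE)
  }
  TRUE
}

stop_if_misaligned <- function(grids, what = "grids", tol = 1e-9) {
  if (!assert_aligned(grids, tol = tol))
    stop(what, " are not aligned on one analysis geometry")
  invisible(TRUE)
}

#' Write a grid as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows north to south. Values are written with `%.17g` so a
#' write-then-read round trip is bit-exact for doubles. The crs tag is stored
#' in a `.prj` sidecar next to the file. Requires square cells
#' (`dx == dy`), the format's constraint.
#'
#' @param g an `eqi_grid`.
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_grid_asc <- function(g, path) {
  stopifnot(inherits(g, "eqi_grid"))
  if (abs(g$dx - g$dy) > 1e-12 * max(g$dx, g$dy))
    stop("ASCII grid requires square cells (dx == dy)")
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", g$xmin),
    sprintf("yllcorner %.17g", g$ymax - nr * g$dy),
    sprintf("cellsize %.17g", g$dx),
    sprintf("NODATA_value %.17g", g$nodata))
  v[is.na(v)] <- g$nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(g$crs, prj_sidecar(path))
  invisible(path)
}

prj_sidecar <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".prj")

#' Read an ESRI ASCII grid
#'
#' Counterpart of [write_grid_asc()]. Cells equal to the header's
#' `NODATA_value` become `NA`. If a `.prj` sidecar exists its first line is
#' used as the crs tag, otherwise `"unspecified"`.
#'
#' @param path path to the `.asc` file.
#' @return an `eqi_grid`.
#' @export
read_grid_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    key <- tolower(tok[1L])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(tok[2L])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == nodata] <- NA_real_
  prj <- prj_sidecar(path)
  crs <- if (file.exists(prj)) readLines(prj, n = 1L) else "unspecified"
  eqi_grid(v, xmin = hdr$xllcorner, ymax = hdr$yllcorner + nr * hdr$cellsize,
           dx = hdr$cellsize, dy = hdr$cellsize, crs = crs, nodata = nodata)
}
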