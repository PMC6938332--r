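#' Lightweight projected raster
#'
#' A single-band raster on a regular grid in a projected coordinate reference
#' system (metres). Values are stored as a matrix with row 1 at the north edge
#' and column 1 at the west edge; `NA` is nodata. All rasters in a pipeline
#' must share the same geometry (see [same_geometry()]).
#'
#' @param values numeric matrix; row 1 = northernmost row.
#' @param xll,yll coordinates (m) of the lower-left corner of the grid.
#' @param cell_size cell edge length in metres.
#' @param crs free-text label of the projected CRS; every raster in a run must
#'   carry the same label.
#' @return An object of class `rf_raster`.
#' @export
rf_raster <- function(values, xll = 0, yll = 0, cell_size = 1000,
                      crs = "local/projected-metres") {
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values))
    stop("raster values must be numeric")
  if (cell_size <= 0) stop("cell_size must be positive")
  structure(
    list(values = values, xll = xll, yll = yll,
         cell_size = cell_size, crs = crs),
    class = "rf_raster")
}

#' @export
print.rf_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("rf_raster: %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$xll, x$yll))
  cat(sprintf("  crs: %s\n  values: [%g, %g], %d nodata\n",
              x$crs, suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.rf_raster <- function(x) dim(x$values)

#' Do two rasters share grid geometry?
#' @param a,b `rf_raster` objects.
#' @return `TRUE` if dimensions, origin, cell size and CRS all match.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cell_size),
                     c(b$xll, b$yll, b$cell_size))) &&
    identical(a$crs, b$crs)
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b)) stop(what, " are not aligned on the same grid")
  invisible(TRUE)
}

#' Cell-centre coordinates of every cell
#' @param r an `rf_raster`.
#' @return data.frame with `row`, `col`, `x`, `y` (metres), in column-major
#'   cell order (the order used by node indices throughout the package).
#' @export
cell_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(row = rows, col = cols,
             x = r$xll + (cols - 0.5) * r$cell_size,
             y = r$yll + (nr - rows + 0.5) * r$cell_size)
}

#' Map projected coordinates to cells
#' @param r an `rf_raster`.
#' @param x,y coordinate vectors in metres.
#' @return data.frame with `row`, `col`; `NA` rows for points off the grid.
#' @export
cells_from_xy <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xll) / r$cell_size) + 1L
  row <- nr - floor((y - r$yll) / r$cell_size)
  off <- col < 1L | col > nc | row < 1L | row > nr
  col[off] <- NA_integer_; row[off] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Raster value at projected points
#' @inheritParams cells_from_xy
#' @return numeric vector; `NA` for points off the grid or on nodata cells.
#' @export
raster_value_at <- function(r, x, y) {
  rc <- cells_from_xy(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- r$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Read/write ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (`NCOLS`, `NROWS`,
#' `XLLCORNER`, `YLLCORNER`, `CELLSIZE`, `NODATA_VALUE`) followed by rows of
#' values from the north edge southward.
#'
#' @param r an `rf_raster`.
#' @param path file path (`.asc`).
#' @param nodata value used to encode `NA` on disk.
#' @return `write_asc` returns `path` invisibly; `read_asc` an `rf_raster`.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("NCOLS %d", ncol(v)), sprintf("NROWS %d", nrow(v)),
           sprintf("XLLCORNER %.10g", r$xll), sprintf("YLLCORNER %.10g", r$yll),
           sprintf("CELLSIZE %.10g", r$cell_size),
           sprintf("NODATA_VALUE %g", nodata))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(v, trim = TRUE, digits = 17), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @param crs CRS label to attach on read (the format does not carry one).
#' @export
read_asc <- function(path, crs = "local/projected-metres") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- toupper(kv[, 1]); val <- as.numeric(kv[, 2])
  g <- setNames(val, key)
  v <- as.matrix(read.table(path, skip = 6))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == g[["NROWS"]], ncol(v) == g[["NCOLS"]])
  v[v == g[["NODATA_VALUE"]]] <- NA_real_
  rf_raster(v, xll = g[["XLLCORNER"]], yll = g[["YLLCORNER"]],
            cell_size = g[["CELLSIZE"]], crs = crs)
}
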