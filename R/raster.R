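#' Lightweight single-band raster grid
#'
#' A minimal in-memory raster: a numeric matrix of cell values with square
#' cells, a projected origin, and a logical mask of missing cells. Row 1 is
#' the northernmost row (row index increases southward), column index
#' increases eastward, matching the usual GIS grid convention. `origin` is
#' the (x, y) of the *outer* corner of the top-left cell, so the centre of
#' cell (row, col) lies at
#' `x = origin[1] + (col - 0.5) * cell_size`,
#' `y = origin[2] - (row - 0.5) * cell_size`.
#'
#' @param values numeric matrix of cell values (rows run north to south).
#' @param cell_size edge length of a (square) cell in metres.
#' @param origin numeric length-2, (x, y) of the top-left outer corner.
#' @param nodata_mask logical matrix, `TRUE` where the cell is missing.
#'   Defaults to `is.na(values)`.
#' @return an object of class `pairscape_raster`.
#' @export
raster_grid <- function(values, cell_size = 1, origin = c(0, nrow(values) * cell_size),
                        nodata_mask = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("raster must be at least 2x2", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("cell_size must be a single positive number", call. = FALSE)
  }
  if (is.null(nodata_mask)) {
    nodata_mask <- is.na(values)
  } else {
    nodata_mask <- nodata_mask | is.na(values)
  }
  if (!identical(dim(nodata_mask), dim(values))) {
    stop("nodata_mask dimensions must match values", call. = FALSE)
  }
  values[nodata_mask] <- NA_real_
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata_mask = nodata_mask),
    class = "pairscape_raster"
  )
}

#' @export
print.pairscape_raster <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<pairscape_raster> %d x %d cells, cell_size = %g m\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  origin (top-left corner): (%g, %g)\n", x$origin[1], x$origin[2]))
  cat(sprintf("  valid cells: %d (%.1f%%)", length(v),
              100 * length(v) / length(x$values)))
  if (length(v)) cat(sprintf(", range [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
dim.pairscape_raster <- function(x) dim(x$values)

#' Valid (non-masked) cell values of a raster
#' @param r a `pairscape_raster`.
#' @return numeric vector of valid cell values.
#' @export
raster_values <- function(r) r$values[!r$nodata_mask]

#' Cell-centre coordinates
#'
#' @param r a `pairscape_raster`.
#' @param rows,cols integer vectors of equal length (1-based indices).
#' @return two-column matrix of (x, y) centre coordinates.
#' @export
cell_centers <- function(r, rows, cols) {
  cbind(x = r$origin[1] + (cols - 0.5) * r$cell_size,
        y = r$origin[2] - (rows - 0.5) * r$cell_size)
}

#' Map projected coordinates to cell indices
#'
#' @param r a `pairscape_raster`.
#' @param x,y coordinate vectors in the raster's projection.
#' @return two-column integer matrix (row, col); coordinates outside the
#'   extent give `NA`.
#' @export
cell_index <- function(r, x, y) {
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - y) / r$cell_size) + 1L
  bad <- row < 1L | row > nrow(r$values) | col < 1L | col > ncol(r$values)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read a raster from disk
#'
#' Reads a single-band raster. The supported on-disk format is the ESRI
#' ASCII grid (`.asc`), a plain-text header (`ncols`, `nrows`, `xllcorner`
#' or `xllcenter`, `yllcorner`/`yllcenter`, `cellsize`, optional
#' `NODATA_value`) followed by rows of cell values, north row first.
#' Integer-valued categorical layers round-trip bit-exactly.
#'
#' @param path file path.
#' @param format currently `"ascii_grid"`.
#' @return a [raster_grid()].
#' @export
read_raster <- function(path, format = c("ascii_grid", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF input is not supported by this build; ",
         "convert to ESRI ASCII grid (gdal_translate -of AAIGrid)",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-+0-9.eE]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "cellsize")
  missing_keys <- setdiff(req, names(hdr))
  if (length(missing_keys)) {
    stop("malformed ASCII grid header, missing: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy) {
    stop("non-square cells (dx != dy) are unsupported", call. = FALSE)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("ASCII grid body has %d values, expected %d (ncols x nrows)",
                 length(vals), nr * nc), call. = FALSE)
  }
  values <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) values[values == hdr$nodata_value] <- NA_real_
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2 else 0
  raster_grid(values, cell_size = hdr$cellsize,
              origin = c(xll, yll + nr * hdr$cellsize))
}

#' Write a raster to disk as an ESRI ASCII grid
#'
#' @param r a `pairscape_raster`.
#' @param path output file path.
#' @param nodata numeric sentinel written for masked cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  v <- r$values
  v[r$nodata_mask] <- nodata
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2] - nr * r$cell_size),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  # %.17g keeps doubles bit-exact on round trip; integers print without decimals
  body <- apply(v, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
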