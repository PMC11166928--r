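#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a matrix of cell values on a regular grid with
#' a cell size and the (x, y) coordinate of the lower-left corner. Row 1 of
#' `values` is the top (northernmost) row, matching the row order of the ESRI
#' ASCII grid format. An optional nodata mask flags cells that are outside
#' the landscape (e.g. ocean); masked cells take no part in resistance
#' composition or least-cost routing.
#'
#' @param values numeric matrix of cell values (at least 2 x 2).
#' @param cell_size side length of a square cell, in map units.
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @param nodata_mask logical matrix of the same shape; `TRUE` marks nodata.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 1, origin = c(0, 0),
                        nodata_mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("a raster_grid needs at least 2 rows and 2 columns")
  if (is.null(nodata_mask))
    nodata_mask <- matrix(FALSE, nrow(values), ncol(values))
  nodata_mask <- as.matrix(nodata_mask)
  if (!identical(dim(nodata_mask), dim(values)))
    stop("nodata_mask and values must have identical dimensions")
  if (any(!is.finite(values[!nodata_mask])))
    stop("unmasked cells must hold finite values")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar")
  structure(
    list(n_rows = nrow(values), n_cols = ncol(values),
         cell_size = as.numeric(cell_size), origin = as.numeric(origin[1:2]),
         values = values, nodata_mask = nodata_mask),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells (cell size %g, origin %g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  v <- x$values[!x$nodata_mask]
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              min(v), max(v), sum(x$nodata_mask)))
  invisible(x)
}

#' Uniform raster
#'
#' Convenience constructor for a constant-valued raster, e.g. the all-ones
#' geographic-distance layer.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param value the constant cell value.
#' @inheritParams raster_grid
#' @return a `raster_grid`.
#' @export
uniform_raster <- function(n_rows, n_cols, value = 1, cell_size = 1,
                           origin = c(0, 0)) {
  raster_grid(matrix(value, n_rows, n_cols), cell_size, origin)
}

# Min-max rescale of unmasked cells to [0, 1]; a constant layer maps to 0
# everywhere (it carries no spatial information).
normalize01 <- function(raster) {
  v <- raster$values
  ok <- !raster$nodata_mask
  rng <- range(v[ok])
  if (diff(rng) == 0) {
    v[ok] <- 0
  } else {
    v[ok] <- (v[ok] - rng[1]) / diff(rng)
  }
  raster$values <- v
  raster
}

same_geometry <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

# Map (row, col) cell indices to map coordinates of the cell centre.
cell_center <- function(raster, row, col) {
  cbind(x = raster$origin[1] + (col - 0.5) * raster$cell_size,
        y = raster$origin[2] + (raster$n_rows - row + 0.5) * raster$cell_size)
}

# Inverse of cell_center (coordinates must fall inside the grid).
coord_to_cell <- function(raster, x, y) {
  col <- floor((x - raster$origin[1]) / raster$cell_size) + 1L
  row <- raster$n_rows - floor((y - raster$origin[2]) / raster$cell_size)
  if (any(col < 1L | col > raster$n_cols | row < 1L | row > raster$n_rows))
    stop("coordinates fall outside the raster extent")
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows of cell
#' values, top row first).
#'
#' @param path file path.
#' @param raster a `raster_grid`.
#' @param nodata_value sentinel written for masked cells.
#' @return `read_esri_ascii` returns a `raster_grid`; `write_esri_ascii`
#'   returns `path` invisibly.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  nodata <- hdr[["nodata_value"]] %||% -9999
  mask <- vals == nodata
  vals[mask] <- 0
  raster_grid(vals, cell_size = hdr$cellsize,
              origin = c(hdr$xllcorner, hdr$yllcorner), nodata_mask = mask)
}

#' @rdname read_esri_ascii
#' @export
write_esri_ascii <- function(raster, path, nodata_value = -9999) {
  v <- raster$values
  v[raster$nodata_mask] <- nodata_value
  hdr <- c(sprintf("ncols %d", raster$n_cols),
           sprintf("nrows %d", raster$n_rows),
           sprintf("xllcorner %.10g", raster$origin[1]),
           sprintf("yllcorner %.10g", raster$origin[2]),
           sprintf("cellsize %.10g", raster$cell_size),
           sprintf("NODATA_value %g", nodata_value))
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
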