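#' Lightweight in-memory raster
#'
#' `ecoserv` works on plain numeric/integer matrices wrapped with the minimal
#' metadata the pipeline needs: a cell size (km) and an optional year label.
#' Cells are row-major with cell `[1, 1]` at the north-west corner; `NA` is
#' the nodata value. Areas are always derived from `cell_size_km^2`, never
#' from coordinate-system math: the synthetic landscapes carry no real CRS.
#'
#' @param values Numeric or integer matrix.
#' @param cell_size_km Positive cell edge length in kilometres.
#' @param year Optional year label (kept as-is, usually integer).
#' @return An object of class `es_raster`: the matrix with attributes
#'   `cell_size_km` and `year`.
#' @examples
#' r <- es_raster(matrix(1, 3, 3), cell_size_km = 1, year = 1990)
#' cell_area_km2(r)
#' @export
es_raster <- function(values, cell_size_km = 1, year = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 ||
      is.na(cell_size_km) || cell_size_km <= 0) {
    stop("`cell_size_km` must be a single positive number")
  }
  structure(values,
            cell_size_km = as.numeric(cell_size_km),
            year = year,
            class = c("es_raster", class(values)))
}

#' @export
print.es_raster <- function(x, ...) {
  cat(sprintf("<es_raster> %d x %d cells, %.3g km cells%s, %d nodata\n",
              nrow(x), ncol(x), attr(x, "cell_size_km"),
              if (is.null(attr(x, "year"))) "" else paste0(", year ", attr(x, "year")),
              sum(is.na(x))))
  invisible(x)
}

#' @rdname es_raster
#' @param x An `es_raster`.
#' @export
cell_size_km <- function(x) {
  cs <- attr(x, "cell_size_km")
  if (is.null(cs)) 1 else cs
}

#' @rdname es_raster
#' @export
cell_area_km2 <- function(x) cell_size_km(x)^2

#' @rdname es_raster
#' @export
raster_year <- function(x) attr(x, "year")

# values as a bare matrix (drops es_raster class, keeps dim)
raster_values <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Check that two rasters share a grid
#'
#' Stops unless both rasters have identical dimensions and cell size; used by
#' every multi-layer operation (co-registration precondition).
#'
#' @param a,b `es_raster` objects.
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`.
#' @export
stopifnot_same_grid <- function(a, b, what = "rasters") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have mismatched shapes: %dx%d vs %dx%d",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)))
  }
  if (abs(cell_size_km(a) - cell_size_km(b)) > 1e-12) {
    stop(sprintf("%s have different cell sizes", what))
  }
  invisible(TRUE)
}

#' Read and write ESRI ASCII grids
#'
#' A dependency-light plain-text raster format: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' rows of values from north to south. Values round-trip losslessly (written
#' with 17 significant digits); `cellsize` is interpreted in kilometres.
#'
#' @param x An `es_raster`.
#' @param path File path.
#' @param year Optional year label attached on read.
#' @return `read_ascii_grid` returns an `es_raster`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(x, path) {
  vals <- raster_values(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(vals)),
    sprintf("nrows %d", nrow(vals)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.17g", cell_size_km(x)),
    "NODATA_value -9999"
  ), con)
  vals[is.na(vals)] <- -9999
  for (i in seq_len(nrow(vals))) {
    writeLines(paste(sprintf("%.17g", vals[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, year = NULL) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path)
  header <- lines[1:6]
  kv <- strsplit(trimws(header), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  for (k in c("ncols", "nrows", "cellsize", "nodata_value")) {
    if (!k %in% keys) stop(sprintf("%s: malformed ASCII grid header (missing %s)", path, k))
  }
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc) {
    stop(sprintf("%s: expected %d values, found %d", path, nr * nc, length(body)))
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  es_raster(m, cell_size_km = vals[["cellsize"]], year = year)
}
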