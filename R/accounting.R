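#' Class areas of a land-use raster
#'
#' Counts cells per land-use class and converts to km^2 via the cell size.
#' Nodata cells are excluded; classes absent from the raster get area 0.
#'
#' @param lu An `es_raster` of land-use codes.
#' @return A data.frame with columns `class` and `area_km2` (one row per
#'   codebook class, in codebook order), with the raster's year attached as
#'   attribute `year`.
#' @examples
#' lu <- es_raster(matrix(1L, 10, 10), year = 1990)
#' class_areas(lu)  # 100 km2 of forest
#' @export
class_areas <- function(lu) {
  check_codes(lu)
  cb <- es_classes()
  counts <- tabulate(factor(as.vector(lu), levels = cb$code), nbins = nrow(cb))
  out <- data.frame(class = cb$class, area_km2 = counts * cell_area_km2(lu),
                    stringsAsFactors = FALSE)
  attr(out, "year") <- raster_year(lu)
  out
}

#' Land-use transfer matrix between two dates
#'
#' Cross-tabulates the area moving from each class at the earlier date (rows)
#' to each class at the later date (columns). Cells that are nodata in
#' *either* year are dropped symmetrically, so row sums equal the earlier
#' year's class areas, column sums equal the later year's, and the grand
#' total is conserved — all on the shared-validity mask.
#'
#' @param lu0,lu1 Co-registered `es_raster`s of land-use codes (earlier,
#'   later).
#' @return A list of class `transfer_matrix`: `matrix` (km^2, classes x
#'   classes), `sum_t0`, `sum_t1` (marginals), `abs_change`, `pct_change`
#'   (per class; `pct_change` is `NA` where `sum_t0` is 0), and the two year
#'   labels.
#' @export
transfer_matrix <- function(lu0, lu1) {
  stopifnot_same_grid(lu0, lu1, "land-use rasters")
  check_codes(lu0); check_codes(lu1)
  cb <- es_classes()
  ok <- !is.na(lu0) & !is.na(lu1)
  f0 <- factor(as.vector(lu0)[ok], levels = cb$code, labels = cb$class)
  f1 <- factor(as.vector(lu1)[ok], levels = cb$code, labels = cb$class)
  m <- table(f0, f1) * cell_area_km2(lu0)
  m <- unclass(m)
  dimnames(m) <- list(from = cb$class, to = cb$class)
  s0 <- rowSums(m); s1 <- colSums(m)
  structure(list(
    matrix = m,
    sum_t0 = s0, sum_t1 = s1,
    abs_change = s1 - s0,
    pct_change = ifelse(s0 > 0, 100 * (s1 - s0) / s0, NA_real_),
    year0 = raster_year(lu0), year1 = raster_year(lu1)
  ), class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> %s -> %s (km2)\n",
              if (is.null(x$year0)) "t0" else x$year0,
              if (is.null(x$year1)) "t1" else x$year1))
  out <- rbind(x$matrix, sum_t1 = x$sum_t1)
  out <- cbind(out, sum_t0 = c(x$sum_t0, sum(x$sum_t0)))
  print(round(out, 2))
  invisible(x)
}

#' Write a transfer matrix as CSV
#'
#' Emits the class-by-class matrix with marginal rows `sum_t0`, `sum_t1`,
#' `abs_change` and `pct_change` appended, matching the layout of published
#' land-use transition tables.
#'
#' @param tm A [transfer_matrix()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transfer_matrix <- function(tm, path) {
  m <- rbind(tm$matrix,
             sum_t0 = tm$sum_t0, sum_t1 = tm$sum_t1,
             abs_change = tm$abs_change, pct_change = tm$pct_change)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Absolute and percent change between two class-area tables
#'
#' @param t0,t1 [class_areas()] tables over the same codebook (earlier,
#'   later).
#' @return A data.frame with `class`, `area_t0`, `area_t1`, `abs_change`
#'   (same unit as the inputs) and `pct_change` (%, `NA` where `area_t0` is
#'   0). Full precision is retained; round for display.
#' @export
change_stats <- function(t0, t1) {
  if (!identical(t0$class, t1$class)) stop("class-area tables have different codebooks")
  d <- t1$area_km2 - t0$area_km2
  data.frame(
    class = t0$class,
    area_t0 = t0$area_km2, area_t1 = t1$area_km2,
    abs_change = d,
    pct_change = ifelse(t0$area_km2 > 0, 100 * d / t0$area_km2, NA_real_),
    stringsAsFactors = FALSE
  )
}
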