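#' Total carbon density of a land-use class
#'
#' Sum of the four carbon pools — above-ground, below-ground, soil, and dead
#' organic matter — giving the per-area stock (t/hm^2) booked to every cell
#' of the class.
#'
#' @param densities Per-class pool table as from [es_carbon_density()].
#' @param class Class key (e.g. `"forest"`) or vector of keys.
#' @return Numeric vector of total densities (t/hm^2).
#' @examples
#' total_density(es_carbon_density(), "forest")  # 238.15
#' @export
total_density <- function(densities, class) {
  idx <- match(class, densities$class)
  if (anyNA(idx)) {
    stop("no carbon density row for class: ",
         paste(class[is.na(idx)], collapse = ", "))
  }
  with(densities[idx, , drop = FALSE], c_above + c_below + c_soil + c_dead)
}

#' Carbon stock of a land-use raster
#'
#' Pure per-class bookkeeping: each cell holds
#' `total_density(class) * cell area` tonnes (1 km^2 = 100 hm^2). No spatial
#' interaction is involved, so a closed-form tabular path
#' (`sum(area_class * density_class)`) is exposed alongside the raster path;
#' the two agree to machine precision and are cross-checked in the test
#' suite.
#'
#' @param lu An `es_raster` of land-use codes.
#' @param densities Per-class pool table as from [es_carbon_density()].
#' @return A list of class `carbon_result`: `stock` (`es_raster`, t per
#'   cell), `class_totals` (named vector, 1e8 t), `total` (1e8 t).
#' @export
carbon_stock <- function(lu, densities) {
  check_codes(lu)
  if (cell_size_km(lu) <= 0) stop("cell size must be positive")
  dens_by_code <- rep(NA_real_, max(es_classes()$code))
  dens_by_code[class_codes(densities$class)] <- total_density(densities, densities$class)
  present <- unique(as.vector(lu)); present <- present[!is.na(present)]
  if (anyNA(dens_by_code[present])) {
    stop("missing carbon density for class code(s): ",
         paste(present[is.na(dens_by_code[present])], collapse = ", "))
  }
  area_hm2 <- cell_area_km2(lu) * 100
  stock <- matrix(dens_by_code[as.vector(lu)] * area_hm2, nrow(lu), ncol(lu))
  ct <- carbon_class_totals(class_areas(lu), densities)
  structure(list(
    stock = es_raster(stock, cell_size_km = cell_size_km(lu), year = raster_year(lu)),
    class_totals = ct,
    total = sum(ct)
  ), class = "carbon_result")
}

#' @rdname carbon_stock
#' @param areas A [class_areas()] table (km^2).
#' @return `carbon_class_totals`: named vector of per-class stocks (1e8 t)
#'   computed on the tabular path.
#' @export
carbon_class_totals <- function(areas, densities) {
  dens <- total_density(densities, areas$class)
  stats::setNames(areas$area_km2 * 100 * dens / 1e8, areas$class)
}
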