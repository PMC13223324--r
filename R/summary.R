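#' Region-level service panel for one year
#'
#' Aggregates the five per-cell service layers over a region partition:
#' sums for the extensive services (carbon, water-yield volume, erosion,
#' food-material value) and the area-weighted cell mean for habitat quality
#' (an intensive index). Per-unit-area columns divide each total by the
#' region area.
#'
#' Panel units: `carbon` 1e8 t, `water_yield` 1e8 m^3, `erosion` 1e4 t,
#' `food_material` 1e8 Yuan, `habitat` mean Q (dimensionless). Per-unit
#' columns: `carbon_per_km2` t/km^2, `water_yield_mm` mm,
#' `erosion_per_km2` t/km^2, `food_material_per_km2` 1e4 Yuan/km^2.
#'
#' @param regions An `es_raster` of integer region ids.
#' @param carbon A `carbon_result`.
#' @param water A `water_yield_result`.
#' @param erosion An `erosion_result`.
#' @param habitat A `habitat_result`.
#' @param esv An `esv_result`.
#' @param year Year label for the rows (defaults to the carbon raster's).
#' @return A data.frame with one row per non-empty region.
#' @export
zonal_totals <- function(regions, carbon, water, erosion, habitat, esv,
                         year = NULL) {
  stopifnot_same_grid(regions, carbon$stock, "regions and service rasters")
  if (is.null(year)) year <- raster_year(carbon$stock)
  rid <- as.vector(raster_values(regions))
  ids <- sort(unique(rid[!is.na(rid)]))
  f <- factor(rid, levels = ids)
  area_cell <- cell_area_km2(regions)
  zsum <- function(x) {
    out <- tapply(as.vector(raster_values(x)), f, sum, na.rm = TRUE, default = 0)
    as.numeric(out)
  }
  zmean <- function(x) {
    out <- tapply(as.vector(raster_values(x)), f, mean, na.rm = TRUE)
    as.numeric(out)
  }
  n_cells <- as.numeric(tapply(rep(1, length(rid)), f, sum, default = 0))
  area <- n_cells * area_cell
  carbon_t <- zsum(carbon$stock)
  yield_mm_sum <- zsum(water$yield)              # sum of cell yield depths
  water_m3 <- yield_mm_sum * area_cell * 1000    # mm * km2 -> m3
  erosion_t <- zsum(erosion$loss)
  food_yuan <- zsum(esv$value)
  data.frame(
    region = ids,
    year = year,
    area_km2 = area,
    carbon = carbon_t / 1e8,
    habitat = zmean(habitat$quality),
    water_yield = water_m3 / 1e8,
    erosion = erosion_t / 1e4,
    food_material = food_yuan / 1e8,
    carbon_per_km2 = carbon_t / area,
    water_yield_mm = water_m3 / area / 1000,
    erosion_per_km2 = erosion_t / area,
    food_material_per_km2 = food_yuan / area / 1e4,
    stringsAsFactors = FALSE
  )
}

#' Per-region land-use proportions
#'
#' @param lu An `es_raster` of land-use codes.
#' @param regions Co-registered `es_raster` of region ids.
#' @return A data.frame with `region`, `year`, and one fraction column per
#'   class (`p_forest`, ..., `p_dry`); fractions sum to 1 per row over
#'   non-nodata cells.
#' @export
landuse_proportions <- function(lu, regions) {
  stopifnot_same_grid(lu, regions, "land use and regions")
  check_codes(lu)
  rid <- as.vector(raster_values(regions))
  codes <- as.vector(raster_values(lu))
  ok <- !is.na(rid) & !is.na(codes)
  tab <- table(region = rid[ok],
               class = factor(codes[ok], levels = es_classes()$code,
                              labels = es_classes()$class))
  props <- sweep(unclass(tab), 1, rowSums(tab), `/`)
  out <- data.frame(region = as.numeric(rownames(props)),
                    year = if (is.null(raster_year(lu))) NA else raster_year(lu),
                    stringsAsFactors = FALSE)
  for (cl in es_classes()$class) out[[paste0("p_", cl)]] <- props[, cl]
  rownames(out) <- NULL
  out
}

#' Service change between two years of a panel
#'
#' For every numeric service column: absolute change `v1 - v0` and percent
#' change `100 (v1 - v0) / v0` (missing where `v0` is 0), matched on a key
#' column. Full precision is returned; round for display.
#'
#' @param panel Data.frame with a `year` column, a key column (`by`), and
#'   numeric service columns.
#' @param y0,y1 The two year labels to compare.
#' @param by Key column name (default `"region"`; use `"class"` for
#'   per-class tables).
#' @param cols Service columns to difference (default: all numeric columns
#'   except `year` and the key).
#' @return Long data.frame: key, `service`, `v0`, `v1`, `abs_change`,
#'   `pct_change`.
#' @export
service_change <- function(panel, y0, y1, by = "region", cols = NULL) {
  if (!"year" %in% names(panel)) stop("panel needs a 'year' column")
  for (y in c(y0, y1)) {
    if (!any(panel$year == y)) stop("year not present in panel: ", y)
  }
  if (is.null(cols)) {
    cols <- setdiff(names(panel)[vapply(panel, is.numeric, TRUE)], c("year", by))
  }
  p0 <- panel[panel$year == y0, , drop = FALSE]
  p1 <- panel[panel$year == y1, , drop = FALSE]
  idx <- match(p0[[by]], p1[[by]])
  if (anyNA(idx)) stop("keys of ", y0, " not all present in ", y1)
  out <- do.call(rbind, lapply(cols, function(cl) {
    v0 <- p0[[cl]]; v1 <- p1[[cl]][idx]
    data.frame(key = p0[[by]], service = cl, v0 = v0, v1 = v1,
               abs_change = v1 - v0,
               pct_change = ifelse(v0 != 0, 100 * (v1 - v0) / v0, NA_real_),
               stringsAsFactors = FALSE)
  }))
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}
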