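#' Budyko-Fu actual evapotranspiration
#'
#' Partitions annual precipitation into evapotranspiration and yield with
#' the Fu/Zhang form of the Budyko curve used by annual water-yield models:
#' \deqn{AET/P = 1 + PET/P - (1 + (PET/P)^\omega)^{1/\omega}}
#' with \eqn{\omega = Z \cdot AWC / P + \omega_0}, where AWC is the
#' plant-available water depth (mm), `Z` a seasonality constant, and
#' \eqn{\omega_0} an empirical offset. The result is clamped to `[0, P]`,
#' which the functional form already guarantees for valid inputs; cells with
#' `P = 0` return `AET = 0`.
#'
#' @param P Annual precipitation (mm); scalar, vector or matrix.
#' @param PET Potential evapotranspiration (mm), conformable with `P`.
#' @param awc Plant-available water depth (mm), conformable with `P`.
#' @param Z Seasonality constant (dimensionless, default 5).
#' @param omega_offset Additive offset of \eqn{\omega} (default 1.25).
#' @return AET (mm), same shape as `P`.
#' @examples
#' budyko_aet(1000, 800, 150)          # omega = 2
#' 1000 - budyko_aet(1000, 800, 150)   # the corresponding yield
#' @export
budyko_aet <- function(P, PET, awc, Z = 5, omega_offset = 1.25) {
  if (any(P < 0, na.rm = TRUE) || any(PET < 0, na.rm = TRUE) ||
      any(awc < 0, na.rm = TRUE)) {
    stop("P, PET and awc must be non-negative")
  }
  if (Z <= 0) stop("Z must be positive")
  d <- dim(P)
  n <- max(length(P), length(PET), length(awc))
  Pv <- rep_len(as.vector(P), n)
  PETv <- rep_len(as.vector(PET), n)
  awcv <- rep_len(as.vector(awc), n)
  aet <- numeric(n)
  pos <- !is.na(Pv) & Pv > 0
  omega <- Z * awcv[pos] / Pv[pos] + omega_offset
  phi <- PETv[pos] / Pv[pos]  # aridity index
  frac <- 1 + phi - (1 + phi^omega)^(1 / omega)
  aet[pos] <- pmin(pmax(frac, 0), 1) * Pv[pos]
  aet[is.na(Pv)] <- NA_real_
  if (!is.null(d) && length(P) == n) dim(aet) <- d
  aet
}

#' Annual water yield over a land-use raster
#'
#' Per cell: potential evapotranspiration is `kc(class) * ET0`, available
#' water depth is `PAWC * min(root_depth(class), restricting depth)`, actual
#' evapotranspiration follows the Budyko-Fu curve, and yield is
#' `Y = P - AET`. Volumes aggregate yield depth over cell areas
#' (1 mm over 1 km^2 = 1000 m^3).
#'
#' @param lu An `es_raster` of land-use codes.
#' @param climate A `climate_stack` (needs `annual_precip` and `pet`).
#' @param soil A `soil_terrain_stack` (needs `PAWC`).
#' @param params Per-class table as from [es_water_params()].
#' @param Z,omega_offset Budyko constants, see [budyko_aet()].
#' @param restricting_depth_mm Optional root-restricting layer depth raster
#'   or scalar (mm); when `NULL` (default) rooting depth alone bounds the
#'   available water.
#' @return A list of class `water_yield_result`: `yield` and `aet`
#'   (`es_raster`s, mm), `class_volumes` (named, 1e8 m^3), `total_volume`
#'   (1e8 m^3).
#' @export
water_yield <- function(lu, climate, soil, params = es_water_params(),
                        Z = 5, omega_offset = 1.25,
                        restricting_depth_mm = NULL) {
  check_codes(lu)
  P <- climate$annual_precip; ET0 <- climate$pet; PAWC <- soil$PAWC
  stopifnot_same_grid(lu, P, "land use and precipitation")
  stopifnot_same_grid(lu, ET0, "land use and reference ET")
  stopifnot_same_grid(lu, PAWC, "land use and PAWC")
  kc_by_code <- root_by_code <- rep(NA_real_, max(es_classes()$code))
  kc_by_code[class_codes(params$class)] <- params$kc
  root_by_code[class_codes(params$class)] <- params$root_depth_mm
  codes <- as.vector(lu)
  present <- unique(codes[!is.na(codes)])
  if (anyNA(kc_by_code[present])) {
    stop("missing water-yield parameters for class code(s): ",
         paste(present[is.na(kc_by_code[present])], collapse = ", "))
  }
  pet_cell <- kc_by_code[codes] * as.vector(raster_values(ET0))
  root <- root_by_code[codes]
  if (!is.null(restricting_depth_mm)) root <- pmin(root, restricting_depth_mm)
  awc <- as.vector(raster_values(PAWC)) * root
  Pv <- as.vector(raster_values(P))
  aet <- budyko_aet(Pv, pet_cell, awc, Z = Z, omega_offset = omega_offset)
  aet[is.na(codes)] <- NA_real_
  y <- Pv - aet
  nr <- nrow(lu); nc <- ncol(lu)
  vol_per_cell <- y * cell_area_km2(lu) * 1000 / 1e8  # mm * km2 -> 1e8 m3
  cls <- factor(codes, levels = es_classes()$code, labels = es_classes()$class)
  class_volumes <- tapply(vol_per_cell, cls, sum, na.rm = TRUE, default = 0)
  structure(list(
    yield = es_raster(matrix(y, nr, nc), cell_size_km = cell_size_km(lu),
                      year = raster_year(lu)),
    aet = es_raster(matrix(aet, nr, nc), cell_size_km = cell_size_km(lu),
                    year = raster_year(lu)),
    class_volumes = c(class_volumes),
    total_volume = sum(vol_per_cell, na.rm = TRUE)
  ), class = "water_yield_result")
}
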