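#' Coefficients from dimensionless service equivalents
#'
#' The equivalent-factor method values each (class, service) pair as a
#' dimensionless equivalent times the regional unit value of one standard
#' equivalent, `E0` (Yuan/hm^2/yr), conventionally one-seventh of the market
#' value of the mean grain yield per unit area. This helper converts an
#' equivalent table into monetary coefficients.
#'
#' @param equivalents Data.frame with a `class` column and one numeric
#'   column per service, all values dimensionless and >= 0.
#' @param E0 Unit equivalent value (Yuan/hm^2), default 1505.8.
#' @return The table with every service column multiplied by `E0`.
#' @export
coefficients_from_equivalents <- function(equivalents, E0 = 1505.8) {
  if (E0 < 0) stop("E0 must be non-negative")
  num <- vapply(equivalents, is.numeric, TRUE)
  if (any(unlist(equivalents[num]) < 0)) stop("equivalents must be non-negative")
  equivalents[num] <- lapply(equivalents[num], function(v) v * E0)
  equivalents
}

#' Food-material supply value of a land-use raster
#'
#' Provisioning-service valuation: each class contributes
#' `area (hm^2) * (food production + raw material)` Yuan per year, with the
#' combined coefficient from [es_esv_coefficients()]. Built-up and unused
#' land carry zero coefficients.
#'
#' @param lu An `es_raster` of land-use codes.
#' @param coeffs Coefficient table as from [es_esv_coefficients()] (needs a
#'   `food_material` column in Yuan/hm^2).
#' @return A list of class `esv_result`: `value` (`es_raster`, Yuan per
#'   cell), `class_totals` (named, 1e8 Yuan), `total` (1e8 Yuan).
#' @export
food_material_value <- function(lu, coeffs = es_esv_coefficients()) {
  check_codes(lu)
  v_by_code <- rep(NA_real_, max(es_classes()$code))
  v_by_code[class_codes(coeffs$class)] <- coeffs$food_material
  codes <- as.vector(lu)
  present <- unique(codes[!is.na(codes)])
  if (anyNA(v_by_code[present])) {
    stop("missing ESV coefficients for class code(s): ",
         paste(present[is.na(v_by_code[present])], collapse = ", "))
  }
  yuan <- v_by_code[codes] * cell_area_km2(lu) * 100  # Yuan/hm2 x hm2
  cls <- factor(codes, levels = es_classes()$code, labels = es_classes()$class)
  class_totals <- tapply(yuan / 1e8, cls, sum, na.rm = TRUE, default = 0)
  structure(list(
    value = es_raster(matrix(yuan, nrow(lu), ncol(lu)),
                      cell_size_km = cell_size_km(lu), year = raster_year(lu)),
    class_totals = c(class_totals),
    total = sum(yuan, na.rm = TRUE) / 1e8
  ), class = "esv_result")
}
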