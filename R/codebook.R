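#' Land-use codebook
#'
#' The pipeline uses a fixed seven-class land-use legend typical of
#' agricultural river-basin studies in eastern China: forest, grassland,
#' water, urban and rural (built-up) land, unused land, paddy land, and dry
#' (rain-fed) cropland. Codes are the integers stored in land-use rasters.
#'
#' @return A data.frame with columns `code` (integer), `class` (short key)
#'   and `label` (long name).
#' @examples
#' es_classes()
#' @export
es_classes <- function() {
  data.frame(
    code = 1:7,
    class = c("forest", "grassland", "water", "urban", "unused", "paddy", "dry"),
    label = c("Forest", "Grassland", "Water", "Urban and rural land",
              "Unused land", "Paddy land", "Dry land"),
    stringsAsFactors = FALSE
  )
}

#' @rdname es_classes
#' @export
es_class_names <- function() es_classes()$class

# map class keys -> codes, stopping on unknown keys
class_codes <- function(classes) {
  cb <- es_classes()
  idx <- match(classes, cb$class)
  if (anyNA(idx)) stop("unknown land-use class: ", paste(classes[is.na(idx)], collapse = ", "))
  cb$code[idx]
}

# validate that all non-NA codes in a raster are legal
check_codes <- function(lu) {
  codes <- unique(as.vector(lu))
  codes <- codes[!is.na(codes)]
  bad <- setdiff(codes, es_classes()$code)
  if (length(bad)) stop("unknown land-use code(s) in raster: ", paste(sort(bad), collapse = ", "))
  invisible(TRUE)
}

# read a per-class parameter CSV shipped with the package (or user-supplied),
# checking that every one of the 7 classes is present and required columns parse
read_class_table <- function(path, required_cols) {
  if (!file.exists(path)) stop("no such parameter table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"class" %in% names(tab)) stop(path, ": parameter table needs a 'class' column")
  missing_cols <- setdiff(required_cols, names(tab))
  if (length(missing_cols)) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(tab$class, es_class_names())
  if (length(unknown)) {
    stop(path, ": unknown class name(s): ", paste(unknown, collapse = ", "))
  }
  missing_cls <- setdiff(es_class_names(), tab$class)
  if (length(missing_cls)) {
    stop(path, ": missing class row(s): ", paste(missing_cls, collapse = ", "))
  }
  for (cl in required_cols) {
    if (!is.numeric(tab[[cl]])) stop(path, ": column '", cl, "' is not numeric")
  }
  tab[match(es_class_names(), tab$class), c("class", required_cols)]
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "ecoserv")
  if (p == "") stop("bundled table not found (is ecoserv installed?): ", file)
  p
}

#' Bundled per-class parameter tables
#'
#' Loaders for the parameter tables the five service models consume, shipped
#' as CSV under `inst/extdata` and validated on read (all seven classes
#' present, numeric columns, stated ranges). Each loader accepts an
#' alternative `path` so users can substitute their own calibration.
#'
#' * `es_carbon_density()`: carbon pool densities (t/hm^2) per class —
#'   above-ground, below-ground, soil, and dead organic matter.
#' * `es_water_params()`: crop coefficient `kc` (multiplies reference
#'   evapotranspiration) and maximum rooting depth (mm).
#' * `es_usle_factors()`: USLE cover factor `c_factor` and support-practice
#'   factor `p_factor`, both in \[0, 1\].
#' * `es_threats()`: habitat threat sources with `weight` in (0, 1\] and
#'   maximum impact distance `d_max_km`.
#' * `es_sensitivity()`: habitat suitability `suitability` in \[0, 1\] and
#'   sensitivity of each class to each threat (columns `s_<threat>`).
#' * `es_esv_coefficients()`: food-production and raw-material unit values
#'   (Yuan/hm^2/yr). By default the combined food-material coefficient is the
#'   sum of the two components; `combined = "printed"` loads the alternative
#'   fixture with the independently rounded combined row.
#'
#' @param path Optional CSV path overriding the bundled fixture.
#' @param combined For `es_esv_coefficients`: `"sum"` (default) or `"printed"`.
#' @return A data.frame keyed by `class`, ordered as [es_classes()].
#' @export
es_carbon_density <- function(path = extdata_path("carbon_density.csv")) {
  tab <- read_class_table(path, c("c_above", "c_below", "c_soil", "c_dead"))
  if (any(as.matrix(tab[-1]) < 0)) stop("carbon densities must be >= 0")
  tab
}

#' @rdname es_carbon_density
#' @export
es_water_params <- function(path = extdata_path("water_params.csv")) {
  tab <- read_class_table(path, c("kc", "root_depth_mm"))
  if (any(tab$kc < 0) || any(tab$root_depth_mm < 0)) {
    stop("kc and root_depth_mm must be >= 0")
  }
  tab
}

#' @rdname es_carbon_density
#' @export
es_usle_factors <- function(path = extdata_path("usle_factors.csv")) {
  tab <- read_class_table(path, c("c_factor", "p_factor"))
  if (any(tab$c_factor < 0 | tab$c_factor > 1) ||
      any(tab$p_factor < 0 | tab$p_factor > 1)) {
    stop("c_factor and p_factor must lie in [0, 1]")
  }
  tab
}

#' @rdname es_carbon_density
#' @export
es_threats <- function(path = extdata_path("threats.csv")) {
  if (!file.exists(path)) stop("no such parameter table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("threat", "weight", "d_max_km", "decay")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(tab$threat, es_class_names())
  if (length(unknown)) stop(path, ": threat(s) not in the codebook: ", paste(unknown, collapse = ", "))
  if (any(tab$weight <= 0 | tab$weight > 1)) stop(path, ": weights must lie in (0, 1]")
  if (any(tab$d_max_km <= 0)) stop(path, ": d_max_km must be > 0")
  if (!all(tab$decay %in% c("linear", "exponential"))) {
    stop(path, ": decay must be 'linear' or 'exponential'")
  }
  tab[, needed]
}

#' @rdname es_carbon_density
#' @export
es_sensitivity <- function(path = extdata_path("sensitivity.csv")) {
  tab <- read_class_table(path, c("suitability", "s_urban", "s_unused", "s_paddy", "s_dry"))
  if (any(as.matrix(tab[-1]) < 0) || any(as.matrix(tab[-1]) > 1)) {
    stop("suitability and sensitivities must lie in [0, 1]")
  }
  tab
}

#' @rdname es_carbon_density
#' @export
es_esv_coefficients <- function(path = extdata_path("esv_coefficients.csv"),
                                combined = c("sum", "printed")) {
  combined <- match.arg(combined)
  tab <- read_class_table(path, c("food_production", "raw_material", "combined_printed"))
  if (any(as.matrix(tab[-1]) < 0)) stop("ESV coefficients must be >= 0")
  tab$food_material <- if (combined == "sum") {
    tab$food_production + tab$raw_material
  } else {
    tab$combined_printed
  }
  tab
}
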