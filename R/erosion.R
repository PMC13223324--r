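#' Rainfall erosivity from monthly precipitation
#'
#' Empirical power-sum estimator of annual rainfall erosivity:
#' \deqn{R = 1.2157 \sum_{i=1}^{12} 10^{\,1.5 \log_{10}(P_i^2 / P) - 0.0818}
#'         = 1.2157 \cdot 10^{-0.0818} \sum_i (P_i^2 / P)^{1.5}}
#' where \eqn{P_i} is the i-th month's precipitation (mm) and \eqn{P} the
#' annual total, recomputed internally as \eqn{\sum_i P_i} (a supplied annual
#' grid that disagrees by more than 0.1% triggers a warning). Months with
#' zero precipitation contribute zero; an all-dry cell has `R = 0`. The
#' estimator is homogeneous of degree 1.5: scaling all months by `c` scales
#' `R` by `c^1.5`.
#'
#' @param monthly List of 12 `es_raster`s (or a length-12 numeric vector for
#'   a single cell) of monthly precipitation (mm).
#' @param annual Optional annual-total raster used only for the consistency
#'   check.
#' @return Erosivity grid (same shape as one monthly layer) or scalar.
#' @examples
#' rainfall_erosivity(rep(100, 12))  # uniform 1200 mm year
#' @export
rainfall_erosivity <- function(monthly, annual = NULL) {
  if (is.numeric(monthly) && length(monthly) == 12) {
    monthly <- lapply(monthly, function(p) matrix(p, 1, 1))
    scalar <- TRUE
  } else scalar <- FALSE
  if (length(monthly) != 12) stop("monthly must have 12 layers")
  layers <- lapply(monthly, function(m) {
    v <- if (inherits(m, "es_raster")) raster_values(m) else m
    if (any(v < 0, na.rm = TRUE)) stop("monthly precipitation must be non-negative")
    v
  })
  P <- Reduce(`+`, layers)
  if (!is.null(annual)) {
    av <- if (inherits(annual, "es_raster")) raster_values(annual) else annual
    rel <- abs(av - P) / pmax(P, .Machine$double.eps)
    if (any(rel > 0.001, na.rm = TRUE)) {
      warning("annual precipitation disagrees with the monthly sum by > 0.1%")
    }
  }
  const <- 1.2157 * 10^(-0.0818)
  R <- P * 0
  for (m in layers) {
    term <- m * 0
    pos <- !is.na(P) & P > 0 & !is.na(m) & m > 0
    term[pos] <- (m[pos]^2 / P[pos])^1.5
    R <- R + term
  }
  R <- const * R
  if (scalar) R[1, 1] else R
}

#' Potential soil loss via the Universal Soil Loss Equation
#'
#' Per-cell loss rate `R * K * LS * C * Pc` (t/hm^2 in the unit system of
#' `R`), where the cover factor `C` and support-practice factor `Pc` are
#' looked up per land-use class and `R`, `K`, `LS` are cell grids. Cell
#' tonnage is the rate times the cell area in hm^2; totals are reported in
#' 1e4 t.
#'
#' @param lu An `es_raster` of land-use codes.
#' @param R Erosivity grid (matrix or `es_raster`), as from
#'   [rainfall_erosivity()].
#' @param soil A `soil_terrain_stack` (needs `K` and `LS`).
#' @param factors Per-class table as from [es_usle_factors()].
#' @return A list of class `erosion_result`: `loss` (`es_raster`, t per
#'   cell), `class_totals` (named, 1e4 t), `total` (1e4 t).
#' @export
usle <- function(lu, R, soil, factors = es_usle_factors()) {
  check_codes(lu)
  K <- soil$K; LS <- soil$LS
  stopifnot_same_grid(lu, K, "land use and K")
  stopifnot_same_grid(lu, LS, "land use and LS")
  Rv <- if (inherits(R, "es_raster")) raster_values(R) else R
  if (!identical(dim(Rv), dim(raster_values(lu)))) stop("R grid shape mismatch")
  if (any(Rv < 0, na.rm = TRUE) || any(K < 0, na.rm = TRUE) || any(LS < 0, na.rm = TRUE)) {
    stop("R, K and LS must be non-negative")
  }
  c_by_code <- p_by_code <- rep(NA_real_, max(es_classes()$code))
  c_by_code[class_codes(factors$class)] <- factors$c_factor
  p_by_code[class_codes(factors$class)] <- factors$p_factor
  codes <- as.vector(lu)
  present <- unique(codes[!is.na(codes)])
  if (anyNA(c_by_code[present])) {
    stop("missing USLE factors for class code(s): ",
         paste(present[is.na(c_by_code[present])], collapse = ", "))
  }
  rate <- as.vector(Rv) * as.vector(raster_values(K)) *
    as.vector(raster_values(LS)) * c_by_code[codes] * p_by_code[codes]
  tonnes <- rate * cell_area_km2(lu) * 100  # rate per hm2 x cell hm2
  cls <- factor(codes, levels = es_classes()$code, labels = es_classes()$class)
  class_totals <- tapply(tonnes / 1e4, cls, sum, na.rm = TRUE, default = 0)
  structure(list(
    loss = es_raster(matrix(tonnes, nrow(lu), ncol(lu)),
                     cell_size_km = cell_size_km(lu), year = raster_year(lu)),
    class_totals = c(class_totals),
    total = sum(tonnes, na.rm = TRUE) / 1e4
  ), class = "erosion_result")
}

#' Slope length-steepness factor from a slope grid
#'
#' Convenience helper deriving an LS grid from slope (degrees) with the
#' common two-piece power form used on gridded data: the slope-length part
#' uses the cell size as flow-path length with exponent depending on slope
#' steepness. The pipeline itself consumes LS as an input raster; this
#' helper exists for users starting from a DEM-derived slope map.
#'
#' @param slope_deg Slope grid in degrees (matrix or `es_raster`).
#' @param cell_size_m Flow-path length (m), default 1000.
#' @return LS grid (matrix).
#' @export
ls_from_slope <- function(slope_deg, cell_size_m = 1000) {
  s <- if (inherits(slope_deg, "es_raster")) raster_values(slope_deg) else slope_deg
  if (any(s < 0, na.rm = TRUE)) stop("slope must be non-negative")
  theta <- s * pi / 180
  beta <- sin(theta) / 0.0896 / (3 * sin(theta)^0.8 + 0.56)
  m_exp <- beta / (1 + beta)
  L <- (cell_size_m / 22.13)^m_exp
  S <- ifelse(s < 5.14, 10.8 * sin(theta) + 0.03, 16.8 * sin(theta) - 0.5)
  L * pmax(S, 0)
}
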