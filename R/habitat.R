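#' Distance-decayed influence of a threat layer
#'
#' For one threat source, computes each cell's exposure as the decayed
#' influence of the *nearest* source cell (max-combine; the default) or the
#' sum over all source cells within range (`combine = "sum"`). Linear decay
#' is `max(0, 1 - d/d_max)`; exponential decay is `exp(-(2.99/d_max) * d)`.
#' Influence is 1 at source cells and, for both kinds, truncated to 0 beyond
#' `d_max`. Distances are Euclidean between cell centres in km.
#'
#' @param threat_mask Logical matrix (or 0/1), `TRUE` at threat source cells.
#' @param d_max_km Maximum impact distance (km, > 0).
#' @param decay `"linear"` or `"exponential"`.
#' @param cell_size_km Cell edge length (km).
#' @param combine `"max"` (influence of the nearest source) or `"sum"`.
#' @return Numeric matrix of influences (in `[0, 1]` for `"max"`).
#' @export
threat_influence <- function(threat_mask, d_max_km,
                             decay = c("linear", "exponential"),
                             cell_size_km = 1, combine = c("max", "sum")) {
  decay <- match.arg(decay); combine <- match.arg(combine)
  if (d_max_km <= 0) stop("d_max_km must be positive")
  mask <- threat_mask
  if (inherits(mask, "es_raster")) mask <- raster_values(mask)
  mask <- !is.na(mask) & mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  inf <- matrix(0, nr, nc)
  if (!any(mask)) return(inf)
  rmax <- floor(d_max_km / cell_size_km)
  mnum <- mask * 1
  for (dr in -rmax:rmax) {
    for (dc in -rmax:rmax) {
      d <- cell_size_km * sqrt(dr^2 + dc^2)
      if (d > d_max_km) next
      v <- if (decay == "linear") 1 - d / d_max_km else exp(-(2.99 / d_max_km) * d)
      if (v <= 0) next
      tr_lo <- max(1, 1 + dr); tr_hi <- min(nr, nr + dr)
      tc_lo <- max(1, 1 + dc); tc_hi <- min(nc, nc + dc)
      if (tr_lo > tr_hi || tc_lo > tc_hi) next  # shift exceeds the grid
      tr <- tr_lo:tr_hi
      tc <- tc_lo:tc_hi
      src <- mnum[tr - dr, tc - dc, drop = FALSE]
      if (combine == "max") {
        inf[tr, tc] <- pmax(inf[tr, tc], v * src)
      } else {
        inf[tr, tc] <- inf[tr, tc] + v * src
      }
    }
  }
  inf
}

#' Habitat degradation from all threat layers
#'
#' Aggregates threat influence into a per-cell degradation degree:
#' \deqn{D_x = \sum_r \frac{w_r}{\sum_r w_r} \; \bar i_{rx} \; S_{j(x),r}}
#' where \eqn{\bar i_{rx}} is the per-threat influence from
#' [threat_influence()] (nearest-source by default), \eqn{w_r} the threat
#' weight, and \eqn{S_{jr}} the sensitivity of the cell's own land-use class
#' to threat `r`. Threat source cells are the cells of the threat's land-use
#' class.
#'
#' @param lu An `es_raster` of land-use codes.
#' @param threats Threat table as from [es_threats()].
#' @param sens Sensitivity table as from [es_sensitivity()].
#' @param combine Per-threat influence aggregation, see [threat_influence()].
#' @return Degradation matrix `D` (NA at nodata cells).
#' @export
degradation <- function(lu, threats = es_threats(), sens = es_sensitivity(),
                        combine = "max") {
  check_codes(lu)
  codes <- raster_values(lu)
  present <- unique(as.vector(codes)); present <- present[!is.na(present)]
  miss <- setdiff(present, class_codes(sens$class))
  if (length(miss)) {
    stop("classes missing from the sensitivity table: code ",
         paste(miss, collapse = ", "))
  }
  wsum <- sum(threats$weight)
  D <- matrix(0, nrow(lu), ncol(lu))
  for (i in seq_len(nrow(threats))) {
    th <- threats[i, ]
    s_col <- paste0("s_", th$threat)
    if (!s_col %in% names(sens)) stop("sensitivity table lacks column ", s_col)
    s_by_code <- rep(0, max(es_classes()$code))
    s_by_code[class_codes(sens$class)] <- sens[[s_col]]
    infl <- threat_influence(codes == class_codes(th$threat), th$d_max_km,
                             decay = th$decay, cell_size_km = cell_size_km(lu),
                             combine = combine)
    s_cell <- matrix(s_by_code[as.vector(codes)], nrow(lu), ncol(lu))
    s_cell[is.na(s_cell)] <- 0
    D <- D + (th$weight / wsum) * infl * s_cell
  }
  D[is.na(codes)] <- NA_real_
  D
}

#' Habitat quality from degradation
#'
#' Converts degradation to quality with a half-saturation response:
#' \deqn{Q_x = H_{j(x)} \left[1 - \frac{D_x^z}{D_x^z + k^z}\right]}
#' where `H` is the habitat suitability of the cell's class, `z` a shape
#' exponent, and `k` the half-saturation constant — by default half the
#' realised maximum degradation, so `Q = H/2` where `D` attains `k`.
#' Threat-source classes with `H = 0` get `Q = 0` everywhere. If the whole
#' map has `D = 0` and no `k` override is given, `Q = H` is returned with a
#' message (the half-saturation rule is degenerate there).
#'
#' @param D Degradation matrix from [degradation()].
#' @param lu The matching `es_raster` of land-use codes.
#' @param sens Sensitivity table as from [es_sensitivity()].
#' @param z Shape exponent (default 2.5).
#' @param k Optional half-saturation override for cross-run comparability.
#' @return A list of class `habitat_result`: `quality` and `degradation`
#'   (`es_raster`s), `k`, `mean_quality` (over non-nodata cells),
#'   `class_sums` (sum of Q per class).
#' @export
habitat_quality <- function(D, lu, sens = es_sensitivity(), z = 2.5, k = NULL) {
  if (z <= 0) stop("z must be positive")
  if (any(D < 0, na.rm = TRUE)) stop("degradation must be non-negative")
  if (!identical(dim(D), dim(raster_values(lu)))) stop("D and land use shapes differ")
  h_by_code <- rep(NA_real_, max(es_classes()$code))
  h_by_code[class_codes(sens$class)] <- sens$suitability
  codes <- as.vector(raster_values(lu))
  H <- matrix(h_by_code[codes], nrow(lu), ncol(lu))
  dmax <- suppressWarnings(max(D, na.rm = TRUE))
  if (is.null(k)) {
    if (!is.finite(dmax) || dmax <= 0) {
      message("degradation is zero everywhere; returning Q = H (no half-saturation)")
      Q <- H
      k <- NA_real_
    } else {
      k <- dmax / 2
    }
  }
  if (!is.na(k)) {
    if (k <= 0) stop("k must be positive")
    Q <- H * (1 - D^z / (D^z + k^z))
  }
  Q[is.na(codes)] <- NA_real_
  cls <- factor(codes, levels = es_classes()$code, labels = es_classes()$class)
  class_sums <- tapply(as.vector(Q), cls, sum, na.rm = TRUE, default = 0)
  structure(list(
    quality = es_raster(Q, cell_size_km = cell_size_km(lu), year = raster_year(lu)),
    degradation = es_raster(D, cell_size_km = cell_size_km(lu), year = raster_year(lu)),
    k = k, z = z,
    mean_quality = mean(Q, na.rm = TRUE),
    class_sums = c(class_sums)
  ), class = "habitat_result")
}

#' Full habitat-quality model
#'
#' Runs [degradation()] then [habitat_quality()] on one land-use raster.
#'
#' @inheritParams degradation
#' @inheritParams habitat_quality
#' @return See [habitat_quality()].
#' @export
habitat_model <- function(lu, threats = es_threats(), sens = es_sensitivity(),
                          z = 2.5, k = NULL, combine = "max") {
  D <- degradation(lu, threats, sens, combine = combine)
  habitat_quality(D, lu, sens, z = z, k = k)
}
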