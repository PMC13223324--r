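#' Pearson correlation with significance stars
#'
#' Cross-sectional correlation between two service vectors with the usual
#' t-test on n - 2 degrees of freedom and star labels: `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, `ns` otherwise. A zero-variance input yields
#' an undefined result (`r`, `p` = `NA`, stars `"undef"`) rather than an
#' error.
#'
#' @param x,y Numeric vectors of equal length >= 3 (pairwise-complete
#'   observations are used).
#' @return A list: `r`, `p`, `stars`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, stars = "undef", n = n))
  }
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, stars = p_stars(p), n = n)
}

p_stars <- function(p) {
  ifelse(is.na(p), "undef",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

panel_service_cols <- function(per_unit) {
  if (per_unit) {
    c(carbon = "carbon_per_km2", habitat = "habitat",
      water_yield = "water_yield_mm", erosion = "erosion_per_km2",
      food_material = "food_material_per_km2")
  } else {
    c(carbon = "carbon", habitat = "habitat", water_yield = "water_yield",
      erosion = "erosion", food_material = "food_material")
  }
}

#' Pairwise service correlation matrix for one year
#'
#' Computes Pearson correlations between all pairs of the five services
#' across regions in one panel year, on the totals scale or the
#' per-unit-area scale. Stars are raw by default; `adjust = "BH"` applies
#' Benjamini-Hochberg correction across the off-diagonal pairs before
#' starring.
#'
#' @param panel A [zonal_totals()]-style panel (stacked years allowed).
#' @param year Year to analyse.
#' @param per_unit Use per-unit-area columns instead of totals.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A list of class `correlation_matrix`: `r`, `p`, `stars` (square
#'   matrices), `n`, `year`, `scale`.
#' @export
service_correlation_matrix <- function(panel, year, per_unit = FALSE,
                                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- panel[panel$year == year, , drop = FALSE]
  if (!nrow(rows)) stop("year not present in panel: ", year)
  if (nrow(rows) < 3) stop("need at least 3 regions")
  cols <- panel_service_cols(per_unit)
  dat <- rows[, cols]
  names(dat) <- names(cols)
  k <- ncol(dat)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(dat), names(dat)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pr <- pearson(dat[[i]], dat[[j]])
      r[i, j] <- r[j, i] <- pr$r
      p[i, j] <- p[j, i] <- pr$p
    }
  }
  p_star <- p
  if (adjust == "BH") {
    up <- upper.tri(p)
    p_star[up] <- stats::p.adjust(p[up], method = "BH")
    p_star[lower.tri(p_star)] <- t(p_star)[lower.tri(p_star)]
  }
  stars <- matrix(p_stars(p_star), k, k, dimnames = dimnames(p))
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars, n = nrow(rows), year = year,
                 scale = if (per_unit) "per_unit" else "total"),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> year %s, %s scale, n = %d regions\n",
              x$year, x$scale, x$n))
  lab <- matrix(paste0(formatC(x$r, digits = 2, format = "f"), x$stars),
                nrow(x$r), dimnames = dimnames(x$r))
  diag(lab) <- "1"
  print(lab, quote = FALSE)
  invisible(x)
}

#' Service vs land-use-proportion correlations
#'
#' Correlates each per-unit-area service with each class-proportion column
#' across regions for one year.
#'
#' @param panel A [zonal_totals()]-style panel.
#' @param proportions A [landuse_proportions()]-style table.
#' @param year Year to analyse.
#' @return A list with matrices `r`, `p`, `stars` (services x classes).
#' @export
proportion_correlations <- function(panel, proportions, year) {
  rows <- panel[panel$year == year, , drop = FALSE]
  props <- proportions[proportions$year == year, , drop = FALSE]
  if (!nrow(rows) || !nrow(props)) stop("year not present: ", year)
  props <- props[match(rows$region, props$region), , drop = FALSE]
  if (anyNA(props$region)) stop("regions of panel and proportions differ")
  scols <- panel_service_cols(per_unit = TRUE)
  pcols <- paste0("p_", es_classes()$class)
  r <- p <- matrix(NA_real_, length(scols), length(pcols),
                   dimnames = list(names(scols), es_classes()$class))
  for (i in seq_along(scols)) {
    for (j in seq_along(pcols)) {
      pr <- pearson(rows[[scols[i]]], props[[pcols[j]]])
      r[i, j] <- pr$r; p[i, j] <- pr$p
    }
  }
  list(r = r, p = p, stars = matrix(p_stars(p), nrow(r), dimnames = dimnames(r)))
}
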