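#' Specification of a synthetic landscape
#'
#' Collects every knob of the synthetic-landscape generator in one validated
#' object. Defaults emulate a large (~243,000 km^2) agricultural river-basin
#' study region in the north-south climatic transition zone of eastern China:
#' seven land-use classes dominated by cropland, about 29 administrative
#' regions, a 992.9 mm domain-mean annual precipitation that increases from
#' north to south, and three decadal steps of land-use change dominated by
#' urban expansion onto cropland.
#'
#' @param grid_rows,grid_cols Grid dimensions (positive integers).
#' @param cell_size_km Cell edge length in km (default 1).
#' @param class_proportions Named numeric vector of target class fractions
#'   (names from [es_class_names()]); must sum to 1 within 1e-9. The default
#'   mirrors the 1990 class shares of the emulated region.
#' @param n_regions Number of contiguous regions to carve (default 29).
#' @param precip_mean_mm Domain-mean annual precipitation (default 992.9).
#' @param precip_gradient_mm_per_km Increase in annual precipitation per km
#'   moving south (i.e. with increasing row index); default 1.
#' @param precip_noise_sd East-west smooth precipitation variability (mm,
#'   standard deviation before centring); default 25.
#' @param pet_mean_mm Domain-mean annual reference evapotranspiration
#'   (default 1000).
#' @param pet_gradient_mm_per_km Increase in reference ET per km moving
#'   north; default 0.5.
#' @param monthly_profile 12 non-negative weights summing to 1 that split
#'   annual precipitation into months; default is a wet-summer profile with
#'   ~60% of rain in May-September.
#' @param years Ordered vector of epoch labels (default 1990, 2000, 2010, 2020).
#' @param change_rules List of per-step conversion rules, each a list with
#'   `from`, `to` (class keys) and `fraction` (share of the source class
#'   converted per step). The default rules emulate decadal urban expansion
#'   onto dry and paddy cropland, cropland encroachment on grassland and
#'   unused land, and growth of water bodies.
#' @param smooth_radius Box-blur radius (cells) of the noise fields; controls
#'   patch size (default 5).
#' @param seed Integer seed; every generator derives its randomness from it.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(grid_rows = 200, grid_cols = 200, cell_size_km = 1,
                           class_proportions = NULL,
                           n_regions = 29,
                           precip_mean_mm = 992.9,
                           precip_gradient_mm_per_km = 1,
                           precip_noise_sd = 25,
                           pet_mean_mm = 1000,
                           pet_gradient_mm_per_km = 0.5,
                           monthly_profile = c(0.02, 0.03, 0.05, 0.07, 0.10, 0.14,
                                               0.18, 0.16, 0.10, 0.07, 0.05, 0.03),
                           years = c(1990, 2000, 2010, 2020),
                           change_rules = default_change_rules(),
                           smooth_radius = 5,
                           seed = 1L) {
  if (is.null(class_proportions)) {
    # 1990 class areas (km^2) of the emulated region, normalised
    a <- c(forest = 23659, grassland = 11015, water = 12854, urban = 30542,
           unused = 741, paddy = 51555, dry = 131038)
    class_proportions <- a / sum(a)
  }
  if (grid_rows < 1 || grid_cols < 1) stop("grid dimensions must be positive")
  if (cell_size_km <= 0) stop("cell_size_km must be positive")
  if (is.null(names(class_proportions)) || any(names(class_proportions) == "")) {
    stop("class_proportions must be a named vector")
  }
  class_codes(names(class_proportions))  # errors on unknown classes
  if (any(class_proportions < 0 | class_proportions > 1)) {
    stop("class proportions must lie in [0, 1]")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop(sprintf("class proportions must sum to 1 (got %.12g)", sum(class_proportions)))
  }
  if (n_regions < 1 || n_regions > grid_rows * grid_cols) {
    stop("n_regions must be between 1 and the number of grid cells")
  }
  if (length(monthly_profile) != 12 || any(monthly_profile < 0) ||
      abs(sum(monthly_profile) - 1) > 1e-9) {
    stop("monthly_profile must be 12 non-negative weights summing to 1")
  }
  for (r in change_rules) {
    class_codes(c(r$from, r$to))
    if (r$fraction < 0 || r$fraction > 1) stop("change-rule fractions must lie in [0, 1]")
  }
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    cell_size_km = cell_size_km, class_proportions = class_proportions,
    n_regions = as.integer(n_regions),
    precip_mean_mm = precip_mean_mm,
    precip_gradient_mm_per_km = precip_gradient_mm_per_km,
    precip_noise_sd = precip_noise_sd,
    pet_mean_mm = pet_mean_mm, pet_gradient_mm_per_km = pet_gradient_mm_per_km,
    monthly_profile = monthly_profile,
    years = years, change_rules = change_rules,
    smooth_radius = as.integer(smooth_radius), seed = as.integer(seed)
  ), class = "landscape_spec")
}

#' @rdname landscape_spec
#' @export
default_change_rules <- function() {
  list(
    list(from = "dry", to = "urban", fraction = 0.020),
    list(from = "paddy", to = "urban", fraction = 0.012),
    list(from = "grassland", to = "dry", fraction = 0.100),
    list(from = "unused", to = "urban", fraction = 0.400),
    list(from = "dry", to = "water", fraction = 0.006)
  )
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable box blur with edge renormalisation, repeated `times` times
box_blur <- function(m, radius, times = 3) {
  if (radius < 1) return(m)
  blur1d <- function(v, r) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - r, 1)
    hi <- pmin(seq_len(n) + r, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(times)) {
    m <- matrix(apply(m, 2, blur1d, r = radius), nrow = nr)
    m <- t(matrix(apply(m, 1, blur1d, r = radius), nrow = nc))
  }
  m
}

# smoothed standard-normal-ish field, standardised to mean 0 / sd 1
smooth_field <- function(nr, nc, radius) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  z <- box_blur(z, radius)
  (z - mean(z)) / stats::sd(z)
}

#' Generate a categorical land-use raster
#'
#' Draws one spatially autocorrelated noise field (box-blurred white noise),
#' ranks its cells, and slices the ranking at the cumulative class
#' proportions, so realised class counts match the request to within one
#' cell while contiguous rank bands form patches. Identical spec and seed
#' give bit-identical output.
#'
#' @param spec A [landscape_spec()].
#' @return An `es_raster` of class codes labelled with the first year in
#'   `spec$years`.
#' @export
generate_landuse <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$grid_rows; nc <- spec$grid_cols
  p <- spec$class_proportions
  codes <- class_codes(names(p))
  field <- with_seed(spec$seed, smooth_field(nr, nc, spec$smooth_radius))
  ord <- order(field)  # ties impossible a.s.; order() is stable anyway
  ncell <- nr * nc
  bounds <- round(cumsum(p) * ncell)
  bounds[length(bounds)] <- ncell
  out <- integer(ncell)
  lo <- 1L
  for (k in seq_along(p)) {
    if (bounds[k] >= lo) out[ord[lo:bounds[k]]] <- codes[k]
    lo <- bounds[k] + 1L
  }
  es_raster(matrix(out, nr, nc), cell_size_km = spec$cell_size_km,
            year = spec$years[1])
}

#' Advance a land-use raster one change step
#'
#' Applies conversion rules `(from, to, fraction)` in order. For each rule,
#' `round(fraction * n_from)` source cells convert, chosen preferentially
#' where they touch existing target-class patches (count of 4-neighbours of
#' the target class, random tie-break), which mimics urban growth accreting
#' onto built-up edges. The cell count is conserved; a rule asking for more
#' cells than remain converts all of them with a warning.
#'
#' @param base An `es_raster` of land-use codes.
#' @param change_rules List of rules as in [landscape_spec()].
#' @param seed Integer seed for the tie-break randomness.
#' @param year Optional year label for the output.
#' @return An `es_raster` with the same grid and cell size.
#' @export
advance_landuse <- function(base, change_rules, seed = 1L, year = NULL) {
  check_codes(base)
  cur <- raster_values(base)
  with_seed(seed, {
    for (rule in change_rules) {
      from <- class_codes(rule$from); to <- class_codes(rule$to)
      avail <- which(cur == from)
      if (!length(avail)) next
      n <- round(rule$fraction * length(avail))
      if (n > length(avail)) {
        warning(sprintf("rule %s->%s: requested %d cells, only %d available",
                        rule$from, rule$to, n, length(avail)))
        n <- length(avail)
      }
      if (n == 0) next
      score <- neighbour_count(cur, to)[avail] + stats::runif(length(avail))
      conv <- avail[order(score, decreasing = TRUE)[seq_len(n)]]
      cur[conv] <- to
    }
  })
  es_raster(cur, cell_size_km = cell_size_km(base),
            year = if (is.null(year)) raster_year(base) else year)
}

# per-cell count of 4-neighbours equal to `code` (edges see fewer neighbours)
neighbour_count <- function(m, code) {
  b <- m == code
  b[is.na(b)] <- FALSE
  nr <- nrow(b); nc <- ncol(b)
  cnt <- matrix(0L, nr, nc)
  cnt[-1, ] <- cnt[-1, ] + b[-nr, ]
  cnt[-nr, ] <- cnt[-nr, ] + b[-1, ]
  cnt[, -1] <- cnt[, -1] + b[, -nc]
  cnt[, -nc] <- cnt[, -nc] + b[, -1]
  cnt
}

#' Generate the climate stack
#'
#' Annual precipitation is a linear north-to-south gradient plus a smooth,
#' exactly mean-centred east-west variability component, so the domain mean
#' equals `precip_mean_mm` exactly and row means increase strictly along the
#' gradient axis. Monthly grids split the annual total by the wet-summer
#' `monthly_profile`; reference evapotranspiration carries the opposite
#' (drier-north) gradient. All grids are clamped to be non-negative.
#'
#' @param spec A [landscape_spec()].
#' @return A list of class `climate_stack`: `annual_precip` (`es_raster`),
#'   `monthly_precip` (list of 12 `es_raster`s), `pet` (`es_raster`).
#' @export
generate_climate <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$grid_rows; nc <- spec$grid_cols; cs <- spec$cell_size_km
  row_off <- (seq_len(nr) - (nr + 1) / 2) * cs
  col_noise <- with_seed(spec$seed + 1000L, {
    v <- stats::rnorm(nc, sd = spec$precip_noise_sd)
    v <- box_blur(matrix(v, 1, nc), spec$smooth_radius)[1, ]
    v - mean(v)
  })
  P <- outer(row_off * spec$precip_gradient_mm_per_km, col_noise, `+`) + spec$precip_mean_mm
  P <- pmax(P, 0)
  PET <- matrix(spec$pet_mean_mm - row_off * spec$pet_gradient_mm_per_km, nr, nc)
  PET <- pmax(PET, 0)
  monthly <- lapply(spec$monthly_profile, function(w) {
    es_raster(P * w, cell_size_km = cs)
  })
  structure(list(
    annual_precip = es_raster(P, cell_size_km = cs),
    monthly_precip = monthly,
    pet = es_raster(PET, cell_size_km = cs)
  ), class = "climate_stack")
}

#' Generate soil and terrain grids
#'
#' Smooth seeded fields with realistic magnitudes: soil erodibility `K`
#' log-normal around 0.035 (t h MJ^-1 mm^-1), slope length-steepness `LS`
#' log-normal around 1.5 (dimensionless, skewed towards flat plains), and
#' plant-available water capacity `PAWC` a fraction squashed into
#' \[0.08, 0.22\].
#'
#' @param spec A [landscape_spec()].
#' @return A list of class `soil_terrain_stack` with `es_raster`s `K`, `LS`,
#'   `PAWC`.
#' @export
generate_soil_terrain <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$grid_rows; nc <- spec$grid_cols; cs <- spec$cell_size_km
  f <- with_seed(spec$seed + 2000L, list(
    k = smooth_field(nr, nc, spec$smooth_radius),
    ls = smooth_field(nr, nc, spec$smooth_radius),
    pawc = smooth_field(nr, nc, spec$smooth_radius)
  ))
  structure(list(
    K = es_raster(0.035 * exp(0.25 * f$k), cell_size_km = cs),
    LS = es_raster(1.5 * exp(0.8 * f$ls), cell_size_km = cs),
    PAWC = es_raster(0.08 + 0.14 * stats::plogis(2 * f$pawc), cell_size_km = cs)
  ), class = "soil_terrain_stack")
}

#' Generate a contiguous region partition
#'
#' Seeded multi-source flood fill: `n_regions` distinct seed cells are drawn,
#' then regions grow one 4-neighbour ring per round until the grid is
#' exhausted. Every cell belongs to exactly one region and every region is
#' contiguous by construction.
#'
#' @param spec A [landscape_spec()].
#' @return An `es_raster` of integer region ids in `1:n_regions`.
#' @export
generate_regions <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$grid_rows; nc <- spec$grid_cols
  reg <- matrix(NA_integer_, nr, nc)
  seeds <- with_seed(spec$seed + 3000L, sample.int(nr * nc, spec$n_regions))
  reg[seeds] <- seq_len(spec$n_regions)
  while (anyNA(reg)) {
    prev <- reg
    # propagate from north, south, west, east in fixed order;
    # first writer wins within a round (deterministic)
    take_from <- function(tgt_rows, tgt_cols, src_rows, src_cols) {
      tgt <- reg[tgt_rows, tgt_cols, drop = FALSE]
      src <- prev[src_rows, src_cols, drop = FALSE]
      idx <- is.na(tgt) & !is.na(src)
      tgt[idx] <- src[idx]
      reg[tgt_rows, tgt_cols] <<- tgt
    }
    all_r <- seq_len(nr); all_c <- seq_len(nc)
    take_from(all_r[-1], all_c, all_r[-nr], all_c)
    take_from(all_r[-nr], all_c, all_r[-1], all_c)
    take_from(all_r, all_c[-1], all_r, all_c[-nc])
    take_from(all_r, all_c[-nc], all_r, all_c[-1])
    if (identical(prev, reg)) stop("flood fill stalled (should be impossible)")
  }
  es_raster(reg, cell_size_km = spec$cell_size_km)
}

#' Generate the land-use time series
#'
#' Convenience wrapper: generates the base-year raster then applies the
#' spec's change rules once per step between consecutive years.
#'
#' @param spec A [landscape_spec()].
#' @return Named list of `es_raster`s, one per year in `spec$years`.
#' @export
generate_landuse_series <- function(spec) {
  out <- vector("list", length(spec$years))
  names(out) <- as.character(spec$years)
  out[[1]] <- generate_landuse(spec)
  for (i in seq_along(spec$years)[-1]) {
    out[[i]] <- advance_landuse(out[[i - 1]], spec$change_rules,
                                seed = spec$seed + 100L + i,
                                year = spec$years[i])
  }
  out
}

#' Moran's I on a 4-neighbour lattice
#'
#' Global spatial autocorrelation of a numeric grid under rook contiguity
#' with binary weights; used to verify that generated landscapes are
#' patchy rather than salt-and-pepper.
#'
#' @param m Numeric matrix (e.g. a class indicator).
#' @return Moran's I (scalar).
#' @export
morans_i <- function(m) {
  z <- m - mean(m)
  nr <- nrow(m); nc <- ncol(m)
  num <- sum(z[-nr, ] * z[-1, ]) + sum(z[, -nc] * z[, -1])
  w <- (nr - 1) * nc + nr * (nc - 1)
  (length(m) / (2 * w)) * (2 * num) / sum(z^2)
}
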