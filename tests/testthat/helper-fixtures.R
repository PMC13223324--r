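# shared toy inputs built in code

# tiny deterministic landscape spec
tiny_spec <- function(n = 40, seed = 11, ...) {
  landscape_spec(grid_rows = n, grid_cols = n, seed = seed, ...)
}

# raster from a vector, filled by row for readable literals
toy_raster <- function(v, nrow, ncol, cell_size_km = 1, year = NULL) {
  es_raster(matrix(v, nrow, ncol, byrow = TRUE), cell_size_km = cell_size_km,
            year = year)
}

# random legal land-use raster (codes 1..7 with some NA)
random_landuse <- function(nr = 12, nc = 12, p_na = 0.05, seed = 1) {
  withr::with_seed(seed, {
    v <- sample(1:7, nr * nc, replace = TRUE)
    v[stats::runif(nr * nc) < p_na] <- NA
    es_raster(matrix(v, nr, nc))
  })
}

# uniform climate stack over a given grid
uniform_climate <- function(nr, nc, P = 1000, pet = 800,
                            profile = rep(1 / 12, 12)) {
  structure(list(
    annual_precip = es_raster(matrix(P, nr, nc)),
    monthly_precip = lapply(profile, function(w) es_raster(matrix(P * w, nr, nc))),
    pet = es_raster(matrix(pet, nr, nc))
  ), class = "climate_stack")
}

uniform_soil <- function(nr, nc, K = 0.03, LS = 2, PAWC = 0.15) {
  structure(list(
    K = es_raster(matrix(K, nr, nc)),
    LS = es_raster(matrix(LS, nr, nc)),
    PAWC = es_raster(matrix(PAWC, nr, nc))
  ), class = "soil_terrain_stack")
}
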