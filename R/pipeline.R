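#' Pipeline configuration
#'
#' Bundles the landscape specification and every model option into one
#' validated object consumed by [run_pipeline()].
#'
#' @param spec A [landscape_spec()].
#' @param carbon_densities,water_params,usle_factors,threats,sensitivity,esv_coefficients
#'   Parameter tables; defaults are the bundled fixtures.
#' @param Z,omega_offset Budyko constants ([budyko_aet()]).
#' @param z Habitat-quality shape exponent.
#' @param habitat_k Optional fixed half-saturation constant applied to every
#'   epoch (cross-epoch comparability); `NULL` recomputes per epoch.
#' @param alpha_in,alpha_out Stepwise thresholds ([stepwise()]).
#' @param out_dir Optional directory; when set, [run_pipeline()] writes the
#'   panel, transfer matrices, correlation and driver tables as CSV and the
#'   land-use rasters as ASCII grids.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = landscape_spec(),
                            carbon_densities = es_carbon_density(),
                            water_params = es_water_params(),
                            usle_factors = es_usle_factors(),
                            threats = es_threats(),
                            sensitivity = es_sensitivity(),
                            esv_coefficients = es_esv_coefficients(),
                            Z = 5, omega_offset = 1.25, z = 2.5,
                            habitat_k = NULL,
                            alpha_in = 0.05, alpha_out = 0.10,
                            out_dir = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  structure(list(spec = spec, carbon_densities = carbon_densities,
                 water_params = water_params, usle_factors = usle_factors,
                 threats = threats, sensitivity = sensitivity,
                 esv_coefficients = esv_coefficients,
                 Z = Z, omega_offset = omega_offset, z = z,
                 habitat_k = habitat_k,
                 alpha_in = alpha_in, alpha_out = alpha_out,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full ecosystem-service pipeline
#'
#' End to end on a synthetic landscape: generates the land-use time series,
#' one climate stack per epoch, soil/terrain grids and the region partition;
#' runs the five service models for every epoch; assembles the region x year
#' service panel and land-use proportions; computes pairwise service
#' correlations per year (totals and per-unit-area scales) and land-use
#' driver attribution (hierarchical partitioning and stepwise equations);
#' and chains pairwise land-use transfer matrices. Deterministic given the
#' spec's seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_result`: `landuse` (per-year rasters),
#'   `regions`, `panel`, `proportions`, `class_areas` (per year),
#'   `transfer_matrices` (consecutive year pairs), `service_results`
#'   (per year: carbon/water/erosion/habitat/esv), `tradeoffs` (per year:
#'   `total` and `per_unit` correlation matrices), `drivers`
#'   (a `driver_result`), `domain_change` (domain-level service change
#'   between first and last year).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec
  say <- function(...) if (!quiet) message(sprintf(...))
  say("generating landscape (%dx%d, %d epochs, seed %d)",
      spec$grid_rows, spec$grid_cols, length(spec$years), spec$seed)
  lus <- generate_landuse_series(spec)
  soil <- generate_soil_terrain(spec)
  regions <- generate_regions(spec)
  panel <- NULL; props <- NULL
  service_results <- list(); areas <- list(); climates <- list()
  for (i in seq_along(spec$years)) {
    y <- spec$years[i]
    say("epoch %s: service models", y)
    spec_y <- spec; spec_y$seed <- spec$seed + 10L * i
    climate <- generate_climate(spec_y)
    lu <- lus[[i]]
    carbon <- carbon_stock(lu, config$carbon_densities)
    water <- water_yield(lu, climate, soil, config$water_params,
                         Z = config$Z, omega_offset = config$omega_offset)
    R <- rainfall_erosivity(climate$monthly_precip, climate$annual_precip)
    erosion <- usle(lu, R, soil, config$usle_factors)
    habitat <- habitat_model(lu, config$threats, config$sensitivity,
                             z = config$z, k = config$habitat_k)
    esv <- food_material_value(lu, config$esv_coefficients)
    service_results[[as.character(y)]] <-
      list(carbon = carbon, water = water, erosion = erosion,
           habitat = habitat, esv = esv)
    climates[[as.character(y)]] <- climate
    areas[[as.character(y)]] <- class_areas(lu)
    panel <- rbind(panel, zonal_totals(regions, carbon, water, erosion,
                                       habitat, esv, year = y))
    props <- rbind(props, landuse_proportions(lu, regions))
  }
  say("land-use accounting")
  tms <- list()
  for (i in seq_along(spec$years)[-1]) {
    key <- paste(spec$years[i - 1], spec$years[i], sep = "_")
    tms[[key]] <- transfer_matrix(lus[[i - 1]], lus[[i]])
  }
  say("trade-off correlations and driver attribution")
  tradeoffs <- lapply(spec$years, function(y) {
    list(total = service_correlation_matrix(panel, y, per_unit = FALSE),
         per_unit = service_correlation_matrix(panel, y, per_unit = TRUE))
  })
  names(tradeoffs) <- as.character(spec$years)
  drivers <- driver_table(panel, props, years = spec$years,
                          alpha_in = config$alpha_in,
                          alpha_out = config$alpha_out)
  domain <- stats::aggregate(
    panel[c("carbon", "water_yield", "erosion", "food_material")],
    by = list(year = panel$year), FUN = sum)
  hab <- vapply(split(panel, panel$year), function(d) {
    sum(d$habitat * d$area_km2) / sum(d$area_km2)
  }, 0)
  domain$habitat <- hab[as.character(domain$year)]
  y0 <- spec$years[1]; y1 <- spec$years[length(spec$years)]
  domain$key <- "domain"
  domain_change <- service_change(domain, y0, y1, by = "key")
  out <- structure(list(
    landuse = lus, regions = regions, soil = soil, climates = climates,
    panel = panel, proportions = props, class_areas = areas,
    transfer_matrices = tms, service_results = service_results,
    tradeoffs = tradeoffs, drivers = drivers,
    domain = domain[setdiff(names(domain), "key")],
    domain_change = domain_change,
    config = config
  ), class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$panel, file.path(dir, "service_panel.csv"), row.names = FALSE)
  utils::write.csv(res$proportions, file.path(dir, "landuse_proportions.csv"),
                   row.names = FALSE)
  utils::write.csv(res$drivers$contributions,
                   file.path(dir, "driver_contributions.csv"), row.names = TRUE)
  for (key in names(res$transfer_matrices)) {
    write_transfer_matrix(res$transfer_matrices[[key]],
                          file.path(dir, paste0("transfer_", key, ".csv")))
  }
  for (y in names(res$landuse)) {
    write_ascii_grid(res$landuse[[y]], file.path(dir, paste0("landuse_", y, ".asc")))
  }
  write_ascii_grid(res$regions, file.path(dir, "regions.asc"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  yrs <- names(x$landuse)
  cat(sprintf("<pipeline_result> %d epochs (%s), %d regions, %dx%d grid\n",
              length(yrs), paste(yrs, collapse = ", "),
              length(unique(x$panel$region)),
              nrow(x$regions), ncol(x$regions)))
  cat("domain totals by year:\n")
  print(x$domain, row.names = FALSE, digits = 4)
  invisible(x)
}
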