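# build the five service results on a shared toy landscape
toy_services <- function(lu) {
  cl <- uniform_climate(nrow(lu), ncol(lu), P = 1000, pet = 800)
  st <- uniform_soil(nrow(lu), ncol(lu))
  list(
    carbon = carbon_stock(lu, es_carbon_density()),
    water = water_yield(lu, cl, st),
    erosion = usle(lu, rainfall_erosivity(cl$monthly_precip), st),
    habitat = habitat_model(lu),
    esv = food_material_value(lu)
  )
}

test_that("zonal_totals: single region equals domain totals; symmetry holds", {
  lu <- random_landuse(10, 10, p_na = 0, seed = 31)
  sv <- toy_services(lu)
  one <- es_raster(matrix(1L, 10, 10))
  pan <- zonal_totals(one, sv$carbon, sv$water, sv$erosion, sv$habitat, sv$esv,
                      year = 1990)
  expect_equal(nrow(pan), 1)
  expect_equal(pan$carbon, sv$carbon$total)
  expect_equal(pan$water_yield, sv$water$total_volume)
  expect_equal(pan$erosion, sv$erosion$total)
  expect_equal(pan$food_material, sv$esv$total)
  expect_equal(pan$habitat, sv$habitat$mean_quality)
  # per-unit-area x area recovers totals
  expect_equal(pan$carbon_per_km2 * pan$area_km2 / 1e8, pan$carbon)
  expect_equal(pan$food_material_per_km2 * pan$area_km2 * 1e4 / 1e8,
               pan$food_material)

  # two equal half-domains of a uniform raster -> identical rows
  lu_u <- es_raster(matrix(7L, 10, 10))
  sv_u <- toy_services(lu_u)
  halves <- es_raster(cbind(matrix(1L, 10, 5), matrix(2L, 10, 5)))
  pan2 <- zonal_totals(halves, sv_u$carbon, sv_u$water, sv_u$erosion,
                       sv_u$habitat, sv_u$esv, year = 1990)
  expect_equal(pan2[1, -1], pan2[2, -1], ignore_attr = TRUE)
})

test_that("zonal_totals matches a manual 3-region oracle and region sums close", {
  lu <- random_landuse(9, 9, p_na = 0, seed = 32)
  sv <- toy_services(lu)
  reg <- es_raster(matrix(rep(1:3, each = 27), 9, 9))
  pan <- zonal_totals(reg, sv$carbon, sv$water, sv$erosion, sv$habitat, sv$esv,
                      year = 2000)
  m <- raster_values(sv$carbon$stock)
  for (id in 1:3) {
    expect_equal(pan$carbon[pan$region == id],
                 sum(m[raster_values(reg) == id]) / 1e8)
  }
  expect_equal(sum(pan$carbon), sv$carbon$total)
  expect_equal(sum(pan$water_yield), sv$water$total_volume)
  expect_equal(sum(pan$erosion), sv$erosion$total)
  expect_equal(sum(pan$food_material), sv$esv$total)
})

test_that("landuse_proportions rows are simplex vectors consistent with class areas", {
  lu <- random_landuse(20, 20, seed = 33)
  reg <- generate_regions(tiny_spec(n = 20, n_regions = 5, seed = 34))
  pr <- landuse_proportions(lu, reg)
  pcols <- paste0("p_", es_class_names())
  expect_true(all(abs(rowSums(pr[pcols]) - 1) < 1e-9))
  expect_true(all(as.matrix(pr[pcols]) >= 0 & as.matrix(pr[pcols]) <= 1))
  # single-region check against class_areas
  one <- es_raster(matrix(1L, 20, 20))
  pr1 <- landuse_proportions(lu, one)
  a <- class_areas(lu)
  expect_equal(as.numeric(pr1[1, pcols]), a$area_km2 / sum(a$area_km2))
})

test_that("service_change reproduces hand arithmetic and flags zero baselines", {
  panel <- data.frame(year = c(1990, 2020), region = c("all", "all"),
                      carbon = c(0.2480, 0.3053), habitat = c(0.5, 0.5),
                      erosion = c(0, 10))
  ch <- service_change(panel, 1990, 2020)
  expect_equal(ch$abs_change[ch$service == "carbon"], 0.0573)
  expect_equal(ch$pct_change[ch$service == "carbon"], 100 * 0.0573 / 0.2480)
  expect_equal(ch$abs_change[ch$service == "habitat"], 0)
  expect_true(is.na(ch$pct_change[ch$service == "erosion"]))
  expect_error(service_change(panel, 1990, 2019), "not present")
})
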