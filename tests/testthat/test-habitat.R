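test_that("threat_influence matches the scalar decay formulas", {
  # single threat cell, d_max = 3 km, linear, 1-km grid
  mask <- matrix(FALSE, 1, 7); mask[1, 1] <- TRUE
  inf <- threat_influence(mask, 3, "linear")
  expect_equal(inf[1, 1:4], c(1, 2 / 3, 1 / 3, 0))
  expect_true(all(inf[1, 4:7] == 0))  # zero at and beyond d_max

  # exponential decay: exp(-(2.99/d_max) d), 1 at source
  infe <- threat_influence(mask, 3, "exponential")
  expect_equal(infe[1, 1], 1)
  expect_equal(infe[1, 3], exp(-(2.99 / 3) * 2))

  # diagonal distances are Euclidean
  m2 <- matrix(FALSE, 3, 3); m2[1, 1] <- TRUE
  inf2 <- threat_influence(m2, 3, "linear")
  expect_equal(inf2[2, 2], 1 - sqrt(2) / 3)

  # max-combine takes the nearest source; sum mode adds
  m3 <- matrix(FALSE, 1, 5); m3[1, c(1, 5)] <- TRUE
  expect_equal(threat_influence(m3, 3, "linear")[1, 3], 1 / 3)
  expect_equal(threat_influence(m3, 3, "linear", combine = "sum")[1, 3], 2 / 3)

  expect_equal(threat_influence(matrix(FALSE, 2, 2), 3, "linear"),
               matrix(0, 2, 2))
  expect_error(threat_influence(mask, 0), "positive")
})

test_that("degradation matches a hand-computed single-threat oracle", {
  threats <- es_threats(); sens <- es_sensitivity()
  # forest cell adjacent to one urban cell, nothing else
  lu <- toy_raster(c(4, 1, 1), 1, 3)
  D <- degradation(lu, threats, sens)
  wsum <- sum(threats$weight)
  w_urban <- threats$weight[threats$threat == "urban"]
  d_max <- threats$d_max_km[threats$threat == "urban"]
  # forest sensitivity to urban is 0.8
  expect_equal(D[1, 2], (w_urban / wsum) * (1 - 1 / d_max) * 0.8)
  expect_equal(D[1, 3], (w_urban / wsum) * (1 - 2 / d_max) * 0.8)

  # landscape with no threat cells -> D = 0 everywhere
  lu_f <- es_raster(matrix(1L, 4, 4))
  expect_equal(degradation(lu_f, threats, sens), matrix(0, 4, 4))

  # zero sensitivity annihilates degradation regardless of threats
  sens0 <- sens
  sens0[c("s_urban", "s_unused", "s_paddy", "s_dry")] <- 0
  expect_equal(degradation(lu, threats, sens0), matrix(0, 1, 3))
})

test_that("habitat_quality obeys suitability bounds and the half-saturation rule", {
  sens <- es_sensitivity()
  lu <- toy_raster(c(1, 1, 1, 4), 2, 2)
  D <- matrix(c(0, 0.1, 0.2, 0.3), 2, 2)
  res <- habitat_quality(D, lu, sens)  # k = max(D)/2 = 0.15
  expect_equal(res$k, 0.15)
  expect_equal(res$quality[1, 1], 1)            # D = 0 -> Q = H
  # urban has H = 0 -> Q = 0 whatever D
  expect_equal(res$quality[2, 2], 0)
  # D = k -> Q = H/2 exactly
  res_k <- habitat_quality(matrix(0.15, 2, 2), lu, sens, k = 0.15)
  expect_equal(res_k$quality[1, 1], 0.5)

  # all-zero D without override degenerates to Q = H, with a message
  expect_message(res0 <- habitat_quality(matrix(0, 2, 2), lu, sens), "zero")
  expect_equal(res0$quality[1, 1], 1)
})

test_that("quality is bounded, monotone in D, and threats never raise Q", {
  threats <- es_threats(); sens <- es_sensitivity()
  lu <- generate_landuse(tiny_spec(n = 30, seed = 17))
  res <- habitat_model(lu, threats, sens)
  Q <- raster_values(res$quality)
  H <- sens$suitability[match(es_classes()$class[as.vector(lu)], sens$class)]
  expect_true(all(Q >= -1e-12))
  expect_true(all(Q <= H + 1e-12))
  # monotone: inflating D (same k) can only lower Q
  D <- raster_values(res$degradation)
  res_hi <- habitat_quality(D * 1.5, lu, sens, k = res$k)
  expect_true(all(raster_values(res_hi$quality) <= Q + 1e-12))
  # adding threat cells never increases any cell's Q (fixed k)
  lu2 <- raster_values(lu); lu2[lu2 == 2] <- 4L  # grassland -> urban
  lu2 <- es_raster(lu2)
  res2 <- habitat_quality(degradation(lu2, threats, sens), lu2, sens, k = res$k)
  expect_true(all(raster_values(res2$quality) <= Q + 1e-12))
})

test_that("regional mean quality agrees with the class-weighted mean on homogeneous toys", {
  sens <- es_sensitivity()
  # two homogeneous half-domains, no threats -> Q = H per class
  lu <- es_raster(cbind(matrix(1L, 4, 2), matrix(2L, 4, 2)))
  res <- habitat_model(lu, sens = sens)
  a <- class_areas(lu)
  w_mean <- sum(a$area_km2 * sens$suitability[match(a$class, sens$class)]) /
    sum(a$area_km2)
  expect_equal(res$mean_quality, w_mean)
})
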