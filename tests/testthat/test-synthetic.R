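test_that("generate_landuse honours proportions, autocorrelation and determinism", {
  # degenerate single-class request
  spec1 <- tiny_spec(n = 10, class_proportions = c(dry = 1))
  lu1 <- generate_landuse(spec1)
  expect_true(all(lu1 == class_codes("dry")))

  # mixed request close to the realised shares, and patchiness
  props <- c(dry = 0.512, paddy = 0.205, urban = 0.165, forest = 0.097,
             water = 0.021)
  spec <- landscape_spec(grid_rows = 200, grid_cols = 200,
                         class_proportions = props, seed = 5)
  lu <- generate_landuse(spec)
  realized <- table(factor(as.vector(lu), levels = class_codes(names(props)))) /
    length(lu)
  expect_true(all(abs(as.numeric(realized) - props) <= 0.02))
  for (cl in c("dry", "urban")) {
    expect_gt(morans_i((raster_values(lu) == class_codes(cl)) * 1), 0)
  }

  # determinism: same spec, same seed -> bit-identical grids
  expect_identical(raster_values(generate_landuse(spec)),
                   raster_values(generate_landuse(spec)))
})

test_that("landscape_spec rejects invalid requests", {
  expect_error(tiny_spec(class_proportions = c(dry = 0.6, paddy = 0.5)),
               "sum to 1")
  expect_error(tiny_spec(class_proportions = c(swamp = 1)), "unknown")
  expect_error(landscape_spec(grid_rows = 0), "positive")
  expect_error(landscape_spec(n_regions = 1e6), "n_regions")
})

test_that("advance_landuse converts exact counts, prefers adjacency, conserves cells", {
  spec <- tiny_spec(n = 40, seed = 3,
                    class_proportions = c(paddy = 0.625, urban = 0.375))
  lu <- generate_landuse(spec)
  n_paddy <- sum(lu == class_codes("paddy"))
  rules <- list(list(from = "paddy", to = "urban", fraction = 0.05))
  lu2 <- advance_landuse(lu, rules, seed = 4)

  # exact count, nothing else touched, total conserved
  changed <- which(raster_values(lu) != raster_values(lu2))
  expect_length(changed, round(0.05 * n_paddy))
  expect_true(all(lu[changed] == class_codes("paddy")))
  expect_true(all(lu2[changed] == class_codes("urban")))
  expect_identical(length(lu), length(lu2))

  # converted cells hug existing urban patches more than average paddy cells do
  adj <- neighbour_count(raster_values(lu), class_codes("urban"))
  expect_gt(mean(adj[changed]), mean(adj[lu == class_codes("paddy")]))

  # empty rule list is the identity
  expect_identical(raster_values(advance_landuse(lu, list(), seed = 1)),
                   raster_values(lu))
})

test_that("advance_landuse feeds a consistent transfer matrix", {
  spec <- tiny_spec(n = 30, seed = 8)
  lu <- generate_landuse(spec)
  lu2 <- advance_landuse(lu, spec$change_rules, seed = 9)
  tm <- transfer_matrix(lu, lu2)
  off_diag <- sum(tm$matrix) - sum(diag(tm$matrix))
  n_changed <- sum(raster_values(lu) != raster_values(lu2))
  expect_equal(off_diag, n_changed * cell_area_km2(lu))
})

test_that("generate_climate hits the stated mean, gradient and monthly closure", {
  spec <- tiny_spec(n = 50, seed = 21)
  cl <- generate_climate(spec)
  # domain mean within 1% of 992.9 mm (it is exact by construction)
  expect_lt(abs(mean(cl$annual_precip) - 992.9), 0.01 * 992.9)
  # row means increase monotonically to the south
  expect_true(all(diff(rowMeans(cl$annual_precip)) > 0))
  # monthly layers close to the annual total cell by cell
  msum <- Reduce(`+`, lapply(cl$monthly_precip, raster_values))
  expect_lt(max(abs(msum - raster_values(cl$annual_precip))), 1e-6)
  expect_true(all(raster_values(cl$pet) >= 0))

  # zero gradient and zero noise -> constant field
  cl0 <- generate_climate(tiny_spec(n = 10, precip_gradient_mm_per_km = 0,
                                    precip_noise_sd = 0))
  expect_true(all(abs(cl0$annual_precip - 992.9) < 1e-9))
})

test_that("generate_soil_terrain respects range invariants", {
  st <- generate_soil_terrain(tiny_spec(n = 30))
  expect_true(all(st$K >= 0))
  expect_true(all(st$LS >= 0))
  expect_true(all(st$PAWC >= 0 & st$PAWC <= 1))
})

test_that("generate_regions tessellates the grid into contiguous regions", {
  spec <- tiny_spec(n = 50, seed = 13)
  rg <- generate_regions(spec)
  ids <- sort(unique(as.vector(rg)))
  expect_identical(ids, 1:29)
  expect_false(anyNA(rg))
  # contiguity: flood fill from one member cell reaches the whole region
  m <- raster_values(rg)
  for (id in sample(ids, 5)) {
    mask <- m == id
    reached <- matrix(FALSE, nrow(m), ncol(m))
    start <- which(mask)[1]
    reached[start] <- TRUE
    repeat {
      grown <- reached
      grown[-1, ] <- grown[-1, ] | reached[-nrow(m), ]
      grown[-nrow(m), ] <- grown[-nrow(m), ] | reached[-1, ]
      grown[, -1] <- grown[, -1] | reached[, -ncol(m)]
      grown[, -ncol(m)] <- grown[, -ncol(m)] | reached[, -1]
      grown <- grown & mask
      if (identical(grown, reached)) break
      reached <- grown
    }
    expect_identical(sum(reached), sum(mask))
  }
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(42); before <- .Random.seed
  invisible(generate_landuse(tiny_spec(n = 10)))
  invisible(generate_regions(tiny_spec(n = 10)))
  expect_identical(before, .Random.seed)
})
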