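# independent oracle: average R2 increments over all k! predictor-entry orders
hp_oracle <- function(y, X) {
  X <- as.data.frame(X)
  k <- ncol(X)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), , drop = FALSE]
  I <- numeric(k)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    prev <- 0
    for (pos in seq_len(k)) {
      cur <- ols_r2(y, X[, ord[seq_len(pos)], drop = FALSE])
      I[ord[pos]] <- I[ord[pos]] + (cur - prev)
      prev <- cur
    }
  }
  I / nrow(perms)
}

test_that("ols_r2 agrees with lm and behaves at the extremes", {
  withr::with_seed(51, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- X %*% c(1, -2, 0.5) + rnorm(40)
  })
  expect_equal(ols_r2(y, X), summary(lm(y ~ X))$r.squared)
  # exact linear dependence -> 1
  expect_equal(ols_r2(X %*% c(1, 1, 1), X), 1)
  # pure noise, large n -> near 0
  withr::with_seed(52, {
    yn <- rnorm(2000); Xn <- matrix(rnorm(2000 * 2), ncol = 2)
  })
  expect_lt(ols_r2(yn, Xn), 0.05)
  # single centred predictor: R2 = r^2
  expect_equal(ols_r2(y, X[, 1, drop = FALSE]), pearson(as.numeric(y), X[, 1])$r^2)
  expect_equal(ols_r2(y, X[, 0, drop = FALSE]), 0)
})

test_that("hierarchical partitioning matches the exhaustive order-averaging oracle", {
  for (k in 2:4) {
    withr::with_seed(60 + k, {
      X <- as.data.frame(matrix(rnorm(35 * k), 35, k))
      y <- rowSums(X[, seq_len(min(2, k)), drop = FALSE]) + rnorm(35, sd = 0.5)
    })
    hp <- hierarchical_partition(y, X)
    expect_equal(unname(hp$I), hp_oracle(y, X), tolerance = 1e-10)
    expect_equal(sum(hp$I), hp$r2_full, tolerance = 1e-8)
    expect_equal(sum(hp$pct_I), 100, tolerance = 1e-6)
  }
})

test_that("hierarchical partitioning degenerate and orthogonal cases", {
  withr::with_seed(65, {
    x1 <- rnorm(50); y <- 2 * x1 + rnorm(50)
  })
  hp1 <- hierarchical_partition(y, data.frame(x1 = x1))
  expect_equal(unname(hp1$I[1]), ols_r2(y, cbind(x1)))
  expect_equal(unname(hp1$J[1]), 0)

  # exactly orthogonal predictors: I_j = r_j^2, J_j = 0
  n <- 40
  b1 <- rep(c(1, -1), n / 2); b2 <- rep(c(1, 1, -1, -1), n / 4)
  stopifnot(sum(b1 * b2) == 0)
  withr::with_seed(66, y2 <- 0.7 * b1 + 0.3 * b2 + rnorm(n))
  # centre so orthogonality survives the intercept
  hp2 <- hierarchical_partition(y2, data.frame(a = b1, b = b2))
  expect_equal(unname(hp2$I),
               c(pearson(y2, b1)$r^2, pearson(y2, b2)$r^2),
               tolerance = 1e-10)
  expect_equal(unname(hp2$J), c(0, 0), tolerance = 1e-10)
  expect_error(hierarchical_partition(y2, matrix(0, 40, 13)), "too large")
})

test_that("stepwise recovers an exact single driver and guards collinearity", {
  withr::with_seed(70, X <- as.data.frame(matrix(rnorm(29 * 5), 29, 5)))
  names(X) <- paste0("x", 1:5)
  y <- 2 * X$x1
  res <- stepwise(y, X)
  expect_identical(res$selected, "x1")
  expect_equal(unname(res$coefficients["x1"]), 2)
  expect_equal(res$r2, 1)

  # duplicate predictor columns: exactly one enters
  Xd <- cbind(X, x1_dup = X$x1)
  resd <- stepwise(y + rnorm(29, sd = 1e-6), Xd)
  expect_length(intersect(resd$selected, c("x1", "x1_dup")), 1)

  expect_error(stepwise(y, X, alpha_in = 0.2, alpha_out = 0.1), "alpha_in")
})

test_that("stepwise type-I behaviour is calibrated to the entry threshold", {
  # single noise candidate: entry rate is the nominal alpha, so the
  # intercept-only model survives ~95% of replicates
  keep1 <- vapply(seq_len(400), function(i) {
    withr::with_seed(2000 + i, {
      y <- rnorm(29)
      X <- data.frame(x1 = rnorm(29))
    })
    length(stepwise(y, X)$selected) == 0
  }, TRUE)
  expect_gte(mean(keep1), 0.90)

  # seven noise candidates: best-of-7 selection inflates entry to
  # ~ 1 - 0.95^7 = 0.30, the known family-wise cost of p-value stepwise
  keep7 <- vapply(seq_len(400), function(i) {
    withr::with_seed(3000 + i, {
      y <- rnorm(29)
      X <- as.data.frame(matrix(rnorm(29 * 7), 29, 7))
    })
    length(stepwise(y, X)$selected) == 0
  }, TRUE)
  expect_gt(mean(keep7), 0.95^7 - 0.08)
  expect_lt(mean(keep7), 0.95^7 + 0.08)
})

test_that("stepwise recovers planted drivers in a region-year panel at high SNR", {
  # 29 regions x 4 years = 116 rows; service linear in two proportions
  withr::with_seed(80, {
    P <- matrix(runif(116 * 7), 116, 7)
    P <- P / rowSums(P)
    colnames(P) <- paste0("p_", es_class_names())
    signal <- 40 * P[, "p_forest"] - 25 * P[, "p_urban"]
    noise_sd <- sd(signal) / 5  # SNR = 5
    y <- 10 + signal + rnorm(116, sd = noise_sd)
  })
  res <- stepwise(y, as.data.frame(P))
  expect_true(all(c("p_forest", "p_urban") %in% res$selected))
  expect_lt(abs(res$coefficients[["p_forest"]] - 40) / 40, 0.10)
  expect_lt(abs(res$coefficients[["p_urban"]] + 25) / 25, 0.10)
})

test_that("driver_table attributes planted single drivers to the right class", {
  withr::with_seed(90, {
    years <- c(1990, 2000)
    rows <- expand.grid(region = 1:29, year = years)
    P <- matrix(runif(nrow(rows) * 7), ncol = 7)
    P <- P / rowSums(P)
    colnames(P) <- paste0("p_", es_class_names())
    props <- cbind(rows, as.data.frame(P))
    panel <- rows
    panel$area_km2 <- 100
    # carbon driven purely by forest share; food purely by paddy share
    panel$carbon_per_km2 <- 500 * P[, "p_forest"]
    panel$habitat <- 0.5 * P[, "p_forest"] + 0.01 * rnorm(nrow(rows))
    panel$water_yield_mm <- runif(nrow(rows))
    panel$erosion_per_km2 <- runif(nrow(rows))
    panel$food_material_per_km2 <- 18.82 + 10 * P[, "p_paddy"]
  })
  dt <- driver_table(panel, props, years = years)
  expect_gt(dt$contributions["forest", "carbon"], 60)
  expect_equal(rownames(dt$contributions)[which.max(dt$contributions$food_material)],
               "paddy")
  # averaging a single year equals that year's shares
  dt1 <- driver_table(panel, props, years = 1990, pooled = FALSE)
  expect_equal(as.matrix(dt1$contributions),
               dt1$contributions_by_year[["1990"]], ignore_attr = TRUE)
  # stepwise equation per service per year is emitted
  expect_named(dt$equations$carbon, as.character(years))
  expect_true("p_forest" %in% dt$equations$carbon[["1990"]]$selected)
})
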