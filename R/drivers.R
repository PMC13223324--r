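#' Coefficient of determination of an OLS fit
#'
#' R-squared of the least-squares fit of `y` on `X` with an intercept.
#' Rank-deficient design matrices are handled by pivoted QR (the fit on the
#' identified subspace), as standard regression software does.
#'
#' @param y Response vector.
#' @param X Predictor matrix or data.frame (0 columns allowed: returns 0,
#'   the intercept-only fit).
#' @return R-squared in `[0, 1]`.
#' @export
ols_r2 <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("y and X have different numbers of rows")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response has zero variance")
  if (ncol(X) == 0) return(0)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  rss <- sum(fit$residuals^2)
  1 - rss / tss
}

#' Hierarchical partitioning of R-squared
#'
#' Decomposes the full-model goodness of fit over `k` predictors into each
#' predictor's independent contribution `I_j` — the average, over all
#' hierarchy levels, of the R-squared increment from adding predictor `j` to
#' a subset not containing it, with subsets weighted so that the average
#' equals the mean over all `k!` orders of predictor entry (the Shapley
#' decomposition) — and its joint contribution `J_j = R2({j}) - I_j`.
#' The `I_j` sum exactly to the full-model R-squared. Negative `I_j`
#' (suppression) are reported, not clipped, and percentage shares are taken
#' of `sum(I)`.
#'
#' @param y Response vector.
#' @param X Predictor matrix or data.frame, `1 <= ncol(X) <= 12` (all
#'   `2^k - 1` subsets are fitted).
#' @param gof Goodness-of-fit function `f(y, X_subset)`; default [ols_r2()].
#' @return A list of class `hp_result`: `I`, `J`, `pct_I` (named by
#'   predictor), `r2_full`, `gof_subsets` (named by comma-joined predictor
#'   indices).
#' @export
hierarchical_partition <- function(y, X, gof = ols_r2) {
  X <- as.data.frame(X)
  k <- ncol(X)
  if (k < 1) stop("need at least one predictor")
  if (k > 12) {
    stop("hierarchical partitioning fits 2^k subsets; k = ", k,
         " is too large (max 12). Reduce or group predictors.")
  }
  nms <- names(X)
  nsub <- bitwShiftL(1L, k)
  g <- numeric(nsub)  # g[mask + 1] = gof of that predictor subset
  g[1] <- 0
  for (mask in seq_len(nsub - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    g[mask + 1] <- gof(y, X[, idx, drop = FALSE])
  }
  # Shapley weights by subset size
  wt <- vapply(0:(k - 1), function(s) {
    exp(lgamma(s + 1) + lgamma(k - s) - lgamma(k + 1))
  }, 0)
  I <- numeric(k)
  sizes <- vapply(0:(nsub - 1), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L), 0L)
  for (j in seq_len(k)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(nsub - 1), bit) == 0L) - 1L  # masks not containing j
    inc <- g[bitwOr(without, bit) + 1] - g[without + 1]
    I[j] <- sum(wt[sizes[without + 1] + 1] * inc)
  }
  single <- g[bitwShiftL(1L, seq_len(k) - 1L) + 1]
  J <- single - I
  structure(list(
    I = stats::setNames(I, nms),
    J = stats::setNames(J, nms),
    pct_I = stats::setNames(100 * I / sum(I), nms),
    r2_full = g[nsub],
    gof_subsets = g[-1]
  ), class = "hp_result")
}

#' Bidirectional stepwise regression by p-value
#'
#' SPSS-style stepwise selection: repeatedly add the excluded predictor with
#' the smallest coefficient p-value below `alpha_in`, then drop any included
#' predictor whose p-value exceeds `alpha_out`, until the model is stable.
#' Ties break on the smaller p, then on predictor order. Candidates that are
#' collinear with the current model (aliased coefficient) are skipped, so
#' duplicate predictors can never both enter. With `alpha_in <= alpha_out`
#' the procedure cannot cycle; a 100-cycle guard enforces this.
#'
#' @param y Response vector.
#' @param X Predictor matrix or data.frame with column names.
#' @param alpha_in Entry threshold (default 0.05).
#' @param alpha_out Removal threshold (default 0.10), must be `>= alpha_in`.
#' @return A list of class `stepwise_result`: `selected` (character),
#'   `coefficients` (including `(Intercept)`), `r2`, `p_overall` (model
#'   F-test; `NA` for the intercept-only model), `n`, `trace` (character log
#'   of add/drop steps).
#' @export
stepwise <- function(y, X, alpha_in = 0.05, alpha_out = 0.10) {
  if (alpha_in > alpha_out) stop("alpha_in must be <= alpha_out")
  X <- as.data.frame(X)
  if (is.null(names(X))) names(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  nms <- names(X)
  included <- character(0)
  trace <- character(0)
  for (cycle in seq_len(100)) {
    changed <- FALSE
    # forward step
    excluded <- setdiff(nms, included)
    if (length(excluded)) {
      cand_p <- rep(NA_real_, length(excluded))
      for (i in seq_along(excluded)) {
        vars <- c(included, excluded[i])
        dat <- cbind(data.frame(.y = y), X[vars])
        fit <- stats::lm(.y ~ ., data = dat)
        cf <- stats::coef(fit)
        nm <- make.names(excluded[i])
        if (is.na(cf[nm])) next  # aliased with current model
        sm <- suppressWarnings(summary(fit))$coefficients
        if (nm %in% rownames(sm)) cand_p[i] <- sm[nm, "Pr(>|t|)"]
      }
      if (any(!is.na(cand_p)) && min(cand_p, na.rm = TRUE) < alpha_in) {
        best <- which.min(cand_p)  # smallest p, first index on ties
        included <- c(included, excluded[best])
        trace <- c(trace, sprintf("add %s (p = %.4g)", excluded[best], cand_p[best]))
        changed <- TRUE
      }
    }
    # backward step(s)
    repeat {
      if (!length(included)) break
      dat <- cbind(data.frame(.y = y), X[included])
      fit <- stats::lm(.y ~ ., data = dat)
      sm <- suppressWarnings(summary(fit))$coefficients
      rows <- make.names(included)
      pv <- stats::setNames(rep(NA_real_, length(included)), included)
      hit <- rows %in% rownames(sm)
      pv[hit] <- sm[rows[hit], "Pr(>|t|)"]
      worst <- which.max(pv)  # NA (aliased) never selected by which.max
      if (length(worst) && !is.na(pv[worst]) && pv[worst] > alpha_out) {
        trace <- c(trace, sprintf("drop %s (p = %.4g)", included[worst], pv[worst]))
        included <- included[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
    if (cycle == 100) stop("stepwise selection did not converge in 100 cycles")
  }
  # final fit
  if (length(included)) {
    dat <- cbind(data.frame(.y = y), X[included])
    fit <- stats::lm(.y ~ ., data = dat)
    sm <- suppressWarnings(summary(fit))
    fs <- sm$fstatistic
    p_overall <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    cf <- stats::coef(fit)
    names(cf) <- c("(Intercept)", included)
    r2 <- sm$r.squared
  } else {
    cf <- c(`(Intercept)` = mean(y))
    p_overall <- NA_real_
    r2 <- 0
  }
  structure(list(selected = included, coefficients = cf, r2 = r2,
                 p_overall = unname(p_overall), n = length(y), trace = trace),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (length(x$selected)) {
    terms <- sprintf("%+.4g %s", x$coefficients[-1], x$selected)
    cat(sprintf("y = %.4g %s\n", x$coefficients[1], paste(terms, collapse = " ")))
  } else {
    cat(sprintf("y = %.4g (intercept only)\n", x$coefficients[1]))
  }
  cat(sprintf("R2 = %.3g, overall p = %.3g, n = %d\n", x$r2, x$p_overall, x$n))
  invisible(x)
}

#' Land-use driver attribution tables
#'
#' For each per-unit-area service: (a) hierarchical partitioning of
#' R-squared over the seven class-proportion predictors, run per year with
#' percentage contributions averaged across years (and optionally pooled
#' over all region-years), and (b) a stepwise regression equation per year.
#'
#' @param panel A [zonal_totals()]-style panel stacked over years.
#' @param proportions A [landuse_proportions()]-style table stacked over the
#'   same years.
#' @param years Years to analyse (default: all years in the panel).
#' @param services Named vector mapping service name to panel column
#'   (default: the five per-unit-area columns).
#' @param pooled Also run HP pooled over all region-years (default TRUE).
#' @param alpha_in,alpha_out Stepwise thresholds, see [stepwise()].
#' @return A list of class `driver_result`: `contributions` (data.frame of
#'   average %I by predictor x service), `contributions_by_year`,
#'   `contributions_pooled` (or NULL), `equations` (nested list
#'   service -> year -> `stepwise_result`).
#' @export
driver_table <- function(panel, proportions, years = sort(unique(panel$year)),
                         services = panel_service_cols(per_unit = TRUE),
                         pooled = TRUE, alpha_in = 0.05, alpha_out = 0.10) {
  pcols <- paste0("p_", es_classes()$class)
  miss <- setdiff(unname(services), names(panel))
  if (length(miss)) stop("panel lacks service column(s): ", paste(miss, collapse = ", "))
  merge_year <- function(y) {
    rows <- panel[panel$year == y, , drop = FALSE]
    pr <- proportions[proportions$year == y, , drop = FALSE]
    if (!nrow(rows) || !nrow(pr)) stop("year not present in panel/proportions: ", y)
    pr <- pr[match(rows$region, pr$region), , drop = FALSE]
    cbind(rows, pr[pcols])
  }
  by_year <- list(); equations <- list()
  for (sv in names(services)) equations[[sv]] <- list()
  for (y in years) {
    dat <- merge_year(y)
    X <- dat[pcols]
    pct <- sapply(names(services), function(sv) {
      hierarchical_partition(dat[[services[[sv]]]], X)$pct_I
    })
    rownames(pct) <- es_classes()$class
    by_year[[as.character(y)]] <- pct
    for (sv in names(services)) {
      equations[[sv]][[as.character(y)]] <-
        stepwise(dat[[services[[sv]]]], X, alpha_in, alpha_out)
    }
  }
  avg <- Reduce(`+`, by_year) / length(by_year)
  pooled_tab <- NULL
  if (pooled) {
    dat <- do.call(rbind, lapply(years, merge_year))
    X <- dat[pcols]
    pooled_tab <- sapply(names(services), function(sv) {
      hierarchical_partition(dat[[services[[sv]]]], X)$pct_I
    })
    rownames(pooled_tab) <- es_classes()$class
  }
  structure(list(
    contributions = as.data.frame(avg),
    contributions_by_year = by_year,
    contributions_pooled = if (is.null(pooled_tab)) NULL else as.data.frame(pooled_tab),
    equations = equations
  ), class = "driver_result")
}
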