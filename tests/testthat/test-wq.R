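test_that("response transforms: natural log everywhere, pH to the fourth", {
  expect_equal(transform_response(exp(1), "DOC"), 1)
  expect_equal(transform_response(2, "pH"), 16)
  expect_equal(transform_response(c(1, 10), "TSS"), c(0, log(10)))
  expect_error(transform_response(c(3, 0, 2), "DOC"), "rows 2")
  # pH is exempt from the positivity precondition
  expect_silent(transform_response(c(7, 0), "pH"))
})

test_that("censored-row removal applies only to TSS, Al and NO3", {
  d <- data.frame(Al = c(0, 1, 2, 0, 5), x = 1:5)
  r <- drop_censored(d, "Al")
  expect_equal(r$n_removed, 2)
  expect_equal(r$data$Al, c(1, 2, 5))
  expect_equal(r$removed_rows, c(1, 4))
  # declared detection limit is removed too
  r <- drop_censored(d, "Al", detection_limits = 5)
  expect_equal(r$n_removed, 3)
  # other constituents pass through untouched (zeros fail at transform)
  d2 <- data.frame(DOC = c(0, 1))
  expect_equal(drop_censored(d2, "DOC")$n_removed, 0)
  # kept rows equal a brute-force filter on synthetic censored data
  set.seed(91)
  v <- round(rexp(200), 1); v[sample(200, 30)] <- 0
  d3 <- data.frame(TSS = v)
  r3 <- drop_censored(d3, "TSS", detection_limits = 0.1)
  expect_equal(r3$data$TSS, v[!(v == 0 | v == 0.1)])
})

test_that("standardization is exact, idempotent and ledgered", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40))
  s <- standardize_columns(d, c("a", "b"))
  expect_equal(mean(s$data$a), 0, tolerance = 1e-12)
  expect_equal(sd(s$data$a), 1, tolerance = 1e-12)
  expect_equal(s$ledger$mean, c(2, 70 / 3))
  s2 <- standardize_columns(s$data, c("a", "b"))
  expect_equal(s2$data$a, s$data$a, tolerance = 1e-10)
  expect_error(standardize_columns(data.frame(a = rep(1, 5)), "a"), "constant")
})

test_that("VIF matches the 1/(1-R^2) definition and flags collinearity", {
  # orthogonal predictors -> both exactly 1
  X <- data.frame(x1 = c(1, 1, -1, -1), x2 = c(1, -1, 1, -1))
  v <- vif_screen(X)
  expect_equal(v$vif, c(1, 1))
  expect_false(attr(v, "flagged"))
  # duplicated predictor -> singularity error
  expect_error(vif_screen(data.frame(x1 = 1:5, x2 = 1:5)), "collinear")
  # random correlated design matches an independent normal-equations fit
  set.seed(92)
  for (i in 1:10) {
    n <- 60
    x1 <- rnorm(n); x2 <- 0.7 * x1 + rnorm(n, 0, 0.5); x3 <- rnorm(n)
    X <- cbind(x1 = x1, x2 = x2, x3 = x3)
    v <- vif_screen(X)
    for (j in 1:3) {
      A <- cbind(1, X[, -j]); y <- X[, j]
      beta <- solve(t(A) %*% A, t(A) %*% y)
      r2 <- 1 - sum((y - A %*% beta)^2) / sum((y - mean(y))^2)
      expect_equal(v$vif[j], 1 / (1 - r2), tolerance = 1e-8)
    }
    expect_true(attr(vif_screen(cbind(x1, x2 = 0.99 * x1 + rnorm(n, 0, 0.05))),
                     "flagged"))
  }
})

test_that("the noiseless simulator limit recovers slopes exactly", {
  d <- simulate_wq(n = 200, n_regions = 4, sd_intercept = 0, sd_slope = 0,
                   sd_resid = 0, seed = 5)
  spec <- wq_model_spec("y")
  fit <- fit_mixed(spec, d, random = character(0))   # degenerate: plain OLS
  # summary.lm warns about the (intentionally) perfect fit
  sl <- suppressWarnings(extract_slopes(fit))
  expect_equal(sl$mean_slope, unname(attr(d, "truth")$slopes),
               tolerance = 1e-8)
  expect_false(any(sl$had_random_component))
})

test_that("single-region mixed data reduces to the OLS estimates", {
  set.seed(6)
  d <- simulate_wq(n = 300, n_regions = 2, sd_intercept = 0, sd_slope = 0,
                   sd_resid = 0.5, seed = 6)
  d$region <- factor(rep(1, nrow(d)))
  spec <- wq_model_spec("y")
  ls <- extract_slopes(fit_mixed(spec, d, random = character(0)))
  mx <- extract_slopes(suppressWarnings(
    fit_mixed(spec, d, random = "(Intercept)")))
  expect_equal(mx$mean_slope, ls$mean_slope, tolerance = 1e-3)
})

test_that("simulated response variance matches the generating model", {
  d <- simulate_wq(n = 4000, n_regions = 8, sd_intercept = 0.3,
                   sd_slope = 0.1, sd_resid = 0.7, seed = 7)
  tr <- attr(d, "truth")
  want <- sum(tr$slopes^2) + tr$sd_intercept^2 +
    length(tr$slopes) * tr$sd_slope^2 + tr$sd_resid^2
  expect_equal(var(d$y), want, tolerance = 0.15)
  expect_identical(d$y, simulate_wq(n = 4000, n_regions = 8,
                                    sd_intercept = 0.3, sd_slope = 0.1,
                                    sd_resid = 0.7, seed = 7)$y)
})

test_that("estimated random-slope variance is near zero when truly zero", {
  d <- simulate_wq(n = 800, n_regions = 8, sd_intercept = 0.4, sd_slope = 0,
                   sd_resid = 0.6, seed = 8)
  spec <- wq_model_spec("y")
  fit <- suppressWarnings(
    fit_mixed(spec, d, random = c("(Intercept)", "pct_Riparian")))
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  slope_sd <- vc$sdcor[vc$var1 == "pct_Riparian" & !is.na(vc$var1)]
  expect_lt(slope_sd, 0.05)
})

test_that("backward selection drops a null covariate but never a class term", {
  set.seed(9)
  d <- simulate_wq(covariate_slopes = c(cov_real = 0.3, cov_null = 0),
                   n = 600, n_regions = 6, sd_intercept = 0.3,
                   sd_slope = 0.03, sd_resid = 0.7, seed = 9)
  spec <- wq_model_spec("y", covariates = c("cov_real", "cov_null"))
  sel <- suppressWarnings(backward_select(spec, d))
  expect_false("cov_null" %in% sel$spec$covariates)
  expect_true("cov_real" %in% sel$spec$covariates)
  expect_true(all(spec$classes %in% sel$spec$classes))
  sl <- extract_slopes(sel)
  expect_equal(sl$class, spec$classes)
  expect_true(all(c("phase", "p_value", "action") %in% names(sel$trace)))
  # a class slope of truly zero is still present in the final model
  d0 <- simulate_wq(slopes = c(pct_Riparian = 0, pct_NRShw = 0.3,
                               pct_NRMid = 0.2, pct_NRDeep = -0.2),
                    n = 500, n_regions = 5, sd_slope = 0.03, seed = 10)
  sel0 <- suppressWarnings(backward_select(wq_model_spec("y"), d0))
  expect_true("pct_Riparian" %in% extract_slopes(sel0)$class)
})

test_that("selection with no removable terms keeps the maximal fixed set", {
  set.seed(12)
  d <- simulate_wq(covariate_slopes = c(cov_strong = 0.8), n = 500,
                   n_regions = 5, sd_intercept = 0.5, sd_slope = 0.02,
                   sd_resid = 0.4, seed = 12)
  spec <- wq_model_spec("y", covariates = "cov_strong")
  sel <- suppressWarnings(backward_select(spec, d))
  expect_true("cov_strong" %in% sel$spec$covariates)
})

test_that("AIC picks the true grouping over shuffled labels", {
  set.seed(13)
  d <- simulate_wq(n = 600, n_regions = 6, sd_intercept = 0.8,
                   sd_slope = 0.05, sd_resid = 0.5, seed = 13)
  d$shuffled <- sample(d$region)
  spec <- wq_model_spec("y", random = "(Intercept)")
  res <- suppressWarnings(select_grouping(spec, d, c("region", "shuffled")))
  expect_equal(res$grouping, "region")
  expect_equal(nrow(res$aic), 2)
  # single candidate returned trivially
  expect_equal(suppressWarnings(select_grouping(spec, d, "region"))$grouping,
               "region")
})

test_that("slope significance follows the two-standard-error rule", {
  d <- simulate_wq(n = 400, n_regions = 4, sd_slope = 0, seed = 14)
  fit <- suppressWarnings(fit_mixed(wq_model_spec("y"), d,
                                    random = "(Intercept)"))
  sl <- extract_slopes(fit)
  expect_equal(sl$significant, abs(sl$mean_slope) > 2 * sl$se)
  # 0.1 +/- 2*0.06 overlaps zero -> not significant (rule arithmetic)
  expect_false(abs(0.1) > 2 * 0.06)
})

test_that("standardized slopes are invariant to raw predictor rescaling", {
  set.seed(15)
  d <- simulate_wq(n = 300, n_regions = 3, sd_slope = 0, seed = 15)
  raw <- data.frame(y = d$y, region = d$region)
  for (nm in names(attr(d, "truth")$slopes)) raw[[nm]] <- d[[paste0("raw_", nm)]]
  spec <- wq_model_spec("y", random = "(Intercept)")
  s1 <- standardize_columns(raw, spec$classes)$data
  raw2 <- raw
  raw2$pct_Riparian <- raw2$pct_Riparian * 1000   # change of units
  s2 <- standardize_columns(raw2, spec$classes)$data
  f1 <- suppressWarnings(fit_mixed(spec, s1))
  f2 <- suppressWarnings(fit_mixed(spec, s2))
  expect_equal(extract_slopes(f1)$mean_slope, extract_slopes(f2)$mean_slope,
               tolerance = 1e-8)
})

test_that("prepare_wq enforces and logs the pipeline order", {
  set.seed(16)
  n <- 120
  d <- data.frame(TSS = c(rexp(n - 10) + 0.1, rep(0, 10)),
                  pct_Riparian = runif(n, 0, 40),
                  pct_NRShw = runif(n, 0, 10),
                  pct_NRMid = runif(n, 0, 10),
                  pct_NRDeep = runif(n, 0, 10),
                  region = factor(rep(1:4, length.out = n)))
  spec <- wq_model_spec("TSS")
  p <- prepare_wq(d, spec)
  expect_equal(nrow(p), n - 10)
  log <- attr(p, "prep_log")
  expect_match(log[1], "drop_censored")
  expect_match(log[2], "transform")
  expect_match(log[3], "standardize")
  expect_equal(mean(p$TSS), 0, tolerance = 1e-10)
  expect_equal(sd(p$pct_Riparian), 1, tolerance = 1e-10)
  expect_s3_class(attr(p, "standardization"), "data.frame")
})

test_that("selection cross-checks against the reference stepwise eliminator", {
  set.seed(17)
  d <- simulate_wq(covariate_slopes = c(cov_real = 0.4, cov_null = 0),
                   n = 800, n_regions = 8, sd_intercept = 0.4,
                   sd_slope = 0, sd_resid = 0.6, seed = 17)
  spec <- wq_model_spec("y", covariates = c("cov_real", "cov_null"))
  sel <- suppressWarnings(backward_select(spec, d))
  # independent route: lmerTest::step with the class terms forced.
  # lmerTest re-evaluates the model call, so the data must be findable from
  # the global environment.
  assign(".wq_xcheck_data", d, envir = globalenv())
  withr::defer(rm(".wq_xcheck_data", envir = globalenv()))
  full <- lmerTest::lmer(
    y ~ pct_Riparian + pct_NRShw + pct_NRMid + pct_NRDeep + cov_real +
      cov_null + (1 | region), data = .wq_xcheck_data, REML = TRUE)
  st <- lmerTest::step(full, keep = c("pct_Riparian", "pct_NRShw",
                                      "pct_NRMid", "pct_NRDeep"))
  kept <- attr(stats::terms(lmerTest::get_model(st)), "term.labels")
  expect_equal("cov_real" %in% kept, "cov_real" %in% sel$spec$covariates)
  expect_equal("cov_null" %in% kept, "cov_null" %in% sel$spec$covariates)
})
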