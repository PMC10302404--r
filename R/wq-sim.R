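# Water-quality simulator for parameter-recovery testing: a standardized
# linear mixed model with region-varying intercepts and slopes, matching
# the form the assessment fits. Ground-truth parameters are stored on the
# result so recovery can be checked exactly.

#' Simulate a water-quality site table with known mixed-model parameters
#'
#' Class percentages are drawn with a realistic right skew (most watersheds
#' hold little wetland area, a few hold much) from a scaled Beta, then
#' standardized; the response is built on the standardized scale as
#' fixed linear predictor + region random intercept + region random slopes
#' + Gaussian residual. Random effects are drawn independently per term
#' (diagonal covariance), the same structure the fitting side uses.
#'
#' @param slopes Named numeric vector of true standardized class slopes, in
#'   class order (default names `pct_Riparian`, `pct_NRShw`, `pct_NRMid`,
#'   `pct_NRDeep`).
#' @param covariate_slopes Named numeric vector of true covariate slopes
#'   (may be empty); covariates are simulated standard normal.
#' @param n Number of sites (>= 50).
#' @param n_regions Number of regions (>= 2); sites are split evenly.
#' @param sd_intercept SD of region random intercepts.
#' @param sd_slope SD of region random slopes, applied to every class and
#'   covariate term.
#' @param sd_resid Residual SD.
#' @param seed Integer seed (sets the RNG).
#' @return `data.frame` with columns `y`, the class percentage columns
#'   (standardized; raw percentages kept as `raw_<name>`), covariates and
#'   `region`. True parameters are attached as attribute `"truth"`.
#' @export
simulate_wq <- function(slopes = c(pct_Riparian = 0.4, pct_NRShw = 0.2,
                                   pct_NRMid = 0.1, pct_NRDeep = -0.2),
                        covariate_slopes = numeric(0),
                        n = 1500, n_regions = 9,
                        sd_intercept = 0.3, sd_slope = 0.05, sd_resid = 0.7,
                        seed = 1) {
  stopifnot(n >= 50, n_regions >= 2)
  set.seed(seed)
  region <- factor(rep_len(seq_len(n_regions), n))
  preds <- list()
  for (nm in names(slopes)) {
    raw <- 100 * stats::rbeta(n, 0.8, 8)     # right-skewed percent cover
    preds[[nm]] <- as.numeric(scale(raw))
    preds[[paste0("raw_", nm)]] <- raw
  }
  for (nm in names(covariate_slopes)) preds[[nm]] <- stats::rnorm(n)
  data <- as.data.frame(preds)
  beta <- c(slopes, covariate_slopes)
  terms <- names(beta)
  u0 <- stats::rnorm(n_regions, 0, sd_intercept)
  u <- matrix(stats::rnorm(n_regions * length(terms), 0, sd_slope),
              n_regions, length(terms), dimnames = list(NULL, terms))
  g <- as.integer(region)
  y <- u0[g] + stats::rnorm(n, 0, sd_resid)
  for (t in terms) y <- y + (beta[[t]] + u[g, t]) * data[[t]]
  data$y <- y
  data$region <- region
  attr(data, "truth") <- list(slopes = slopes,
                              covariate_slopes = covariate_slopes,
                              sd_intercept = sd_intercept, sd_slope = sd_slope,
                              sd_resid = sd_resid)
  data
}
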