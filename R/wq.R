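# Standardized mixed-effects assessment linking watershed wetland-class
# percentages to stream water-quality constituents.
#
# Pipeline order (enforced by prepare_wq and logged): censored-row removal
# -> response/covariate transformation -> standardization -> VIF screen ->
# mixed-model fit -> backward selection -> slope extraction. Responses are
# natural-log transformed except pH, which is raised to the fourth power;
# predictors and responses are standardized to mean 0, SD 1 so slopes are
# comparable across constituents whose raw ranges differ by orders of
# magnitude. The four wetland-class fixed effects are retained in every
# model regardless of significance so their standardized population-mean
# slopes can always be extracted.

#' Water-quality constituents and their functional groups
#' @export
WQ_CONSTITUENTS <- c(cond = "acidification", Ca = "acidification",
                     Mg = "acidification", Al = "acidification",
                     pH = "acidification", ANC = "acidification",
                     DOC = "brownification", colour = "brownification",
                     NO3 = "eutrophication", turb = "sedimentation",
                     TSS = "sedimentation")

# constituents whose residual diagnostics show censoring stripes (zeros /
# detection limits) and therefore get censored-row removal
.censored_constituents <- c("TSS", "Al", "NO3")

#' Transform a response variable
#'
#' Natural log for every constituent except pH, which is raised to the
#' fourth power (pH is already a log scale; the quartic meets residual
#' normality instead). Nonpositive values on the log branch are an error
#' identifying the offending rows — censored values must be removed first.
#'
#' @param values Numeric vector.
#' @param constituent Constituent name (see [WQ_CONSTITUENTS]).
#' @return Transformed numeric vector.
#' @export
transform_response <- function(values, constituent) {
  if (constituent == "pH") return(values^4)
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad) > 0)
    stop(sprintf("cannot log-transform %s: nonpositive values at rows %s",
                 constituent, paste(utils::head(bad, 10), collapse = ", ")))
  log(values)
}

#' Remove censored observations
#'
#' Drops rows at zero or at a declared detection-limit value. Applies only
#' to the constituents whose residual plots show censoring stripes (TSS, Al,
#' NO3); all other constituents pass through untouched. Detection limits are
#' configuration, not inference: no automatic stripe detection is attempted.
#'
#' @param data `data.frame` of site rows.
#' @param constituent Column name of the response.
#' @param detection_limits Numeric vector of values (besides 0) to drop.
#' @return List: `data` (kept rows), `n_removed`, `removed_rows` (indices in
#'   the input).
#' @export
drop_censored <- function(data, constituent, detection_limits = numeric(0)) {
  if (!constituent %in% .censored_constituents)
    return(list(data = data, n_removed = 0L, removed_rows = integer(0)))
  v <- data[[constituent]]
  hit <- !is.na(v) & (v == 0 | v %in% detection_limits)
  list(data = data[!hit, , drop = FALSE],
       n_removed = sum(hit), removed_rows = which(hit))
}

#' Standardize columns to mean 0, SD 1
#'
#' @param data `data.frame`.
#' @param cols Column names to standardize (after transformation, on the
#'   modeling subset).
#' @return List: `data` (standardized), `ledger` (`data.frame` of column,
#'   mean, sd, kept for back-transformation). A constant column is an error.
#' @export
standardize_columns <- function(data, cols) {
  ledger <- data.frame(column = cols, mean = NA_real_, sd = NA_real_,
                       stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    v <- data[[cols[i]]]
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("cannot standardize constant column: ", cols[i])
    data[[cols[i]]] <- (v - m) / s
    ledger$mean[i] <- m; ledger$sd[i] <- s
  }
  list(data = data, ledger = ledger)
}

#' Variance-inflation-factor screen
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from regressing predictor j on all
#' the others. A VIF at or above 2 raises a flag (not an error): the
#' modeling convention here treats anything below 2 as low collinearity.
#' Perfect collinearity is an error.
#'
#' @param data `data.frame` or matrix of predictor columns (>= 2).
#' @return `data.frame` with `predictor` and `vif`; attribute `"flagged"` is
#'   `TRUE` when any VIF >= 2.
#' @export
vif_screen <- function(data) {
  X <- as.matrix(data)
  p <- ncol(X)
  if (p < 2) stop("VIF needs at least two predictors")
  if (nrow(X) <= p) stop("VIF needs more rows than predictors")
  if (qr(cbind(1, X))$rank < p + 1)
    stop("predictors are perfectly collinear; VIF undefined")
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, numeric(1))
  out <- data.frame(predictor = colnames(X), vif = vif,
                    stringsAsFactors = FALSE)
  attr(out, "flagged") <- any(vif >= 2)
  out
}

#' Model specification for the water-quality assessment
#'
#' @param response Response column name.
#' @param classes The four wetland-class percentage columns; always retained
#'   as fixed effects.
#' @param covariates Additional fixed-effect columns (eligible for backward
#'   elimination).
#' @param grouping Region grouping factor column.
#' @param random Columns with candidate random slopes (plus the intercept);
#'   default: intercept, classes and covariates — the maximal model.
#' @param alpha Elimination significance level.
#' @return List of class `wq_model_spec`.
#' @export
wq_model_spec <- function(response,
                          classes = c("pct_Riparian", "pct_NRShw",
                                      "pct_NRMid", "pct_NRDeep"),
                          covariates = character(0), grouping = "region",
                          random = NULL, alpha = 0.05) {
  if (is.null(random)) random <- c("(Intercept)", classes, covariates)
  structure(list(response = response, classes = classes,
                 covariates = covariates, grouping = grouping,
                 random = random, alpha = alpha),
            class = "wq_model_spec")
}

# build an lmer/lm formula from a spec; random terms are uncorrelated
# ((1|g) + (0 + x|g)) so each is independently removable by a 1-df LRT
.wq_formula <- function(spec, random = spec$random) {
  fixed <- c(spec$classes, spec$covariates)
  rhs <- paste(fixed, collapse = " + ")
  if (length(random) > 0) {
    rterms <- vapply(random, function(r) {
      if (r == "(Intercept)") sprintf("(1 | %s)", spec$grouping)
      else sprintf("(0 + %s | %s)", r, spec$grouping)
    }, character(1))
    rhs <- paste(c(rhs, rterms), collapse = " + ")
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Fit the (mixed) water-quality model
#'
#' REML fit via `lme4::lmer` when any random term is present, otherwise an
#' ordinary least-squares fit — the degenerate single-group limit.
#'
#' @param spec A [wq_model_spec()].
#' @param data Prepared `data.frame` (transformed, filtered, standardized).
#' @param random Random terms to use (default those in `spec`).
#' @param REML Logical; ML refits are used internally for fixed-effect
#'   likelihood-ratio comparisons.
#' @return Object of class `wq_fit`: the underlying fit plus bookkeeping.
#' @export
fit_mixed <- function(spec, data, random = spec$random, REML = TRUE) {
  # degenerate grouping limit: with < 2 region levels the random terms are
  # unidentifiable and the model reduces to ordinary least squares
  if (length(random) > 0 &&
      length(unique(stats::na.omit(data[[spec$grouping]]))) < 2)
    random <- character(0)
  f <- .wq_formula(spec, random)
  if (length(random) > 0) {
    fit <- lme4::lmer(f, data = data, REML = REML,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    conv <- fit@optinfo$conv$lme4
    if (!is.null(conv$code) && conv$code != 0)
      stop("mixed-model fit failed to converge: ",
           paste(unlist(conv$messages), collapse = "; "))
  } else {
    fit <- stats::lm(f, data = data)
  }
  structure(list(fit = fit, spec = spec, random = random,
                 is_mixed = length(random) > 0),
            class = "wq_fit")
}

#' Fixed-effect table of a fitted model
#'
#' @param object A `wq_fit`.
#' @return `data.frame`: `term`, `estimate`, `se`.
#' @export
fixed_effects <- function(object) {
  if (object$is_mixed) {
    est <- lme4::fixef(object$fit)
    se <- sqrt(diag(as.matrix(stats::vcov(object$fit))))
  } else {
    cf <- summary(object$fit)$coefficients
    est <- cf[, 1]; se <- cf[, 2]
  }
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             stringsAsFactors = FALSE)
}

#' @export
logLik.wq_fit <- function(object, ...) stats::logLik(object$fit, ...)

#' @export
AIC.wq_fit <- function(object, ..., k = 2) stats::AIC(object$fit, k = k)

#' Backward selection with forced retention of the class terms
#'
#' Iterative single-term elimination by likelihood-ratio test at `alpha`:
#' random terms first (REML fits compared term against term), then fixed
#' covariates (ML refits, since REML likelihoods are not comparable across
#' fixed structures). The four wetland-class fixed effects are never
#' candidates for removal. Random-effect LRT p-values are used without a
#' boundary correction (documented simplification). A term whose reduced
#' refit fails to converge is skipped with a warning and recorded.
#'
#' @param spec A [wq_model_spec()] describing the maximal model.
#' @param data Prepared `data.frame`.
#' @return List of class `wq_selection`: `fit` (final REML `wq_fit`),
#'   `trace` (`data.frame` of step, phase, term, p_value, action).
#' @export
backward_select <- function(spec, data) {
  alpha <- spec$alpha
  trace <- data.frame(step = integer(0), phase = character(0),
                      term = character(0), p_value = numeric(0),
                      action = character(0), stringsAsFactors = FALSE)
  note <- function(step, phase, term, p, action) {
    rbind(trace, data.frame(step = step, phase = phase, term = term,
                            p_value = p, action = action,
                            stringsAsFactors = FALSE))
  }
  step <- 0L
  random <- spec$random
  # phase 1: random effects, REML likelihood-ratio tests
  repeat {
    if (length(random) == 0) break
    full <- fit_mixed(spec, data, random = random, REML = TRUE)
    pvals <- rep(NA_real_, length(random))
    for (i in seq_along(random)) {
      red <- tryCatch(
        fit_mixed(spec, data, random = random[-i], REML = TRUE),
        error = function(e) NULL)
      if (is.null(red)) {
        warning("reduced fit without random term '", random[i],
                "' failed; term kept")
        next
      }
      lr <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
      pvals[i] <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    }
    if (all(is.na(pvals))) break
    worst <- which.max(pvals)
    step <- step + 1L
    if (pvals[worst] >= alpha) {
      trace <- note(step, "random", random[worst], pvals[worst], "removed")
      random <- random[-worst]
    } else {
      trace <- note(step, "random", random[worst], pvals[worst], "stopped")
      break
    }
  }
  # phase 2: fixed covariates, ML likelihood-ratio tests; classes retained
  covariates <- spec$covariates
  repeat {
    if (length(covariates) == 0) break
    cur <- spec
    cur$covariates <- covariates
    cur_random <- intersect(random, c("(Intercept)", spec$classes, covariates))
    full <- fit_mixed(cur, data, random = cur_random, REML = FALSE)
    pvals <- rep(NA_real_, length(covariates))
    for (i in seq_along(covariates)) {
      red_spec <- cur
      red_spec$covariates <- covariates[-i]
      red_random <- setdiff(cur_random, covariates[i])
      red <- tryCatch(
        fit_mixed(red_spec, data, random = red_random, REML = FALSE),
        error = function(e) NULL)
      if (is.null(red)) {
        warning("reduced fit without fixed term '", covariates[i],
                "' failed; term kept")
        next
      }
      df <- 1 + as.integer(covariates[i] %in% cur_random)
      lr <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
      pvals[i] <- stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
    }
    if (all(is.na(pvals))) break
    worst <- which.max(pvals)
    step <- step + 1L
    if (pvals[worst] >= alpha) {
      trace <- note(step, "fixed", covariates[worst], pvals[worst], "removed")
      random <- setdiff(random, covariates[worst])
      covariates <- covariates[-worst]
    } else {
      trace <- note(step, "fixed", covariates[worst], pvals[worst], "stopped")
      break
    }
  }
  final_spec <- spec
  final_spec$covariates <- covariates
  final_spec$random <- random
  stopifnot(all(spec$classes %in% c(final_spec$classes)))  # never eliminated
  final <- fit_mixed(final_spec, data, random = random, REML = TRUE)
  structure(list(fit = final, trace = trace, spec = final_spec),
            class = "wq_selection")
}

#' Choose the region grouping by AIC
#'
#' Fits the model under each candidate grouping column and returns the one
#' with minimal AIC (ML fits, so likelihoods are comparable).
#'
#' @param spec A [wq_model_spec()].
#' @param data Prepared `data.frame`.
#' @param groupings Character vector of candidate grouping columns (>= 1).
#' @return List: `grouping` (chosen column), `aic` (`data.frame` of
#'   candidate AICs).
#' @export
select_grouping <- function(spec, data, groupings) {
  stopifnot(length(groupings) >= 1)
  aics <- vapply(groupings, function(g) {
    s <- spec; s$grouping <- g
    AIC(fit_mixed(s, data, REML = FALSE))
  }, numeric(1))
  list(grouping = groupings[which.min(aics)],
       aic = data.frame(grouping = groupings, aic = unname(aics),
                        stringsAsFactors = FALSE))
}

#' Extract standardized population-mean slopes for the wetland classes
#'
#' When a class term also carries a random slope, the fixed-effect estimate
#' is the population mean of the region-varying slopes; otherwise it is the
#' common slope. A slope of 0.5 reads as: the response changes by one-half
#' SD per one-SD change in that class percentage. Significance uses the
#' two-standard-error rule: the interval `mean_slope +/- 2 * se` must
#' exclude zero.
#'
#' @param object A `wq_fit` or `wq_selection`.
#' @return `data.frame`: `class`, `mean_slope`, `se`, `significant`,
#'   `had_random_component`.
#' @export
extract_slopes <- function(object) {
  if (inherits(object, "wq_selection")) object <- object$fit
  fe <- fixed_effects(object)
  classes <- object$spec$classes
  miss <- setdiff(classes, fe$term)
  if (length(miss) > 0)
    stop("fitted model lacks class term(s): ", paste(miss, collapse = ", "))
  i <- match(classes, fe$term)
  data.frame(
    class = classes,
    mean_slope = fe$estimate[i],
    se = fe$se[i],
    significant = abs(fe$estimate[i]) > 2 * fe$se[i],
    had_random_component = classes %in% object$random,
    stringsAsFactors = FALSE
  )
}

#' Prepare a water-quality table for modeling
#'
#' Applies, in order: censored-row removal (for the affected constituents),
#' response transformation, covariate log transformation (optional),
#' standardization of response, classes and covariates. The order is logged
#' on the result (`attr(, "prep_log")`).
#'
#' @param data Raw site `data.frame`.
#' @param spec A [wq_model_spec()].
#' @param detection_limits Values (besides 0) treated as censored.
#' @param log_covariates Covariate columns to natural-log before
#'   standardizing.
#' @return Prepared `data.frame` with a `prep_log` attribute and a
#'   `standardization` attribute (the mean/sd ledger).
#' @export
prepare_wq <- function(data, spec, detection_limits = numeric(0),
                       log_covariates = character(0)) {
  log <- character(0)
  cens <- drop_censored(data, spec$response, detection_limits)
  data <- cens$data
  log <- c(log, sprintf("drop_censored: removed %d rows", cens$n_removed))
  data[[spec$response]] <- transform_response(data[[spec$response]],
                                              spec$response)
  log <- c(log, sprintf("transform: %s",
                        if (spec$response == "pH") "pH^4" else "ln"))
  for (cv in log_covariates) data[[cv]] <- log(data[[cv]])
  std <- standardize_columns(data, c(spec$response, spec$classes,
                                     spec$covariates))
  data <- std$data
  log <- c(log, "standardize: mean 0, sd 1")
  attr(data, "prep_log") <- log
  attr(data, "standardization") <- std$ledger
  data
}
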