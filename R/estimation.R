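# Adjusted between-arm mean differences.
#
# Base case: follow-up outcomes (quarterly health-sector costs, SF-6D
# utilities, MADRS) are modelled jointly across waves with an arm x wave
# cell-mean structure, adjusted for the baseline value of the outcome,
# sex and national origin, with a fully unstructured within-participant
# residual covariance estimated by REML (nlme::gls with corSymm +
# varIdent). All available waves contribute, so participants with partial
# follow-up are retained. Sensitivity analyses use identity-link GLMs on
# the 3-12-month totals with family selection guided by the modified Park
# test and link adequacy checked by Pearson-correlation, Pregibon and
# modified Hosmer-Lemeshow tests.

COMPARISONS <- list(`2v1` = c(2L, 1L), `3v1` = c(3L, 1L), `2v3` = c(2L, 3L))

# QALY contribution of each follow-up wave's utility under the trapezoid
# (baseline is absorbed by the adjustment, its weight drops out of
# between-arm differences).
QALY_WAVE_WEIGHTS <- c(`3` = 0.25, `6` = 0.25, `9` = 0.25, `12` = 0.125)

build_followup_frame <- function(data, outcome, breakdown = NULL) {
  sched <- attr(data, "wave_schedule") %||% WAVE_SCHEDULE
  base_wave <- sched[1]
  value_col <- switch(outcome, cost = "cost_aud", utility = "utility",
                      madrs = "madrs")
  delivery <- if (is.null(breakdown)) c(0, 0, 0) else
    breakdown$per_participant

  base <- data[data$wave == base_wave,
               c("participant_id", value_col)]
  names(base)[2] <- "baseline"
  d <- data[data$wave != base_wave,
            c("participant_id", "arm", "sex", "country", "wave", value_col)]
  names(d)[6] <- "value"
  if (outcome == "cost") {
    d$value <- d$value + ifelse(d$wave == 3, delivery[d$arm], 0)
  }
  d <- left_join(d, base, by = "participant_id")
  d$sexm <- as.integer(d$sex == "male")
  d$cty_au <- as.integer(d$country == "Australia")
  d$cty_other <- as.integer(d$country == "other")
  d$wavef <- factor(d$wave, levels = setdiff(sched, base_wave))
  d$armf <- factor(d$arm, levels = 1:3)
  d$pos <- as.integer(d$wavef)
  d <- d[!is.na(d$value) & !is.na(d$baseline), ]
  d[order(d$participant_id, d$pos), ]
}

#' Repeated-measures adjusted mean differences
#'
#' Fits the base-case longitudinal model for one outcome and returns
#' adjusted between-arm differences per follow-up wave plus a 3-12-month
#' total: the sum of per-wave differences for costs, the
#' trapezoid-weighted QALY difference for utilities, and the 12-month
#' (primary time point) difference for MADRS. MADRS differences are
#' sign-flipped to the improvement convention (positive favours the
#' intervention).
#'
#' When the unstructured-covariance REML fit cannot be estimated (e.g.
#' residual variance numerically zero), the same mean structure is fit by
#' ordinary least squares and flagged in the result's `method`.
#'
#' @param data a priced `trial_data`.
#' @param outcome `"cost"`, `"utility"` or `"madrs"`.
#' @param config an [analysis_config()].
#' @param breakdown delivery-cost breakdown attached at the 3-month wave
#'   for the cost outcome.
#' @return a `wave_estimates` tibble: comparison, wave, estimate, se,
#'   95% CI and p-value (normal approximation), with attribute `method`.
#' @export
fit_repeated_measures <- function(data,
                                  outcome = c("cost", "utility", "madrs"),
                                  config = analysis_config(),
                                  breakdown = NULL) {
  outcome <- match.arg(outcome)
  d <- build_followup_frame(data, outcome, breakdown)
  waves <- levels(d$wavef)
  per_arm_wave <- table(d$armf, d$wavef)
  if (any(per_arm_wave == 0)) {
    abort(paste0("cannot fit: wave with an all-missing arm (",
                 paste(which(per_arm_wave == 0, arr.ind = TRUE)[1, ],
                       collapse = ", "), ")"))
  }

  d$cell <- interaction(d$wavef, d$armf, sep = "_a", lex.order = FALSE)
  fml <- value ~ 0 + cell + baseline + sexm + cty_au + cty_other
  method <- "gls_unstructured_reml"
  fit <- tryCatch(
    nlme::gls(fml, data = d,
              correlation = nlme::corSymm(form = ~pos | participant_id),
              weights = nlme::varIdent(form = ~1 | wavef),
              method = "REML",
              control = nlme::glsControl(maxIter = 100, msMaxIter = 100,
                                         returnObject = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    diag_msg <- conditionMessage(fit)
    fit <- tryCatch(lm(fml, data = d), error = function(e) {
      abort(paste0("repeated-measures fit failed: ", diag_msg))
    })
    method <- paste0("ols_fallback (", diag_msg, ")")
  }

  beta <- coef(fit)
  Vf <- vcov(fit)
  # OLS fallback may drop collinear covariates (NA coefficients); treat
  # them as zero with zero variance
  V <- matrix(0, length(beta), length(beta),
              dimnames = list(names(beta), names(beta)))
  V[rownames(Vf), colnames(Vf)] <- Vf
  beta[is.na(beta)] <- 0
  cell_name <- function(w, a) paste0("cell", w, "_a", a)

  rows <- list()
  for (cmp in names(COMPARISONS)) {
    a <- COMPARISONS[[cmp]][1]; b <- COMPARISONS[[cmp]][2]
    Ltot <- setNames(numeric(length(beta)), names(beta))
    tot_w <- switch(outcome,
                    cost = setNames(rep(1, length(waves)), waves),
                    utility = QALY_WAVE_WEIGHTS[waves],
                    madrs = setNames(as.numeric(waves == max(waves)),
                                     waves))
    for (w in waves) {
      L <- setNames(numeric(length(beta)), names(beta))
      L[cell_name(w, a)] <- 1
      L[cell_name(w, b)] <- -1
      est <- sum(L * beta)
      se <- sqrt(drop(t(L) %*% V %*% L))
      if (outcome == "madrs") est <- -est
      rows[[length(rows) + 1]] <- tibble::tibble(
        comparison = cmp, wave = w, estimate = est, se = se)
      Ltot <- Ltot + tot_w[w] * L
    }
    est <- sum(Ltot * beta)
    se <- sqrt(drop(t(Ltot) %*% V %*% Ltot))
    if (outcome == "madrs") est <- -est
    rows[[length(rows) + 1]] <- tibble::tibble(
      comparison = cmp, wave = "total_3_12", estimate = est, se = se)
  }
  out <- dplyr::bind_rows(rows)
  z <- qnorm(1 - config$alpha / 2)
  out$lo <- out$estimate - z * out$se
  out$hi <- out$estimate + z * out$se
  out$p <- 2 * pnorm(-abs(out$estimate / out$se))
  structure(out, outcome = outcome, method = method,
            class = c("wave_estimates", class(out)))
}

glm_identity_adjusted <- function(df, response, family, config,
                                  baseline_col) {
  df <- df[!is.na(df[[response]]) & !is.na(df[[baseline_col]]), ]
  y <- df[[response]]
  positive_family <- family$family %in% c("Gamma", "inverse.gaussian")
  shift <- 0
  if (positive_family && any(y <= 0)) {
    if (config$glm_zero_policy == "half_min_shift") {
      shift <- min(y[y > 0]) / 2
      y <- y + shift
    } else {
      family <- gaussian(link = "identity")
      positive_family <- FALSE
    }
  }
  df$.y <- y
  fml <- as.formula(paste(".y ~ armf +", baseline_col,
                          "+ sexm + cty_au + cty_other"))
  df$armf <- factor(df$arm, levels = 1:3)
  start <- coef(lm(fml, data = df))
  fit <- tryCatch(
    suppressWarnings(glm(fml, data = df, family = family, start = start,
                         control = glm.control(maxit = 200))),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$converged) {
    # inverse-Gaussian identity fits on noisy data are fragile; gaussian
    # identity targets the same mean difference
    fit <- glm(fml, data = df, family = gaussian(link = "identity"))
  }
  list(fit = fit, shift = shift)
}

glm_comparisons <- function(fit, config, flip_sign = FALSE) {
  beta <- coef(fit)
  # collinear covariates (e.g. a constant dummy) are dropped by the
  # fitter; treat them as zero with zero variance
  Vf <- vcov(fit)
  V <- matrix(0, length(beta), length(beta),
              dimnames = list(names(beta), names(beta)))
  V[rownames(Vf), colnames(Vf)] <- Vf
  V[is.na(V)] <- 0
  beta[is.na(beta)] <- 0
  z <- qnorm(1 - config$alpha / 2)
  grab <- function(L) {
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    if (flip_sign) est <- -est
    tibble::tibble(estimate = est, se = se,
                   lo = est - z * se, hi = est + z * se,
                   p = 2 * pnorm(-abs(est / se)))
  }
  L0 <- setNames(numeric(length(beta)), names(beta))
  L2 <- L0; L2["armf2"] <- 1
  L3 <- L0; L3["armf3"] <- 1
  L23 <- L2 - L3
  dplyr::bind_rows(`2v1` = grab(L2), `3v1` = grab(L3), `2v3` = grab(L23),
                   .id = "comparison")
}

#' Adjusted total-cost differences from an identity-link gamma GLM
#'
#' Regresses the 3-12-month health-sector total (complete cases) on arm,
#' baseline cost, sex and national origin with a gamma family and
#' identity link, so coefficients are adjusted mean differences in AUD.
#'
#' @param summary_df a [participant_summary()] table.
#' @param config an [analysis_config()].
#' @return tibble of adjusted differences per comparison, with the fitted
#'   model in attribute `fit`.
#' @export
fit_cost_glm <- function(summary_df, config = analysis_config()) {
  res <- glm_identity_adjusted(summary_df, "total_3_12",
                               Gamma(link = "identity"), config,
                               "baseline_cost")
  out <- glm_comparisons(res$fit, config)
  structure(out, fit = res$fit, shift = res$shift,
            class = c("glm_estimates", class(out)))
}

#' Adjusted QALY differences from an identity-link inverse-Gaussian GLM
#'
#' @inheritParams fit_cost_glm
#' @return tibble of adjusted QALY differences per comparison.
#' @export
fit_qaly_glm <- function(summary_df, config = analysis_config()) {
  res <- glm_identity_adjusted(summary_df, "qaly",
                               inverse.gaussian(link = "identity"), config,
                               "baseline_utility")
  out <- glm_comparisons(res$fit, config)
  structure(out, fit = res$fit, shift = res$shift,
            class = c("glm_estimates", class(out)))
}

#' Adjusted 12-month MADRS improvement from a gaussian identity GLM
#'
#' @inheritParams fit_cost_glm
#' @return tibble of adjusted differences per comparison, on the
#'   improvement scale (positive favours the intervention).
#' @export
fit_madrs_glm <- function(summary_df, config = analysis_config()) {
  res <- glm_identity_adjusted(summary_df, "madrs_12",
                               gaussian(link = "identity"), config,
                               "baseline_madrs")
  out <- glm_comparisons(res$fit, config, flip_sign = TRUE)
  structure(out, fit = res$fit, class = c("glm_estimates", class(out)))
}

extract_y_fitted <- function(object) {
  if (is.list(object) && !is.null(object$y) && !is.null(object$fitted) &&
      !inherits(object, c("lm", "glm"))) {
    return(list(y = object$y, fitted = object$fitted))
  }
  if (inherits(object, "glm")) {
    return(list(y = object$y, fitted = fitted(object)))
  }
  if (inherits(object, "lm")) {
    mf <- stats::model.frame(object)
    return(list(y = stats::model.response(mf), fitted = fitted(object)))
  }
  abort("supply a fitted lm/glm or a list(y =, fitted =)")
}

#' Modified Park test for GLM family selection
#'
#' Regresses the log squared residuals of an identity-link fit on the log
#' predictions; the slope estimates the power in Var(y) = phi * mu^gamma,
#' and the recommended family is the one whose index (gaussian 0, poisson
#' 1, gamma 2, inverse-Gaussian 3) is nearest the estimate.
#'
#' @param object fitted lm/glm with positive predictions, or
#'   `list(y =, fitted =)`.
#' @return list: `park_coefficient`, `se`, `recommended_family`,
#'   `family_index`.
#' @export
modified_park_test <- function(object) {
  yf <- extract_y_fitted(object)
  r2 <- (yf$y - yf$fitted)^2
  if (any(yf$fitted <= 0)) abort("Park test needs positive predictions")
  if (all(r2 < .Machine$double.eps)) {
    abort("degenerate fit: all residuals are zero")
  }
  keep <- r2 > 0
  park <- lm(log(r2[keep]) ~ log(yf$fitted[keep]))
  gamma_hat <- unname(coef(park)[2])
  se <- sqrt(vcov(park)[2, 2])
  fams <- c(gaussian = 0, poisson = 1, gamma = 2, inverse.gaussian = 3)
  rec <- names(fams)[which.min(abs(fams - gamma_hat))]
  list(park_coefficient = gamma_hat, se = se,
       recommended_family = rec, family_index = unname(fams[rec]))
}

#' Link adequacy diagnostics for an identity-link fit
#'
#' Three checks: (i) Pearson correlation of raw residuals with
#' predictions; (ii) Pregibon link test, refitting on the linear
#' predictor and its square and testing the squared term; (iii) modified
#' Hosmer-Lemeshow F test that mean residuals are jointly zero across
#' deciles of the prediction. The link is deemed adequate when all three
#' are non-significant at the 5% level.
#'
#' @param object fitted lm or glm (at least 20 observations).
#' @return list with the three p-values, correlations/coefficients, and
#'   `adequate`.
#' @export
link_diagnostics <- function(object) {
  yf <- extract_y_fitted(object)
  y <- yf$y
  mu <- yf$fitted
  n <- length(y)
  if (n < 20) abort("need at least 20 observations for decile diagnostics")
  r <- y - mu

  if (sd(mu) < .Machine$double.eps) {
    pearson <- list(estimate = 0, p.value = 1)
  } else {
    ct <- cor.test(r, mu)
    pearson <- list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }

  eta <- if (inherits(object, "glm")) object$linear.predictors else mu
  preg_df <- data.frame(y = y, eta = eta, eta2 = eta^2)
  preg_fit <- tryCatch({
    if (inherits(object, "glm")) {
      glm(y ~ eta + eta2, data = preg_df, family = stats::family(object),
          start = c(0, 1, 0), control = glm.control(maxit = 200))
    } else {
      lm(y ~ eta + eta2, data = preg_df)
    }
  }, error = function(e) lm(y ~ eta + eta2, data = preg_df))
  preg_cf <- summary(preg_fit)$coefficients
  pregibon <- if ("eta2" %in% rownames(preg_cf)) {
    list(coefficient = preg_cf["eta2", 1], p.value = preg_cf["eta2", 4])
  } else {
    # squared term collinear (e.g. constant predictor): nothing to test
    list(coefficient = 0, p.value = 1)
  }

  g <- factor(ceiling(10 * rank(mu, ties.method = "first") / n))
  hl_fit <- lm(r ~ 0 + g)
  fs <- summary(hl_fit)$fstatistic
  hl <- list(F = unname(fs[1]),
             p.value = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))

  list(pearson = pearson, pregibon = pregibon, hosmer_lemeshow = hl,
       adequate = pearson$p.value > 0.05 && pregibon$p.value > 0.05 &&
         hl$p.value > 0.05)
}

#' Logistic model of 12-month data completeness
#'
#' Regresses an indicator of complete cost and QALY data over all waves
#' on sex, national origin, arm and baseline outcome values, reporting
#' odds ratios with Wald CIs. Degenerate outcomes (everyone complete or
#' everyone incomplete) and separation are flagged rather than reported
#' as estimates.
#'
#' @param summary_df a [participant_summary()] table (or a `trial_data`,
#'   which is summarised first).
#' @param config an [analysis_config()].
#' @return list: `table` (term, OR, CI, p), `degenerate`, `separation`.
#' @export
missingness_model <- function(summary_df, config = analysis_config()) {
  if (inherits(summary_df, "trial_data")) {
    summary_df <- participant_summary(summary_df)
  }
  d <- summary_df
  d$complete <- as.integer(d$complete_cost & d$complete_qaly)
  if (length(unique(d$complete)) < 2) {
    return(list(table = NULL, degenerate = TRUE, separation = FALSE))
  }
  d$armf <- factor(d$arm, levels = 1:3)
  covs <- c("sexm", "cty_au", "cty_other", "armf")
  if (!all(is.na(d$baseline_utility)) &&
      sum(!is.na(d$baseline_utility)) > 10) covs <- c(covs,
                                                      "baseline_utility")
  if (!all(is.na(d$baseline_cost)) &&
      sum(!is.na(d$baseline_cost)) > 10) covs <- c(covs, "baseline_cost")
  fml <- as.formula(paste("complete ~", paste(covs, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = d, family = binomial()))
  cf <- summary(fit)$coefficients
  z <- qnorm(1 - config$alpha / 2)
  tab <- tibble::tibble(
    term = rownames(cf)[-1],
    or = exp(cf[-1, 1]),
    lo = exp(cf[-1, 1] - z * cf[-1, 2]),
    hi = exp(cf[-1, 1] + z * cf[-1, 2]),
    p = cf[-1, 4])
  separation <- any(abs(cf[, 1]) > 10 | cf[, 2] > 10)
  list(table = tab, degenerate = FALSE, separation = separation,
       fit = fit)
}
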