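# Chained-equation imputation with predictive mean matching, and the
# imputation-nested bootstrap.
#
# Each bootstrap resample receives a single imputation: wave-level costs,
# utilities and MADRS scores are imputed one variable at a time in time
# order, regressing each on the other wave-level variables plus the
# baseline values, arm, sex and national origin, and replacing a missing
# entry with the observed value of one of the k donors whose predicted
# means are nearest (so imputed values always lie in the observed
# support). The GLM-based incremental pair is then computed on the
# completed resample, and the B pairs are summarized downstream by the
# reordered percentile method.

pmm_draw <- function(pred_obs, pred_mis, values_obs, k) {
  # k-nearest-prediction donors located on the sorted prediction axis:
  # the k nearest of any query lie within k positions of its insertion
  # point, so only a 2k window needs scanning
  o <- order(pred_obs)
  po <- pred_obs[o]
  vo <- values_obs[o]
  n <- length(po)
  k <- min(k, n)
  pos <- findInterval(pred_mis, po)
  m <- length(pred_mis)
  u <- sample.int(k, m, replace = TRUE)
  # the k nearest donors form a contiguous block on the sorted axis;
  # take them in nearness order with a two-pointer sweep (ties go left);
  # +/-Inf sentinels make exhausted sides unreachable
  po2 <- c(-Inf, po, Inf)
  lo <- pos
  hi <- pos + 1L
  out <- numeric(m)
  for (step in seq_len(k)) {
    dl <- pred_mis - po2[lo + 1L]
    dr <- po2[hi + 1L] - pred_mis
    left <- dl <= dr
    idx <- hi
    idx[left] <- lo[left]
    hit <- u == step
    out[hit] <- vo[idx[hit]]
    lo <- lo - left
    hi <- hi + !left
  }
  out
}

#' Single chained-equation PMM imputation
#'
#' Fills missing entries of the target columns by predictive mean
#' matching, cycling through the targets in the order given. Consumes no
#' random numbers when nothing is missing.
#'
#' @param df data frame.
#' @param target_cols columns to impute, in time order.
#' @param predictor_cols complete numeric columns used in every
#'   imputation model.
#' @param donors donor pool size k (default 5).
#' @param cycles chained-equation cycles (default 10).
#' @return `df` with targets completed.
#' @export
pmm_impute <- function(df, target_cols, predictor_cols, donors = 5,
                       cycles = 10) {
  M <- as.matrix(as.data.frame(df)[c(target_cols, predictor_cols)])
  nr <- nrow(M)
  miss <- lapply(target_cols, function(v) which(is.na(M[, v])))
  names(miss) <- target_cols
  miss <- miss[lengths(miss) > 0]
  if (length(miss) == 0) return(df)
  if (anyNA(M[, predictor_cols])) {
    abort("predictor columns must be complete")
  }

  obs_vals <- lapply(names(miss), function(v) M[-miss[[v]], v])
  names(obs_vals) <- names(miss)
  for (v in names(miss)) {
    if (length(obs_vals[[v]]) < donors) {
      abort(paste0("too few observed values to impute ", v))
    }
    M[miss[[v]], v] <- sample(obs_vals[[v]], length(miss[[v]]),
                              replace = TRUE)
  }

  X <- cbind(1, M)
  vcol <- setNames(match(target_cols, colnames(M)) + 1L, target_cols)
  for (cyc in seq_len(cycles)) {
    for (v in names(miss)) {
      mi <- miss[[v]]
      Xv <- X[, -vcol[v], drop = FALSE]
      fit <- lm.fit(Xv[-mi, , drop = FALSE], M[-mi, v])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- drop(Xv %*% beta)
      M[mi, v] <- pmm_draw(pred[-mi], pred[mi], obs_vals[[v]], donors)
      X[mi, vcol[v]] <- M[mi, v]
    }
  }
  for (v in names(miss)) df[[v]] <- M[, v]
  df
}

#' Imputation-nested bootstrap of incremental pairs
#'
#' For each of B within-arm bootstrap resamples, imputes the wave-level
#' costs, utilities and MADRS scores once by chained-equation predictive
#' mean matching, recomputes the 3-12-month totals and QALYs, and fits
#' the identity-link GLMs to obtain the adjusted incremental pair.
#' Imputation is stratified by randomized arm (donors come only from a
#' participant's own arm), the standard recommendation for trials so
#' that cross-arm donor borrowing cannot attenuate the between-arm
#' estimand. With no missing data this reduces exactly to
#' [bootstrap_incrementals()] with the GLM estimator under the same
#' seed.
#'
#' @param data a priced `trial_data` with missingness confined to
#'   post-baseline waves.
#' @param config an [analysis_config()] (`mi_donors`, `mi_cycles`,
#'   `bootstrap_B`, `seed`).
#' @param breakdown delivery-cost breakdown.
#' @param comparison `"2v1"`, `"3v1"` or `"2v3"`.
#' @param effect `"qaly"` or `"madrs"`.
#' @return a `bootstrap_distribution`.
#' @export
mi_nested_bootstrap <- function(data, config = analysis_config(),
                                breakdown = NULL, comparison = "2v1",
                                effect = "qaly") {
  s <- participant_summary(data, breakdown)
  sched <- attr(data, "wave_schedule") %||% WAVE_SCHEDULE
  base_wave <- sched[1]
  fup <- setdiff(sched, base_wave)
  target_cols <- c(paste0("cost_", fup), paste0("util_", fup),
                   paste0("madrs_", fup))
  predictor_cols <- c(paste0("cost_", base_wave),
                      paste0("util_", base_wave),
                      paste0("madrs_", base_wave),
                      "sexm", "cty_au", "cty_other")
  if (anyNA(s[predictor_cols])) {
    abort("baseline (wave 0) values must be complete for imputation")
  }

  est <- estimator_impute_glm(target_cols, predictor_cols, fup, base_wave,
                              config, comparison, effect)
  bootstrap_incrementals(s, est, config,
                         estimator_tag = paste0("mi_pmm_glm_", comparison),
                         effect_kind = effect)
}

estimator_impute_glm <- function(target_cols, predictor_cols, fup,
                                 base_wave, config, comparison, effect) {
  function(s) {
    # imputation is stratified by randomized arm: donors are drawn only
    # within a participant's own arm, the standard recommendation for
    # trials so that imputation cannot dilute the estimand (the
    # between-arm difference)
    imp <- dplyr::bind_rows(lapply(
      split(s, s$arm),
      pmm_impute, target_cols = target_cols,
      predictor_cols = predictor_cols,
      donors = config$mi_donors, cycles = config$mi_cycles))
    imp$total_3_12 <- imp$delivery_cost +
      rowSums(imp[paste0("cost_", fup)])
    util_cols <- paste0("util_", c(base_wave, fup))
    imp$qaly <- qaly_auc(as.matrix(imp[util_cols]))
    imp$madrs_12 <- imp[[paste0("madrs_", max(fup))]]
    cost <- fit_cost_glm(imp, config)
    eff <- if (effect == "qaly") fit_qaly_glm(imp, config)
           else fit_madrs_glm(imp, config)
    c(delta_cost = cost$estimate[cost$comparison == comparison],
      delta_effect = eff$estimate[eff$comparison == comparison])
  }
}
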