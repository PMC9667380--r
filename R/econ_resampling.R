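# Economic inference: paired bootstrap of incremental cost-effect pairs,
# ICER and dominance classification, reordered-percentile confidence
# intervals, cost-effectiveness planes and acceptability curves.
#
# Convention throughout: the cost-effectiveness plane has the incremental
# effect on the abscissa and the incremental cost on the ordinate.
# Quadrants: NE (more costly, more effective), SE (less costly, more
# effective: dominant), SW (less costly, less effective), NW (more
# costly, less effective: dominated).

#' Classify an incremental cost-effect pair
#'
#' @param delta_cost incremental cost, AUD.
#' @param delta_effect incremental effect (positive favours the
#'   intervention).
#' @param tol effects smaller than this in magnitude give no meaningful
#'   ratio; such pairs are labelled `"undefined"` and should be reported
#'   through net monetary benefit instead.
#' @return an `icer_result` list: `kind` (`"ratio"`, `"dominant"`,
#'   `"dominated"` or `"undefined"`), `value` (ratio rounded to whole
#'   AUD when kind is `"ratio"`), `ratio_raw`, and `quadrant`.
#' @export
icer_point <- function(delta_cost, delta_effect, tol = 1e-9) {
  stopifnot(is.finite(delta_cost), is.finite(delta_effect))
  quadrant <- if (delta_effect > 0 && delta_cost < 0) "SE"
  else if (delta_effect <= 0 && delta_cost < 0) "SW"
  else if (delta_effect < 0 && delta_cost >= 0) "NW"
  else "NE"

  if (delta_cost < 0 && delta_effect > 0) {
    kind <- "dominant"; ratio <- NA_real_
  } else if (delta_cost > 0 && delta_effect < 0) {
    kind <- "dominated"; ratio <- NA_real_
  } else if (abs(delta_effect) < tol) {
    kind <- "undefined"; ratio <- NA_real_
  } else {
    kind <- "ratio"; ratio <- delta_cost / delta_effect
  }
  structure(list(kind = kind,
                 value = if (kind == "ratio") round_half_up(ratio, 0)
                         else NA_real_,
                 ratio_raw = ratio,
                 quadrant = quadrant,
                 delta_cost = delta_cost,
                 delta_effect = delta_effect),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  lab <- switch(x$kind, ratio = format(x$value, big.mark = ","), x$kind)
  cat("ICER:", lab, "(quadrant ", x$quadrant, ")\n")
  invisible(x)
}

resampler <- function(data) {
  # Returns a function(void) -> resampled data, stratified within arm so
  # the randomized arm sizes are preserved.
  if ("wave" %in% names(data)) {
    ids <- unique(data$participant_id)
    arm_of <- data$arm[match(ids, data$participant_id)]
    rows_of <- split(seq_len(nrow(data)), data$participant_id)[ids]
    by_arm <- split(seq_along(ids), arm_of)
    function() {
      pick <- unlist(lapply(by_arm, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      rows <- rows_of[pick]
      out <- data[unlist(rows, use.names = FALSE), ]
      out$participant_id <- rep(sprintf("R%05d", seq_along(pick)),
                                lengths(rows))
      attributes(out)$wave_schedule <- attr(data, "wave_schedule")
      out
    }
  } else {
    by_arm <- split(seq_len(nrow(data)), data$arm)
    function() {
      pick <- unlist(lapply(by_arm, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      data[pick, ]
    }
  }
}

#' Nonparametric bootstrap of incremental cost-effect pairs
#'
#' Resamples participants with replacement within arm (preserving the
#' randomized arm sizes), applies the estimator to each resample and
#' collects B incremental pairs. A replicate on which the estimator fails
#' is redrawn (never dropped), so the distribution always holds exactly B
#' replicates; the redraw count is recorded. Deterministic given
#' `config$seed`.
#'
#' @param data a `trial_data` (participant-wave rows) or a
#'   participant-level table with an `arm` column.
#' @param estimator function mapping a dataset like `data` to
#'   `c(delta_cost =, delta_effect =)`.
#' @param config an [analysis_config()] supplying `bootstrap_B` and
#'   `seed`.
#' @param estimator_tag label stored with the distribution.
#' @param effect_kind `"qaly"` or `"madrs"`, stored with the
#'   distribution.
#' @return a `bootstrap_distribution`: `replicates` tibble
#'   (`delta_cost`, `delta_effect`), `point_estimate`, `B`, `seed`,
#'   `estimator_tag`, `redraws`.
#' @export
bootstrap_incrementals <- function(data, estimator,
                                   config = analysis_config(),
                                   estimator_tag = "estimator",
                                   effect_kind = "qaly") {
  set.seed(config$seed)
  pt <- estimator(data)
  draw <- resampler(data)
  B <- config$bootstrap_B
  dc <- numeric(B); de <- numeric(B); redraws <- 0L
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in 1:100) {
      res <- tryCatch(estimator(draw()), error = function(e) NULL)
      if (!is.null(res) && all(is.finite(unlist(res)[1:2]))) {
        ok <- TRUE; break
      }
      redraws <- redraws + 1L
    }
    if (!ok) abort("bootstrap replicate failed 100 consecutive redraws")
    res <- unlist(res)
    dc[b] <- res[["delta_cost"]]
    de[b] <- res[["delta_effect"]]
  }
  structure(list(replicates = tibble::tibble(delta_cost = dc,
                                             delta_effect = de),
                 point_estimate = unlist(pt)[c("delta_cost",
                                               "delta_effect")],
                 B = B, seed = config$seed,
                 estimator_tag = estimator_tag,
                 effect_kind = effect_kind,
                 redraws = redraws),
            class = "bootstrap_distribution")
}

#' Unadjusted mean-difference estimator on participant summaries
#'
#' @param comparison `"2v1"`, `"3v1"` or `"2v3"`.
#' @param effect `"qaly"` or `"madrs"`.
#' @param breakdown delivery-cost breakdown used when `data` passed to
#'   the estimator is a `trial_data` rather than a summary table.
#' @return an estimator function for [bootstrap_incrementals()].
#' @export
estimator_mean_difference <- function(comparison = "2v1", effect = "qaly",
                                      breakdown = NULL) {
  pair <- COMPARISONS[[comparison]]
  force(effect)
  function(data) {
    s <- if (inherits(data, "trial_data")) {
      participant_summary(data, breakdown)
    } else data
    a <- s[s$arm == pair[1], ]
    b <- s[s$arm == pair[2], ]
    dc <- mean(a$total_3_12, na.rm = TRUE) -
      mean(b$total_3_12, na.rm = TRUE)
    de <- if (effect == "qaly") {
      effect_difference("qaly", a$qaly, b$qaly)
    } else {
      effect_difference("madrs", a$madrs_12, b$madrs_12)
    }
    c(delta_cost = dc, delta_effect = de)
  }
}

#' Covariate-adjusted GLM estimator on complete cases
#'
#' Cost difference from the identity-link gamma GLM, effect difference
#' from the identity-link inverse-Gaussian GLM (QALYs) or gaussian GLM on
#' the improvement scale (MADRS), all adjusted for baseline value, sex
#' and national origin.
#'
#' @inheritParams estimator_mean_difference
#' @param config an [analysis_config()].
#' @return an estimator function for [bootstrap_incrementals()].
#' @export
estimator_glm_totals <- function(comparison = "2v1", effect = "qaly",
                                 config = analysis_config(),
                                 breakdown = NULL) {
  force(comparison); force(effect)
  function(data) {
    s <- if (inherits(data, "trial_data")) {
      participant_summary(data, breakdown)
    } else data
    cost <- fit_cost_glm(s, config)
    eff <- if (effect == "qaly") fit_qaly_glm(s, config)
           else fit_madrs_glm(s, config)
    c(delta_cost = cost$estimate[cost$comparison == comparison],
      delta_effect = eff$estimate[eff$comparison == comparison])
  }
}

ce_angle <- function(delta_cost, delta_effect) {
  # Angular position on the CE plane measured counterclockwise from the
  # positive-cost axis, so the ordering runs NW (dominated) -> SW -> SE
  # (dominant) -> NE and economic preference is monotone along it.
  (atan2(delta_cost, delta_effect) - pi / 2) %% (2 * pi)
}

#' Reordered bootstrap percentile confidence interval
#'
#' Orders the bootstrap replicates by their angle on the
#' cost-effectiveness plane (counterclockwise from the positive-cost
#' axis, so dominated replicates sit at one end of the ordering and
#' dominant ones toward the other) and takes the alpha/2 and 1 - alpha/2
#' order statistics as confidence limits. A bound falling in the SE
#' quadrant is reported as "dominant" and in the NW quadrant as
#' "dominated"; otherwise its cost-effect ratio is reported. When the
#' replicates spread over all four quadrants the interval is flagged as
#' hard to interpret.
#'
#' @param dist a `bootstrap_distribution` (B >= 100 recommended).
#' @param alpha two-sided level (default 0.05).
#' @return list: `lower` and `upper` (each `label`, `value`,
#'   `delta_cost`, `delta_effect`), `spans_all_quadrants`, `alpha`, `B`.
#' @export
reordered_percentile_ci <- function(dist, alpha = 0.05) {
  r <- dist$replicates
  B <- nrow(r)
  key <- ce_angle(r$delta_cost, r$delta_effect)
  ord <- order(key)
  lo_i <- ord[max(1L, ceiling(B * alpha / 2))]
  hi_i <- ord[min(B, floor(B * (1 - alpha / 2)))]
  bound <- function(i) {
    ic <- icer_point(r$delta_cost[i], r$delta_effect[i])
    list(label = if (ic$kind == "ratio")
                   as.character(ic$value) else ic$kind,
         value = ic$value,
         delta_cost = r$delta_cost[i], delta_effect = r$delta_effect[i])
  }
  quads <- vapply(seq_len(B), function(i) {
    icer_point(r$delta_cost[i], r$delta_effect[i])$quadrant
  }, character(1))
  list(lower = bound(lo_i), upper = bound(hi_i),
       spans_all_quadrants = length(unique(quads)) == 4,
       alpha = alpha, B = B)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability of being
#' cost-effective is the fraction of bootstrap replicates with positive
#' net monetary benefit, lambda x delta_effect - delta_cost > 0 (strict:
#' ties count as not cost-effective). At lambda = 0 this is the fraction
#' of cost-saving replicates; as lambda grows it tends to the fraction
#' with positive incremental effect.
#'
#' @param dist a `bootstrap_distribution`.
#' @param grid willingness-to-pay thresholds, AUD per unit effect.
#' @return a `ceac_curve` tibble (`wtp`, `probability`).
#' @export
ceac <- function(dist, grid = seq(0, 100000, by = 1000)) {
  stopifnot(length(grid) >= 1)
  r <- dist$replicates
  p <- vapply(grid, function(l) {
    mean(l * r$delta_effect - r$delta_cost > 0)
  }, numeric(1))
  structure(tibble::tibble(wtp = grid, probability = p),
            effect_kind = dist$effect_kind, B = dist$B,
            class = c("ceac_curve", class(tibble::tibble())))
}

#' Export the cost-effectiveness plane points
#'
#' Lossless table of the B bootstrapped (delta_effect, delta_cost) points
#' (effect on the abscissa, cost on the ordinate) with the point estimate
#' attached as an attribute.
#'
#' @param dist a `bootstrap_distribution`.
#' @return tibble with `delta_effect`, `delta_cost`.
#' @export
ce_plane_export <- function(dist) {
  out <- tibble::tibble(delta_effect = dist$replicates$delta_effect,
                        delta_cost = dist$replicates$delta_cost)
  attr(out, "point_estimate") <- dist$point_estimate
  out
}

#' Plot a cost-effectiveness plane
#'
#' @param dist a `bootstrap_distribution`.
#' @param wtp optional willingness-to-pay threshold drawn as a line
#'   through the origin.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(dist, wtp = NULL) {
  df <- ce_plane_export(dist)
  pt <- attr(df, "point_estimate")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_effect,
                                        y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::annotate("point", x = pt[["delta_effect"]],
                      y = pt[["delta_cost"]], colour = "red", size = 2) +
    ggplot2::labs(x = "Incremental effect", y = "Incremental cost (AUD)")
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(intercept = 0, slope = wtp,
                                  linetype = "dashed")
  }
  p
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve a `ceac_curve`.
#' @param headline optional threshold highlighted with a vertical line.
#' @return a ggplot object.
#' @export
plot_ceac <- function(curve, headline = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp,
                                           y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (AUD per unit effect)",
                  y = "Probability cost-effective")
  if (!is.null(headline)) {
    p <- p + ggplot2::geom_vline(xintercept = headline,
                                 linetype = "dashed")
  }
  p
}
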