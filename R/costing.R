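# Microcosting of intervention delivery and pricing of service use.
#
# Delivery resources are costed bottom-up: the website development and
# maintenance total is split across the three arms by fixed complexity
# shares; equipment (computer leases) and personnel line items are
# apportioned in proportion to arm size (n_arm / N). Line items are kept
# at full precision internally; printed values are rounded half-up to
# cents, per-participant averages half-up to whole dollars, and the
# overall total is the sum of the rounded arm totals (matching published
# microcosting tables, where columns are totalled before rounding but the
# grand total is the sum of the printed column totals).

#' Intervention resource ledger
#'
#' @param website_total website development and maintenance total, AUD.
#' @param website_shares per-arm complexity shares (sum to 1).
#' @param equipment_total computer-lease total, AUD, apportioned by arm
#'   size.
#' @param personnel data frame (`label`, `total`) of personnel line items,
#'   AUD, apportioned by arm size.
#' @param overhead_rate employer overhead fraction applied to wages.
#' @param overhead_applied if `TRUE` (default) the personnel totals are
#'   already overhead-inclusive; if `FALSE` they are raw wages and are
#'   multiplied by `1 + overhead_rate`.
#' @param arm_sizes randomized participants per arm.
#' @return an `intervention_ledger` list.
#' @export
intervention_ledger <- function(website_total,
                                website_shares,
                                equipment_total,
                                personnel,
                                overhead_rate = 0.25,
                                overhead_applied = TRUE,
                                arm_sizes) {
  stopifnot(length(website_shares) == 3, length(arm_sizes) == 3)
  if (abs(sum(website_shares) - 1) > 1e-9) {
    abort("website complexity shares must sum to 1")
  }
  personnel <- tibble::as_tibble(personnel)
  stopifnot(all(c("label", "total") %in% names(personnel)))
  if (website_total < 0 || equipment_total < 0 || any(personnel$total < 0)) {
    abort("ledger totals must be nonnegative")
  }
  if (any(arm_sizes <= 0)) abort("arm sizes must be positive")
  if (!overhead_applied) {
    personnel$total <- personnel$total * (1 + overhead_rate)
  }
  structure(list(website_total = website_total,
                 website_shares = website_shares,
                 equipment_total = equipment_total,
                 personnel = personnel,
                 overhead_rate = overhead_rate,
                 arm_sizes = as.integer(arm_sizes)),
            class = "intervention_ledger")
}

#' The trial's delivery-cost ledger
#'
#' Website total Aus $120,000 split 0.19 / 0.38 / 0.43 by intervention
#' complexity; desktop computer leases Aus $3,590.14; overhead-inclusive
#' personnel totals for forum monitoring (Aus $44,046.65), research
#' assistant debriefing (Aus $4,404.66) and supervisor debriefing
#' (Aus $8,015.85); arms of 102, 102 and 100 participants.
#'
#' @return an `intervention_ledger`.
#' @export
default_ledger <- function() {
  intervention_ledger(
    website_total = 120000,
    website_shares = c(0.19, 0.38, 0.43),
    equipment_total = 3590.14,
    personnel = tibble::tibble(
      label = c("Research assistant (monitoring)",
                "Research assistant (debriefing)",
                "Supervisor (debriefing)"),
      total = c(44046.65, 4404.66, 8015.85)),
    arm_sizes = c(102L, 102L, 100L))
}

#' Microcost intervention delivery across arms
#'
#' @param ledger an [intervention_ledger()].
#' @return an `arm_cost_breakdown`: `lines` (tibble of line items by arm,
#'   rounded to cents, with unrounded values retained in attribute
#'   `"unrounded"`), `arm_totals`, `overall_total` and `per_participant`
#'   (average per randomized participant, whole AUD).
#' @export
microcost_interventions <- function(ledger) {
  stopifnot(inherits(ledger, "intervention_ledger"))
  n <- ledger$arm_sizes
  N <- sum(n)
  if (N <= 0) abort("zero total participants")
  frac <- n / N

  items <- c("Website development and maintenance",
             "Desktop computers", ledger$personnel$label)
  raw <- rbind(ledger$website_total * ledger$website_shares,
               ledger$equipment_total * frac,
               t(vapply(ledger$personnel$total, function(tt) tt * frac,
                        numeric(3))))
  rownames(raw) <- items

  arm_totals <- round_half_up(colSums(raw), 2)
  overall_total <- sum(arm_totals)
  per_participant <- round_half_up(arm_totals / n, 0)
  overall_avg <- round_half_up(overall_total / N, 0)

  lines <- tibble::tibble(
    item = items,
    arm1 = unname(round_half_up(raw[, 1], 2)),
    arm2 = unname(round_half_up(raw[, 2], 2)),
    arm3 = unname(round_half_up(raw[, 3], 2)))
  lines$overall <- unname(round_half_up(rowSums(raw), 2))

  structure(list(lines = lines,
                 arm_totals = arm_totals,
                 overall_total = overall_total,
                 per_participant = per_participant,
                 overall_per_participant = overall_avg,
                 arm_sizes = n),
            unrounded = raw,
            class = "arm_cost_breakdown")
}

#' @export
print.arm_cost_breakdown <- function(x, ...) {
  cat("Intervention delivery cost breakdown (AUD)\n")
  print(as.data.frame(x$lines))
  cat("Arm totals: ", paste(format(x$arm_totals, nsmall = 2),
                            collapse = "  "), "\n")
  cat("Overall total:", format(x$overall_total, nsmall = 2), "\n")
  cat("Average per randomized participant:",
      paste(x$per_participant, collapse = " / "),
      "(overall", paste0(x$overall_per_participant, ")"), "\n")
  invisible(x)
}

#' Price self-reported service use
#'
#' Multiplies each `svc_*` count column by its unit cost and sums to a
#' per-record health-sector cost. A record whose counts are missing (the
#' questionnaire was not returned) gets a missing cost, never zero; a
#' returned questionnaire with no services costs 0.
#'
#' @param data a `trial_data` with `svc_*` columns.
#' @param prices a [unit_cost_table()] covering every `svc_*` category.
#' @return `data` with `cost_aud` filled in.
#' @export
cost_service_use <- function(data, prices) {
  svc <- service_columns(data)
  if (length(svc) == 0) abort("no `svc_*` service-use columns found")
  cats <- sub("^svc_", "", svc)
  missing_price <- setdiff(cats, prices$category)
  if (length(missing_price) > 0) {
    abort(paste0("no unit cost for service category: ",
                 paste(missing_price, collapse = ", ")))
  }
  p <- setNames(prices$unit_cost_aud, prices$category)[cats]
  counts <- as.matrix(data[, svc])
  cost <- as.numeric(counts %*% p)
  cost[!complete.cases(counts)] <- NA_real_
  data$cost_aud <- cost
  data
}

#' Per-participant cost, QALY and MADRS summary
#'
#' Builds the participant-level analysis table: baseline covariates,
#' per-wave service costs and utilities, the arm's per-capita delivery
#' cost (attached at the 3-month wave, the first follow-up after
#' randomization), the 3-12-month health-sector total (missing unless all
#' four follow-up waves are observed, the base-case complete-sum rule),
#' the 12-month QALY (missing unless all five waves are observed), the
#' 12-month MADRS score, and completeness flags. Baseline cost is excluded
#' from totals but kept as an adjustment covariate.
#'
#' @param data a priced `trial_data`.
#' @param breakdown an [microcost_interventions()] result supplying the
#'   per-arm delivery cost; `NULL` for zero delivery cost.
#' @return a tibble, one row per participant.
#' @export
participant_summary <- function(data, breakdown = NULL) {
  delivery <- if (is.null(breakdown)) c(0, 0, 0) else
    breakdown$per_participant
  sched <- attr(data, "wave_schedule") %||% WAVE_SCHEDULE
  base_wave <- sched[1]
  fup <- setdiff(sched, base_wave)

  wide_cost <- tidyr::pivot_wider(
    data[, c("participant_id", "wave", "cost_aud")],
    names_from = "wave", values_from = "cost_aud", names_prefix = "cost_")
  wide_util <- tidyr::pivot_wider(
    data[, c("participant_id", "wave", "utility")],
    names_from = "wave", values_from = "utility", names_prefix = "util_")
  wide_madrs <- tidyr::pivot_wider(
    data[, c("participant_id", "wave", "madrs")],
    names_from = "wave", values_from = "madrs", names_prefix = "madrs_")

  base <- dplyr::distinct(data[, c("participant_id", "arm", "sex",
                                   "country")])
  out <- base %>%
    left_join(wide_cost, by = "participant_id") %>%
    left_join(wide_util, by = "participant_id") %>%
    left_join(wide_madrs, by = "participant_id")

  cost_cols <- paste0("cost_", fup)
  util_cols <- paste0("util_", sched)
  out$delivery_cost <- delivery[out$arm]
  svc_total <- rowSums(out[, cost_cols])
  out$total_3_12 <- out$delivery_cost + svc_total  # NA when any wave missing
  out$qaly <- qaly_auc(as.matrix(out[, util_cols]), schedule = sched)
  out$madrs_12 <- out[[paste0("madrs_", max(sched))]]
  out$baseline_cost <- out[[paste0("cost_", base_wave)]]
  out$baseline_utility <- out[[paste0("util_", base_wave)]]
  out$baseline_madrs <- out[[paste0("madrs_", base_wave)]]
  out$complete_cost <- !is.na(svc_total)
  out$complete_qaly <- !is.na(out$qaly)
  out$sexm <- as.integer(out$sex == "male")
  out$cty_au <- as.integer(out$country == "Australia")
  out$cty_other <- as.integer(out$country == "other")
  # plain tibble: one row per participant, no longer trial_data
  class(out) <- class(tibble::tibble())
  out
}

#' Threshold delivery cost equalizing two arms' mean totals
#'
#' Solves for the delivery cost c* of arm b at which its mean 3-12-month
#' total equals arm a's: c* = current delivery cost + (mean_a - mean_b).
#' Any mean-difference estimator may be supplied in place of the raw
#' complete-case means (e.g. an adjusted model estimate).
#'
#' @param arm_a_totals,arm_b_totals complete 3-12-month totals (including
#'   current delivery cost) for the two arms; ignored when `mean_diff` is
#'   given.
#' @param delivery_cost_b arm b's current per-participant delivery cost.
#' @param mean_diff optional externally estimated mean_a - mean_b.
#' @return threshold delivery cost c*, AUD.
#' @export
threshold_intervention_cost <- function(arm_a_totals = NULL,
                                        arm_b_totals = NULL,
                                        delivery_cost_b,
                                        mean_diff = NULL) {
  if (is.null(mean_diff)) {
    a <- arm_a_totals[!is.na(arm_a_totals)]
    b <- arm_b_totals[!is.na(arm_b_totals)]
    if (length(a) == 0 || length(b) == 0) {
      abort("no complete totals in one of the arms")
    }
    mean_diff <- mean(a) - mean(b)
  }
  delivery_cost_b + mean_diff
}

#' Population-rollout per-user delivery cost
#'
#' Scales the fixed website cost over all potential users nationwide
#' (population stratum counts x diagnosis prevalence x the fraction using
#' health services for their mental health) and adds the per-participant
#' variable cost (equipment and personnel) unchanged.
#'
#' @param ledger an [intervention_ledger()].
#' @param population vector (or single total) of population stratum
#'   counts.
#' @param prevalence diagnosis prevalence (default 0.741%).
#' @param service_use_fraction fraction of diagnosed people using services
#'   for their mental health (default 67.7%).
#' @return list with `users` and `per_user_cost` (by arm, AUD).
#' @export
population_rollout_cost <- function(ledger, population,
                                    prevalence = 0.00741,
                                    service_use_fraction = 0.677) {
  if (any(population <= 0)) abort("population counts must be positive")
  users <- sum(population * prevalence * service_use_fraction)
  if (users <= 0) abort("zero potential users")
  fixed_per_user <- ledger$website_total * ledger$website_shares / users
  variable_per_participant <-
    (ledger$equipment_total + sum(ledger$personnel$total)) /
    sum(ledger$arm_sizes)
  list(users = users,
       fixed_per_user = fixed_per_user,
       variable_per_participant = variable_per_participant,
       per_user_cost = fixed_per_user + variable_per_participant)
}
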