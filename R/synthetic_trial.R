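# Synthetic three-arm trial generator.
#
# Emulates the statistical structure the downstream analysis assumes: three
# arms of 102/102/100 participants, right-skewed quarterly health-sector
# costs with SDs up to about twice their means, SF-6D utilities near 0.63
# at baseline with small arm drifts, a MADRS advantage for the
# psychoeducation arm, and missing-at-random loss to follow-up driven by
# sex and wave with completion falling to about 29% by 12 months.
#
# Service costs are generated as gamma-mixed Poisson counts: a gamma latent
# intensity (mean = the target category cost, shape controlling skew) is
# divided by the unit price and fed to a Poisson draw. Counts stay integer,
# priced cost equals count x unit price exactly, and the expected cost
# equals the gamma mean, so planted between-arm cost differences are exact
# in expectation while retaining the heavy right skew seen in such data.

#' Default unit-cost table for synthetic data
#'
#' Four Cornell-style service groupings (medical, psychological, acute
#' care, support) with illustrative 2018-19 AUD costs per occasion of
#' service. Real analyses supply their own table via [read_unit_costs()].
#'
#' @return a `unit_cost_table`.
#' @export
default_unit_costs <- function() {
  unit_cost_table(c(medical = 120, psychological = 200,
                    acute = 1100, support = 55))
}

#' Simulation scenario for the synthetic trial
#'
#' All defaults encode the study conditions the generator emulates; see
#' [default_scenario()] for their provenance. Gamma shapes for the cost
#' model, when not supplied, are solved from the per-arm 3-12-month total
#' cost SD targets so that generated totals match both the target means
#' and spreads.
#'
#' @param arm_sizes three positive integers.
#' @param cost_model list: `unit_costs` (a [unit_cost_table()]),
#'   `category_share` (3 x category matrix of within-arm cost shares),
#'   `wave_mean_total` (per-arm mean service cost per follow-up wave),
#'   `baseline_mean_total` (pre-randomization mean, common to arms),
#'   `total_sd_target` (per-arm SD of the 4-wave total) and optionally
#'   `shape` (per-arm gamma shape overriding the SD calibration).
#' @param utility_model list: `baseline_mean`, `baseline_sd`, `wave_sd`,
#'   and `drift`, a 3 x 4 matrix of per-arm additive utility drifts at the
#'   follow-up waves.
#' @param madrs_model list: `baseline_mean`, `baseline_sd`, `slope`
#'   (tracking of baseline severity into follow-up), `wave_sd`,
#'   `control_means` (4 follow-up means for arm 1) and `advantage`
#'   (3 x 4 matrix of score reductions relative to arm 1; positive =
#'   fewer symptoms than control).
#' @param missingness list: `completion_target` (named per-wave marginal
#'   completion fractions), `sex_or_female` (completion odds ratio for
#'   women vs men), `arm_effect` (3 log-odds offsets, default 0),
#'   `engagement_sd` (SD of a participant-level completion intercept that
#'   makes wave completion strongly correlated within participant, as
#'   observed; 0 for independent waves) and `monotone` (drop all later
#'   waves after the first missing one).
#' @param sex_fraction fraction of women.
#' @param country_probs national origin probabilities (US, Australia,
#'   other); normalized to sum to 1.
#' @param seed integer seed; each arm uses an independent substream so
#'   changing one arm's parameters leaves the others' draws unchanged.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(arm_sizes = c(102L, 102L, 100L),
                         cost_model = NULL,
                         utility_model = NULL,
                         madrs_model = NULL,
                         missingness = NULL,
                         sex_fraction = 0.82,
                         country_probs = c(US = 0.385, Australia = 0.335,
                                           other = 0.28),
                         seed = 1L) {
  stopifnot(length(arm_sizes) == 3, all(arm_sizes > 0))

  cost_defaults <- list(
    unit_costs = default_unit_costs(),
    category_share = rbind(
      c(medical = 0.22, psychological = 0.28, acute = 0.41, support = 0.09),
      c(medical = 0.33, psychological = 0.45, acute = 0.115, support = 0.105),
      c(medical = 0.22, psychological = 0.28, acute = 0.41, support = 0.09)),
    wave_mean_total = c(3688.5, 2196.5, 3701),
    baseline_mean_total = 3688.5,
    total_sd_target = c(17206, 8540, 30523),
    shape = NULL)
  cost_model <- modifyList(cost_defaults, cost_model %||% list())

  # Per-wave QALY weight of a constant follow-up drift is 0.875 (trapezoid
  # weights 0.25, 0.25, 0.25, 0.125), so drift d plants a QALY difference
  # of 0.875 d.
  utility_defaults <- list(
    baseline_mean = 0.63, baseline_sd = 0.08, wave_sd = 0.05,
    drift = rbind(rep(0, 4),
                  rep(0.012 / 0.875, 4),
                  rep(0.002 / 0.875, 4)))
  utility_model <- modifyList(utility_defaults, utility_model %||% list())

  madrs_defaults <- list(
    baseline_mean = 20, baseline_sd = 6, slope = 0.5, wave_sd = 5,
    control_means = c(19, 18.5, 18.5, 18),
    advantage = rbind(rep(0, 4),
                      c(4, 5.5, 3.6, 3.8),
                      c(1.1, 4.8, 2.5, 3.6)))
  madrs_model <- modifyList(madrs_defaults, madrs_model %||% list())

  miss_defaults <- list(
    completion_target = c(`3` = 0.395, `6` = 0.339, `9` = 0.355,
                          `12` = 0.293),
    sex_or_female = 0.6,
    arm_effect = c(0, 0, 0),
    engagement_sd = 4,
    monotone = FALSE)
  missingness <- modifyList(miss_defaults, missingness %||% list())

  if (any(cost_model$wave_mean_total <= 0) ||
      cost_model$baseline_mean_total <= 0) {
    abort("cost model means must be positive")
  }
  if (utility_model$baseline_sd <= 0 && utility_model$wave_sd <= 0) {
    abort("degenerate utility model: zero variance everywhere")
  }

  country_probs <- country_probs / sum(country_probs)
  structure(list(arm_sizes = as.integer(arm_sizes),
                 cost_model = cost_model,
                 utility_model = utility_model,
                 madrs_model = madrs_model,
                 missingness = missingness,
                 sex_fraction = sex_fraction,
                 country_probs = country_probs,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' The default synthetic scenario
#'
#' Encodes the published study conditions: arms of 102/102/100; 82% women;
#' national origin 38.5% US / 33.5% Australia / 28% other; baseline SF-6D
#' utility mean 0.63; a constant arm-2 utility drift planting a 12-month
#' QALY gain of 0.012 (arm 3: 0.002); MADRS advantages for arm 2 of
#' 4/5.5/3.6/3.8 points at the four follow-ups; per-arm 3-12-month mean
#' service costs of Aus $14,754 / $8,786 / $14,804 with total-cost SD
#' targets 17,206 / 8,540 / 30,523; and MAR wave completion targeting
#' 39.5/33.9/35.5/29.3% at months 3/6/9/12 with a female completion odds
#' ratio of 0.6.
#'
#' @param seed integer seed.
#' @return a `sim_scenario`.
#' @export
default_scenario <- function(seed = 1L) sim_scenario(seed = seed)

arm_seed <- function(seed, arm, salt = 0L) {
  as.integer((as.numeric(seed) * 31 + arm * 1000003 + salt * 7919) %%
               2147483629)
}

# Solve per-arm gamma shape from the total-SD target:
#   per-wave var = sum_c m_c^2 / s + sum_c price_c m_c   (gamma-Poisson)
#   total var over 4 independent waves = 4 x per-wave var.
cost_shapes <- function(cost_model) {
  if (!is.null(cost_model$shape)) return(cost_model$shape)
  prices <- setNames(cost_model$unit_costs$unit_cost_aud,
                     cost_model$unit_costs$category)
  vapply(1:3, function(a) {
    share <- cost_model$category_share[a, ]
    m <- cost_model$wave_mean_total[a] * share
    p <- prices[colnames(cost_model$category_share) %||% names(share)]
    v_wave <- cost_model$total_sd_target[a]^2 / 4
    denom <- v_wave - sum(p * m)
    if (denom <= 0) abort("total SD target too small for Poisson pricing noise")
    sum(m^2) / denom
  }, numeric(1))
}

#' Generate a complete synthetic trial dataset
#'
#' Deterministic given the scenario seed; no missingness (apply the MAR
#' mechanism separately with [apply_missingness()]). Each arm is generated
#' from its own random substream.
#'
#' @param scenario a [sim_scenario()].
#' @return a `trial_data` tibble with `svc_*` counts, priced `cost_aud`,
#'   `utility` and `madrs` at every wave.
#' @export
generate_trial <- function(scenario = default_scenario()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  cm <- scenario$cost_model
  um <- scenario$utility_model
  mm <- scenario$madrs_model
  prices <- setNames(cm$unit_costs$unit_cost_aud, cm$unit_costs$category)
  cats <- colnames(cm$category_share)
  shapes <- cost_shapes(cm)
  waves <- FOLLOWUP_WAVES

  arms <- lapply(1:3, function(a) {
    set.seed(arm_seed(scenario$seed, a))
    n <- scenario$arm_sizes[a]
    id <- sprintf("A%dP%04d", a, seq_len(n))
    sex <- ifelse(runif(n) < scenario$sex_fraction, "female", "male")
    country <- sample(names(scenario$country_probs), n, replace = TRUE,
                      prob = scenario$country_probs)
    u0 <- pmin(1, pmax(0, rnorm(n, um$baseline_mean, um$baseline_sd)))
    m0 <- pmin(60, pmax(0, rnorm(n, mm$baseline_mean, mm$baseline_sd)))

    draw_counts <- function(mean_total, share, shape) {
      out <- sapply(cats, function(cc) {
        m <- mean_total * share[cc]
        if (m <= 0) return(rep(0L, n))
        lam <- rgamma(n, shape = shape, scale = m / shape) / prices[cc]
        rpois(n, lam)
      })
      matrix(out, nrow = n, dimnames = list(NULL, cats))
    }

    rows <- vector("list", length(WAVE_SCHEDULE))
    for (wi in seq_along(WAVE_SCHEDULE)) {
      w <- WAVE_SCHEDULE[wi]
      if (w == 0) {
        counts <- draw_counts(cm$baseline_mean_total,
                              cm$category_share[1, ], shapes[1])
        utility <- u0
        madrs <- m0
      } else {
        k <- match(w, waves)
        counts <- draw_counts(cm$wave_mean_total[a],
                              cm$category_share[a, ], shapes[a])
        utility <- pmin(1, pmax(0, u0 + um$drift[a, k] +
                                  rnorm(n, 0, um$wave_sd)))
        madrs <- pmin(60, pmax(0, mm$control_means[k] +
                                 mm$slope * (m0 - mm$baseline_mean) -
                                 mm$advantage[a, k] +
                                 rnorm(n, 0, mm$wave_sd)))
      }
      cost <- as.numeric(counts %*% prices[cats])
      df <- tibble::tibble(participant_id = id, arm = a, sex = sex,
                           country = country, wave = w)
      for (cc in cats) df[[paste0("svc_", cc)]] <- as.integer(counts[, cc])
      df$cost_aud <- cost
      df$utility <- utility
      df$madrs <- madrs
      rows[[wi]] <- df
    }
    dplyr::bind_rows(rows)
  })

  as_trial_data(dplyr::bind_rows(arms))
}

#' Generate synthetic SF-12 level profiles
#'
#' Draws random health-state profiles over the six SF-6D dimensions of a
#' scoring model and scores them, for exercising the table-driven scoring
#' path (utilities in [generate_trial()] are otherwise drawn directly).
#'
#' @param n number of profiles.
#' @param model an [sf6d_model()]; defaults to the synthetic toy table.
#' @param seed integer seed.
#' @return tibble of dimension levels plus the scored `utility`.
#' @export
generate_sf12_profiles <- function(n, model = sf6d_toy_model(),
                                   seed = 1L) {
  set.seed(seed)
  dims <- unique(model$decrements$dimension)
  out <- tibble::as_tibble(setNames(lapply(dims, function(d) {
    sample.int(model$worst_levels[[d]], n, replace = TRUE)
  }), dims))
  out$utility <- vapply(seq_len(n), function(i) {
    score_sf6d(unlist(out[i, dims]), model)
  }, numeric(1))
  out
}

solve_completion_intercept <- function(target, female_frac, beta_female,
                                       engagement_sd = 0) {
  # marginal completion integrates over the participant engagement
  # intercept (quadrature on a +/- 5 SD grid)
  if (engagement_sd > 0) {
    u <- seq(-5, 5, length.out = 61) * engagement_sd
    w <- stats::dnorm(u, 0, engagement_sd)
    w <- w / sum(w)
  } else {
    u <- 0; w <- 1
  }
  if (target >= 1 - 1e-12) return(36)   # saturates: completion certain
  if (target <= 0) abort("completion target must be positive")
  uniroot(function(a) {
    sum(w * (female_frac * plogis(a + beta_female + u) +
               (1 - female_frac) * plogis(a + u))) - target
  }, interval = c(-30, 30))$root
}

#' Apply the missing-at-random wave-completion mechanism
#'
#' Post-baseline waves are marked missing (service counts, cost, utility
#' and MADRS set to `NA`) according to a logistic model of wave completion
#' on sex and wave (and optionally arm). Baseline is never removed, and
#' the deletion decisions never read any outcome value, so the mechanism
#' is MAR by construction. The realized per-wave completion fractions are
#' attached as attribute `"completion_realized"`.
#'
#' @param data a complete `trial_data`.
#' @param scenario the [sim_scenario()] holding the mechanism and seed.
#' @return `trial_data` with explicit wave-level missingness.
#' @export
apply_missingness <- function(data, scenario) {
  mi <- scenario$missingness
  beta_f <- log(mi$sex_or_female)
  sd_u <- mi$engagement_sd %||% 0
  targets <- mi$completion_target
  intercepts <- vapply(targets, solve_completion_intercept,
                       numeric(1),
                       female_frac = scenario$sex_fraction,
                       beta_female = beta_f,
                       engagement_sd = sd_u)

  set.seed(arm_seed(scenario$seed, 0L, salt = 104729L))
  x <- data
  ids <- unique(x$participant_id)
  engagement <- setNames(rnorm(length(ids), 0, sd_u), ids)
  follow <- x$wave != attr(data, "wave_schedule")[1]
  eta <- intercepts[as.character(x$wave[follow])] +
    beta_f * (x$sex[follow] == "female") +
    mi$arm_effect[x$arm[follow]] +
    engagement[x$participant_id[follow]]
  p <- pmin(1, pmax(1e-12, plogis(eta)))
  complete <- runif(sum(follow)) < p

  if (isTRUE(mi$monotone)) {
    keymat <- tibble::tibble(id = x$participant_id[follow],
                             wave = x$wave[follow], complete = complete)
    keymat <- keymat[order(keymat$id, keymat$wave), ]
    keep <- unlist(lapply(split(keymat$complete, keymat$id),
                          function(z) cumprod(z) > 0), use.names = FALSE)
    ord <- order(order(x$participant_id[follow], x$wave[follow]))
    complete <- keep[ord]
  }

  measure_cols <- c(service_columns(x), "cost_aud", "utility", "madrs")
  measure_cols <- intersect(measure_cols, names(x))
  idx <- which(follow)[!complete]
  for (col in measure_cols) x[[col]][idx] <- NA

  realized <- tapply(complete, x$wave[follow], mean)
  attr(x, "completion_realized") <- realized
  x
}
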