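# Input/output, validation, and run configuration.
#
# The canonical container is a long participant-wave tibble of class
# "trial_data": one row per participant per assessment wave, with service
# use counts in `svc_*` columns, priced cost in `cost_aud`, SF-6D utility
# in `utility` and depression severity in `madrs`. Missingness is explicit
# (NA), never encoded as zero.

#' Construct and validate a trial dataset
#'
#' Validates a long participant-wave table and returns it as a
#' `trial_data` tibble. Required columns: `participant_id`, `arm` (1, 2 or
#' 3), `sex` ("female"/"male"), `country` ("US"/"Australia"/"other"),
#' `wave` (months, within the schedule). Optional measurement columns:
#' `svc_*` service-use counts, `cost_aud`, `utility`, `madrs`.
#'
#' Validation is total: every malformed row is reported with its row
#' number and the offending field; no bad row can enter silently.
#'
#' @param records data frame in long participant-wave format.
#' @param wave_schedule assessment months; defaults to 0, 3, 6, 9, 12.
#' @param arm_labels named character vector labelling arm codes.
#' @return a `trial_data` tibble.
#' @export
as_trial_data <- function(records,
                          wave_schedule = WAVE_SCHEDULE,
                          arm_labels = ARM_LABELS) {
  x <- tibble::as_tibble(records)
  required <- c("participant_id", "arm", "sex", "country", "wave")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("trial data is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  x$participant_id <- as.character(x$participant_id)
  x$arm <- as.integer(x$arm)
  x$wave <- as.integer(x$wave)

  problems <- character()
  bad <- which(!(x$arm %in% as.integer(names(arm_labels))))
  if (length(bad) > 0) {
    problems <- c(problems, paste0(
      "row ", bad[1], ": unknown arm code '", x$arm[bad[1]], "'",
      if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)")))
  }
  bad <- which(!(x$wave %in% wave_schedule))
  if (length(bad) > 0) {
    problems <- c(problems, paste0(
      "row ", bad[1], ": wave ", x$wave[bad[1]],
      " outside schedule {", paste(wave_schedule, collapse = ","), "}",
      if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)")))
  }
  dup <- duplicated(x[, c("participant_id", "wave")])
  if (any(dup)) {
    i <- which(dup)[1]
    problems <- c(problems, paste0(
      "duplicate (participant, wave): (", x$participant_id[i], ", ",
      x$wave[i], ")",
      if (sum(dup) > 1) paste0(" (and ", sum(dup) - 1, " more)")))
  }

  if ("utility" %in% names(x)) {
    bad <- which(!is.na(x$utility) & (x$utility < 0 | x$utility > 1))
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "row ", bad[1], ": utility ", x$utility[bad[1]],
        " outside [0, 1]"))
    }
  }
  if ("madrs" %in% names(x)) {
    bad <- which(!is.na(x$madrs) & (x$madrs < 0 | x$madrs > 60))
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "row ", bad[1], ": MADRS score ", x$madrs[bad[1]],
        " outside [0, 60]"))
    }
  }
  if ("cost_aud" %in% names(x)) {
    bad <- which(!is.na(x$cost_aud) & x$cost_aud < 0)
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "row ", bad[1], ": negative cost ", x$cost_aud[bad[1]]))
    }
  }
  for (sc in service_columns(x)) {
    v <- x[[sc]]
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "row ", bad[1], ": ", sc, " = ", v[bad[1]],
        " is not a nonnegative integer count"))
    }
  }

  no_baseline <- setdiff(unique(x$participant_id),
                         x$participant_id[x$wave == wave_schedule[1]])
  if (length(no_baseline) > 0) {
    problems <- c(problems, paste0(
      "participant(s) without a baseline (wave ", wave_schedule[1],
      ") record: ", paste(head(no_baseline, 3), collapse = ", "),
      if (length(no_baseline) > 3) " ..."))
  }

  if (length(problems) > 0) {
    abort(paste0("invalid trial data:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }

  x <- dplyr::arrange(x, .data$participant_id, .data$wave)
  structure(x,
            wave_schedule = wave_schedule,
            arm_labels = arm_labels,
            class = c("trial_data", class(tibble::tibble())))
}

service_columns <- function(x) grep("^svc_", names(x), value = TRUE)

#' Read a long-format trial dataset from CSV
#'
#' One participant-wave per row with a header. Empty cells become explicit
#' missing values (never zeros). Rows failing validation are reported with
#' row-level diagnostics.
#'
#' @param path CSV file path.
#' @inheritParams as_trial_data
#' @return a `trial_data` tibble.
#' @export
read_trial_long <- function(path, wave_schedule = WAVE_SCHEDULE) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trial_data(x, wave_schedule = wave_schedule)
}

#' Construct a unit-cost table
#'
#' Maps each service category to its cost per occasion of service in
#' 2018-19 Australian dollars. The US-dollar exchange rate (Aus $1 =
#' US $0.7058) is carried as metadata only and never used in computation.
#'
#' @param entries named numeric vector or two-column data frame
#'   (`category`, `unit_cost_aud`) of positive unit costs.
#' @param currency_year metadata string.
#' @return a `unit_cost_table` tibble.
#' @export
unit_cost_table <- function(entries, currency_year = "2018-19 AUD") {
  if (is.numeric(entries) && !is.null(names(entries))) {
    entries <- tibble::tibble(category = names(entries),
                              unit_cost_aud = unname(entries))
  }
  x <- tibble::as_tibble(entries)
  if (!all(c("category", "unit_cost_aud") %in% names(x))) {
    abort("unit cost table needs columns `category` and `unit_cost_aud`")
  }
  if (anyDuplicated(x$category)) {
    abort(paste0("duplicate service category: ",
                 x$category[duplicated(x$category)][1]))
  }
  bad <- which(is.na(x$unit_cost_aud) | x$unit_cost_aud <= 0)
  if (length(bad) > 0) {
    abort(paste0("nonpositive unit cost for category '",
                 x$category[bad[1]], "'"))
  }
  structure(x,
            currency_year = currency_year,
            fx_note = "Aus $1 = US $0.7058 (metadata only)",
            class = c("unit_cost_table", class(tibble::tibble())))
}

#' Read a unit-cost table from CSV
#'
#' @param path two-column CSV (`category`, `unit_cost_aud`).
#' @return a `unit_cost_table` tibble.
#' @export
read_unit_costs <- function(path) {
  unit_cost_table(readr::read_csv(path, show_col_types = FALSE,
                                  progress = FALSE))
}

#' Analysis configuration
#'
#' Holds the run parameters shared across the pipeline: bootstrap size,
#' willingness-to-pay grid, a priori adjustment covariates (baseline value
#' of the outcome, sex, national origin), analysis mode, and the seed that
#' makes every resampling step reproducible.
#'
#' @param bootstrap_B bootstrap iterations (default 1000).
#' @param alpha two-sided significance level.
#' @param wtp_grid ascending willingness-to-pay grid in AUD per unit
#'   effect; default 0 to 100,000 by 1,000.
#' @param wtp_headline the headline threshold (default Aus $50,000/QALY);
#'   must lie on the grid.
#' @param seed integer seed.
#' @param analysis_mode one of `"base_case"`, `"complete_case"`,
#'   `"multiple_imputation"`, `"population_cost"`.
#' @param mi_cycles chained-equation cycles for imputation (default 10).
#' @param mi_donors predictive-mean-matching donor pool size (default 5).
#' @param glm_zero_policy how identity-link gamma/inverse-Gaussian fits
#'   treat nonpositive outcomes: `"half_min_shift"` adds half the smallest
#'   positive observed value, `"gaussian_fallback"` refits with a gaussian
#'   family.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(bootstrap_B = 1000,
                            alpha = 0.05,
                            wtp_grid = seq(0, 100000, by = 1000),
                            wtp_headline = 50000,
                            seed = 1L,
                            analysis_mode = c("base_case", "complete_case",
                                              "multiple_imputation",
                                              "population_cost"),
                            mi_cycles = 10L,
                            mi_donors = 5L,
                            glm_zero_policy = c("half_min_shift",
                                                "gaussian_fallback")) {
  analysis_mode <- match.arg(analysis_mode)
  glm_zero_policy <- match.arg(glm_zero_policy)
  stopifnot(bootstrap_B >= 1, alpha > 0, alpha < 1,
            length(wtp_grid) >= 1, !is.unsorted(wtp_grid),
            mi_cycles >= 1, mi_donors >= 1)
  if (!wtp_headline %in% wtp_grid) {
    abort("`wtp_headline` must be a point on `wtp_grid`")
  }
  cfg <- list(bootstrap_B = as.integer(bootstrap_B), alpha = alpha,
              wtp_grid = wtp_grid, wtp_headline = wtp_headline,
              seed = as.integer(seed),
              covariates = c("baseline", "sex", "country"),
              analysis_mode = analysis_mode,
              mi_cycles = as.integer(mi_cycles),
              mi_donors = as.integer(mi_donors),
              glm_zero_policy = glm_zero_policy)
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [analysis_config()]; the
#' willingness-to-pay grid may be given as `wtp_grid: {from, to, by}` or
#' as an explicit list.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$wtp_grid)) {
    if (is.list(y$wtp_grid)) {
      y$wtp_grid <- seq(y$wtp_grid$from, y$wtp_grid$to,
                        by = y$wtp_grid$by)
    }
    y$wtp_grid <- as.numeric(y$wtp_grid)
  }
  known <- intersect(names(y), names(formals(analysis_config)))
  do.call(analysis_config, y[known])
}

#' Read an intervention resource ledger from a YAML file
#'
#' Keys mirror [intervention_ledger()]; `personnel` is a list of
#' `{label, total}` entries.
#'
#' @param path YAML file.
#' @return an `intervention_ledger`.
#' @export
read_intervention_ledger <- function(path) {
  y <- yaml::read_yaml(path)
  personnel <- dplyr::bind_rows(lapply(y$personnel, tibble::as_tibble))
  intervention_ledger(
    website_total = y$website_total,
    website_shares = unlist(y$website_shares),
    equipment_total = y$equipment_total,
    personnel = personnel,
    overhead_rate = y$overhead_rate %||% 0.25,
    overhead_applied = y$overhead_applied %||% TRUE,
    arm_sizes = unlist(y$arm_sizes))
}

#' Hash a configuration (or any R object) for run manifests
#'
#' @param x object to fingerprint.
#' @return a short hash string.
#' @export
config_hash <- function(x) rlang::hash(x)

#' Write a result table with provenance metadata
#'
#' Writes a flat table as CSV preceded by `#`-prefixed metadata lines
#' carrying the run seed and configuration hash, so that every output can
#' be traced to the run that produced it. [read_results()] round-trips
#' values at full stored precision.
#'
#' @param x data frame to write.
#' @param path output path.
#' @param seed seed recorded in the header (optional).
#' @param config `analysis_config` (or any object) whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, seed = NULL, config = NULL) {
  meta <- c(
    paste0("# written_by: trialcea ",
           as.character(utils::packageVersion("trialcea"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config)) paste0("# config_hash: ", config_hash(config))
  )
  body <- readr::format_csv(as.data.frame(x))
  writeLines(c(meta, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path file written by [write_results()].
#' @return tibble with the stored values at full precision.
#' @export
read_results <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
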