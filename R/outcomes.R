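# Health outcomes: SF-6D utility scoring and QALYs.
#
# The SF-6D classifies health on six dimensions (physical functioning,
# role limitation, social functioning, pain, mental health, vitality)
# derived from the SF-12, and scores a state as 1 minus the sum of
# level-specific utility decrements, minus an additional "most severe"
# term when any dimension sits at its worst level, floored at the
# instrument's minimum. The published preference weights are licensed and
# not redistributed here: scoring is table-driven, the package ships a
# clearly-labelled synthetic toy table for tests, and users supply the
# licensed decrement table via CSV.

#' SF-6D scoring model
#'
#' @param decrements data frame (`dimension`, `level`, `decrement`) with
#'   decrement 0 at level 1 of every dimension and nonnegative decrements
#'   elsewhere.
#' @param most_severe_term decrement applied once when any dimension is at
#'   its worst (highest) level; set 0 to disable.
#' @param floor minimum achievable utility.
#' @return an `sf6d_model` list.
#' @export
sf6d_model <- function(decrements, most_severe_term = 0, floor = 0.29) {
  x <- tibble::as_tibble(decrements)
  stopifnot(all(c("dimension", "level", "decrement") %in% names(x)))
  if (any(x$decrement < 0)) abort("decrements must be nonnegative")
  lvl1 <- x$decrement[x$level == 1]
  if (any(lvl1 != 0)) abort("level 1 must carry decrement 0")
  if (most_severe_term < 0) abort("most severe term must be nonnegative")
  worst <- tapply(x$level, x$dimension, max)
  structure(list(decrements = x,
                 most_severe_term = most_severe_term,
                 floor = floor,
                 worst_levels = worst),
            class = "sf6d_model")
}

#' Read an SF-6D decrement table from CSV
#'
#' @param path CSV with columns `dimension`, `level`, `decrement`.
#' @inheritParams sf6d_model
#' @return an `sf6d_model`.
#' @export
read_sf6d_model <- function(path, most_severe_term = 0.061, floor = 0.29) {
  sf6d_model(readr::read_csv(path, show_col_types = FALSE,
                             progress = FALSE),
             most_severe_term = most_severe_term, floor = floor)
}

#' Synthetic toy SF-6D model for tests and examples
#'
#' A made-up decrement table with the structure of the real instrument
#' (six dimensions, 3-5 levels, a most-severe term, floor 0.29) but
#' fabricated weights. Not for real analyses.
#'
#' @return an `sf6d_model`.
#' @export
sf6d_toy_model <- function() {
  read_sf6d_model(system.file("extdata", "sf6d_toy_decrements_synthetic.csv",
                              package = "trialcea"),
                  most_severe_term = 0.061, floor = 0.29)
}

#' Score an SF-6D health-state profile
#'
#' @param profile named integer vector giving the level of each of the six
#'   dimensions, e.g. `c(PF = 1, RL = 2, SF = 1, PAIN = 3, MH = 1,
#'   VIT = 2)`.
#' @param model an [sf6d_model()].
#' @return utility in `[floor, 1]`.
#' @export
score_sf6d <- function(profile, model) {
  stopifnot(inherits(model, "sf6d_model"))
  dims <- unique(model$decrements$dimension)
  missing_dim <- setdiff(dims, names(profile))
  if (length(missing_dim) > 0) {
    abort(paste0("profile is missing dimension(s): ",
                 paste(missing_dim, collapse = ", ")))
  }
  dec <- 0
  for (d in dims) {
    lev <- profile[[d]]
    row <- model$decrements$dimension == d & model$decrements$level == lev
    if (!any(row)) {
      abort(paste0("unknown level ", lev, " for dimension ", d))
    }
    dec <- dec + model$decrements$decrement[row][1]
  }
  worst_hit <- any(vapply(dims, function(d) {
    profile[[d]] == model$worst_levels[[d]]
  }, logical(1)))
  u <- 1 - dec - if (worst_hit) model$most_severe_term else 0
  max(model$floor, u)
}

#' QALYs by the area-under-the-curve method
#'
#' Trapezoidal area under the piecewise-linear utility trajectory over the
#' 12-month horizon: with quarterly assessments each interval contributes
#' 0.25 x (u_t + u_t+1)/2 years. The base case requires all five waves;
#' any missing utility yields a missing QALY (imputation or modelling is
#' the caller's decision). Discounting is not applied (12-month horizon).
#'
#' @param utilities numeric vector of utilities at the scheduled waves, or
#'   a matrix with one trajectory per row.
#' @param schedule assessment months.
#' @return QALYs (years); same length as trajectories supplied.
#' @export
qaly_auc <- function(utilities, schedule = WAVE_SCHEDULE) {
  if (is.matrix(utilities)) {
    stopifnot(ncol(utilities) == length(schedule))
    w <- trapezoid_weights(schedule)
    return(as.numeric(utilities %*% w))
  }
  stopifnot(length(utilities) == length(schedule))
  sum(trapezoid_weights(schedule) * utilities)
}

trapezoid_weights <- function(schedule) {
  yrs <- diff(schedule) / 12
  w <- numeric(length(schedule))
  w[-length(w)] <- w[-length(w)] + yrs / 2
  w[-1] <- w[-1] + yrs / 2
  w
}

#' Between-arm effect difference conventions
#'
#' For QALYs the incremental effect is mean(arm) - mean(control): positive
#' favours the intervention. MADRS is scored so that lower is better, and
#' differences are expressed as the intervention's improvement over
#' control, so the incremental effect is mean(control) - mean(arm)
#' (applicable to raw follow-up scores or to change scores alike):
#' positive again favours the intervention.
#'
#' @param effect_kind `"qaly"` or `"madrs"`.
#' @param arm_values,control_values outcome values in the two groups.
#' @return the incremental effect, positive favouring the intervention.
#' @export
effect_difference <- function(effect_kind = c("qaly", "madrs"),
                              arm_values, control_values) {
  effect_kind <- match.arg(effect_kind)
  a <- arm_values[!is.na(arm_values)]
  c0 <- control_values[!is.na(control_values)]
  if (length(a) == 0 || length(c0) == 0) abort("empty group")
  if (effect_kind == "qaly") mean(a) - mean(c0) else mean(c0) - mean(a)
}
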