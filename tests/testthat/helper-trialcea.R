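# Shared fixtures, all built in code.

# Minimal deterministic three-arm trial frame: `n_per_arm` participants
# per arm, constant outcomes unless overridden.
make_trial_df <- function(n_per_arm = 4, waves = c(0, 3, 6, 9, 12),
                          cost = 100, utility = 0.6, madrs = 20) {
  ids <- sprintf("P%03d", seq_len(3 * n_per_arm))
  arm <- rep(1:3, each = n_per_arm)
  sex <- rep(c("female", "male"), length.out = length(ids))
  country <- rep(c("US", "Australia", "other"), length.out = length(ids))
  d <- expand.grid(participant_id = ids, wave = waves,
                   stringsAsFactors = FALSE)
  d$arm <- arm[match(d$participant_id, ids)]
  d$sex <- sex[match(d$participant_id, ids)]
  d$country <- country[match(d$participant_id, ids)]
  d$cost_aud <- cost
  d$utility <- utility
  d$madrs <- madrs
  d
}

# Value-only view of a trial table: drops the container's metadata
# attributes so datasets can be compared on their contents.
strip_meta <- function(df) {
  df <- as.data.frame(df)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  df
}

# Independent angular-ordering oracle for the reordered percentile
# method: complex argument of the CE-plane point rotated so the
# positive-cost axis maps to angle zero, traversed counterclockwise.
oracle_ce_order <- function(delta_cost, delta_effect) {
  z <- complex(real = delta_effect, imaginary = delta_cost) *
    exp(complex(imaginary = -pi / 2))
  order(Arg(z) %% (2 * pi))
}

# Fine-grid trapezoid oracle for the piecewise-linear QALY trajectory;
# the grid contains every knot, so the quadrature is exact for a
# piecewise-linear integrand up to floating point.
oracle_qaly <- function(utilities, schedule = c(0, 3, 6, 9, 12)) {
  tt <- seq(0, max(schedule), by = 0.0025)
  u <- approx(schedule, utilities, xout = tt)$y
  dt <- diff(tt) / 12
  sum(dt * (u[-length(u)] + u[-1]) / 2)
}
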