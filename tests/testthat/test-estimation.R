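test_that("noise-free data returns the planted difference at every wave", {
  d <- make_trial_df(20, cost = NA)
  d$cost_aud <- 1000 + 10 * d$wave -
    ifelse(d$arm == 2, 500, 0) * (d$wave > 0)
  est <- suppressWarnings(fit_repeated_measures(as_trial_data(d), "cost"))
  e21 <- est[est$comparison == "2v1", ]
  expect_equal(e21$estimate[e21$wave != "total_3_12"], rep(-500, 4),
               tolerance = 1e-8)
  expect_equal(e21$estimate[e21$wave == "total_3_12"], -2000,
               tolerance = 1e-8)
  e23 <- est[est$comparison == "2v3", ]
  expect_equal(e23$estimate[e23$wave == "3"], -500, tolerance = 1e-8)
})

test_that("estimates equal the closed-form GLS oracle on balanced data", {
  sc <- sim_scenario(arm_sizes = c(50L, 50L, 50L), seed = 11)
  d <- generate_trial(sc)
  est <- fit_repeated_measures(d, "utility")
  expect_identical(attr(est, "method"), "gls_unstructured_reml")

  f <- trialcea:::build_followup_frame(d, "utility")
  f$cell <- interaction(f$wavef, f$armf, sep = "_a")
  fit <- nlme::gls(
    value ~ 0 + cell + baseline + sexm + cty_au + cty_other, data = f,
    correlation = nlme::corSymm(form = ~pos | participant_id),
    weights = nlme::varIdent(form = ~1 | wavef), method = "REML")
  Sigma <- nlme::getVarCov(fit)
  X <- stats::model.matrix(~ 0 + cell + baseline + sexm + cty_au +
                             cty_other, data = f)
  W <- kronecker(diag(length(unique(f$participant_id))), solve(Sigma))
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% f$value)[, 1]

  for (w in c("3", "6", "9", "12")) {
    oracle <- beta[paste0("cell", w, "_a2")] - beta[paste0("cell", w, "_a1")]
    got <- est$estimate[est$comparison == "2v1" & est$wave == w]
    expect_equal(got, unname(oracle), tolerance = 1e-6)
  }
})

test_that("comparisons are antisymmetric under arm relabelling", {
  sc <- sim_scenario(arm_sizes = c(40L, 40L, 40L), seed = 17)
  d <- generate_trial(sc)
  est <- fit_repeated_measures(d, "cost",
                               breakdown =
                                 microcost_interventions(default_ledger()))
  # 2v3 must equal (2v1) - (3v1) cell algebra at every wave
  for (w in c("3", "6", "9", "12", "total_3_12")) {
    e21 <- est$estimate[est$comparison == "2v1" & est$wave == w]
    e31 <- est$estimate[est$comparison == "3v1" & est$wave == w]
    e23 <- est$estimate[est$comparison == "2v3" & est$wave == w]
    expect_equal(e23, e21 - e31, tolerance = 1e-8)
  }
})

test_that("identity-link gamma GLM recovers a planted total-cost difference", {
  set.seed(23)
  n <- 3000
  arm <- sample(1:3, n, replace = TRUE)
  base <- rgamma(n, shape = 1, scale = 3000)
  mu <- 12000 - 2858 * (arm == 2) + 0.5 * base
  s <- tibble::tibble(
    arm = arm, baseline_cost = base,
    total_3_12 = rgamma(n, shape = 2, scale = mu / 2),
    sexm = rbinom(n, 1, 0.2),
    cty_au = rbinom(n, 1, 0.3), cty_other = 0,
    qaly = 0.6, baseline_utility = 0.6, madrs_12 = 20, baseline_madrs = 20)
  fitc <- fit_cost_glm(s)
  e21 <- fitc[fitc$comparison == "2v1", ]
  expect_lt(abs(e21$estimate - (-2858)), 2 * e21$se)

  s$total_3_12 <- 5000  # constant outcome: zero difference, zero SE
  fit0 <- fit_cost_glm(s)
  expect_equal(fit0$estimate, rep(0, 3), tolerance = 1e-8)
  expect_equal(fit0$se, rep(0, 3), tolerance = 1e-6)
})

test_that("modified Park test identifies the variance power", {
  set.seed(29)
  n <- 2000
  x <- runif(n)
  mu <- 500 + 4500 * x
  y <- rgamma(n, shape = 1, scale = mu)      # variance ~ mu^2
  pk <- modified_park_test(lm(y ~ x))
  expect_lt(abs(pk$park_coefficient - 2), 3 * pk$se)
  expect_identical(pk$recommended_family, "gamma")

  y0 <- 500 + 4500 * x + rnorm(n, 0, 300)    # homoskedastic
  pk0 <- modified_park_test(lm(y0 ~ x))
  expect_lt(abs(pk0$park_coefficient), 3 * pk0$se)
  expect_identical(pk0$recommended_family, "gaussian")

  fit <- lm(y ~ 0 + I(y))                    # perfect fit: degenerate
  expect_error(modified_park_test(list(y = y, fitted = y)), "degenerate")
})

test_that("link diagnostics: degenerate inputs and type-I calibration", {
  set.seed(31)
  y <- rnorm(50, 10)
  expect_error(link_diagnostics(list(y = y[1:10], fitted = y[1:10] + 1)),
               "at least 20")
  const <- link_diagnostics(list(y = y, fitted = rep(10, 50)))
  expect_equal(const$pearson$estimate, 0)

  # calibration under the model class the pipeline fits: identity-link
  # gamma GLM, correctly specified (raw OLS residuals are exactly
  # orthogonal to fitted values, so lm is not informative here)
  rej <- matrix(0, 200, 3)
  for (i in 1:200) {
    x <- runif(300)
    mu <- 500 + 4500 * x
    yy <- rgamma(300, shape = 2, scale = mu / 2)
    fit <- suppressWarnings(glm(yy ~ x, family = Gamma(link = "identity"),
                                start = c(500, 4500)))
    dg <- link_diagnostics(fit)
    rej[i, ] <- c(dg$pearson$p.value, dg$pregibon$p.value,
                  dg$hosmer_lemeshow$p.value) < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates >= 0.005 & rates <= 0.12))
})

test_that("a misspecified link is flagged by the Pregibon test", {
  set.seed(37)
  rejected <- 0
  for (i in 1:50) {
    x <- runif(400)
    y <- exp(1 + 2.5 * x) * (1 + rnorm(400, 0, 0.1))
    dg <- link_diagnostics(lm(y ~ x))
    rejected <- rejected + (dg$pregibon$p.value < 0.05)
  }
  expect_gt(rejected / 50, 0.5)
})

test_that("missingness model flags degenerate outcomes and fits the null", {
  sc <- sim_scenario(arm_sizes = c(30L, 30L, 30L), seed = 41)
  d <- generate_trial(sc)
  res <- missingness_model(d)
  expect_true(res$degenerate)

  sc2 <- sim_scenario(
    arm_sizes = c(700L, 700L, 700L),
    missingness = list(sex_or_female = 1, engagement_sd = 0,
                       completion_target = c(`3` = 0.8, `6` = 0.8,
                                             `9` = 0.8, `12` = 0.8)),
    seed = 43)
  dm <- apply_missingness(generate_trial(sc2), sc2)
  res2 <- missingness_model(dm)
  expect_false(res2$degenerate)
  expect_false(res2$separation)
  sex_or <- res2$table$or[res2$table$term == "sexm"]
  expect_lt(abs(log(sex_or)), 0.5)
})
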