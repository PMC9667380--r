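test_that("ICER classification is exhaustive and exclusive on the sign grid", {
  cases <- expand.grid(dc = c(-1, 0, 1), de = c(-1, 0, 1))
  kinds <- mapply(function(dc, de) icer_point(dc, de)$kind,
                  cases$dc, cases$de)
  expected <- c(dominant = sum(cases$dc < 0 & cases$de > 0),
                dominated = sum(cases$dc > 0 & cases$de < 0))
  expect_identical(sum(kinds == "dominant"), as.integer(expected["dominant"]))
  expect_identical(sum(kinds == "dominated"),
                   as.integer(expected["dominated"]))
  expect_identical(icer_point(-1, 1)$quadrant, "SE")
  expect_identical(icer_point(1, -1)$quadrant, "NW")
  expect_identical(icer_point(-1, -1)$kind, "ratio")
  expect_identical(icer_point(-1, -1)$value, 1)
  expect_identical(icer_point(5, 0)$kind, "undefined")
  expect_identical(icer_point(1e4, 1e-12)$kind, "undefined")
})

test_that("published incremental pairs give the published ratios and labels", {
  expect_identical(icer_point(743, 3.6)$value, 206)
  expect_identical(icer_point(113, 1.1)$value, 103)
  expect_identical(icer_point(7798, 0.7)$value, 11140)
  expect_identical(icer_point(466, 0.3)$value, 1553)
  expect_identical(icer_point(-2858, 3.8)$kind, "dominant")
  expect_identical(icer_point(7798, -0.004)$kind, "dominated")
})

test_that("reordered percentile bounds equal known order statistics", {
  # 40 points on the unit circle with known angular order from the
  # positive-cost axis, counterclockwise
  key <- seq(0.05, 2 * pi - 0.05, length.out = 40)
  theta <- pi / 2 + key
  pts <- tibble::tibble(delta_effect = cos(theta),
                        delta_cost = sin(theta))
  set.seed(47)
  shuffle <- sample(40)
  dist <- structure(list(replicates = pts[shuffle, ],
                         point_estimate = c(delta_cost = 0,
                                            delta_effect = 0),
                         B = 40L, seed = 1L, effect_kind = "qaly"),
                    class = "bootstrap_distribution")
  ci <- reordered_percentile_ci(dist, alpha = 0.05)
  expect_equal(c(ci$lower$delta_effect, ci$lower$delta_cost),
               c(pts$delta_effect[1], pts$delta_cost[1]))
  expect_equal(c(ci$upper$delta_effect, ci$upper$delta_cost),
               c(pts$delta_effect[39], pts$delta_cost[39]))
  expect_true(ci$spans_all_quadrants)
  # point 1 sits just counterclockwise of +cost in NW: dominated label
  expect_identical(ci$lower$label, "dominated")
})

test_that("reordered ordering matches the brute-force angular oracle", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    dc <- rnorm(n, sample(c(-2000, 0, 2000), 1), 3000)
    de <- rnorm(n, sample(c(-0.01, 0.01), 1), 0.02)
    got <- order(trialcea:::ce_angle(dc, de))
    expect_identical(got, oracle_ce_order(dc, de))
  }
})

test_that("CEAC counts net-benefit-positive replicates exactly", {
  mk <- function(dc, de) structure(
    list(replicates = tibble::tibble(delta_cost = dc, delta_effect = de),
         point_estimate = c(delta_cost = mean(dc),
                            delta_effect = mean(de)),
         B = length(dc), seed = 1L, effect_kind = "qaly"),
    class = "bootstrap_distribution")

  two <- mk(c(-1, 1), c(-1, 1))
  cc <- ceac(two, c(0, 1e9))
  expect_equal(cc$probability, c(0.5, 0.5))

  all_se <- mk(rep(-1, 5), rep(1, 5))
  expect_true(all(ceac(all_se, c(0, 1000, 1e6))$probability == 1))

  set.seed(59)
  rnd <- mk(rnorm(500, -100, 2000), rnorm(500, 0.005, 0.02))
  expect_equal(ceac(rnd, 0)$probability,
               mean(rnd$replicates$delta_cost < 0))
  expect_equal(ceac(rnd, 1e12)$probability[1],
               mean(rnd$replicates$delta_effect > 0))
})

test_that("bootstrap is deterministic, preserves arm sizes, and centers
           on the point estimate", {
  sc <- sim_scenario(arm_sizes = c(60L, 60L, 60L), seed = 61)
  b <- microcost_interventions(default_ledger())
  s <- participant_summary(generate_trial(sc), b)
  cfg <- analysis_config(bootstrap_B = 200, seed = 9)
  est <- estimator_mean_difference("2v1", "qaly")

  d1 <- bootstrap_incrementals(s, est, cfg)
  d2 <- bootstrap_incrementals(s, est, cfg)
  expect_identical(d1$replicates, d2$replicates)
  expect_identical(nrow(d1$replicates), 200L)

  mc_se <- sd(d1$replicates$delta_cost) / sqrt(d1$B)
  expect_lt(abs(mean(d1$replicates$delta_cost) -
                  d1$point_estimate[["delta_cost"]]), 3 * mc_se)

  # identical participants: every replicate equals the point estimate
  s0 <- s
  for (cl in setdiff(names(s0), c("participant_id", "arm"))) {
    s0[[cl]] <- rep(s0[[cl]][1], nrow(s0))
  }
  s0$total_3_12 <- 1000; s0$qaly <- 0.5
  dd <- bootstrap_incrementals(s0, est, analysis_config(bootstrap_B = 20,
                                                        seed = 2))
  expect_true(all(dd$replicates$delta_cost == 0))
  expect_true(all(dd$replicates$delta_effect == 0))
})

test_that("failed replicates are redrawn, never dropped", {
  sc <- sim_scenario(arm_sizes = c(30L, 30L, 30L), seed = 67)
  s <- participant_summary(generate_trial(sc))
  med <- median(s$total_3_12[s$arm == 1])
  est <- function(d) {
    if (d$total_3_12[d$arm == 1][1] > med) stop("unlucky resample")
    c(delta_cost = mean(d$total_3_12[d$arm == 2]) -
        mean(d$total_3_12[d$arm == 1]),
      delta_effect = 0.01)
  }
  # point estimate must succeed: put a low-total participant first
  s <- s[order(s$total_3_12), ]
  dd <- bootstrap_incrementals(s, est, analysis_config(bootstrap_B = 50,
                                                       seed = 3))
  expect_identical(nrow(dd$replicates), 50L)
  expect_gt(dd$redraws, 0L)
})

test_that("CE-plane export is lossless and round-trips through disk", {
  sc <- sim_scenario(arm_sizes = c(25L, 25L, 25L), seed = 71)
  s <- participant_summary(generate_trial(sc))
  dd <- bootstrap_incrementals(s, estimator_mean_difference("3v1", "qaly"),
                               analysis_config(bootstrap_B = 40, seed = 4))
  exp_tab <- ce_plane_export(dd)
  expect_identical(nrow(exp_tab), 40L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_results(exp_tab, p, seed = 4)
  back <- read_results(p)
  expect_equal(as.data.frame(back), as.data.frame(exp_tab),
               ignore_attr = TRUE)
})

test_that("imputation bootstrap degenerates to the plain bootstrap when
           nothing is missing", {
  sc <- sim_scenario(arm_sizes = c(40L, 40L, 40L), seed = 73)
  b <- microcost_interventions(default_ledger())
  d <- generate_trial(sc)
  cfg <- analysis_config(bootstrap_B = 25, seed = 8)
  plain <- bootstrap_incrementals(
    participant_summary(d, b),
    estimator_glm_totals("2v1", "qaly", cfg), cfg)
  nested <- mi_nested_bootstrap(d, cfg, b, "2v1", "qaly")
  expect_equal(plain$replicates, nested$replicates)
})

test_that("PMM imputes only values from the observed support", {
  sc <- sim_scenario(arm_sizes = c(80L, 80L, 80L), seed = 79)
  d <- apply_missingness(generate_trial(sc), sc)
  s <- participant_summary(d)
  fup <- c(3, 6, 9, 12)
  targets <- c(paste0("cost_", fup), paste0("util_", fup),
               paste0("madrs_", fup))
  preds <- c("cost_0", "util_0", "madrs_0", "arm", "sexm", "cty_au",
             "cty_other")
  set.seed(5)
  imp <- pmm_impute(s, targets, preds)
  expect_false(anyNA(imp[targets]))
  for (v in targets) {
    was_missing <- is.na(s[[v]])
    if (!any(was_missing)) next
    expect_true(all(imp[[v]][was_missing] %in% s[[v]][!was_missing]))
  }
})
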