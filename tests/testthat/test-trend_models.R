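test_that("flat cohorts fit zero slopes in every treatment", {
  co <- flat_cohort(n_per = 4, k = 8)
  fit <- suppressWarnings(fit_duration_trend(co, "immobility"))
  expect_true(all(abs(fit$slopes$estimate) < 1e-8))
  fitm <- suppressWarnings(fit_duration_trend(co, "movement"))
  expect_true(all(abs(fitm$slopes$estimate) < 1e-8))
})

test_that("estimates are invariant to row order and contrasts are exact slope differences", {
  spec <- list(paper = scenario_spec("paper", n_individuals = 6),
               shallow_sand = scenario_spec("shallow_sand"),
               deep_sand = scenario_spec("deep_sand"))
  study <- simulate_study(seed = 5, tracks = FALSE, specs = spec)
  df <- do.call(rbind, lapply(study, function(co)
    cohort_durations(co, "immobility")))
  fit1 <- suppressWarnings(fit_duration_trend(df, "immobility"))
  set.seed(1)
  fit2 <- suppressWarnings(
    fit_duration_trend(df[sample(nrow(df)), ], "immobility"))
  expect_equal(fit1$slopes$estimate, fit2$slopes$estimate, tolerance = 1e-6)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-6)

  ct <- contrast_slopes(fit1, adjust = "none")
  sl <- setNames(fit1$slopes$estimate, fit1$slopes$treatment)
  expect_equal(ct$estimate[ct$pair == "paper - deep_sand"],
               unname(sl["paper"] - sl["deep_sand"]))
  expect_equal(ct$estimate[ct$pair == "paper - shallow_sand"],
               unname(sl["paper"] - sl["shallow_sand"]))
  # z = 0 maps to adjusted p = 1 (a contrast of a slope with itself)
  expect_equal(pcimove:::single_step_p(0, diag(3)), 1)
})

test_that("the single-step adjustment lies between none and Bonferroni", {
  study <- simulate_study(seed = 6, tracks = FALSE)
  fit <- suppressWarnings(fit_duration_trend(
    do.call(rbind, lapply(study, cohort_durations, "movement")),
    "movement"))
  p_none <- contrast_slopes(fit, adjust = "none")$p
  p_ss <- contrast_slopes(fit, adjust = "single-step")$p
  p_bon <- contrast_slopes(fit, adjust = "bonferroni")$p
  expect_true(all(p_ss >= p_none - 1e-6))
  expect_true(all(p_ss <= p_bon + 1e-6))
})

test_that("the random factor never fits worse than the fixed-effects model", {
  study <- simulate_study(seed = 11, tracks = FALSE)
  fit <- suppressWarnings(fit_duration_trend(
    do.call(rbind, lapply(study, cohort_durations, "immobility")),
    "immobility"))
  expect_gte(fit$lrt_random[["statistic"]], 0)
})

test_that("generating slopes are recovered within their fitted CIs (quick check)", {
  # the full 200-replicate coverage test runs with the acceptance suite;
  # here a handful of replicates guards against gross estimator bias
  specs <- list(
    paper = scenario_spec("paper", imm_intercept = 2.0, imm_slope = -1.2,
                          sd_intercept = 0.2, sd_slope = 0.1,
                          sd_resid = 0.3),
    shallow_sand = scenario_spec("shallow_sand", imm_intercept = 2.0,
                                 imm_slope = -1.0, sd_intercept = 0.2,
                                 sd_slope = 0.1, sd_resid = 0.3),
    deep_sand = scenario_spec("deep_sand", imm_intercept = 2.0,
                              imm_slope = -0.3, sd_intercept = 0.2,
                              sd_slope = 0.1, sd_resid = 0.3))
  truth <- c(paper = -1.2, shallow_sand = -1.0, deep_sand = -0.3)
  hits <- 0L; total <- 0L
  for (r in 1:15) {
    study <- simulate_study(seed = 300 + r, tracks = FALSE, specs = specs)
    fit <- suppressWarnings(fit_duration_trend(
      do.call(rbind, lapply(study, cohort_durations, "immobility")),
      "immobility"))
    s <- fit$slopes
    for (i in seq_len(nrow(s))) {
      half <- qt(0.975, s$df[i]) * s$se[i]
      hits <- hits + (abs(s$estimate[i] - truth[[s$treatment[i]]]) <= half)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("displacement model reports medians, floors zeros, and finds no effect in null data", {
  df <- data.frame(
    individual_id = sprintf("AL%02d", c(1:10, 1:5, 6:10)),
    treatment = rep(c("paper", "shallow_sand", "deep_sand"), c(10, 5, 5)),
    displacement = 20)
  fit0 <- suppressWarnings(suppressMessages(fit_displacement_model(df)))
  expect_true(all(fit0$contrasts$p > 0.9))
  expect_equal(unname(fit0$medians), rep(20, 3))

  df$displacement[1] <- 0
  expect_message(suppressWarnings(fit_displacement_model(df)), "floored")
})

test_that("a 10x displacement ratio is detected reliably (power check)", {
  detected <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    set.seed(700 + r)
    df <- data.frame(
      individual_id = sprintf("AL%02d", c(1:22, 1:8, 9:16)),
      treatment = rep(c("paper", "shallow_sand", "deep_sand"),
                      c(22, 8, 8)),
      displacement = 10^(c(rep(2, 22), rep(1, 16)) + rnorm(38, 0, 0.2)))
    fit <- suppressWarnings(suppressMessages(fit_displacement_model(df)))
    ps <- fit$contrasts
    p1 <- ps$p[ps$pair == "paper - shallow_sand"]
    p2 <- ps$p[ps$pair == "paper - deep_sand"]
    detected <- detected + (p1 < 0.05 && p2 < 0.05)
  }
  expect_gte(detected / n_rep, 0.95)
})
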