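test_that("log bins cover the window with geometric-mean midpoints", {
  b <- log_bins(14, 1.6, 5400)
  expect_equal(nrow(b), 14)
  expect_equal(b$lower[1], 1.6)
  expect_equal(b$upper[14], 5400)
  expect_equal(b$midpoint, sqrt(b$lower * b$upper))
  expect_true(all(diff(b$midpoint) > 0))
  # constant width on the log scale
  expect_equal(diff(log(b$lower)), rep(diff(log(c(1.6, 5400))) / 14, 13))
})

test_that("a stationary cohort has zero MSD in every populated bin", {
  trks <- lapply(1:3, function(i) toy_track(rep(100, 300), dt = 1.6,
                                            id = paste0("s", i)))
  ends <- setNames(rep(0, 3), paste0("s", 1:3))
  prof <- msd_profile(trks, ends, move_threshold = 0)$profile
  pop <- prof$n_individuals > 0
  expect_true(any(pop))
  expect_true(all(prof$mean[pop] == 0))
  # and zero speed in every populated MIS bin
  mis <- mis_profile(trks, ends, move_threshold = 0)$profile
  expect_true(all(mis$mean[mis$n_individuals > 0] == 0))
})

test_that("a constant-velocity track yields unit mean instantaneous speed", {
  n <- 120
  tr <- toy_track(10 + 1.6 * (seq_len(n) - 1), dt = 1.6, id = "cv")
  mis <- mis_profile(list(tr), c(cv = 0), move_threshold = 0,
                     n_bins = 8, t_max = 1.6 * (n - 1))$profile
  pop <- mis$n_individuals > 0
  expect_true(any(pop))
  expect_equal(mis$mean[pop], rep(1, sum(pop)))
  # n = 1 averaging identity: the profile is that individual's binned values
  expect_true(all(mis$n_individuals <= 1))
  expect_true(all(is.na(mis$upper_ci)))
})

test_that("MSD is invariant under rigid rotation and translation", {
  trks <- lapply(1:4, function(i) brownian_track(400, D = 0.02,
                                                 id = paste0("b", i),
                                                 seed = 80 + i))
  ends <- setNames(rep(0, 4), paste0("b", 1:4))
  p0 <- msd_profile(trks, ends, move_threshold = 0)$profile
  th <- 0.7
  rot <- lapply(trks, function(tr) {
    x <- tr$x - 112.5; y <- tr$y - 112.5
    suppressWarnings(pci_track(tr$individual_id, tr$treatment, tr$t,
                               112.5 + 3 + cos(th) * x - sin(th) * y,
                               112.5 - 5 + sin(th) * x + cos(th) * y))
  })
  p1 <- msd_profile(rot, ends, move_threshold = 0)$profile
  expect_equal(p1$mean, p0$mean, tolerance = 1e-10)
  expect_equal(p1$n_individuals, p0$n_individuals)
})

test_that("Brownian walkers produce a diffusive log-log MSD profile", {
  n_w <- 25
  D <- 0.05
  trks <- lapply(seq_len(n_w), function(i)
    brownian_track(2000, D = D, id = paste0("w", i), seed = 900 + i))
  ends <- setNames(rep(0, n_w), paste0("w", seq_len(n_w)))
  prof <- msd_profile(trks, ends, move_threshold = 0, t_max = 1.6 * 1999)
  p <- prof$profile
  keep <- p$n_individuals >= 2
  fit <- lm(log10(mean) ~ log10(midpoint), data = p[keep, ])
  expect_gt(coef(fit)[2], 0.8)
  expect_lt(coef(fit)[2], 1.2)
  # binned MSD tracks the analytic 4 D t in every well-populated bin
  ratio <- p$mean[keep] / (4 * D * p$midpoint[keep])
  expect_true(all(ratio > 0.6 & ratio < 1.6))
})

test_that("segmented regression declines a breakpoint on exactly linear data", {
  x <- seq(0, 6, length.out = 14)
  y <- 2 * x + 1
  f <- segmented_fit(x, y + rnorm(14, 0, 1e-9))
  expect_equal(f$model, "linear")
  expect_gt(f$davies_p, 0.05)
  expect_equal(f$slope1[["estimate"]], 2, tolerance = 1e-4)
  expect_true(is.na(f$psi[["estimate"]]))
})

test_that("segmented regression recovers a constructed breakpoint", {
  set.seed(123)
  x <- seq(0, 6, length.out = 14)
  y <- ifelse(x <= 3, 0.5 * x, 0.5 * 3 + 2 * (x - 3)) + rnorm(14, 0, 0.05)
  f <- segmented_fit(x, y)
  expect_equal(f$model, "segmented")
  expect_lt(f$davies_p, 0.05)
  expect_gt(f$psi[["estimate"]], 2.5)
  expect_lt(f$psi[["estimate"]], 3.5)
  expect_true(f$slope1[["lower"]] <= 0.5 && 0.5 <= f$slope1[["upper"]])
  expect_true(f$slope2[["lower"]] <= 2.0 && 2.0 <= f$slope2[["upper"]])
  expect_lte(f$r2adj, 1)

  # independent oracle: the segmented package's Muggeo estimator
  o <- segmented::segmented(lm(y ~ x), seg.Z = ~x, psi = 2)
  expect_equal(f$psi[["estimate"]], o$psi[1, "Est."], tolerance = 0.15)
  expect_equal(unname(segmented::slope(o)$x[, "Est."]),
               c(f$slope1[["estimate"]], f$slope2[["estimate"]]),
               tolerance = 0.05)
})

test_that("diffusion classification follows the designated slope CI", {
  mk <- function(lo, hi) structure(
    list(model = "linear",
         slope1 = c(estimate = (lo + hi) / 2, lower = lo, upper = hi)),
    class = "segmented_fit")
  expect_equal(classify_diffusion(mk(1.2, 1.6)), "super_diffusive")
  expect_equal(classify_diffusion(mk(0.9, 1.1)), "diffusive")
  expect_equal(classify_diffusion(mk(0.5, 0.9)), "sub_diffusive")
})

test_that("start-to-finish displacement matches geometry", {
  expect_equal(start_finish_displacement(c(5, 5), c(5, 5)), 0)
  expect_equal(start_finish_displacement(c(112.5, 112.5), c(0, 0)),
               sqrt(2) * 112.5, tolerance = 1e-12)
  # ~159.1 mm, the arena half-diagonal ceiling
  expect_equal(round(start_finish_displacement(c(112.5, 112.5), c(0, 0)), 1),
               159.1)
  # wall rule: the final position is at wall arrival, not at record end
  xw <- c(rep(112, 4), 112 + 4.8 * seq_len(23))
  xw <- c(xw, rev(xw))
  tr <- toy_track(xw, dt = 1.6, id = "wr")
  d_wall <- start_finish_displacement(tr, wall_rule = TRUE)
  d_end <- start_finish_displacement(tr)
  expect_gt(d_wall, 100)
  expect_lt(d_end, 1e-9)
})
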