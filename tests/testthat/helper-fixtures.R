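# Small builders used across the test files. All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

# track from explicit coordinate vectors at a fixed sampling interval
toy_track <- function(x, y = rep(112, length(x)), dt = 1, t0 = 0,
                      id = "toy", treatment = "paper") {
  pci_track(id, treatment, t0 + dt * (seq_along(x) - 1), x, y)
}

# still / move / still track: n_still frames at rest, n_move frames stepping
# `step` mm in x, n_still frames at rest again
smk_track <- function(n_still = 10, n_move = 10, step = 2, dt = 1.6,
                      id = "smk") {
  x <- c(rep(10, n_still), 10 + step * seq_len(n_move),
         rep(10 + step * n_move, n_still))
  toy_track(x, dt = dt, id = id)
}

# 2-D Brownian walker: isotropic Gaussian steps with per-axis variance
# 2 * D * dt, started at the arena centre (may leave the arena for large D;
# out-of-arena positions are kept, so the warning is suppressed)
brownian_track <- function(n = 1000, D = 0.05, dt = 1.6, id = "bm",
                           seed = 1) {
  set.seed(seed)
  sx <- sqrt(2 * D * dt)
  x <- 112.5 + cumsum(c(0, rnorm(n - 1, 0, sx)))
  y <- 112.5 + cumsum(c(0, rnorm(n - 1, 0, sx)))
  suppressWarnings(pci_track(id, "paper", dt * (seq_len(n) - 1), x, y))
}

# cohort of perfectly flat bout sequences (no trend, no noise)
flat_cohort <- function(n_per = 3, k = 6, dur_i = 10, dur_m = 5) {
  bouts <- list()
  for (tr in c("paper", "shallow_sand", "deep_sand")) {
    for (i in seq_len(n_per)) {
      bouts[[length(bouts) + 1L]] <- bout_sequence(
        sprintf("%s%02d", tr, i), tr,
        immobility = rep(dur_i, k), movement = rep(dur_m, k))
    }
  }
  pci_cohort(bouts = bouts)
}

expect_alternating <- function(events) {
  expect_true(all(events$end > events$start))
  if (nrow(events) > 1) {
    kinds <- events$kind
    expect_true(all(kinds[-1] != kinds[-length(kinds)]))
    expect_equal(events$start[-1], events$end[-nrow(events)])
  }
}
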