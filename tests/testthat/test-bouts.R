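test_that("an all-still track is one immobility bout spanning the record", {
  tr <- toy_track(rep(10, 20), dt = 1.6)
  ev <- segment_bouts(tr, move_threshold = 0.5, still_gap = 3.2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "immobility")
  expect_equal(ev$start, tr$t[1])
  expect_equal(ev$end, tr$t[length(tr$t)])
})

test_that("still/move/still toy track is segmented at the constructed boundaries", {
  tr <- smk_track(n_still = 10, n_move = 10, step = 2, dt = 1.6)
  ev <- segment_bouts(tr, move_threshold = 0.5, still_gap = 3.2)
  expect_equal(ev$kind, c("immobility", "movement", "immobility"))
  # frames 10 and 20 are 0-based times 9*1.6 and 19*1.6
  expect_equal(ev$start, c(0, 9 * 1.6, 19 * 1.6))
  expect_equal(ev$end, c(9 * 1.6, 19 * 1.6, 29 * 1.6))
  expect_alternating(ev)
  # total duration equals the segmented span exactly
  expect_equal(sum(ev$end - ev$start), tr$t[length(tr$t)] - tr$t[1])
})

test_that("still gaps shorter than still_gap are bridged into a movement bout", {
  # move 5, still 1 frame (1.6 s < 3.2 s), move 5: one movement bout
  x <- c(rep(10, 6), 10 + 2 * 1:5, rep(20, 1), 20 + 2 * 1:5,
         rep(30, 6))
  tr <- toy_track(x, dt = 1.6)
  ev <- segment_bouts(tr, move_threshold = 0.5, still_gap = 3.2)
  expect_equal(sum(ev$kind == "movement"), 1L)
  # widen the gap to 3 frames (4.8 s >= 3.2 s): two movement bouts
  x2 <- c(rep(10, 6), 10 + 2 * 1:5, rep(20, 3), 20 + 2 * 1:5, rep(30, 6))
  ev2 <- segment_bouts(toy_track(x2, dt = 1.6), 0.5, 3.2)
  expect_equal(sum(ev2$kind == "movement"), 2L)
  # the terminal gap belongs to the following immobility bout
  imm2 <- ev2[ev2$kind == "immobility", ]
  expect_equal(imm2$start[2], ev2$end[ev2$kind == "movement"][1])
})

test_that("raising the threshold never increases total movement time", {
  set.seed(31)
  spec <- scenario_spec("paper")
  co <- gen_bout_cohort(spec, seed = 9)
  tr <- coarse_grain(gen_track(co$bouts[[2]], spec, seed = 10), 4)
  thresholds <- c(0.05, 0.2, 0.5, 1, 2)
  mt <- vapply(thresholds, function(th) {
    ev <- segment_bouts(tr, th, 3.2)
    sum(ev$end[ev$kind == "movement"] - ev$start[ev$kind == "movement"])
  }, 0)
  expect_true(all(diff(mt) <= 1e-9))
})

test_that("sequences truncate at 16 pairs and at wall arrival", {
  # 20 pairs in -> 16 pairs out
  n <- 20
  x <- 10
  for (i in seq_len(n)) x <- c(x, rep(x[length(x)], 3),
                               x[length(x)] + 2 * 1:3)
  tr <- toy_track(c(x, rep(x[length(x)], 4)), dt = 1.6, id = "trunc")
  ev <- segment_bouts(tr, 0.5, 3.2)
  expect_gte(sum(ev$kind == "movement"), 17)
  sq <- extract_sequence(ev, track = tr)
  expect_length(sq$immobility, 16)
  expect_length(sq$movement, 16)

  # a track crossing near x = 225 mid-bout ends the sequence at that bout
  xw <- c(rep(112, 6), 112 + 4.8 * seq_len(23))
  xw <- c(xw, rep(xw[length(xw)], 6))
  trw <- toy_track(xw, y = rep(112, length(xw)), dt = 1.6, id = "wall")
  evw <- segment_bouts(trw, 0.5, 3.2)
  sqw <- extract_sequence(evw, track = trw, wall_rule = TRUE)
  expect_true(sqw$reached_wall)
  expect_length(sqw$immobility, 1)
  expect_length(sqw$movement, 1)
  wt <- wall_arrival_time(trw)
  expect_equal(sum(sqw$immobility) + sum(sqw$movement), wt - trw$t0)
})

test_that("segmentation recovers generated bout boundaries within tolerance", {
  # long, well-separated bouts so every boundary is resolvable at 1.6 s
  spec <- scenario_spec("paper", turn_sd = 0.1)
  truth <- bout_sequence("rec", "paper",
                         immobility = c(120, 60, 90, 45),
                         movement = c(40, 55, 35, 50),
                         arrival_time = 50)
  tr <- gen_track(truth, spec, seed = 12, wall_margin = Inf)
  cg <- coarse_grain(tr, 4)
  ev <- segment_bouts(cg, "auto", 3.2)
  sq <- extract_sequence(ev, track = cg)
  tol <- 3.2 + 1.6
  # a final immobility bout covers the remainder of the window
  expect_length(sq$immobility, 5)
  expect_length(sq$movement, 4)
  expect_true(all(abs(sq$immobility[1:4] - truth$immobility) <= 2 * tol))
  expect_true(all(abs(sq$movement - truth$movement) <= 2 * tol))
  # absolute boundary times: cumulative within the per-boundary tolerance
  b_true <- truth$arrival_time + cumsum(as.vector(rbind(truth$immobility,
                                                        truth$movement)))
  b_est <- sq$arrival_time + cumsum(as.vector(rbind(sq$immobility[1:4],
                                                    sq$movement)))
  expect_true(all(abs(b_true - b_est) <= tol))
})

test_that("clipping a bout sequence at a time point truncates in place", {
  b <- bout_sequence("c", "paper", c(100, 50), c(30, 20),
                     arrival_time = 10)
  # clip inside movement 1 (movement spans [110, 140])
  cl <- clip_bout_sequence(b, 125)
  expect_equal(cl$immobility, 100)
  expect_equal(cl$movement, 15)
  expect_true(cl$reached_wall)
  # clip inside immobility 2 (spans [140, 190])
  cl2 <- clip_bout_sequence(b, 160)
  expect_equal(cl2$immobility, c(100, 20))
  expect_equal(cl2$movement, 30)
  # durations always sum to the clipped span
  expect_equal(sum(cl2$immobility) + sum(cl2$movement), 160 - 10)
})

test_that("the auto threshold sits above immobility jitter and below real steps", {
  spec <- scenario_spec("paper")
  b <- bout_sequence("th", "paper", c(60, 60), 45, arrival_time = 0)
  tr <- coarse_grain(gen_track(b, spec, seed = 13, wall_margin = Inf), 4)
  th <- estimate_move_threshold(tr)
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  # interior movement frames (bout boundaries give partial steps)
  moving_frames <- tr$t[-length(tr$t)] >= 62 & tr$t[-length(tr$t)] < 102
  still_frames <- tr$t[-length(tr$t)] < 58 |
    tr$t[-length(tr$t)] >= 107
  expect_gt(min(steps[moving_frames]), th)     # real movement detected
  expect_lt(mean(steps[still_frames] > th), 0.005)  # jitter below
})
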