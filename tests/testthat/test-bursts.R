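test_that("moving-average smoothing uses truncated windows at the edges", {
  expect_equal(smooth_trajectory(c(0, 0, 10, 0, 0), 5),
               c(10 / 3, 10 / 4, 2, 10 / 4, 10 / 3))
  expect_equal(smooth_trajectory(rep(4, 7), 5), rep(4, 7))
  x <- rnorm(10)
  expect_equal(smooth_trajectory(x, 1), x)
  expect_error(smooth_trajectory(1:3, 5), "window")
  expect_error(smooth_trajectory(1:9, 4))   # even window rejected
})

test_that("burst calling follows the stated rules on a plateau trace", {
  x <- c(rep(0, 10), rep(100, 20), rep(0, 20))
  sm <- smooth_trajectory(x, 5)
  cl <- call_bursts(sm, threshold = 10)
  # smoothed trace crosses 10 at frame 9, drops below 55% of the 100 peak at
  # frame 31 (exclusive), then the interval shifts 2 frames: [11, 32]
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start_frame, 11)
  expect_equal(cl$end_frame, 32)
  expect_equal(cl$peak_value, 100)
  # identical to the stepwise oracle
  orc <- oracle_call_bursts(sm, 10)
  expect_equal(cl$start_frame, orc$start_frame)
  expect_equal(cl$end_frame, orc$end_frame)
})

test_that("silent traces, short spikes and initial declines yield no burst", {
  expect_equal(nrow(call_bursts(rep(0, 50), 10)), 0L)
  spike <- c(rep(0, 20), 50, 50, 50, rep(0, 27))   # 3 frames above threshold
  expect_equal(nrow(call_bursts(spike, 10)), 0L)
  decay <- c(seq(100, 20, length.out = 12), rep(0, 38))
  expect_equal(nrow(call_bursts(decay, 10)), 0L)
  # the same decay later in the trace is a regular (discarded-or-not) event,
  # not an initial-decline case: prepend silence and add a rise before it
  rise <- c(rep(0, 5), seq(20, 100, length.out = 6),
            seq(95, 20, length.out = 10), rep(0, 29))
  expect_gt(nrow(call_bursts(rise, 10)), 0L)
})

test_that("call_bursts matches the brute-force oracle on 500 random traces", {
  set.seed(77)
  for (rep in seq_len(500)) {
    x <- smooth_trajectory(random_burst_trace(120), 5)
    thr <- runif(1, 0.5, 8)
    a <- call_bursts(x, thr)
    b <- oracle_call_bursts(x, thr)
    expect_identical(nrow(a), nrow(b))
    expect_equal(a$start_frame, b$start_frame)
    expect_equal(a$end_frame, b$end_frame)
  }
})

test_that("the min_len filter leaves durations of surviving bursts unchanged", {
  set.seed(5)
  p <- telegraph_params(k_on = 0.3, k_off = 1.2, r_load = 20, dwell = 1.5,
                        noise_sd = 0.6, onset_delay = 3, n_frames = 150)
  g <- simulate_group(p, 40, seed = 6)
  thr <- group_threshold(g$trajectories)
  lens_filtered <- c(); lens_all <- c()
  for (id in unique(g$trajectories$nucleus_id)) {
    sm <- smooth_trajectory(
      g$trajectories$intensity[g$trajectories$nucleus_id == id], 5)
    a <- call_bursts(sm, thr, min_len = 5)
    b <- call_bursts(sm, thr, min_len = 1)
    la <- a$end_frame - a$start_frame + 1
    lb <- b$end_frame - b$start_frame + 1
    lens_filtered <- c(lens_filtered, la)
    lens_all <- c(lens_all, lb[lb >= 5])
  }
  expect_identical(sort(lens_filtered), sort(lens_all))
})

test_that("burst statistics implement the stated definitions", {
  # one burst of 10 frames with smoothed peak 50 at dt = 16.8 s
  raw <- c(rep(0, 10), rep(50, 10), rep(0, 10))
  sm <- raw
  cl <- data.frame(start_frame = 11, end_frame = 20, peak_value = 50,
                   peak_frame = 11)
  st <- burst_stats(cl, raw, sm, 16.8)
  expect_equal(st$amplitude, 50)
  expect_equal(st$duration, 168)
  expect_equal(st$total_output, 50 * 10 * 16.8)
  # rate: 2 bursts, first at 100 s, trace ending at 700 s -> 0.2 / min
  raw2 <- rep(1, 71); fi <- 10          # dt = 10 s: t_first = 100, T_end = 700
  cl2 <- data.frame(start_frame = c(11, 41), end_frame = c(20, 50),
                    peak_value = c(5, 5), peak_frame = c(11, 41))
  st2 <- burst_stats(cl2, raw2, raw2, fi)
  expect_equal(st2$t_first, 100)
  expect_equal(st2$induction_rate, 2 / 600 * 60)
  # total output is the full-trace rectangle rule
  st3 <- burst_stats(cl2[0, ], rep(1, 100), rep(1, 100), 16.8)
  expect_equal(st3$total_output, 1680)
  expect_equal(st3$n_bursts, 0L)
  expect_true(is.na(st3$t_first))
})

test_that("group thresholds follow the 10%-of-max rule per experiment set", {
  tr <- data.frame(nucleus_id = rep(1:2, each = 10),
                   intensity = c(rep(200, 10), rep(50, 10)))
  expect_equal(group_threshold(tr), 20)
  expect_equal(group_threshold(tr, override = 15), 15)
  tr2 <- data.frame(nucleus_id = 1, intensity = rep(80, 10))
  expect_equal(group_threshold(tr2), 8)   # each set gets its own threshold
  expect_error(group_threshold(data.frame(nucleus_id = 1, intensity = rep(0, 10))),
               "positive")
})
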