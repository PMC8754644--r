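test_that("parameter validation rejects non-finite or negative values", {
  expect_error(telegraph_params(k_on = -1, k_off = 1, r_load = 1, dwell = 1),
               "k_on")
  expect_error(telegraph_params(k_on = NA, k_off = 1, r_load = 1, dwell = 1),
               "k_on")
  expect_error(telegraph_params(k_on = 1, k_off = 1, r_load = 1, dwell = 1,
                                n_frames = 0), "n_frames")
  expect_error(telegraph_params(k_on = 1, k_off = 1, r_load = 1, dwell = 1,
                                frame_interval = 0), "frame_interval")
})

test_that("a promoter that can never activate stays silent", {
  p <- telegraph_params(k_on = 0, k_off = 1, r_load = 10, dwell = 1.5,
                        noise_sd = 0, n_frames = 200)
  s <- simulate_trajectory(p, seed = 1)
  expect_equal(nrow(s$on_intervals), 0L)
  expect_true(all(s$trajectory$intensity == 0))
  p2 <- telegraph_params(k_on = 0, k_off = 1, r_load = 10, dwell = 1.5,
                         noise_sd = 0.5, n_frames = 200)
  s2 <- simulate_trajectory(p2, seed = 1)
  expect_lt(max(s2$trajectory$intensity), 5 * 0.5)  # noise only
})

test_that("a permanently ON promoter fluctuates around r_load * dwell", {
  p <- telegraph_params(k_on = 100, k_off = 0, r_load = 10, dwell = 1.5,
                        unit_intensity = 1, noise_sd = 0, onset_delay = 0,
                        n_frames = 400)
  s <- simulate_trajectory(p, seed = 7)
  expect_equal(nrow(s$on_intervals), 1L)
  # steady state after one dwell time: mean count = r_load * dwell = 15
  late <- s$trajectory$intensity[s$trajectory$time_s / 60 > 2 * p$dwell]
  expect_lt(abs(mean(late) - p$r_load * p$dwell) / (p$r_load * p$dwell), 0.10)
})

test_that("OFF durations are exponential with rate k_on", {
  # long traces, no loading events needed for the switching statistics
  p <- telegraph_params(k_on = 0.5, k_off = 1.0, r_load = 0, dwell = 1,
                        n_frames = 5000, frame_interval = 60)
  g <- simulate_group(p, 60, seed = 11)
  off_min <- true_off_durations(g$on_intervals) / 60
  expect_gt(length(off_min), 10000)
  mle_rate <- 1 / mean(off_min)
  expect_lt(abs(mle_rate - 0.5) / 0.5, 0.05)
  ks <- suppressWarnings(stats::ks.test(off_min, "pexp", rate = mle_rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("ON-interval rate matches the stationary telegraph rate", {
  # expected bursts per min = k_on * k_off / (k_on + k_off)
  p <- telegraph_params(k_on = 0.5, k_off = 1.0, r_load = 0, dwell = 1,
                        n_frames = 10000, frame_interval = 60)
  s <- simulate_trajectory(p, seed = 3)
  t_total <- p$n_frames * p$frame_interval / 60
  rate <- nrow(s$on_intervals) / t_total
  expect_lt(abs(rate - 0.5 * 1.0 / 1.5) / (0.5 * 1.0 / 1.5), 0.05)
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  p <- telegraph_params(k_on = 0.3, k_off = 1.2, r_load = 20, dwell = 1.5,
                        noise_sd = 0.5, n_frames = 150)
  a <- simulate_trajectory(p, seed = 99)
  b <- simulate_trajectory(p, seed = 99)
  expect_identical(a, b)
})

test_that("Erlang OFF-switching lengthens and reshapes ON durations", {
  base <- telegraph_params(k_on = 0.5, k_off = 1.0, r_load = 0, dwell = 1,
                           n_frames = 3000, frame_interval = 60)
  erl <- telegraph_params(k_on = 0.5, k_off = 3.0, r_load = 0, dwell = 1,
                          n_frames = 3000, frame_interval = 60, off_steps = 3)
  on_b <- with(simulate_group(base, 20, seed = 5)$on_intervals,
               (t_end_s - t_start_s) / 60)
  on_e <- with(simulate_group(erl, 20, seed = 5)$on_intervals,
               (t_end_s - t_start_s) / 60)
  # same mean ON duration (1 min) but the Erlang shape is not exponential
  expect_lt(abs(mean(on_e) - 1), 0.1)
  ks <- suppressWarnings(stats::ks.test(on_e, "pexp", rate = 1 / mean(on_e)))
  expect_lt(ks$p.value, 0.01)
  ks_b <- suppressWarnings(stats::ks.test(on_b, "pexp", rate = 1 / mean(on_b)))
  expect_gt(ks_b$p.value, 0.01)
})

test_that("variant presets encode the documented ordinal relations", {
  wt <- variant_presets("WT")
  expect_gt(wt$r_load, variant_presets("mTATA")$r_load)      # amplitude
  expect_gt(wt$k_on, variant_presets("mDPE")$k_on)           # frequency
  expect_gt(wt$k_on, variant_presets("mInr")$k_on)
  expect_gt(variant_presets("mMTE")$k_on, variant_presets("mDPE")$k_on)
  expect_lt(variant_presets("Zelda")$onset_delay, wt$onset_delay)
  expect_error(variant_presets("mBRE"), "valid presets")
})

test_that("periodic simulation has the requested period structure", {
  g <- simulate_periodic_group(5, n_frames = 60, period_frames = 20,
                               on_frames = 5, amplitude = 10, noise_sd = 0,
                               seed = 2)
  one <- g$intensity[g$nucleus_id == 1]
  expect_identical(one[1:40], one[21:60])  # exact 20-frame periodicity
  expect_equal(sum(one[1:20] > 0), 5)
})
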