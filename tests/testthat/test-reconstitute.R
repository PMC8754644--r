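test_that("a unit pulse retains exactly half after one half-life", {
  # pulse 7 min before the end of a trace sampled at 60 s
  n <- 15                               # times 0..840 s; pulse at t = 420 s
  intens <- numeric(n); intens[8] <- 1  # t = 420 s, t_end = 840 s: age 7 min
  for (model in c("exponential", "linear")) {
    rem <- remaining_mrna(intens, decay_params(7, model), t_end = 840,
                          frame_interval = 60)
    expect_equal(rem, 0.5 * 1 * 60)
  }
  # a pulse at t_end does not decay at all
  intens2 <- numeric(n); intens2[n] <- 1
  expect_equal(remaining_mrna(intens2, decay_params(7), t_end = 840,
                              frame_interval = 60), 60)
})

test_that("constant production approaches r * half_life / ln 2", {
  dt <- 5; hl <- 7
  n <- ceiling(20 * hl * 60 / dt)       # 20 half-lives of history
  r <- 3
  rem <- remaining_mrna(rep(r, n), decay_params(hl), frame_interval = dt)
  # exact discrete value: geometric sum over cohort ages
  q <- 2^(-dt / (hl * 60))
  ages <- (n - 1):0
  exact <- sum(r * dt * q^ages)
  expect_equal(rem, exact, tolerance = 1e-12)
  expect_lt(abs(rem - r * hl * 60 / log(2)) / (r * hl * 60 / log(2)), 0.01)
})

test_that("remaining mRNA is linear and reduces to the integral without decay", {
  set.seed(8)
  a <- runif(50); b <- runif(50)
  pars <- decay_params(7)
  ra <- remaining_mrna(a, pars, frame_interval = 16.8)
  rb <- remaining_mrna(b, pars, frame_interval = 16.8)
  expect_equal(remaining_mrna(a + b, pars, frame_interval = 16.8), ra + rb)
  expect_equal(remaining_mrna(3 * a, pars, frame_interval = 16.8), 3 * ra)
  # half_life -> infinity: plain rectangle-rule time integral
  rem_inf <- remaining_mrna(a, decay_params(1e12), frame_interval = 16.8)
  expect_equal(rem_inf, sum(a) * 16.8, tolerance = 1e-6)
  expect_error(remaining_mrna(c(1, -2, 3), pars, frame_interval = 16.8),
               "negative")
  expect_error(remaining_mrna(a, pars, t_end = 10, frame_interval = 16.8),
               "t_end")
})

test_that("false-colored patterns track the per-nucleus amounts", {
  mask <- matrix(0L, 40, 40)
  mask[5:10, 5:10] <- 1L; mask[25:30, 25:30] <- 2L
  amounts <- data.frame(nucleus_id = 1:2, amount = c(4, 4))
  img <- render_pattern(mask, amounts)
  expect_equal(dim(img), c(40L, 40L, 3L))
  expect_equal(unique(img[, , 2][mask == 1L]), 1)   # equal amounts: same color
  expect_equal(unique(img[, , 2][mask == 2L]), 1)
  amounts2 <- data.frame(nucleus_id = 1:2, amount = c(0, 0))
  img2 <- render_pattern(mask, amounts2)
  expect_true(all(img2[, , 2] == 0))                # histone-only (no overlay)
  amounts3 <- data.frame(nucleus_id = 1:2, amount = c(2, 4))
  img3 <- render_pattern(mask, amounts3)
  expect_equal(unique(img3[, , 2][mask == 1L]), 0.5)
})

test_that("stripe simulations reconstitute into their ground-truth stripes", {
  tp <- telegraph_params(k_on = 1, k_off = 1.2, r_load = 20, dwell = 1.5,
                         onset_delay = 0, n_frames = 20)
  fld <- field_params(image_shape = c(100L, 200L), n_nuclei = 20L,
                      stripe_pattern = list(list(x_range = c(1, 70),
                                                 params = tp)))
  rn <- render_movie(fld, seed = 14)
  amounts <- remaining_mrna_group(rn$truth$trajectories)
  img <- render_pattern(rn$truth$masks[[20]], amounts, rn$truth$tracks)
  green <- img[, , 2]
  on_ids <- which(rn$truth$stripe_id > 0)
  off_ids <- which(rn$truth$stripe_id == 0)
  mask <- rn$truth$masks[[20]]
  expect_true(all(green[mask %in% off_ids] == 0))
  expect_gt(max(green[mask %in% on_ids]), 0.5)
})
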