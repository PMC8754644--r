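gauss_plane <- function(h, w, cy, cx, I0, sx, sy, alpha = 0) {
  yy <- matrix(rep(seq_len(h), w), h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  alpha + I0 * exp(-((xx - cx)^2 / (2 * sx^2) + (yy - cy)^2 / (2 * sy^2)))
}

test_that("locate_spot finds the brightest voxel with deterministic ties", {
  vol <- array(0, c(20, 20, 4))
  mask <- matrix(1L, 20, 20)
  vol[7, 12, 3] <- 5
  expect_equal(unname(locate_spot(vol, mask, 1L)), c(3, 7, 12))
  # two dots in one nucleus: the brighter one wins
  vol[15, 4, 2] <- 7
  expect_equal(unname(locate_spot(vol, mask, 1L)), c(2, 15, 4))
  # uniform volume: lowest z, then row-major order
  expect_equal(unname(locate_spot(array(1, c(5, 5, 3)), matrix(1L, 5, 5), 1L)),
               c(1, 1, 1))
  expect_error(locate_spot(vol, matrix(0L, 20, 20), 1L), "empty region")
})

test_that("noiseless Gaussian parameters are recovered to 1e-3 relative", {
  pl <- gauss_plane(31, 31, 15.7, 16.3, 100, 1.2, 1.2, alpha = 10)
  f <- fit_spot(pl, c(16, 16))
  expect_true(f$valid)
  expect_lt(abs(f$alpha - 10) / 10, 1e-3)
  expect_lt(abs(f$I0 - 100) / 100, 1e-3)
  expect_lt(abs(f$x0 - 16.3) / 16.3, 1e-3)
  expect_lt(abs(f$y0 - 15.7) / 15.7, 1e-3)
  expect_lt(abs(f$sigma_x - 1.2) / 1.2, 1e-3)
  expect_lt(abs(f$sigma_y - 1.2) / 1.2, 1e-3)
})

test_that("the integral identity 2*pi*sx*sy*I0 holds bit-exactly", {
  pl <- gauss_plane(21, 21, 11, 11, 1, 1, 1)
  f <- fit_spot(pl, c(11, 11))
  expect_identical(f$integral, 2 * pi * f$sigma_x * f$sigma_y * f$I0)
  expect_lt(abs(f$integral - 2 * pi), 1e-4)   # unit-amplitude unit-sigma dot
})

test_that("flat and oversized dots are handled per the exclusion rules", {
  flat <- fit_spot(matrix(3, 21, 21), c(11, 11))
  expect_true(!flat$valid || abs(flat$integral) < 1e-6)
  wide <- fit_spot(gauss_plane(21, 21, 11, 11, 50, 4, 4), c(11, 11))
  expect_false(wide$valid)         # 2*sigma = 8 > 11/2
  expect_true(is.na(wide$integral))
  rec <- spot_invalidation(wide, nucleus_id = 3, frame = 12)
  expect_equal(rec$reason, "oversized")
  expect_null(spot_invalidation(fit_spot(gauss_plane(21, 21, 11, 11, 50, 1.2, 1.2),
                                         c(11, 11)), 3, 12))
})

test_that("edge-clipped windows are fitted but flagged", {
  pl <- gauss_plane(15, 15, 3, 3, 80, 1.2, 1.2, alpha = 5)
  f <- fit_spot(pl, c(3, 3))
  expect_true(f$clipped)
  expect_lt(abs(f$integral - 2 * pi * 1.2^2 * 80) / (2 * pi * 1.2^2 * 80), 0.01)
})

test_that("spot integrals tolerate 5% noise with < 3% median error", {
  set.seed(31)
  errs <- replicate(200, {
    I0 <- runif(1, 50, 150); sx <- runif(1, 1.0, 1.8); sy <- runif(1, 1.0, 1.8)
    pl <- gauss_plane(21, 21, 11 + runif(1, -.5, .5), 11 + runif(1, -.5, .5),
                      I0, sx, sy, alpha = 20)
    pl <- pl + rnorm(length(pl), 0, 0.05 * I0)
    f <- fit_spot(pl, c(11, 11))
    truth <- 2 * pi * sx * sy * I0
    if (f$valid) abs(f$integral - truth) / truth else NA_real_
  })
  expect_lt(median(errs, na.rm = TRUE), 0.03)
})

test_that("baseline correction zeroes the trajectory minimum", {
  expect_equal(baseline_correct(c(5, 7, 5, 9)), c(0, 2, 0, 4))
  expect_equal(baseline_correct(rep(3, 6)), rep(0, 6))
  expect_equal(baseline_correct(c(0, 2, 1)), c(0, 2, 1))
  expect_error(baseline_correct(rep(NA_real_, 4)), "no finite")
  df <- data.frame(nucleus_id = rep(1:2, each = 3),
                   intensity = c(5, 7, 6, 1, 3, 2),
                   excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- baseline_correct(df)
  expect_equal(out$intensity, c(0, 2, 1, -1, 1, 0))  # excluded frame ignored
  expect_error(baseline_correct(data.frame(nucleus_id = 1, intensity = 2,
                                           excluded = TRUE)),
               "fully excluded")
})

test_that("noiseless movie trajectories round-trip through quantification", {
  rn <- small_movie()
  seg <- segment_movie(rn$movie, method = 1)
  tr <- link_nuclei(seg$masks, max_disp = 7)
  qt <- quantify_movie(rn$movie, seg$masks, tr, baseline = FALSE)
  map <- match_tracks_to_truth(tr, rn$truth)
  scale <- max(rn$truth$trajectories$intensity)
  for (id in unique(qt$trajectories$nucleus_id)[1:10]) {
    tid <- map$truth_id[map$nucleus_id == id]
    rec <- qt$trajectories$intensity[qt$trajectories$nucleus_id == id]
    tru <- rn$truth$trajectories$intensity[rn$truth$trajectories$nucleus_id == tid]
    expect_lt(max(abs(rec - tru)) / scale, 0.01)
  }
})
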