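disk_raster <- function(h, w, centers, r, level = 1) {
  m <- matrix(0, h, w)
  for (k in seq_len(nrow(centers))) {
    yy <- row(m) - centers[k, 1]; xx <- col(m) - centers[k, 2]
    m[yy^2 + xx^2 <= r^2] <- level
  }
  m
}

test_that("max projection reduces z-stacks and passes 2D rasters through", {
  m <- matrix(runif(25), 5, 5)
  expect_identical(max_project(m), m)
  st <- array(0, c(5, 5, 8))
  st[3, 4, 5] <- 9
  pr <- max_project(st)
  expect_equal(pr[3, 4], 9)
  expect_equal(max_project(array(0, c(4, 4, 3))), matrix(0, 4, 4))
  expect_error(max_project(array(0, c(4, 4, 0))), "empty")
  expect_error(max_project(1:5), "2D matrix or a 3D")
})

test_that("default crops mirror the 430x430 and 300x430 field reductions", {
  m <- matrix(0, 512, 512)
  expect_equal(dim(crop_field(m)), c(430L, 430L))
  expect_equal(dim(crop_field(m, ratio = "dv")), c(300L, 430L))
  expect_identical(unclass(crop_field(m, crop_box = c(1, 512, 1, 512)))[, ],
                   m)
  expect_error(crop_field(m, crop_box = c(0, 10, 1, 10)), "out of bounds")
  expect_error(crop_field(m, crop_box = c(1, 600, 1, 10)), "out of bounds")
})

test_that("method 1 separates disks, splits touching pairs, handles blanks", {
  sep <- disk_raster(100, 100, rbind(c(30, 30), c(70, 70)), 10)
  m <- segment_method1(sep, seg_config(tophat_radius = 12))
  expect_equal(max(m), 2L)
  # tangent disks: the distance transform has two maxima -> watershed splits
  touch <- disk_raster(100, 100, rbind(c(50, 40), c(50, 60)), 10)
  m2 <- segment_method1(touch, seg_config(tophat_radius = 12))
  expect_equal(max(m2), 2L)
  expect_warning(m3 <- segment_method1(matrix(0, 50, 50)), "blank")
  expect_equal(max(m3), 0L)
})

test_that("both methods recover rendered nuclei at IoU >= 0.7", {
  rn <- small_movie()
  his <- max_project(rn$movie$frames[[1]]$histone)
  m1 <- segment_method1(his)
  r1 <- segmentation_recall(rn$truth$masks[[1]], m1)
  expect_gte(r1$recall, 0.95)
  m2 <- segment_method2(his, max_project(rn$movie$frames[[1]]$ms2))
  r2 <- segmentation_recall(rn$truth$masks[[1]], m2)
  expect_gte(r2$recall, 0.95)
  # method-2 centroids match ground truth within 1 px
  cen <- msburst:::.centroids_of(m2)
  tru <- rn$truth$tracks[rn$truth$tracks$frame == 1, ]
  for (k in seq_len(nrow(cen))) {
    d <- sqrt(min((tru$y - cen[k, 1])^2 + (tru$x - cen[k, 2])^2))
    expect_lt(d, 1)
  }
})

test_that("method-2 spot refinement pulls outside dots into the nearest nucleus", {
  his <- disk_raster(80, 80, rbind(c(30, 30), c(55, 55)), 8, level = 0.8)
  ms2 <- matrix(abs(rnorm(6400, 0.05, 0.01)), 80, 80)
  # dot 2 px outside the first nucleus boundary
  ms2[30, 41] <- 5; ms2[30, 42] <- 5
  m <- segment_method2(his, ms2, seg_config(expected_n = 2))
  expect_equal(max(m), 2L)
  lab_near <- m[30, 30]
  expect_equal(m[30, 41], lab_near)
  expect_equal(m[30, 42], lab_near)
  # invariant: every pixel >= 2x MS2 mean lies inside some label
  spot_px <- which(ms2 > 2 * mean(ms2))
  expect_true(all(m[spot_px] > 0))
  # labels stay single connected components
  for (k in seq_len(max(m)))
    expect_equal(max(EBImage::bwlabel(m == k)), 1)
})

test_that("a spotless MS2 raster leaves method-2 labels untouched", {
  his <- disk_raster(80, 80, rbind(c(30, 30), c(55, 55)), 8, level = 0.8)
  set.seed(1)
  flat <- matrix(runif(6400, 0.9, 1.1), 80, 80)  # nothing above 2x mean
  a <- segment_method2(his, flat, seg_config(expected_n = 2))
  b <- segment_method2(his, NULL, seg_config(expected_n = 2))
  expect_identical(unclass(a)[, ], unclass(b)[, ])
})

test_that("override masks replace computed labels where nonzero", {
  m <- matrix(0L, 10, 10); m[2:4, 2:4] <- 1L
  z <- matrix(0L, 10, 10)
  expect_identical(apply_override(m, z)[, ], m[, ])
  ov <- matrix(7L, 10, 10)
  expect_true(all(apply_override(m, ov) == 7L))
  part <- matrix(0L, 10, 10); part[2:4, 2:4] <- 9L
  out <- apply_override(m, part)
  expect_true(all(out[2:4, 2:4] == 9L))
  expect_true(all(out[5:10, ] == 0L))
  expect_error(apply_override(m, matrix(0L, 5, 5)), "shape")
})
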