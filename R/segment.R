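#' Maximum z-projection
#'
#' @param x a 2D matrix (returned unchanged) or a 3D `y, x, z` array.
#' @return 2D matrix of per-pixel maxima over z.
#' @export
max_project <- function(x) {
  if (is.matrix(x)) return(x)
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("max_project: input must be a 2D matrix or a 3D y,x,z array")
  if (dim(x)[3] == 0L) stop("max_project: empty stack")
  apply(x, c(1L, 2L), max)
}

#' Crop the field of view
#'
#' Removes edge nuclei by cropping to a centered sub-raster. The default
#' ratios mirror standard 512 -> 430 x 430 ("square") and 512 -> 300 x 430
#' ("dv", dorsoventral strip) crops and scale with the input size.
#'
#' @param raster 2D matrix.
#' @param crop_box optional `c(y0, y1, x0, x1)` (1-based, inclusive); when
#'   given it overrides `ratio`.
#' @param ratio `"square"` (430/512 on both axes) or `"dv"`
#'   (300/512 x 430/512).
#' @return the cropped matrix; the box used is attached as attribute
#'   `"crop_box"`.
#' @export
crop_field <- function(raster, crop_box = NULL, ratio = c("square", "dv")) {
  stopifnot(is.matrix(raster))
  h <- nrow(raster); w <- ncol(raster)
  if (is.null(crop_box)) {
    ratio <- match.arg(ratio)
    fy <- if (ratio == "dv") 300 / 512 else 430 / 512
    fx <- 430 / 512
    th <- round(h * fy); tw <- round(w * fx)
    y0 <- floor((h - th) / 2) + 1L; x0 <- floor((w - tw) / 2) + 1L
    crop_box <- c(y0, y0 + th - 1L, x0, x0 + tw - 1L)
  }
  if (length(crop_box) != 4L || crop_box[1] < 1 || crop_box[3] < 1 ||
      crop_box[2] > h || crop_box[4] > w || crop_box[1] > crop_box[2] ||
      crop_box[3] > crop_box[4])
    stop("crop_field: crop_box out of bounds")
  out <- raster[crop_box[1]:crop_box[2], crop_box[3]:crop_box[4], drop = FALSE]
  attr(out, "crop_box") <- as.integer(crop_box)
  out
}

#' Segmentation configuration
#'
#' Filter and scoring parameters for both nuclei-segmentation methods. The
#' defaults suit nuclei of radius ~5-10 px in fields of a few hundred pixels.
#'
#' @param blur_sigma Gaussian blur sigma (px).
#' @param tophat_radius white top-hat structuring disk radius (px); roughly
#'   the nucleus radius times two.
#' @param clahe_tiles CLAHE tile grid (tiles per side).
#' @param seed_min_sep minimum separation between watershed seeds (px);
#'   seeds are local maxima of the distance transform, and maxima closer
#'   than this collapse onto the deeper one. Roughly half the nucleus
#'   radius.
#' @param seed_min_depth minimum distance-transform depth for a seed (px);
#'   suppresses boundary artifacts.
#' @param min_area minimum component area kept (px).
#' @param expected_n expected nucleus count for the method-2 threshold score;
#'   `NULL` = estimate from the Otsu blob count (per-frame runs carry the
#'   previous frame's count forward).
#' @param size_bounds component-area plausibility bounds for the method-2
#'   score, as multiples of the median Otsu-threshold component area.
#' @param n_candidates number of candidate thresholds scanned by method 2.
#' @param spot_factor MS2 spot rule: pixels above `spot_factor` times the MS2
#'   channel mean are transcription dots.
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(blur_sigma = 2, tophat_radius = 15, clahe_tiles = 8,
                       seed_min_sep = 4, seed_min_depth = 2, min_area = 9,
                       expected_n = NULL,
                       size_bounds = c(0.3, 3.0), n_candidates = 40,
                       spot_factor = 2) {
  structure(list(blur_sigma = blur_sigma, tophat_radius = tophat_radius,
                 clahe_tiles = clahe_tiles, seed_min_sep = seed_min_sep,
                 seed_min_depth = seed_min_depth,
                 min_area = min_area, expected_n = expected_n,
                 size_bounds = size_bounds, n_candidates = n_candidates,
                 spot_factor = spot_factor),
            class = "seg_config")
}

.normalize01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

.finalize_mask <- function(lab, method, threshold = NA_real_) {
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  attr(lab, "method") <- method
  attr(lab, "threshold") <- threshold
  lab
}

# drop small components and relabel 1..n preserving scan order
.clean_labels <- function(lab, min_area) {
  tb <- tabulate(lab[lab > 0L])
  keep <- which(tb >= min_area)
  if (!length(keep)) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(max(lab)); map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- map[lab[pos]]
  out
}

#' Nuclei segmentation, method 1 (Otsu + watershed)
#'
#' Gaussian smoothing, white top-hat background removal and contrast-limited
#' adaptive histogram equalization enhance the histone channel; the image is
#' then binarized at the Otsu threshold and touching nuclei are split by a
#' watershed on the distance transform.
#'
#' @param raster 2D histone raster (max projection).
#' @param config a [seg_config()].
#' @return integer label matrix (0 = background) with attributes `method`
#'   and `threshold`; an all-background result returns an empty mask with a
#'   warning.
#' @export
segment_method1 <- function(raster, config = seg_config()) {
  stopifnot(is.matrix(raster))
  img <- .normalize01(raster)
  if (max(img) == 0) {
    warning("segment_method1: blank raster, returning empty mask")
    return(.finalize_mask(matrix(0L, nrow(raster), ncol(raster)), "method-1"))
  }
  img <- EBImage::gblur(img, sigma = config$blur_sigma)
  brush <- EBImage::makeBrush(2L * as.integer(config$tophat_radius) + 1L, "disc")
  img <- EBImage::whiteTopHat(img, brush)
  img <- .normalize01(img)
  # clahe needs dimensions divisible by the tile grid: pad by edge replication
  tiles <- config$clahe_tiles
  py <- (tiles - nrow(img) %% tiles) %% tiles
  px <- (tiles - ncol(img) %% tiles) %% tiles
  padded <- img[c(seq_len(nrow(img)), rep(nrow(img), py)),
                c(seq_len(ncol(img)), rep(ncol(img), px)), drop = FALSE]
  eq <- EBImage::clahe(padded, nx = tiles, ny = tiles)
  img <- .normalize01(as.matrix(eq)[seq_len(nrow(img)), seq_len(ncol(img))])
  thr <- EBImage::otsu(EBImage::Image(img))
  bin <- img > thr
  if (!any(bin)) {
    warning("segment_method1: no foreground at Otsu threshold")
    return(.finalize_mask(matrix(0L, nrow(raster), ncol(raster)), "method-1", thr))
  }
  dm <- EBImage::distmap(bin)
  lab <- .seeded_watershed(dm, bin, config$seed_min_sep, config$seed_min_depth)
  lab <- .clean_labels(lab, config$min_area)
  .finalize_mask(lab, "method-1", thr)
}

# marker-based watershed: seeds at distance-transform local maxima with a
# minimum separation (greedy, deeper maximum wins), propagated over the
# binary foreground by geodesic nearest-seed assignment
.seeded_watershed <- function(dm, bin, min_sep, min_depth) {
  dmm <- as.matrix(dm)
  h <- nrow(dmm); w <- ncol(dmm)
  k <- 2L * ceiling(min_sep) + 1L
  mx <- as.matrix(EBImage::dilate(dm, EBImage::makeBrush(k, "disc")))
  cand <- which(dmm >= mx - 1e-9 & dmm >= min_depth)
  if (!length(cand)) return(matrix(0L, h, w))
  cand <- cand[order(-dmm[cand], cand)]
  py <- (cand - 1L) %% h + 1L
  px <- (cand - 1L) %/% h + 1L
  ky <- numeric(0); kx <- numeric(0)
  for (i in seq_along(cand)) {
    if (!length(ky) || min((ky - py[i])^2 + (kx - px[i])^2) >= min_sep^2) {
      ky <- c(ky, py[i]); kx <- c(kx, px[i])
    }
  }
  seeds <- matrix(0L, h, w)
  seeds[cbind(ky, kx)] <- seq_along(ky)
  lab <- EBImage::propagate(EBImage::Image(matrix(0, h, w)),
                            EBImage::Image(seeds), mask = bin)
  matrix(as.integer(round(as.matrix(lab))), h, w)
}

# nearest-centroid (Voronoi) owner for pixel indices, given centroids (y, x)
.voronoi_owner <- function(idx, nrow_, centroids) {
  py <- (idx - 1L) %% nrow_ + 1L
  px <- (idx - 1L) %/% nrow_ + 1L
  n <- nrow(centroids)
  best <- rep(1L, length(idx)); bd <- rep(Inf, length(idx))
  for (k in seq_len(n)) {
    d <- (py - centroids[k, 1L])^2 + (px - centroids[k, 2L])^2
    better <- d < bd
    best[better] <- k; bd[better] <- d[better]
  }
  best
}

.centroids_of <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(matrix(numeric(0), 0L, 2L))
  k <- lab[idx]
  py <- (idx - 1L) %% nrow(lab) + 1L
  px <- (idx - 1L) %/% nrow(lab) + 1L
  cy <- tapply(py, k, mean); cx <- tapply(px, k, mean)
  ids <- sort(unique(k))
  cbind(y = as.numeric(cy[as.character(ids)]), x = as.numeric(cx[as.character(ids)]))
}

#' Nuclei segmentation, method 2 (adaptive threshold + spot-aware Voronoi)
#'
#' Blurs the histone channel, clips saturated pixels (above 95% of the global
#' maximum) to the local 3x3 median, then scans candidate thresholds over the
#' intensity histogram, scoring each by closeness of the connected-component
#' count to the expected nucleus count and by component-size plausibility.
#' MS2 pixels brighter than twice the channel mean are transcription dots;
#' any dot outside all nuclei pulls the boundary of the nucleus with the
#' nearest centroid until it is covered. Labels are finally clipped to the
#' Voronoi cells of the component centroids, which makes them disjoint.
#'
#' @param raster 2D histone raster.
#' @param ms2_raster optional co-registered 2D MS2 raster (max projection)
#'   for the spot-aware refinement; `NULL` skips it.
#' @param config a [seg_config()].
#' @return integer label matrix with attributes `method` and `threshold`.
#' @export
segment_method2 <- function(raster, ms2_raster = NULL, config = seg_config()) {
  stopifnot(is.matrix(raster))
  h <- nrow(raster); w <- ncol(raster)
  img <- .normalize01(raster)
  if (max(img) == 0) {
    warning("segment_method2: blank raster, returning empty mask")
    return(.finalize_mask(matrix(0L, h, w), "method-2"))
  }
  img <- EBImage::gblur(img, sigma = config$blur_sigma)
  img <- .normalize01(img)
  # clip near-saturated pixels to the local median
  hi <- img > 0.95
  if (any(hi)) {
    med <- as.matrix(EBImage::medianFilter(EBImage::Image(img), size = 1L))
    img[hi] <- med[hi]
    img <- .normalize01(img)
  }
  thr_otsu <- EBImage::otsu(EBImage::Image(img))
  lab_otsu <- as.matrix(EBImage::bwlabel(img > thr_otsu))
  areas <- tabulate(lab_otsu[lab_otsu > 0L])
  areas <- areas[areas >= config$min_area]
  expected <- config$expected_n
  if (is.null(expected)) expected <- max(1L, length(areas))
  med_area <- if (length(areas)) stats::median(areas) else config$min_area * 4
  lo <- config$size_bounds[1] * med_area
  hi_a <- config$size_bounds[2] * med_area

  cands <- stats::quantile(img, probs = seq(0.30, 0.99, length.out = config$n_candidates),
                           names = FALSE)
  cands <- sort(unique(cands))
  best <- NULL; best_score <- Inf; best_thr <- NA_real_
  for (thr in cands) {
    lab <- as.matrix(EBImage::bwlabel(img > thr))
    a <- tabulate(lab[lab > 0L])
    a <- a[a >= config$min_area]
    if (!length(a)) next
    frac_bad <- mean(a < lo | a > hi_a)
    score <- abs(length(a) - expected) / max(1, expected) + frac_bad +
      abs(stats::median(a) - med_area) / med_area
    if (score < best_score - 1e-12) {   # ties: lower threshold wins
      best_score <- score; best <- lab; best_thr <- thr
    }
  }
  if (is.null(best)) {
    warning("segment_method2: no candidate threshold yields a component")
    return(.finalize_mask(matrix(0L, h, w), "method-2"))
  }
  lab <- .clean_labels(best, config$min_area)
  if (!max(lab)) {
    warning("segment_method2: all components below min_area")
    return(.finalize_mask(matrix(0L, h, w), "method-2", best_thr))
  }
  cen <- .centroids_of(lab)

  # spot-aware refinement
  spot_bin <- NULL
  if (!is.null(ms2_raster)) {
    ms2_mean <- mean(ms2_raster)
    spot_bin <- ms2_raster > config$spot_factor * ms2_mean
    if (any(spot_bin)) {
      spot_lab <- as.matrix(EBImage::bwlabel(spot_bin))
      for (s in seq_len(max(spot_lab))) {
        sidx <- which(spot_lab == s)
        if (all(lab[sidx] > 0L)) next
        py <- mean((sidx - 1L) %% h + 1L)
        px <- mean((sidx - 1L) %/% h + 1L)
        owner <- which.min((cen[, 1L] - py)^2 + (cen[, 2L] - px)^2)
        lab <- .dilate_to_cover(lab, owner, sidx, limit = NULL)
      }
    }
  }

  # Voronoi clipping: each label keeps only pixels in its own cell
  idx <- which(lab > 0L)
  own <- .voronoi_owner(idx, h, cen)
  keep <- lab[idx] == own
  lab[idx[!keep]] <- 0L

  # recover any spot pixel dropped by clipping: grow its cell owner to it
  if (!is.null(spot_bin) && any(spot_bin)) {
    out_idx <- which(spot_bin & lab == 0L)
    if (length(out_idx)) {
      own2 <- .voronoi_owner(out_idx, h, cen)
      for (k in unique(own2)) {
        lab <- .dilate_to_cover(lab, k, out_idx[own2 == k],
                                limit = .voronoi_cell_mask(h, w, cen, k))
      }
    }
  }
  .finalize_mask(lab, "method-2", best_thr)
}

.voronoi_cell_mask <- function(h, w, cen, k) {
  idx <- seq_len(h * w)
  own <- .voronoi_owner(idx, h, cen)
  m <- matrix(FALSE, h, w); m[idx[own == k]] <- TRUE
  m
}

# grow label k by 3x3 dilation steps (optionally restricted to `limit`)
# until it covers all pixels in `target_idx`
.dilate_to_cover <- function(lab, k, target_idx, limit = NULL, max_iter = 100L) {
  kern <- EBImage::makeBrush(3L, "box")
  for (i in seq_len(max_iter)) {
    if (all(lab[target_idx] == k)) break
    reg <- lab == k
    grown <- as.matrix(EBImage::dilate(reg, kern)) > 0
    new <- grown & lab == 0L
    if (!is.null(limit)) new <- new & limit
    if (!any(new)) break
    lab[new] <- k
  }
  lab
}

#' Replace computed labels with a manual override mask
#'
#' File-based stand-in for interactive mask correction: wherever the override
#' raster is nonzero its labels replace the computed ones.
#'
#' @param mask computed integer label matrix.
#' @param override_mask integer label matrix of the same shape.
#' @return corrected label matrix (provenance attribute set to `"override"`
#'   where any pixel changed).
#' @export
apply_override <- function(mask, override_mask) {
  if (!all(dim(mask) == dim(override_mask)))
    stop("apply_override: shape mismatch")
  out <- mask
  nz <- override_mask != 0L
  out[nz] <- as.integer(override_mask[nz])
  attr(out, "method") <- if (any(nz)) "override" else attr(mask, "method")
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Segment every frame of a movie
#'
#' Runs [segment_method1()] or [segment_method2()] on the max-projected
#' histone channel of each frame. For method 2 the expected nucleus count of
#' each frame defaults to the previous frame's count (temporal continuity).
#'
#' @param movie an `ms2_movie`.
#' @param method 1 or 2.
#' @param config a [seg_config()].
#' @param use_ms2 logical; feed the projected MS2 channel to method 2's
#'   spot-aware refinement.
#' @return list with `masks` (per-frame label matrices) and `report`
#'   (data.frame `frame`, `n_labels`, `threshold`, `method`).
#' @export
segment_movie <- function(movie, method = 1L, config = seg_config(),
                          use_ms2 = TRUE) {
  stopifnot(inherits(movie, "ms2_movie"))
  n_f <- length(movie$frames)
  masks <- vector("list", n_f)
  rep_rows <- vector("list", n_f)
  prev_n <- config$expected_n
  for (f in seq_len(n_f)) {
    his <- max_project(movie$frames[[f]]$histone)
    if (method == 1L) {
      m <- segment_method1(his, config)
    } else {
      cfg <- config; cfg$expected_n <- prev_n
      ms2 <- if (use_ms2) max_project(movie$frames[[f]]$ms2) else NULL
      m <- segment_method2(his, ms2, cfg)
      if (max(m) > 0L) prev_n <- max(m)
    }
    masks[[f]] <- m
    rep_rows[[f]] <- data.frame(frame = f, n_labels = max(m),
                                threshold = attr(m, "threshold"),
                                method = attr(m, "method"))
  }
  list(masks = masks, report = do.call(rbind, rep_rows))
}

#' Match segmented labels to ground-truth labels by IoU
#'
#' Greedy best-overlap matching between truth and predicted labels; a truth
#' nucleus counts as recovered when its best-matching predicted label reaches
#' the IoU cutoff.
#'
#' @param truth_mask,pred_mask integer label matrices of equal shape.
#' @param iou_cutoff intersection-over-union threshold (default 0.7).
#' @return list with `recall`, `n_truth`, `n_matched`, and a per-truth-label
#'   data.frame `matches` (`truth`, `pred`, `iou`).
#' @export
segmentation_recall <- function(truth_mask, pred_mask, iou_cutoff = 0.7) {
  stopifnot(all(dim(truth_mask) == dim(pred_mask)))
  tl <- sort(unique(truth_mask[truth_mask > 0L]))
  rows <- lapply(tl, function(t) {
    tidx <- truth_mask == t
    preds <- pred_mask[tidx]
    preds <- preds[preds > 0L]
    if (!length(preds)) return(data.frame(truth = t, pred = NA_integer_, iou = 0))
    cand <- as.integer(names(sort(table(preds), decreasing = TRUE)))
    best <- 0; best_p <- NA_integer_
    for (p in cand[seq_len(min(3L, length(cand)))]) {
      pidx <- pred_mask == p
      i <- sum(tidx & pidx); u <- sum(tidx | pidx)
      if (i / u > best) { best <- i / u; best_p <- p }
    }
    data.frame(truth = t, pred = best_p, iou = best)
  })
  m <- do.call(rbind, rows)
  list(recall = mean(m$iou >= iou_cutoff), n_truth = length(tl),
       n_matched = sum(m$iou >= iou_cutoff), matches = m)
}
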