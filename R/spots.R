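#' Locate the transcription spot of one nucleus in a 3D MS2 stack
#'
#' The spot position is the brightest voxel among all z-planes over the
#' nucleus's projected (y, x) footprint; ties are broken by lowest z, then
#' row-major (y, then x) order.
#'
#' @param volume 3D `y, x, z` array (one timepoint of the raw MS2 channel).
#' @param mask 2D integer label matrix co-registered with the projection.
#' @param label nucleus label to search.
#' @return integer vector `c(z, y, x)`.
#' @export
locate_spot <- function(volume, mask, label) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  idx <- which(mask == label)
  if (!length(idx)) stop("locate_spot: label ", label, " has an empty region")
  h <- dim(volume)[1L]
  n_z <- dim(volume)[3L]
  plane_len <- h * dim(volume)[2L]
  vals <- vapply(seq_len(n_z), function(z) volume[idx + (z - 1L) * plane_len],
                 numeric(length(idx)))
  vals <- matrix(vals, nrow = length(idx))
  mx <- max(vals)
  hit <- which(vals == mx, arr.ind = TRUE)
  py <- (idx[hit[, 1L]] - 1L) %% h + 1L
  px <- (idx[hit[, 1L]] - 1L) %/% h + 1L
  ord <- order(hit[, 2L], py, px)[1L]
  c(z = hit[ord, 2L], y = py[ord], x = px[ord])
}

#' Fit a 2D Gaussian to a transcription spot
#'
#' Nonlinear least-squares fit of
#' `I(x, y) = alpha + I0 * exp(-((x - x0)^2 / (2 sx^2) + (y - y0)^2 / (2 sy^2)))`
#' over an odd `window` centered on the located spot, where `alpha` is the
#' local background, `I0` the peak amplitude, `(x0, y0)` the center and
#' `sx`, `sy` the spreads of the fluorescent dot. The spot intensity is the
#' background-subtracted integral `2 * pi * sx * sy * I0`. A fit whose
#' estimated dot exceeds the fitted region (`2 * sigma > window / 2` on
#' either axis) or whose solver fails is flagged invalid and carries no
#' integral; near-flat windows converge to `I0 ~ 0` and stay valid with an
#' integral of ~0.
#'
#' @param plane 2D raster (the spot's z-plane).
#' @param center `c(y, x)` spot position (pixels, 1-based).
#' @param window odd window size in pixels (default 11). Windows clipped at
#'   the image edge are fitted anyway and flagged `clipped`.
#' @return an object of class `spot_fit`: `alpha`, `I0`, `x0`, `y0`,
#'   `sigma_x`, `sigma_y`, `integral` (NA when invalid), `residual`, `valid`,
#'   `clipped`.
#' @export
fit_spot <- function(plane, center, window = 11L) {
  stopifnot(is.matrix(plane), window %% 2L == 1L, window >= 3L)
  half <- window %/% 2L
  cy <- as.integer(round(center[1L])); cx <- as.integer(round(center[2L]))
  y0r <- max(1L, cy - half); y1r <- min(nrow(plane), cy + half)
  x0r <- max(1L, cx - half); x1r <- min(ncol(plane), cx + half)
  clipped <- (y1r - y0r + 1L) < window || (x1r - x0r + 1L) < window
  sub <- plane[y0r:y1r, x0r:x1r, drop = FALSE]
  ys <- y0r:y1r; xs <- x0r:x1r
  yy <- rep(ys, times = length(xs)); xx <- rep(xs, each = length(ys))
  vv <- as.vector(sub)
  border <- sub[c(1L, nrow(sub)), , drop = FALSE]
  alpha0 <- stats::median(c(border, sub[, c(1L, ncol(sub))]))
  i00 <- max(plane[cy, cx] - alpha0, 0)
  start <- c(alpha = alpha0, I0 = i00, x0 = cx, y0 = cy, sx = 1.5, sy = 1.5)
  lower <- c(-Inf, 0, x0r - 1, y0r - 1, 0.3, 0.3)
  upper <- c(Inf, Inf, x1r + 1, y1r + 1, 8, 8)
  resid_fun <- function(p) {
    p[1L] + p[2L] * exp(-((xx - p[3L])^2 / (2 * p[5L]^2) +
                          (yy - p[4L])^2 / (2 * p[6L]^2))) - vv
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$info %in% 1:4
  if (!ok) {
    return(structure(list(alpha = NA_real_, I0 = NA_real_, x0 = NA_real_,
                          y0 = NA_real_, sigma_x = NA_real_, sigma_y = NA_real_,
                          integral = NA_real_, residual = NA_real_,
                          valid = FALSE, clipped = clipped),
                     class = "spot_fit"))
  }
  p <- fit$par
  oversized <- (2 * p[5L] > window / 2) || (2 * p[6L] > window / 2)
  near_flat <- p[2L] <= 1e-8 * max(1, abs(p[1L]))
  valid <- !oversized || near_flat
  integral <- if (valid) 2 * pi * p[5L] * p[6L] * p[2L] else NA_real_
  structure(list(alpha = unname(p[1L]), I0 = unname(p[2L]),
                 x0 = unname(p[3L]), y0 = unname(p[4L]),
                 sigma_x = unname(p[5L]), sigma_y = unname(p[6L]),
                 integral = unname(integral),
                 residual = sum(fit$fvec^2), valid = valid, clipped = clipped),
            class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf("spot_fit: I0=%.3g alpha=%.3g center=(%.2f, %.2f) sigma=(%.2f, %.2f) integral=%.4g valid=%s\n",
              x$I0, x$alpha, x$y0, x$x0, x$sigma_y, x$sigma_x, x$integral,
              x$valid))
  invisible(x)
}

#' Record an exclusion for a failed spot fit
#'
#' Invalid fits (oversized dot or solver failure) exclude the whole timepoint
#' of the corresponding nucleus from quantitative output.
#'
#' @param fit a `spot_fit`.
#' @param nucleus_id,frame identifiers of the fitted nucleus and timepoint.
#' @return `NULL` for a valid fit, else a one-row data.frame
#'   `nucleus_id`, `frame`, `reason`.
#' @export
spot_invalidation <- function(fit, nucleus_id, frame) {
  if (isTRUE(fit$valid)) return(NULL)
  reason <- if (is.na(fit$I0)) "solver" else "oversized"
  data.frame(nucleus_id = nucleus_id, frame = frame, reason = reason)
}

#' Subtract the per-trajectory minimum so the baseline is zero
#'
#' @param x a numeric intensity vector, or a long trajectory data.frame with
#'   `nucleus_id` and `intensity` columns (corrected per nucleus; rows flagged
#'   in an `excluded` column are ignored when taking the minimum).
#' @return the baseline-corrected object (same shape as the input).
#' @export
baseline_correct <- function(x) {
  if (is.numeric(x)) {
    v <- x[is.finite(x)]
    if (!length(v)) stop("baseline_correct: no finite values")
    return(x - min(v))
  }
  stopifnot(is.data.frame(x), all(c("nucleus_id", "intensity") %in% names(x)))
  fi <- attr(x, "frame_interval")
  for (id in unique(x$nucleus_id)) {
    sel <- x$nucleus_id == id
    use <- sel & is.finite(x$intensity)
    if (!is.null(x$excluded)) use <- use & !x$excluded
    if (!any(use)) stop("baseline_correct: trajectory ", id, " is fully excluded")
    x$intensity[sel] <- x$intensity[sel] - min(x$intensity[use])
  }
  attr(x, "frame_interval") <- fi
  attr(x, "baseline_corrected") <- TRUE
  x
}

.center_in_label <- function(mask, label, y0, x0, margin = 1L) {
  ry <- round(y0); rx <- round(x0)
  yy <- max(1L, ry - margin):min(nrow(mask), ry + margin)
  xx <- max(1L, rx - margin):min(ncol(mask), rx + margin)
  if (ry < 1 - margin || ry > nrow(mask) + margin ||
      rx < 1 - margin || rx > ncol(mask) + margin) return(FALSE)
  any(mask[yy, xx] == label)
}

#' Quantify MS2 trajectories for every tracked nucleus
#'
#' For each tracked nucleus and frame: locate the brightest voxel inside the
#' nucleus footprint in the raw 3D MS2 stack, fit a 2D Gaussian at its
#' z-plane, and take the background-subtracted integral as the spot
#' intensity. Invalid fits exclude the timepoint; excluded and untracked
#' (gap) frames are filled by linear interpolation and flagged so downstream
#' totals can ignore them. Trajectories are baseline-corrected (per-nucleus
#' minimum subtracted) unless `baseline = FALSE`.
#'
#' @param movie an `ms2_movie`.
#' @param masks per-frame label matrices.
#' @param tracks a `nucleus_tracks` table from [link_nuclei()].
#' @param window Gaussian fit window (odd, default 11).
#' @param baseline apply [baseline_correct()] (default TRUE).
#' @return list with `trajectories` (long data.frame `nucleus_id`, `frame`,
#'   `time_s`, `intensity`, `excluded`, with attribute `frame_interval`) and
#'   `fits` (one row per fitted spot with all `spot_fit` fields).
#' @export
quantify_movie <- function(movie, masks, tracks, window = 11L,
                           baseline = TRUE) {
  stopifnot(inherits(movie, "ms2_movie"))
  n_frames <- length(movie$frames)
  ids <- sort(unique(tracks$nucleus_id))
  fit_rows <- list(); fi <- 0L
  traj_rows <- list()
  for (id in ids) {
    tr <- tracks[tracks$nucleus_id == id, ]
    intens <- rep(NA_real_, n_frames)
    excl <- rep(TRUE, n_frames)
    for (q in seq_len(nrow(tr))) {
      f <- tr$frame[q]
      vol <- movie$frames[[f]]$ms2
      pos <- tryCatch(locate_spot(vol, masks[[f]], tr$label[q]),
                      error = function(e) NULL)
      if (is.null(pos)) next
      fit <- fit_spot(vol[, , pos[1L]], pos[2:3], window = window)
      fi <- fi + 1L
      fit_rows[[fi]] <- data.frame(nucleus_id = id, frame = f,
                                   z = pos[1L], alpha = fit$alpha, I0 = fit$I0,
                                   x0 = fit$x0, y0 = fit$y0,
                                   sigma_x = fit$sigma_x, sigma_y = fit$sigma_y,
                                   integral = fit$integral,
                                   residual = fit$residual,
                                   valid = fit$valid, clipped = fit$clipped)
      if (fit$valid) {
        # a transcription site must lie inside its nucleus: a fit whose
        # center sits outside the label footprint (1 px margin) has locked
        # onto a neighboring nucleus's dot and counts as no dot here
        if (fit$I0 > 0 && !.center_in_label(masks[[f]], tr$label[q],
                                            fit$y0, fit$x0)) {
          intens[f] <- 0
        } else {
          intens[f] <- fit$integral
        }
        excl[f] <- FALSE
      }
    }
    if (all(excl)) {
      warning("quantify_movie: nucleus ", id, " has no valid fit; set to zero")
      intens[] <- 0
    } else if (any(excl)) {
      known <- which(!excl)
      intens <- stats::approx(known, intens[known], xout = seq_len(n_frames),
                              rule = 2)$y
    }
    traj_rows[[length(traj_rows) + 1L]] <-
      data.frame(nucleus_id = id, frame = seq_len(n_frames),
                 time_s = (seq_len(n_frames) - 1L) * movie$frame_interval,
                 intensity = intens, excluded = excl)
  }
  trajs <- do.call(rbind, traj_rows)
  attr(trajs, "frame_interval") <- movie$frame_interval
  if (baseline) trajs <- baseline_correct(trajs)
  list(trajectories = trajs,
       fits = if (fi) do.call(rbind, fit_rows) else NULL)
}
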