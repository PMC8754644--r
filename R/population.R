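#' Instantaneous and cumulative active-nucleus fractions
#'
#' A nucleus is instantaneously active at a frame when its raw MS2 intensity
#' exceeds the group activity threshold, 10% of the maximum intensity across
#' all trajectories of the group. The cumulative fraction counts nuclei that
#' have been active at any frame up to and including the current one. The
#' mean and standard deviation of the intensity among instantaneously active
#' nuclei are reported per frame.
#'
#' @param trajectories long data.frame `nucleus_id`, `frame`, `time_s`,
#'   `intensity`.
#' @param frac threshold fraction of the global maximum (default 0.10).
#' @param threshold optional fixed activity threshold (AU) overriding the
#'   rule.
#' @return data.frame `frame`, `time_s`, `inst_fraction`, `cum_fraction`,
#'   `mean_active`, `sd_active` with attribute `threshold`; class
#'   `population_series`.
#' @export
active_fractions <- function(trajectories, frac = 0.10, threshold = NULL) {
  stopifnot(nrow(trajectories) > 0)
  if (is.null(threshold)) threshold <- frac * max(trajectories$intensity)
  ids <- sort(unique(trajectories$nucleus_id))
  frames <- sort(unique(trajectories$frame))
  wide <- matrix(NA_real_, length(ids), length(frames),
                 dimnames = list(ids, frames))
  wide[cbind(match(trajectories$nucleus_id, ids),
             match(trajectories$frame, frames))] <- trajectories$intensity
  act <- wide > threshold
  inst <- colMeans(act, na.rm = TRUE)
  ever <- apply(act, 1L, cummax)           # frames x nuclei
  cum <- rowMeans(ever)
  mean_act <- vapply(seq_along(frames), function(j) {
    v <- wide[act[, j], j]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  sd_act <- vapply(seq_along(frames), function(j) {
    v <- wide[act[, j], j]
    if (length(v) > 1L) stats::sd(v) else NA_real_
  }, 0)
  ts <- trajectories$time_s[match(frames, trajectories$frame)]
  out <- data.frame(frame = frames, time_s = ts, inst_fraction = inst,
                    cum_fraction = cum, mean_active = mean_act,
                    sd_active = sd_act)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("population_series", "data.frame")
  out
}

#' Fit an exponential distribution to OFF (or ON) durations
#'
#' Maximum-likelihood single-exponential fit (rate = 1 / mean) with a
#' Kolmogorov-Smirnov goodness-of-fit test against the fitted distribution.
#' OFF durations between consecutive bursts are expected to fit a single
#' exponential when burst initiation is one rate-limiting step; ON durations
#' under multi-step OFF-switching are expected to fail the same test.
#'
#' @param durations numeric vector of durations (at least 10).
#' @return list `rate` (1 / duration unit), `mean`, `ks_stat`, `p_value`,
#'   `n`.
#' @export
fit_off_durations <- function(durations) {
  durations <- durations[is.finite(durations) & durations > 0]
  if (length(durations) < 10L)
    stop("fit_off_durations: need at least 10 positive durations")
  rate <- 1 / mean(durations)
  ks <- suppressWarnings(stats::ks.test(durations, "pexp", rate = rate))
  list(rate = rate, mean = mean(durations),
       ks_stat = unname(ks$statistic), p_value = ks$p.value,
       n = length(durations))
}

# biased sample autocovariance of a series at lags 0..max_lag
.autocov <- function(d, max_lag) {
  n <- length(d); m <- mean(d)
  vapply(0:max_lag, function(k)
    sum((d[seq_len(n - k)] - m) * (d[seq_len(n - k) + k] - m)) / n, 0)
}

#' Autocorrelation periodicity of MS2 trajectories with a shuffled null
#'
#' Per nucleus: the trace is smoothed (window 5), its first derivative taken
#' to remove slow trends, and the biased sample autocorrelation computed at
#' integer-frame lags, then normalized to 1 at the smallest lag of the
#' frame-interval lag grid (lag 0 by default; `norm_lag = 1` normalizes at
#' the first nonzero lag instead, which is ill-conditioned for
#' uncorrelated traces). The reported curve is the mean over nuclei. The
#' null curve is built from per-nucleus random permutations of the
#' trend-removed derivative sequence, which destroys all temporal structure;
#' permuting the raw trace instead would reintroduce the smoothing filter's
#' own deterministic autocorrelation and leave the null non-flat.
#'
#' @param trajectories long data.frame `nucleus_id`, `frame`, `intensity`
#'   (attribute `frame_interval`, or pass it).
#' @param frame_interval sampling period (s).
#' @param max_lag largest lag (frames); default covers half the trace.
#' @param smooth_window smoothing window (frames).
#' @param norm_lag lag (frames) at which curves are normalized to 1.
#' @param shuffle_seed seed for the time-shuffled null.
#' @return list of class `autocorr_result`: `lag_s`, `lag_frames`,
#'   `mean_ac`, `null_ac`, `per_nucleus` (matrix lags x nuclei),
#'   `shuffle_seed`, `skipped` (ids of constant traces).
#' @export
autocorrelate <- function(trajectories, frame_interval = NULL, max_lag = NULL,
                          smooth_window = 5L, norm_lag = 0L,
                          shuffle_seed = 1L) {
  if (is.null(frame_interval)) frame_interval <- attr(trajectories, "frame_interval")
  stopifnot(!is.null(frame_interval), norm_lag %in% c(0L, 1L))
  traces <- split(trajectories$intensity, trajectories$nucleus_id)
  n_fr <- min(lengths(traces))
  if (n_fr < 2L) stop("autocorrelate: need at least 2 frames per trajectory")
  if (is.null(max_lag)) max_lag <- max(2L, (n_fr - 1L) %/% 2L)
  set.seed(shuffle_seed)
  curve_of <- function(d) {
    ac <- .autocov(d, max_lag)
    denom <- ac[norm_lag + 1L]
    if (denom == 0) return(NULL)
    ac / denom
  }
  curves <- list(); null_curves <- list(); skipped <- c()
  for (id in names(traces)) {
    d <- diff(smooth_trajectory(traces[[id]], smooth_window))
    cv <- if (stats::sd(d) > 0) curve_of(d) else NULL
    if (is.null(cv)) { skipped <- c(skipped, id); next }
    curves[[id]] <- cv
    nv <- curve_of(sample(d))
    null_curves[[id]] <- if (is.null(nv)) rep(NA_real_, max_lag + 1L) else nv
  }
  if (length(skipped))
    warning("autocorrelate: skipped constant trajectories: ",
            paste(skipped, collapse = ", "))
  if (!length(curves)) stop("autocorrelate: no usable trajectory")
  per <- do.call(cbind, curves)
  nul <- do.call(cbind, null_curves)
  keep <- (norm_lag + 1L):(max_lag + 1L)   # report from the smallest lag on
  lag_frames <- (0:max_lag)[keep]
  structure(list(lag_s = lag_frames * frame_interval,
                 lag_frames = lag_frames,
                 mean_ac = rowMeans(per)[keep],
                 null_ac = rowMeans(nul, na.rm = TRUE)[keep],
                 per_nucleus = per[keep, , drop = FALSE],
                 shuffle_seed = shuffle_seed, skipped = skipped),
            class = "autocorr_result")
}

#' First periodicity peak of an autocorrelation curve
#'
#' Finds the first local maximum after the initial anti-correlation dip:
#' the curve is followed downhill from the smallest lag to its first turning
#' point and the peak is the largest value beyond it.
#'
#' @param res an `autocorr_result`.
#' @return list `lag_frames`, `lag_s`, `value`; `NA`s when no interior peak
#'   exists.
#' @export
autocorr_peak <- function(res) {
  v <- res$mean_ac
  turn <- which(diff(v) > 0)
  if (!length(turn)) return(list(lag_frames = NA, lag_s = NA, value = NA))
  k0 <- turn[1L] + 1L
  k <- k0 - 1L + which.max(v[k0:length(v)])
  list(lag_frames = res$lag_frames[k], lag_s = res$lag_s[k], value = v[k])
}
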