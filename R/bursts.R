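#' Centered moving-average smoothing
#'
#' Averages within a centered window of `window` timeframes; at the trace
#' edges the window is truncated to the available frames.
#'
#' @param x numeric trace.
#' @param window odd window length (frames); `1` is the identity.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_trajectory <- function(x, window = 5L) {
  stopifnot(is.numeric(x), window >= 1L, window %% 2L == 1L)
  n <- length(x)
  if (window > n) stop("smooth_trajectory: window longer than the trace")
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect transcriptional bursts in a smoothed trajectory
#'
#' A burst opens at the first frame strictly above `threshold` and tracks its
#' running local peak; it closes at the first frame that drops strictly below
#' `end_frac` of that peak (that frame is excluded). The detected interval is
#' then moved `shift` frames later (clamped at the trace end) to better
#' capture the center of the event. Bursts shorter than `min_len` frames
#' after the shift are discarded as detection noise, as is a burst that
#' starts at the very first frame on a monotonically decreasing run of
#' `min_len` frames (a trace caught mid-decay). Shifted bursts that come to
#' overlap are merged; detection resumes at the closing frame.
#'
#' @param smoothed smoothed intensity trace (see [smooth_trajectory()]).
#' @param threshold burst-start threshold (AU), must be > 0; see
#'   [group_threshold()].
#' @param min_len minimum burst length in frames (default 5).
#' @param end_frac burst-end fraction of the running local peak (default
#'   0.55).
#' @param shift frames by which the detected interval is moved (default 2).
#' @return data.frame `start_frame`, `end_frame` (inclusive), `peak_value`,
#'   `peak_frame` (from the smoothed trace over the final interval), with
#'   attributes `threshold` and `n_frames`; zero rows for silent traces.
#' @export
call_bursts <- function(smoothed, threshold, min_len = 5L, end_frac = 0.55,
                        shift = 2L) {
  stopifnot(is.numeric(smoothed), threshold > 0)
  x <- smoothed; n <- length(x)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (x[i] > threshold) {
      start <- i; peak <- x[i]
      j <- i + 1L
      while (j <= n && !(x[j] < end_frac * peak)) {
        if (x[j] > peak) peak <- x[j]
        j <- j + 1L
      }
      starts <- c(starts, start); ends <- c(ends, j - 1L)
      i <- j
    } else i <- i + 1L
  }
  keep_decline <- rep(TRUE, length(starts))
  for (b in seq_along(starts)) {
    if (starts[b] == 1L && min_len >= 2L &&
        (ends[b] - starts[b] + 1L) >= min_len) {
      run <- x[seq.int(starts[b], starts[b] + min_len - 1L)]
      if (all(diff(run) < 0)) keep_decline[b] <- FALSE
    }
  }
  starts <- starts[keep_decline]; ends <- ends[keep_decline]
  # shift and clamp
  s2 <- starts + shift
  e2 <- pmin(ends + shift, n)
  on_trace <- s2 <= n
  s2 <- s2[on_trace]; e2 <- e2[on_trace]
  # merge shifted bursts that overlap after clamping
  if (length(s2) > 1L) {
    ms <- s2[1L]; me <- e2[1L]; outs <- integer(0); oute <- integer(0)
    for (b in 2L:length(s2)) {
      if (s2[b] <= me) me <- max(me, e2[b])
      else { outs <- c(outs, ms); oute <- c(oute, me); ms <- s2[b]; me <- e2[b] }
    }
    s2 <- c(outs, ms); e2 <- c(oute, me)
  }
  keep <- (e2 - s2 + 1L) >= min_len
  s2 <- s2[keep]; e2 <- e2[keep]
  if (length(s2)) {
    pk <- vapply(seq_along(s2), function(b) max(x[s2[b]:e2[b]]), 0)
    pf <- vapply(seq_along(s2), function(b)
      s2[b] + which.max(x[s2[b]:e2[b]]) - 1L, 0L)
  } else { pk <- numeric(0); pf <- integer(0) }
  out <- data.frame(start_frame = s2, end_frame = e2,
                    peak_value = pk, peak_frame = pf)
  attr(out, "threshold") <- threshold
  attr(out, "n_frames") <- n
  out
}

#' Per-nucleus bursting statistics
#'
#' Amplitude is the mean over bursts of the smoothed-trace peak within each
#' burst; duration is the mean burst length; total output is the
#' rectangle-rule area under the full raw trajectory (not only in-burst
#' frames); the induction rate is the number of bursts divided by the time
#' elapsed from the first burst to the end of the trace.
#'
#' @param call a burst table from [call_bursts()].
#' @param raw raw intensity trace (same frames).
#' @param smoothed smoothed trace used for calling.
#' @param frame_interval sampling period (s).
#' @return list of class `burst_stats`: `n_bursts`, `amplitude` (AU),
#'   `duration` (s), `total_output` (AU s), `t_first` (s),
#'   `induction_rate` (bursts/min), `on_durations`, `off_durations` (s).
#'   Undefined quantities for silent nuclei are `NA`.
#' @export
burst_stats <- function(call, raw, smoothed, frame_interval) {
  nb <- nrow(call)
  total_output <- sum(raw) * frame_interval
  if (nb == 0L) {
    return(structure(list(n_bursts = 0L, amplitude = NA_real_,
                          duration = NA_real_, total_output = total_output,
                          t_first = NA_real_, induction_rate = NA_real_,
                          on_durations = numeric(0), off_durations = numeric(0)),
                     class = "burst_stats"))
  }
  lens <- call$end_frame - call$start_frame + 1L
  on_dur <- lens * frame_interval
  off_dur <- if (nb > 1L)
    (call$start_frame[-1L] - call$end_frame[-nb] - 1L) * frame_interval
  else numeric(0)
  t_first <- (call$start_frame[1L] - 1L) * frame_interval
  t_end <- (length(raw) - 1L) * frame_interval
  rate <- if (t_end > t_first) nb / (t_end - t_first) * 60 else NA_real_
  structure(list(n_bursts = nb, amplitude = mean(call$peak_value),
                 duration = mean(on_dur), total_output = total_output,
                 t_first = t_first, induction_rate = rate,
                 on_durations = on_dur, off_durations = off_dur),
            class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat(sprintf("burst_stats: %d bursts, amplitude %.3g AU, duration %.3g s, output %.4g AU*s, t_first %.3g s, rate %.3g /min\n",
              x$n_bursts, x$amplitude, x$duration, x$total_output, x$t_first,
              x$induction_rate))
  invisible(x)
}

#' Shared burst-start threshold for one experiment set
#'
#' One threshold per set of experiments: by default 10% of the maximum
#' smoothed intensity across all trajectories of the group (the same
#' fraction used to classify instantaneous activity), overridable with a
#' fixed value.
#'
#' @param trajectories long data.frame with `nucleus_id` and `intensity`.
#' @param frac fraction of the global smoothed maximum (default 0.10).
#' @param override fixed threshold (AU) bypassing the rule.
#' @param smooth_window smoothing window used before taking the maximum.
#' @return threshold (AU).
#' @export
group_threshold <- function(trajectories, frac = 0.10, override = NULL,
                            smooth_window = 5L) {
  if (!is.null(override)) return(override)
  mx <- max(unlist(lapply(split(trajectories$intensity, trajectories$nucleus_id),
                          smooth_trajectory, window = smooth_window)))
  if (!is.finite(mx) || mx <= 0)
    stop("group_threshold: group maximum is not positive")
  frac * mx
}

#' Call bursts and compute statistics for a whole group
#'
#' Applies the smoothing, shared-threshold burst calling and per-nucleus
#' statistics to every trajectory of one experiment set.
#'
#' @param trajectories long data.frame `nucleus_id`, `frame`, `intensity`
#'   (attribute `frame_interval`, or pass it explicitly).
#' @param frame_interval sampling period (s).
#' @param threshold `"auto"` (group rule) or a numeric value.
#' @param smooth_window,min_len,end_frac,shift burst-caller parameters.
#' @return list with `calls` (named list of per-nucleus burst tables),
#'   `stats` (data.frame, one row per nucleus), `threshold`,
#'   `on_durations`, `off_durations` (pooled, s).
#' @export
call_bursts_group <- function(trajectories, frame_interval = NULL,
                              threshold = "auto", smooth_window = 5L,
                              min_len = 5L, end_frac = 0.55, shift = 2L) {
  if (is.null(frame_interval)) frame_interval <- attr(trajectories, "frame_interval")
  stopifnot(!is.null(frame_interval))
  thr <- if (identical(threshold, "auto"))
    group_threshold(trajectories, smooth_window = smooth_window)
  else threshold
  ids <- sort(unique(trajectories$nucleus_id))
  calls <- list(); stat_rows <- list()
  for (id in ids) {
    raw <- trajectories$intensity[trajectories$nucleus_id == id]
    sm <- smooth_trajectory(raw, smooth_window)
    cl <- call_bursts(sm, thr, min_len = min_len, end_frac = end_frac,
                      shift = shift)
    st <- burst_stats(cl, raw, sm, frame_interval)
    calls[[as.character(id)]] <- cl
    stat_rows[[length(stat_rows) + 1L]] <-
      data.frame(nucleus_id = id, n_bursts = st$n_bursts,
                 amplitude = st$amplitude, duration = st$duration,
                 total_output = st$total_output, t_first = st$t_first,
                 induction_rate = st$induction_rate)
  }
  stats_df <- do.call(rbind, stat_rows)
  on_d <- unlist(lapply(calls, function(cl)
    (cl$end_frame - cl$start_frame + 1L) * frame_interval), use.names = FALSE)
  off_d <- unlist(lapply(calls, function(cl) {
    if (nrow(cl) > 1L)
      (cl$start_frame[-1L] - cl$end_frame[-nrow(cl)] - 1L) * frame_interval
    else numeric(0)
  }), use.names = FALSE)
  list(calls = calls, stats = stats_df, threshold = thr,
       on_durations = on_d, off_durations = off_d)
}
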