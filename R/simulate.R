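#' Simulate one MS2 trajectory from the telegraph model
#'
#' Event-driven (Gillespie-style) simulation of a two-state promoter:
#' OFF -> ON waiting times are Exponential(`k_on`); the ON -> OFF switch is
#' the sum of `off_steps` Exponential(`k_off`) steps (Erlang ON durations,
#' classic telegraph at `off_steps = 1`). While ON, Pol II initiation events
#' occur as a Poisson process at `r_load`. The fluorescence at each frame is
#' `unit_intensity` times the number of transcripts initiated within the last
#' `dwell` minutes (boxcar dwell kernel), plus Gaussian noise, clipped at 0.
#'
#' @param params a [telegraph_params()] object.
#' @param seed integer seed; the simulation is bit-reproducible given the seed.
#' @return a list with
#'   \describe{
#'     \item{trajectory}{data.frame `frame`, `time_s`, `intensity` (AU)}
#'     \item{on_intervals}{data.frame `t_start_s`, `t_end_s` of true ON periods}
#'     \item{init_times_s}{initiation event times (s)}
#'   }
#' @examples
#' p <- telegraph_params(k_on = 0.3, k_off = 1.2, r_load = 20, dwell = 1.5,
#'                       n_frames = 100)
#' sim <- simulate_trajectory(p, seed = 1)
#' @export
simulate_trajectory <- function(params, seed = NULL) {
  stopifnot(inherits(params, "telegraph_params"))
  if (!is.null(seed)) set.seed(seed)
  T_total <- params$n_frames * params$frame_interval / 60  # min
  t <- params$onset_delay
  on_start <- numeric(0); on_end <- numeric(0)
  init <- numeric(0)
  if (params$k_on > 0) {
    while (t < T_total) {
      t_on <- t + stats::rexp(1L, params$k_on)
      if (t_on >= T_total) break
      dur <- if (params$k_off > 0)
        sum(stats::rexp(params$off_steps, params$k_off)) else Inf
      t_off <- min(t_on + dur, T_total)
      on_start <- c(on_start, t_on); on_end <- c(on_end, t_off)
      span <- t_off - t_on
      if (params$r_load > 0 && span > 0) {
        k <- stats::rpois(1L, params$r_load * span)
        if (k > 0) init <- c(init, t_on + sort(stats::runif(k, 0, span)))
      }
      t <- t_on + dur
    }
  }
  ft <- (seq_len(params$n_frames) - 1L) * params$frame_interval / 60  # min
  counts <- if (length(init))
    vapply(ft, function(tf) sum(init > tf - params$dwell & init <= tf), 0)
  else rep(0, params$n_frames)
  sig <- params$unit_intensity * counts
  if (params$noise_sd > 0)
    sig <- pmax(0, sig + stats::rnorm(params$n_frames, 0, params$noise_sd))
  list(
    trajectory = data.frame(
      frame = seq_len(params$n_frames),
      time_s = (seq_len(params$n_frames) - 1L) * params$frame_interval,
      intensity = sig),
    on_intervals = data.frame(t_start_s = on_start * 60, t_end_s = on_end * 60),
    init_times_s = init * 60
  )
}

#' Simulate a group of telegraph trajectories
#'
#' Convenience wrapper producing a long-format trajectory table for a
#' population of nuclei sharing one parameter set (one "experiment set").
#'
#' @param params a [telegraph_params()] object.
#' @param n_nuclei number of nuclei.
#' @param seed base seed; nucleus `i` uses `seed + i`.
#' @return list with `trajectories` (long data.frame `nucleus_id`, `frame`,
#'   `time_s`, `intensity`) and `on_intervals` (data.frame with `nucleus_id`,
#'   `t_start_s`, `t_end_s`).
#' @export
simulate_group <- function(params, n_nuclei, seed = 1L) {
  sims <- lapply(seq_len(n_nuclei), function(i) simulate_trajectory(params, seed + i))
  trajs <- do.call(rbind, lapply(seq_len(n_nuclei), function(i) {
    tr <- sims[[i]]$trajectory
    cbind(nucleus_id = i, tr)
  }))
  ons <- do.call(rbind, lapply(seq_len(n_nuclei), function(i) {
    oi <- sims[[i]]$on_intervals
    if (nrow(oi)) cbind(nucleus_id = i, oi) else NULL
  }))
  if (is.null(ons))
    ons <- data.frame(nucleus_id = integer(0), t_start_s = numeric(0),
                      t_end_s = numeric(0))
  attr(trajs, "frame_interval") <- params$frame_interval
  list(trajectories = trajs, on_intervals = ons)
}

#' Simulate deterministic periodic bursting
#'
#' Square-wave bursting with a fixed period, used to validate periodicity
#' detection by autocorrelation: each nucleus is ON (at `amplitude`) for
#' `on_frames` frames out of every `period_frames`, with a per-nucleus random
#' phase, plus Gaussian noise clipped at 0.
#'
#' @param n_nuclei number of nuclei.
#' @param n_frames trace length.
#' @param period_frames bursting period (frames).
#' @param on_frames ON portion of each period (frames).
#' @param amplitude ON-level signal (AU).
#' @param noise_sd additive Gaussian noise (AU).
#' @param frame_interval sampling period (s).
#' @param seed integer seed.
#' @return long data.frame `nucleus_id`, `frame`, `time_s`, `intensity` with
#'   a `frame_interval` attribute.
#' @export
simulate_periodic_group <- function(n_nuclei, n_frames = 200L,
                                    period_frames = 20L, on_frames = 5L,
                                    amplitude = 10, noise_sd = 0.5,
                                    frame_interval = 16.8, seed = 1L) {
  stopifnot(period_frames >= 2L, on_frames >= 1L, on_frames < period_frames)
  set.seed(seed)
  out <- lapply(seq_len(n_nuclei), function(i) {
    phase <- sample.int(period_frames, 1L) - 1L
    pos <- ((seq_len(n_frames) - 1L + phase) %% period_frames)
    sig <- ifelse(pos < on_frames, amplitude, 0)
    if (noise_sd > 0) sig <- pmax(0, sig + stats::rnorm(n_frames, 0, noise_sd))
    data.frame(nucleus_id = i, frame = seq_len(n_frames),
               time_s = (seq_len(n_frames) - 1L) * frame_interval,
               intensity = sig)
  })
  res <- do.call(rbind, out)
  attr(res, "frame_interval") <- frame_interval
  res
}

#' True OFF durations between consecutive ON intervals
#'
#' @param on_intervals data.frame with `t_start_s`, `t_end_s` (optionally a
#'   `nucleus_id` column; gaps are computed within each nucleus).
#' @return numeric vector of OFF durations (s).
#' @export
true_off_durations <- function(on_intervals) {
  if (!nrow(on_intervals)) return(numeric(0))
  if (is.null(on_intervals$nucleus_id)) on_intervals$nucleus_id <- 1L
  unlist(lapply(split(on_intervals, on_intervals$nucleus_id), function(d) {
    d <- d[order(d$t_start_s), ]
    if (nrow(d) < 2L) return(numeric(0))
    d$t_start_s[-1L] - d$t_end_s[-nrow(d)]
  }), use.names = FALSE)
}
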