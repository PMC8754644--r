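#' Telegraph-model parameters for one promoter
#'
#' Parameter container for the two-state (ON/OFF) telegraph model of promoter
#' activity with Poisson Pol II loading while ON. Each initiated transcript
#' contributes `unit_intensity` fluorescence units for `dwell` minutes (boxcar
#' dwell kernel), emulating the residence of a nascent transcript at the
#' transcription site.
#'
#' @param k_on promoter activation rate (1/min).
#' @param k_off promoter inactivation rate (1/min). With `off_steps > 1` this
#'   is the rate of each sequential inactivation step, so the mean ON duration
#'   is `off_steps / k_off` and ON durations are Erlang distributed.
#' @param r_load Pol II initiation rate while ON (initiations/min).
#' @param dwell residence time of one nascent transcript's signal (min).
#' @param unit_intensity fluorescence contribution of one transcript (AU).
#' @param noise_sd additive Gaussian noise scale (AU).
#' @param onset_delay time before the promoter may first activate (min).
#' @param frame_interval sampling period (s).
#' @param n_frames trajectory length (frames).
#' @param off_steps number of sequential exponential steps for the ON->OFF
#'   switch (default 1 = classic telegraph).
#'
#' @return an object of class `telegraph_params`.
#' @examples
#' p <- telegraph_params(k_on = 0.3, k_off = 1.2, r_load = 20, dwell = 1.5)
#' @export
telegraph_params <- function(k_on, k_off, r_load, dwell,
                             unit_intensity = 1, noise_sd = 0,
                             onset_delay = 0, frame_interval = 16.8,
                             n_frames = 150, off_steps = 1L) {
  p <- list(k_on = k_on, k_off = k_off, r_load = r_load, dwell = dwell,
            unit_intensity = unit_intensity, noise_sd = noise_sd,
            onset_delay = onset_delay, frame_interval = frame_interval,
            n_frames = as.integer(n_frames), off_steps = as.integer(off_steps))
  num <- c("k_on", "k_off", "r_load", "dwell", "unit_intensity", "noise_sd",
           "onset_delay", "frame_interval")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("telegraph_params: `", nm, "` must be a finite non-negative scalar")
  }
  if (p$frame_interval <= 0) stop("telegraph_params: `frame_interval` must be > 0")
  if (p$n_frames < 1L) stop("telegraph_params: `n_frames` must be >= 1")
  if (p$off_steps < 1L) stop("telegraph_params: `off_steps` must be >= 1")
  structure(p, class = "telegraph_params")
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat("telegraph_params: k_on", x$k_on, "k_off", x$k_off, "(1/min), r_load",
      x$r_load, "/min, dwell", x$dwell, "min,", x$n_frames, "frames @",
      x$frame_interval, "s\n")
  invisible(x)
}

#' Synthetic imaging-field parameters
#'
#' Geometry and noise of the rendered two-channel field: a histone-like
#' nuclear channel (filled textured disks) and an MS2 channel with one
#' diffraction-limited dot per transcribing nucleus.
#'
#' @param image_shape raster height x width in pixels.
#' @param n_z number of z-planes in the MS2 stack.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius nucleus disk radius (pixels).
#' @param drift_sd per-frame Gaussian centroid displacement scale (pixels);
#'   must be smaller than `nucleus_radius`. Nuclei jitter around anchored
#'   sites (mean-reverting, stationary sd `drift_sd`) while the whole field
#'   shares a slow random-walk drift, as in an embryo held on the stage.
#' @param psf_sigma isotropic Gaussian spread of the rendered dot (pixels).
#' @param stripe_pattern optional list of stripes along the anterior-posterior
#'   (x) axis; each element is `list(x_range = c(x0, x1), params =
#'   telegraph_params(...))`. Nuclei outside every stripe stay silent.
#' @param histone_level peak histone disk intensity (AU).
#' @param histone_noise_sd additive noise in the histone channel (AU).
#' @param ms2_background MS2 channel background level (AU).
#' @param ms2_noise_sd additive noise in the MS2 channel (AU).
#' @param min_spacing minimum center-to-center distance at placement
#'   (pixels); default `2 * nucleus_radius + 5` keeps drifting disks apart.
#'
#' @return an object of class `field_params`.
#' @export
field_params <- function(image_shape = c(300L, 300L), n_z = 3L,
                         n_nuclei = 100L, nucleus_radius = 7,
                         drift_sd = 0.3, psf_sigma = 1.3,
                         stripe_pattern = NULL,
                         histone_level = 0.6, histone_noise_sd = 0.02,
                         ms2_background = 0, ms2_noise_sd = 0,
                         min_spacing = NULL) {
  if (length(image_shape) != 2L || any(image_shape < 16))
    stop("field_params: `image_shape` must be height, width >= 16")
  if (n_z < 1L) stop("field_params: `n_z` must be >= 1")
  if (n_nuclei < 1L) stop("field_params: `n_nuclei` must be >= 1")
  if (drift_sd >= nucleus_radius)
    stop("field_params: `drift_sd` must be < `nucleus_radius`")
  if (is.null(min_spacing)) min_spacing <- 2 * nucleus_radius + 5
  structure(list(image_shape = as.integer(image_shape), n_z = as.integer(n_z),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius, drift_sd = drift_sd,
                 psf_sigma = psf_sigma, stripe_pattern = stripe_pattern,
                 histone_level = histone_level,
                 histone_noise_sd = histone_noise_sd,
                 ms2_background = ms2_background, ms2_noise_sd = ms2_noise_sd,
                 min_spacing = min_spacing),
            class = "field_params")
}

# Preset table: absolute rates are package choices; only the ordinal
# relations between variants (amplitude, frequency, onset) are meaningful.
.variant_table <- function() {
  list(
    WT    = list(k_on = 0.30, k_off = 1.2, r_load = 20, onset_delay = 6),
    mTATA = list(k_on = 0.15, k_off = 1.2, r_load = 7,  onset_delay = 10),
    mInr  = list(k_on = 0.10, k_off = 1.2, r_load = 16, onset_delay = 12),
    mMTE  = list(k_on = 0.18, k_off = 1.2, r_load = 18, onset_delay = 9),
    mDPE  = list(k_on = 0.10, k_off = 1.2, r_load = 18, onset_delay = 12),
    Zelda = list(k_on = 0.36, k_off = 1.2, r_load = 22, onset_delay = 2.5)
  )
}

#' Telegraph presets emulating core-promoter variants
#'
#' Returns a [telegraph_params()] set for one of the promoter variants the
#' bursting regimes emulate. The presets encode ordinal relations only:
#' the TATA mutant has reduced amplitude (`r_load`) and frequency (`k_on`);
#' the Inr/MTE/DPE mutants mainly reduce burst frequency and delay onset,
#' with the MTE mutant the mildest; the Zelda variant shortens the onset
#' delay and bursts slightly more frequently than WT. Absolute rates are
#' package choices, not measured values.
#'
#' @param name one of `"WT"`, `"mTATA"`, `"mInr"`, `"mMTE"`, `"mDPE"`,
#'   `"Zelda"`.
#' @param ... overrides passed on to [telegraph_params()] (e.g. `n_frames`).
#' @return a `telegraph_params` object.
#' @examples
#' variant_presets("WT")$r_load > variant_presets("mTATA")$r_load
#' @export
variant_presets <- function(name, ...) {
  tab <- .variant_table()
  if (!is.character(name) || length(name) != 1L || !name %in% names(tab))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(tab), collapse = ", "))
  v <- tab[[name]]
  dots <- list(...)
  args <- list(k_on = v$k_on, k_off = v$k_off, r_load = v$r_load,
               dwell = 1.5, unit_intensity = 1, noise_sd = 0.6,
               onset_delay = v$onset_delay)
  args[names(dots)] <- dots
  do.call(telegraph_params, args)
}
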