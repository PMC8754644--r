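#' mRNA decay parameters
#'
#' First-order decay parameterized by a half-life (default 7 min, the
#' measured turnover of ftz transcripts in early embryos). The default
#' `"exponential"` model applies standard first-order kinetics
#' `2^(-age / half_life)`; the `"linear"` alternative decays each frame's
#' cohort linearly to zero over `2 * half_life`. Both retain exactly half of
#' a cohort at one half-life.
#'
#' @param half_life mRNA half-life (min), > 0.
#' @param model `"exponential"` (default) or `"linear"`.
#' @return list of class `decay_params`.
#' @export
decay_params <- function(half_life = 7, model = c("exponential", "linear")) {
  if (!is.numeric(half_life) || half_life <= 0)
    stop("decay_params: `half_life` must be > 0")
  structure(list(half_life = half_life, model = match.arg(model)),
            class = "decay_params")
}

#' Predicted intact mRNA remaining at the end of the analysis
#'
#' Treats the raw MS2 intensity at each frame as a production-rate proxy:
#' the cohort produced at frame time `t_f` contributes
#' `intensity * frame_interval` mRNA equivalents, decayed over the age
#' `t_end - t_f` by the configured model.
#'
#' @param traj numeric intensity vector, or a single-nucleus data.frame with
#'   `time_s` and `intensity`.
#' @param params a [decay_params()].
#' @param t_end end of the analysis window (s); must be at or after the last
#'   frame.
#' @param frame_interval sampling period (s), required for the vector form.
#' @return remaining intact mRNA (AU s equivalents).
#' @export
remaining_mrna <- function(traj, params = decay_params(), t_end = NULL,
                           frame_interval = NULL) {
  stopifnot(inherits(params, "decay_params"))
  if (is.data.frame(traj)) {
    time_s <- traj$time_s; intens <- traj$intensity
    if (is.null(frame_interval))
      frame_interval <- if (length(time_s) > 1L) diff(time_s[1:2]) else
        attr(traj, "frame_interval")
  } else {
    stopifnot(!is.null(frame_interval))
    intens <- traj
    time_s <- (seq_along(traj) - 1L) * frame_interval
  }
  if (any(intens < 0))
    stop("remaining_mrna: negative intensities; baseline-correct first")
  if (is.null(t_end)) t_end <- max(time_s)
  if (t_end < max(time_s)) stop("remaining_mrna: t_end before the last frame")
  age_min <- (t_end - time_s) / 60
  frac <- switch(params$model,
                 exponential = 2^(-age_min / params$half_life),
                 linear = pmax(0, 1 - age_min / (2 * params$half_life)))
  sum(intens * frame_interval * frac)
}

#' Remaining mRNA for every nucleus of a group
#'
#' @param trajectories long data.frame `nucleus_id`, `time_s`, `intensity`.
#' @param params a [decay_params()].
#' @param t_end end of the analysis window (s); default = last frame.
#' @return data.frame `nucleus_id`, `amount`.
#' @export
remaining_mrna_group <- function(trajectories, params = decay_params(),
                                 t_end = NULL) {
  if (is.null(t_end)) t_end <- max(trajectories$time_s)
  ids <- sort(unique(trajectories$nucleus_id))
  amt <- vapply(ids, function(id)
    remaining_mrna(trajectories[trajectories$nucleus_id == id, ],
                   params, t_end), 0)
  data.frame(nucleus_id = ids, amount = amt)
}

#' False-colored spatial reconstitution of the expression pattern
#'
#' Fills each final-frame nucleus region with an intensity proportional to
#' its predicted intact mRNA level, scaled to the population maximum, and
#' overlays it (green) on the histone projection (gray).
#'
#' @param mask final-frame label matrix.
#' @param amounts data.frame `nucleus_id`, `amount` from
#'   [remaining_mrna_group()].
#' @param tracks `nucleus_tracks` table mapping nucleus ids to final-frame
#'   labels; `NULL` assumes `nucleus_id` equals the mask label.
#' @param histone optional histone raster for the overlay (same shape).
#' @param final_frame frame index of `mask` within `tracks` (default: the
#'   last frame present).
#' @return an `height x width x 3` RGB array in `[0, 1]`.
#' @export
render_pattern <- function(mask, amounts, tracks = NULL, histone = NULL,
                           final_frame = NULL) {
  h <- nrow(mask); w <- ncol(mask)
  lab_of <- amounts$nucleus_id
  if (!is.null(tracks)) {
    if (is.null(final_frame)) final_frame <- max(tracks$frame)
    fin <- tracks[tracks$frame == final_frame, ]
    lab_of <- fin$label[match(amounts$nucleus_id, fin$nucleus_id)]
    if (anyNA(lab_of))
      warning("render_pattern: ", sum(is.na(lab_of)),
              " nuclei not tracked in the final frame; rendered at zero")
  }
  mx <- max(amounts$amount, 0)
  level <- if (mx > 0) amounts$amount / mx else rep(0, nrow(amounts))
  fill <- matrix(0, h, w)
  for (q in seq_len(nrow(amounts))) {
    if (is.na(lab_of[q])) next
    fill[mask == lab_of[q]] <- level[q]
  }
  base <- if (is.null(histone)) matrix(0, h, w) else .normalize01(histone) * 0.5
  rgb <- array(0, c(h, w, 3L))
  rgb[, , 1L] <- base
  rgb[, , 2L] <- pmin(1, base + fill)
  rgb[, , 3L] <- base
  rgb
}
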