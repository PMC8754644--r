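#' Link segmented nuclei across frames into lineages
#'
#' Nearest-centroid lineage linking: for each new frame, candidate pairs
#' between open tracks and current labels are accepted greedily in ascending
#' Euclidean distance (ties broken by lower track id, then lower label), and
#' pairs farther apart than `max_disp` are refused, ending the track and
#' starting a new one. Because greedy ascending-distance matching is
#' symmetric in the two frames, the forward and backward passes agree by
#' construction. Tracks missing from up to `gap_max` consecutive frames are
#' bridged (the gap frames are flagged); longer absences split the lineage.
#'
#' @param masks list of per-frame integer label matrices.
#' @param max_disp maximum allowed centroid displacement per frame step (px).
#' @param gap_max longest bridged gap (frames), default 2.
#' @return data.frame `nucleus_id`, `frame`, `label`, `y`, `x`, `gap`
#'   (logical: frame reached across a gap), class `nucleus_tracks`.
#' @export
link_nuclei <- function(masks, max_disp, gap_max = 2L) {
  stopifnot(length(masks) >= 1L, max_disp > 0)
  cents <- lapply(masks, function(m) {
    cen <- .centroids_of(m)
    ids <- sort(unique(m[m > 0L]))
    data.frame(label = ids, y = cen[, 1L], x = cen[, 2L])
  })
  rows <- list(); ri <- 0L
  # open tracks: id -> list(y, x, last_frame)
  track_y <- numeric(0); track_x <- numeric(0); track_last <- integer(0)
  next_id <- 1L
  for (f in seq_along(cents)) {
    cc <- cents[[f]]
    assigned_track <- integer(0); assigned_label <- integer(0)
    if (nrow(cc) && length(track_y)) {
      open <- which(track_last >= f - 1L - gap_max)
      if (length(open)) {
        d <- outer(track_y[open], cc$y, "-")^2 + outer(track_x[open], cc$x, "-")^2
        cand <- which(d <= max_disp^2, arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(d[cand], open[cand[, 1L]], cc$label[cand[, 2L]])
          used_t <- logical(length(open)); used_l <- logical(nrow(cc))
          for (q in ord) {
            ti <- cand[q, 1L]; li <- cand[q, 2L]
            if (!used_t[ti] && !used_l[li]) {
              used_t[ti] <- TRUE; used_l[li] <- TRUE
              assigned_track <- c(assigned_track, open[ti])
              assigned_label <- c(assigned_label, li)
            }
          }
        }
      }
    }
    taken <- rep(FALSE, nrow(cc))
    if (length(assigned_label)) taken[assigned_label] <- TRUE
    for (q in seq_along(assigned_track)) {
      tid <- assigned_track[q]; li <- assigned_label[q]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(nucleus_id = tid, frame = f,
                               label = cc$label[li], y = cc$y[li], x = cc$x[li],
                               gap = track_last[tid] < f - 1L)
      track_y[tid] <- cc$y[li]; track_x[tid] <- cc$x[li]; track_last[tid] <- f
    }
    if (any(!taken)) for (li in which(!taken)) {
      tid <- next_id; next_id <- next_id + 1L
      track_y[tid] <- cc$y[li]; track_x[tid] <- cc$x[li]; track_last[tid] <- f
      ri <- ri + 1L
      rows[[ri]] <- data.frame(nucleus_id = tid, frame = f,
                               label = cc$label[li], y = cc$y[li], x = cc$x[li],
                               gap = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$nucleus_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("nucleus_tracks", "data.frame")
  attr(out, "max_disp") <- max_disp
  out
}

#' Check the (frame, label) exclusivity invariant of a track table
#'
#' @param tracks a `nucleus_tracks` data.frame.
#' @return TRUE invisibly; stops if any (frame, label) pair is claimed by two
#'   lineages or a lineage revisits a frame.
#' @export
validate_tracks <- function(tracks) {
  key <- paste(tracks$frame, tracks$label)
  if (anyDuplicated(key))
    stop("validate_tracks: a (frame, label) pair belongs to two tracks")
  per <- split(tracks$frame, tracks$nucleus_id)
  if (any(vapply(per, anyDuplicated, 0L) > 0L))
    stop("validate_tracks: a track visits the same frame twice")
  invisible(TRUE)
}
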