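# Shared small synthetic movie, rendered once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_movie <- function() {
  if (is.null(.fixture_env$small)) {
    tp <- telegraph_params(k_on = 0.3, k_off = 1.2, r_load = 20, dwell = 1.5,
                           noise_sd = 0, onset_delay = 0, n_frames = 30)
    fld <- field_params(image_shape = c(200L, 200L), n_nuclei = 40L,
                        drift_sd = 0.3)
    .fixture_env$small <- render_movie(fld, tp, seed = 42)
  }
  .fixture_env$small
}

# map recovered track ids to ground-truth nucleus ids by first-frame position
match_tracks_to_truth <- function(tracks, truth, frame = 1L) {
  rec <- tracks[tracks$frame == frame, ]
  tru <- truth$tracks[truth$tracks$frame == frame, ]
  idx <- vapply(seq_len(nrow(rec)), function(i)
    which.min((tru$y - rec$y[i])^2 + (tru$x - rec$x[i])^2), 0L)
  data.frame(nucleus_id = rec$nucleus_id, truth_id = tru$nucleus_id[idx])
}
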