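# Image and table I/O. Movies are multi-page 16-bit TIFFs with pages in
# T, Z, C order (histone single-plane channel is replicated across z);
# masks are 16-bit label TIFFs; tables are CSV with an optional "# key: value"
# comment header.

#' Write a movie as a multi-page 16-bit TIFF
#'
#' Pages are ordered T (slowest), Z, C (fastest), with C = 1 the histone
#' channel and C = 2 the MS2 channel. Intensities are scaled by a single
#' global factor to the 16-bit range; the factor is returned for inversion.
#'
#' @param movie an `ms2_movie`.
#' @param path output file.
#' @return invisibly, the intensity scale factor used.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "ms2_movie"))
  mx <- max(vapply(movie$frames, function(fr)
    max(max(fr$histone), max(fr$ms2)), 0))
  scale <- if (mx > 0) 1 / mx else 1
  pages <- list()
  for (fr in movie$frames) {
    for (z in seq_len(movie$n_z)) {
      pages[[length(pages) + 1L]] <- fr$histone * scale
      pages[[length(pages) + 1L]] <- fr$ms2[, , z] * scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF file.
#' @param n_z z-planes per timepoint.
#' @param frame_interval sampling period (s).
#' @param scale intensity scale factor returned by the writer (default 1).
#' @return an `ms2_movie`.
#' @export
read_movie_tiff <- function(path, n_z, frame_interval, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  per_t <- 2L * n_z
  stopifnot(length(pages) %% per_t == 0L)
  n_frames <- length(pages) %/% per_t
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    base <- (f - 1L) * per_t
    his <- pages[[base + 1L]] / scale
    ms2 <- array(0, c(dim(his), n_z))
    for (z in seq_len(n_z)) ms2[, , z] <- pages[[base + 2L * z]] / scale
    frames[[f]] <- list(histone = his, ms2 = ms2)
  }
  structure(list(frames = frames, frame_interval = frame_interval,
                 n_z = n_z, shape = dim(frames[[1L]]$histone)),
            class = "ms2_movie")
}

#' Write per-frame label masks as a multi-page 16-bit TIFF
#' @param masks list of integer label matrices (0 = background).
#' @param path output file.
#' @export
write_masks_tiff <- function(masks, path) {
  pages <- lapply(masks, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read label masks written by [write_masks_tiff()]
#' @param path TIFF file.
#' @return list of integer label matrices.
#' @export
read_masks_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) matrix(as.integer(round(p * 65535)),
                                   nrow(p), ncol(p)))
}

#' Write a table as CSV with a comment header
#' @param df data.frame.
#' @param path output file.
#' @param comments named character vector written as `# name: value` lines.
#' @export
write_table_csv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste0("# ", names(comments), ": ", comments), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path CSV file.
#' @return data.frame (comment lines skipped).
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
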