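# Independent, deliberately plain re-implementation of the burst-detection
# rules, executed stepwise: (1) a burst opens at the first frame strictly
# above the threshold and tracks its running local peak; (2) it closes at
# the first frame strictly below end_frac of that peak, which is excluded;
# (3) a burst opening at the first frame of the trace on a strictly
# decreasing run of min_len frames is dropped; (4) the interval is moved
# `shift` frames later and clamped at the trace end, dropping bursts pushed
# fully off; overlapping shifted intervals merge; (5) bursts shorter than
# min_len frames are dropped. Used as the oracle against call_bursts().
oracle_call_bursts <- function(x, threshold, min_len = 5, end_frac = 0.55,
                               shift = 2) {
  n <- length(x)
  raw <- list()
  f <- 1
  while (f <= n) {
    if (x[f] > threshold) {
      b_start <- f
      peak <- x[f]
      f <- f + 1
      closed_at <- NA
      while (f <= n) {
        if (x[f] < end_frac * peak) { closed_at <- f; break }
        if (x[f] > peak) peak <- x[f]
        f <- f + 1
      }
      b_end <- if (is.na(closed_at)) n else closed_at - 1
      raw[[length(raw) + 1]] <- list(start = b_start, end = b_end)
      f <- if (is.na(closed_at)) n + 1 else closed_at
    } else {
      f <- f + 1
    }
  }
  kept <- list()
  for (b in raw) {
    drop <- FALSE
    if (b$start == 1 && min_len >= 2 && (b$end - b$start + 1) >= min_len) {
      seg <- x[1:min_len]
      decreasing <- TRUE
      for (k in 2:min_len) if (!(seg[k] < seg[k - 1])) decreasing <- FALSE
      if (decreasing) drop <- TRUE
    }
    if (!drop) kept[[length(kept) + 1]] <- b
  }
  shifted <- list()
  for (b in kept) {
    s <- b$start + shift
    e <- min(b$end + shift, n)
    if (s <= n) shifted[[length(shifted) + 1]] <- list(start = s, end = e)
  }
  merged <- list()
  for (b in shifted) {
    last <- length(merged)
    if (last > 0 && b$start <= merged[[last]]$end) {
      merged[[last]]$end <- max(merged[[last]]$end, b$end)
    } else {
      merged[[length(merged) + 1]] <- b
    }
  }
  final <- list()
  for (b in merged)
    if ((b$end - b$start + 1) >= min_len) final[[length(final) + 1]] <- b
  data.frame(start_frame = vapply(final, function(b) b$start, 0),
             end_frame = vapply(final, function(b) b$end, 0))
}

# bursty random traces for the equivalence test: telegraph-like square waves
# with noise, drifting baselines and occasional pure-noise traces
random_burst_trace <- function(n = 120) {
  kind <- sample(3, 1)
  if (kind == 1) return(abs(stats::rnorm(n, 0, 1)))
  x <- numeric(n); level <- 0
  for (f in seq_len(n)) {
    if (level == 0 && stats::runif(1) < 0.08) level <- stats::runif(1, 5, 40)
    else if (level > 0 && stats::runif(1) < 0.2) level <- 0
    x[f] <- level
  }
  x <- x + stats::rnorm(n, 0, 1)
  if (kind == 3) x <- x + seq(0, stats::runif(1, 0, 10), length.out = n)
  pmax(x, 0)
}
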