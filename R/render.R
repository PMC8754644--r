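# Rejection-sample n non-overlapping centers (y, x) with a minimum spacing.
.place_nuclei <- function(shape, n, radius, min_spacing, max_attempts = 1000L) {
  margin <- radius + 2
  ys <- numeric(0); xs <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      y <- stats::runif(1, margin, shape[1] - margin + 1)
      x <- stats::runif(1, margin, shape[2] - margin + 1)
      if (!length(ys) || min((ys - y)^2 + (xs - x)^2) >= min_spacing^2) {
        ys <- c(ys, y); xs <- c(xs, x); ok <- TRUE; break
      }
    }
    if (!ok)
      stop("render_movie: could not place ", n, " non-overlapping nuclei in a ",
           shape[1], "x", shape[2], " field after ", max_attempts, " attempts")
  }
  cbind(y = ys, x = xs)
}

# Paint non-background disk labels; overlap resolved by nearest center.
.paint_labels <- function(shape, centers, radius) {
  lab <- matrix(0L, shape[1], shape[2])
  best <- matrix(Inf, shape[1], shape[2])
  r_ceil <- ceiling(radius)
  for (k in seq_len(nrow(centers))) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    yy <- max(1L, floor(cy - r_ceil)):min(shape[1], ceiling(cy + r_ceil))
    xx <- max(1L, floor(cx - r_ceil)):min(shape[2], ceiling(cx + r_ceil))
    d2 <- outer((yy - cy)^2, (xx - cx)^2, "+")
    inside <- d2 <= radius^2
    sub_b <- best[yy, xx, drop = FALSE]
    take <- inside & d2 < sub_b
    if (any(take)) {
      sub_l <- lab[yy, xx, drop = FALSE]
      sub_l[take] <- k
      sub_b[take] <- d2[take]
      lab[yy, xx] <- sub_l
      best[yy, xx] <- sub_b
    }
  }
  lab
}

# Add one isotropic Gaussian dot (total integrated intensity = total_int) to
# each z-plane of a (y, x, z) stack, attenuated away from z0.
.add_dot <- function(stack, cy, cx, z0, total_int, sigma, z_sigma = 0.7) {
  if (total_int <= 0) return(stack)
  shape <- dim(stack)
  ext <- ceiling(4 * sigma)
  yy <- max(1L, floor(cy - ext)):min(shape[1], ceiling(cy + ext))
  xx <- max(1L, floor(cx - ext)):min(shape[2], ceiling(cx + ext))
  g <- outer(exp(-(yy - cy)^2 / (2 * sigma^2)),
             exp(-(xx - cx)^2 / (2 * sigma^2)))
  amp <- total_int / (2 * pi * sigma^2)
  for (z in seq_len(shape[3])) {
    att <- exp(-(z - z0)^2 / (2 * z_sigma^2))
    if (att > 1e-4)
      stack[yy, xx, z] <- stack[yy, xx, z] + amp * att * g
  }
  stack
}

.stripe_of <- function(x, stripe_pattern) {
  for (s in seq_along(stripe_pattern)) {
    r <- stripe_pattern[[s]]$x_range
    if (x >= r[1] && x <= r[2]) return(s)
  }
  0L
}

#' Render a synthetic two-channel live-imaging movie with ground truth
#'
#' Builds a histone-like nuclear channel (textured disks, single plane) and an
#' MS2 z-stack channel in which each transcribing nucleus carries one
#' diffraction-limited Gaussian dot whose integrated intensity equals the true
#' telegraph trajectory value at that frame. Nuclei drift by Gaussian steps
#' clamped to keep the disks inside the field. Returns the movie together
#' with per-frame label masks, tracks, true trajectories, true ON intervals
#' and spot centers.
#'
#' @param field a [field_params()] object.
#' @param params a single [telegraph_params()] (shared by all nuclei) or a
#'   list of one per nucleus; ignored for stripe fields (each stripe carries
#'   its own parameters and off-stripe nuclei stay silent).
#' @param seed integer seed.
#' @param trajectories optional long data.frame `nucleus_id`, `frame`,
#'   `intensity` of externally supplied true trajectories (one per nucleus),
#'   rendered instead of simulating; `frame_interval` is read from its
#'   attribute or from `params`.
#' @return list with `movie` (class `ms2_movie`: per-frame `histone` matrix
#'   and `ms2` y,x,z array, plus `frame_interval`) and `truth` (class
#'   `ground_truth`: `masks`, `tracks`, `trajectories`, `on_intervals`,
#'   `spots`).
#' @export
render_movie <- function(field, params = NULL, seed = 1L,
                         trajectories = NULL) {
  stopifnot(inherits(field, "field_params"))
  set.seed(seed)
  shape <- field$image_shape
  n <- field$n_nuclei
  centers0 <- .place_nuclei(shape, n, field$nucleus_radius, field$min_spacing)

  if (!is.null(trajectories)) {
    ids <- sort(unique(trajectories$nucleus_id))
    stopifnot(length(ids) == n)
    n_frames <- max(trajectories$frame)
    frame_interval <- attr(trajectories, "frame_interval") %||%
      (if (inherits(params, "telegraph_params")) params$frame_interval else 16.8)
    sims <- lapply(ids, function(id) {
      tr <- trajectories[trajectories$nucleus_id == id, ]
      tr <- tr[order(tr$frame), ]
      list(trajectory = data.frame(frame = seq_len(n_frames),
                                   time_s = (seq_len(n_frames) - 1L) * frame_interval,
                                   intensity = tr$intensity),
           on_intervals = data.frame(t_start_s = numeric(0), t_end_s = numeric(0)))
    })
    stripe_id <- rep(NA_integer_, n)
  } else if (!is.null(field$stripe_pattern)) {
    stripe_id <- vapply(seq_len(n),
                        function(k) .stripe_of(centers0[k, 2], field$stripe_pattern), 0L)
    plist <- lapply(seq_len(n), function(k) {
      if (stripe_id[k] > 0) field$stripe_pattern[[stripe_id[k]]]$params else NULL
    })
    base <- Filter(Negate(is.null), plist)
    if (!length(base)) stop("render_movie: stripe_pattern has no active stripes")
    n_frames <- base[[1]]$n_frames
    frame_interval <- base[[1]]$frame_interval
  } else {
    if (inherits(params, "telegraph_params")) {
      plist <- rep(list(params), n)
    } else if (is.list(params) && length(params) == n) {
      plist <- params
    } else stop("render_movie: `params` must be a telegraph_params or a list of one per nucleus")
    n_frames <- plist[[1]]$n_frames
    frame_interval <- plist[[1]]$frame_interval
    stripe_id <- rep(NA_integer_, n)
  }

  # true trajectories (seeded per nucleus)
  if (is.null(trajectories)) sims <- lapply(seq_len(n), function(k) {
    if (is.null(plist[[k]])) {
      list(trajectory = data.frame(frame = seq_len(n_frames),
                                   time_s = (seq_len(n_frames) - 1L) * frame_interval,
                                   intensity = rep(0, n_frames)),
           on_intervals = data.frame(t_start_s = numeric(0), t_end_s = numeric(0)))
    } else simulate_trajectory(plist[[k]], seed = seed + k)
  })

  # Nuclei motion: anchored interphase nuclei jitter around their sites
  # (mean-reverting, stationary sd = drift_sd) while the whole field drifts
  # as a shared random walk (step sd = drift_sd / 2), so spacing is
  # preserved and per-frame displacements stay at the drift_sd scale.
  margin <- field$nucleus_radius + 2
  pos <- array(0, c(n, 2L, n_frames))
  pos[, , 1L] <- centers0
  theta <- 0.1
  jit_step <- field$drift_sd * sqrt(1 - (1 - theta)^2)
  wlim <- c(min(centers0[, 1L]) - margin,
            shape[1] - margin + 1 - max(centers0[, 1L]),
            min(centers0[, 2L]) - margin,
            shape[2] - margin + 1 - max(centers0[, 2L]))
  w <- c(0, 0)
  jit <- matrix(0, n, 2L)
  if (n_frames > 1L) for (f in 2L:n_frames) {
    w <- w + stats::rnorm(2L, 0, field$drift_sd / 2)
    w[1L] <- min(max(w[1L], -wlim[1L]), wlim[2L])
    w[2L] <- min(max(w[2L], -wlim[3L]), wlim[4L])
    jit <- jit * (1 - theta) + matrix(stats::rnorm(2L * n, 0, jit_step), n, 2L)
    p <- centers0 + rep(w, each = n) + jit
    p[, 1L] <- pmin(pmax(p[, 1L], margin), shape[1] - margin + 1)
    p[, 2L] <- pmin(pmax(p[, 2L], margin), shape[2] - margin + 1)
    pos[, , f] <- p
  }

  # fixed per-nucleus dot offset inside the nucleus and brightest z-plane
  off_r <- stats::runif(n, 0, field$nucleus_radius / 3)
  off_a <- stats::runif(n, 0, 2 * pi)
  dot_off <- cbind(off_r * sin(off_a), off_r * cos(off_a))
  dot_z <- sample.int(field$n_z, n, replace = TRUE)

  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  tracks <- vector("list", n_frames)
  spots <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    cen <- pos[, , f, drop = FALSE]; dim(cen) <- c(n, 2L)
    lab <- .paint_labels(shape, cen, field$nucleus_radius)
    his <- matrix(0, shape[1], shape[2])
    # textured disks: quadratic radial falloff
    idx <- which(lab > 0L)
    if (length(idx)) {
      ky <- (idx - 1L) %% shape[1] + 1L
      kx <- (idx - 1L) %/% shape[1] + 1L
      k <- lab[idx]
      r2 <- (ky - cen[k, 1L])^2 + (kx - cen[k, 2L])^2
      his[idx] <- field$histone_level *
        (1 - 0.35 * r2 / field$nucleus_radius^2)
    }
    if (field$histone_noise_sd > 0)
      his <- pmax(his + matrix(stats::rnorm(length(his), 0, field$histone_noise_sd),
                               shape[1], shape[2]), 0)
    ms2 <- array(field$ms2_background, c(shape[1], shape[2], field$n_z))
    sp <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      v <- sims[[k]]$trajectory$intensity[f]
      cy <- cen[k, 1L] + dot_off[k, 1L]
      cx <- cen[k, 2L] + dot_off[k, 2L]
      sp[k, ] <- c(dot_z[k], cy, cx)
      if (v > 0)
        ms2 <- .add_dot(ms2, cy, cx, dot_z[k], v, field$psf_sigma)
    }
    if (field$ms2_noise_sd > 0)
      ms2 <- pmax(ms2 + array(stats::rnorm(length(ms2), 0, field$ms2_noise_sd),
                              dim(ms2)), 0)
    frames[[f]] <- list(histone = his, ms2 = ms2)
    masks[[f]] <- lab
    tracks[[f]] <- data.frame(nucleus_id = seq_len(n), frame = f,
                              y = cen[, 1L], x = cen[, 2L],
                              label = seq_len(n))
    spots[[f]] <- data.frame(nucleus_id = seq_len(n), frame = f,
                             z = sp[, 1L], y = sp[, 2L], x = sp[, 3L])
  }

  trajs <- do.call(rbind, lapply(seq_len(n), function(k)
    cbind(nucleus_id = k, sims[[k]]$trajectory)))
  attr(trajs, "frame_interval") <- frame_interval
  ons <- do.call(rbind, lapply(seq_len(n), function(k) {
    oi <- sims[[k]]$on_intervals
    if (nrow(oi)) cbind(nucleus_id = k, oi) else NULL
  }))
  if (is.null(ons))
    ons <- data.frame(nucleus_id = integer(0), t_start_s = numeric(0),
                      t_end_s = numeric(0))

  movie <- structure(list(frames = frames, frame_interval = frame_interval,
                          n_z = field$n_z, shape = shape),
                     class = "ms2_movie")
  truth <- structure(list(masks = masks,
                          tracks = do.call(rbind, tracks),
                          trajectories = trajs,
                          on_intervals = ons,
                          spots = do.call(rbind, spots),
                          stripe_id = stripe_id),
                     class = "ground_truth")
  list(movie = movie, truth = truth)
}

#' @export
print.ms2_movie <- function(x, ...) {
  cat("ms2_movie:", length(x$frames), "frames,", x$shape[1], "x", x$shape[2],
      "px,", x$n_z, "z-planes, dt =", x$frame_interval, "s\n")
  invisible(x)
}
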