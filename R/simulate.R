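#' Simulate a single-photon miniscope recording with ground truth
#'
#' Generates a synthetic movie mimicking one-photon miniscope data:
#' Gaussian-blob cells with AR(2) calcium dynamics driven by sparse
#' Bernoulli spikes, a smooth local background field with slow temporal
#' modulation, a static radial vignetting profile, rigid frame-to-frame
#' motion (a Gaussian-smoothed integer random walk), and additive Gaussian
#' sensor noise of sd 1 on the 8-bit (0-255) intensity scale.  Ground-truth
#' footprints, calcium, spikes and shifts are returned in the unshifted
#' frame of reference; the video is clipped to `[0, 255]`.
#'
#' Construction steps: (1) cell centres drawn uniformly with minimum
#' separation `2 * cell_sigma`; footprints are isotropic Gaussians of sd
#' `cell_sigma` truncated at four sigma, peak 1. (2) spikes are
#' Bernoulli(`spike_rate / fps`) per frame and cell; calcium is the AR(2)
#' filter of the spikes with poles from a 0.1 s rise and 1.0 s decay.
#' (3) the clean cell signal is `signal_level * amp * A C'`, with `amp`
#' fixed so one isolated spike peaks at 20 intensity units when
#' `signal_level = 1`. (4) background and vignetting are added, (5) the
#' composed frame is rigidly shifted, and (6) noise is added.
#'
#' @param ncell number of cells.
#' @param dims `c(height, width)` in pixels.
#' @param nframes number of frames.
#' @param signal_level multiplier on the clean cell signal.
#' @param fps frames per second.
#' @param spike_rate mean spiking rate in Hz.
#' @param cell_sigma Gaussian footprint sd in pixels.
#' @param motion_sigma per-frame sd of the motion random walk, in pixels
#'   (`0` disables motion); shifts are clipped to +/- 4 px.
#' @param seed integer seed; the dataset is a deterministic function of
#'   `(parameters, seed)`.
#' @return an object of class `simulated_miniscope`: list with `video`
#'   ([video_array()]), `truth_A` `(height, width, cell)`, `truth_C`,
#'   `truth_S` `(frame, cell)`, `truth_shifts` (data.frame), `params`.
#' @export
simulate_miniscope <- function(ncell = 30, dims = c(128, 128),
                               nframes = 3000, signal_level = 1, fps = 30,
                               spike_rate = 0.25, cell_sigma = 2.5,
                               motion_sigma = 0.1, seed = 0) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  H <- dims[1]; W <- dims[2]
  # compose on a canvas padded by the maximum shift so that motion reveals
  # real scene content at the borders instead of empty pixels
  pad <- 4L
  Hc <- H + 2L * pad; Wc <- W + 2L * pad
  centers <- place_centers(ncell, H, W, min_sep = 2 * cell_sigma,
                           margin = 2 * cell_sigma)
  Ac <- array(0, c(Hc, Wc, ncell))
  if (ncell > 0) for (k in seq_len(ncell)) {
    Ac[, , k] <- gaussian_blob(Hc, Wc, centers[k, 1] + pad,
                               centers[k, 2] + pad, cell_sigma)
  }
  A <- Ac[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
  # AR(2) calcium kernel: poles from 0.1 s rise, 1.0 s decay time constants
  p1 <- exp(-1 / (fps * 1.0)); p2 <- exp(-1 / (fps * 0.1))
  gamma <- c(p1 + p2, -p1 * p2)
  S <- matrix(stats::rbinom(nframes * ncell, 1, min(1, spike_rate / fps)),
              nframes, ncell)
  C <- apply(S, 2, function(s)
    as.vector(stats::filter(s, gamma, method = "recursive")))
  if (ncell == 0) C <- matrix(0, nframes, 0)
  amp <- 20 / max(ar_impulse(gamma, 10 * fps))
  clean <- if (ncell > 0) (signal_level * amp) * (C %*% t(flatten_A(Ac)))
           else matrix(0, nframes, Hc * Wc)
  # smooth background field x slow temporal modulation, plus vignetting
  b0 <- EBImage::gblur(matrix(stats::rnorm(Hc * Wc), Hc, Wc), sigma = Hc / 8)
  b0 <- (b0 - min(b0)) / diff(range(b0)) * 20
  mod <- filter_trace(stats::rnorm(nframes), cutoff = min(0.2, fps / 4),
                      btype = "low", fps = fps)
  mod <- 1 + 0.15 * mod / max(abs(mod), 1e-12)
  rr <- (seq_len(Hc) - (Hc + 1) / 2) / (Hc / 2)
  cc <- (seq_len(Wc) - (Wc + 1) / 2) / (Wc / 2)
  vig <- 60 * (1 - 0.8 * pmin(1, outer(rr^2, cc^2, `+`)))
  static <- as.vector(vig) + as.vector(b0)
  shifts <- simulate_walk(nframes, motion_sigma)
  video <- matrix(0, nframes, H * W)
  ri <- pad + seq_len(H); ci <- pad + seq_len(W)
  for (t in seq_len(nframes)) {
    fr <- matrix(clean[t, ] + static * mod[t], Hc, Wc)
    # content displaced by +shift == window displaced by -shift
    video[t, ] <- fr[ri - shifts[t, 1], ci - shifts[t, 2]]
  }
  video <- video + stats::rnorm(length(video), sd = 1)
  video[video < 0] <- 0; video[video > 255] <- 255
  dim(video) <- c(nframes, H, W)
  structure(list(
    video = video_array(video, fps = fps),
    truth_A = A, truth_C = C, truth_S = S,
    truth_shifts = structure(
      data.frame(frame = seq_len(nframes) - 1L,
                 shift_row = shifts[, 1], shift_col = shifts[, 2]),
      class = c("motion_shifts", "data.frame")),
    params = list(ncell = ncell, dims = dims, nframes = nframes,
                  signal_level = signal_level, fps = fps,
                  spike_rate = spike_rate, cell_sigma = cell_sigma,
                  motion_sigma = motion_sigma, seed = seed,
                  gamma = gamma, amplitude = amp)),
    class = "simulated_miniscope")
}

place_centers <- function(ncell, H, W, min_sep, margin) {
  if (ncell == 0) return(matrix(0, 0, 2))
  centers <- matrix(0, ncell, 2)
  placed <- 0
  for (tries in seq_len(ncell * 2000)) {
    cand <- c(stats::runif(1, 1 + margin, H - margin),
              stats::runif(1, 1 + margin, W - margin))
    if (placed == 0 ||
        min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                               2, cand)^2))) >= min_sep) {
      placed <- placed + 1
      centers[placed, ] <- cand
      if (placed == ncell) return(centers)
    }
  }
  stop(sprintf("cannot place %d cell centres with separation %.1f px",
               ncell, min_sep))
}

gaussian_blob <- function(H, W, r0, c0, sigma) {
  out <- matrix(0, H, W)
  rad <- ceiling(4 * sigma)
  rows <- max(1, floor(r0 - rad)):min(H, ceiling(r0 + rad))
  cols <- max(1, floor(c0 - rad)):min(W, ceiling(c0 + rad))
  d2 <- outer((rows - r0)^2, (cols - c0)^2, `+`)
  g <- exp(-d2 / (2 * sigma^2))
  g[d2 > (4 * sigma)^2] <- 0
  out[rows, cols] <- g
  out
}

simulate_walk <- function(nframes, motion_sigma) {
  if (motion_sigma <= 0 || nframes == 0)
    return(matrix(0L, nframes, 2))
  raw <- apply(matrix(stats::rnorm(nframes * 2, sd = motion_sigma),
                      nframes, 2), 2, cumsum)
  # temporal Gaussian smoothing (sd 10 frames), then integer clip to +/-4
  k <- stats::dnorm(-30:30, sd = 10); k <- k / sum(k)
  sm <- apply(raw, 2, function(x)
    stats::filter(c(rep(x[1], 30), x, rep(x[length(x)], 30)), k)[31:(30 + nframes)])
  matrix(pmax(-4L, pmin(4L, as.integer(round(sm)))), nframes, 2)
}
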