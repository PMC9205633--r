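#' Generate an over-complete set of candidate seeds
#'
#' Repeatedly max-projects subsets of frames (a rolling window by default,
#' or random draws) and marks pixels that are local maxima within a
#' `max_wnd`-diameter neighbourhood and exceed the projection minimum by
#' more than `diff_thres` intensity units.  The union over subsets is
#' returned, so cells active only briefly are not masked by a whole-movie
#' projection.
#'
#' @param video a [video_array()] (preprocessed, motion corrected).
#' @param wnd_size frames per rolling window.
#' @param step_size interval between window starts.
#' @param method `"rolling"` or `"random"`.
#' @param n_iter number of random draws when `method = "random"`.
#' @param max_wnd neighbourhood diameter (px) defining a local maximum;
#'   use the expected cell diameter.
#' @param diff_thres intensity threshold above the projection minimum
#'   (default 3, on the 0-255 scale of 8-bit data).
#' @return a data.frame (class `seeds`) with columns `row_px`, `col_px`
#'   (0-based), `max_intensity`, and refinement masks added later.
#' @export
seeds_init <- function(video, wnd_size = 1000, step_size = 200,
                       method = c("rolling", "random"), n_iter = 10,
                       max_wnd = 10, diff_thres = 3) {
  method <- match.arg(method)
  d <- dim(video)
  arr <- va_data(video)
  if (method == "rolling") {
    starts <- seq(1L, max(1L, d[1] - 1L), by = step_size)
    subsets <- lapply(starts, function(s) s:min(s + wnd_size - 1L, d[1]))
  } else {
    subsets <- lapply(seq_len(n_iter), function(i)
      sample.int(d[1], min(wnd_size, d[1])))
  }
  if (any(lengths(subsets) == 0)) stop("empty frame subset")
  kern <- disc_kernel(max_wnd)
  hits <- matrix(FALSE, d[2], d[3])
  peak <- matrix(-Inf, d[2], d[3])
  for (ss in subsets) {
    proj <- apply(arr[ss, , , drop = FALSE], c(2, 3), max)
    loc <- local_maxima(proj, kern, diff_thres)
    hits <- hits | loc
    peak <- pmax(peak, ifelse(loc, proj, -Inf))
  }
  ij <- which(hits, arr.ind = TRUE)
  seeds <- data.frame(row_px = ij[, 1] - 1L, col_px = ij[, 2] - 1L,
                      max_intensity = peak[ij])
  seeds <- seeds[order(seeds$row_px, seeds$col_px), , drop = FALSE]
  rownames(seeds) <- NULL
  structure(seeds, class = c("seeds", "data.frame"))
}

local_maxima <- function(proj, kern, diff_thres) {
  dil <- if (length(kern) > 1) dilate_gray(proj, kern) else proj
  (proj >= dil) & (proj - min(proj) > diff_thres)
}

#' Which seeds are still active
#'
#' A seed is active iff every refinement mask present (`mask_pnr`,
#' `mask_ks`, `mask_mrg`) is `TRUE`; refinements only ever deactivate
#' seeds.
#'
#' @param seeds a `seeds` data.frame.
#' @return logical vector.
#' @export
seed_active <- function(seeds) {
  masks <- intersect(c("mask_pnr", "mask_ks", "mask_mrg"), names(seeds))
  act <- rep(TRUE, nrow(seeds))
  for (m in masks) act <- act & seeds[[m]]
  act
}

seed_traces <- function(video, seeds) {
  d <- dim(video)
  mat <- va_matrix(video)
  px <- seeds$row_px + 1L + seeds$col_px * d[2]
  mat[, px, drop = FALSE]
}

#' Brick-wall frequency filtering of a trace
#'
#' Frequency-domain filter that zeroes Fourier bins strictly above
#' (`btype = "low"`) or at/below (`btype = "high"`) the cutoff, so the two
#' components always sum exactly to the original trace and the low-pass
#' component retains the DC level.
#'
#' @param trace numeric vector.
#' @param cutoff cutoff frequency in Hz, in `(0, fps/2)`.
#' @param btype `"low"` or `"high"`.
#' @param fps sampling rate in Hz.
#' @return filtered numeric vector.
#' @export
filter_trace <- function(trace, cutoff, btype = c("low", "high"), fps = 30) {
  btype <- match.arg(btype)
  if (cutoff <= 0 || cutoff >= fps / 2) stop("cutoff must be in (0, fps/2)")
  n <- length(trace)
  freq <- bin_freq(n, fps)
  keep <- if (btype == "low") freq <= cutoff else freq > cutoff
  Re(stats::fft(stats::fft(trace) * keep, inverse = TRUE)) / n
}

bin_freq <- function(n, fps) {
  k <- seq_len(n) - 1L
  pmin(k, n - k) * fps / n
}

# low/high-pass an entire (frame x series) matrix at once
filter_mat <- function(m, cutoff, btype, fps) {
  keep <- bin_freq(nrow(m), fps) <= cutoff
  if (btype == "high") keep <- !keep
  Re(stats::mvfft(stats::mvfft(m) * keep, inverse = TRUE)) / nrow(m)
}

#' Refine seeds by peak-to-noise ratio
#'
#' Splits each seed's trace into a sub-`noise_freq` "signal" and a
#' supra-`noise_freq` "noise" component and computes the ratio of their
#' peak-to-peak amplitudes.  Seeds with a ratio at or below `thres` are
#' deactivated.  A zero noise peak-to-peak gives an infinite ratio and the
#' seed is kept.
#'
#' @param video a [video_array()].
#' @param seeds a `seeds` data.frame.
#' @param noise_freq signal/noise cutoff in Hz (default 1).
#' @param thres ratio threshold (default 1).
#' @return `seeds` with columns `pnr` and `mask_pnr`.
#' @export
pnr_refine <- function(video, seeds, noise_freq = 1, thres = 1) {
  tr <- seed_traces(video, seeds)
  fps <- attr(video, "fps")
  lo <- filter_mat(tr, noise_freq, "low", fps)
  hi <- tr - lo
  ptp <- function(m) apply(m, 2, function(x) diff(range(x)))
  num <- ptp(lo); den <- ptp(hi)
  pnr <- ifelse(den == 0, Inf, num / den)
  seeds$pnr <- pnr
  seeds$mask_pnr <- pnr > thres
  seeds
}

#' Refine seeds by a Kolmogorov-Smirnov normality test
#'
#' A pixel trace that only contains noise should be approximately Gaussian,
#' while calcium transients produce a heavy right tail.  Each active seed's
#' z-scored trace is tested against the standard normal with a one-sample
#' KS test; seeds whose traces look normal (p >= `sig`) are deactivated.
#' Constant traces are deactivated.
#'
#' @param video a [video_array()].
#' @param seeds a `seeds` data.frame.
#' @param sig significance threshold (default 0.05).
#' @return `seeds` with columns `ks_pval` and `mask_ks`.
#' @export
ks_refine <- function(video, seeds, sig = 0.05) {
  tr <- seed_traces(video, seeds)
  pv <- apply(tr, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) return(1)
    suppressWarnings(stats::ks.test((x - mean(x)) / s, "pnorm")$p.value)
  })
  seeds$ks_pval <- pv
  seeds$mask_ks <- pv < sig
  seeds
}

#' Merge nearby, correlated seeds
#'
#' Builds a graph over active seeds with an edge wherever the Euclidean
#' distance is at most `thres_dist` and the Pearson correlation of the
#' low-pass-smoothed traces is at least `thres_corr`; within each connected
#' component only the seed with the highest `max_intensity` stays active.
#'
#' @param video a [video_array()].
#' @param seeds a `seeds` data.frame.
#' @param thres_dist distance threshold in pixels.
#' @param thres_corr correlation threshold (default 0.8).
#' @param noise_freq low-pass cutoff (Hz) for the smoothing before the
#'   correlation; use the peak-to-noise cutoff.
#' @return `seeds` with column `mask_mrg`.
#' @export
seeds_merge <- function(video, seeds, thres_dist = 4, thres_corr = 0.8,
                        noise_freq = 1) {
  act <- which(seed_active(seeds))
  seeds$mask_mrg <- seed_active(seeds)
  if (length(act) < 2) return(seeds)
  tr <- seed_traces(video, seeds[act, , drop = FALSE])
  lo <- filter_mat(tr, noise_freq, "low", attr(video, "fps"))
  cc <- suppressWarnings(stats::cor(lo))
  cc[is.na(cc)] <- 0
  dmat <- as.matrix(stats::dist(cbind(seeds$row_px[act], seeds$col_px[act])))
  adj <- (dmat <= thres_dist) & (cc >= thres_corr)
  diag(adj) <- FALSE
  comp <- graph_components(adj)
  for (cid in unique(comp)) {
    mem <- act[comp == cid]
    if (length(mem) < 2) next
    keep <- mem[which.max(seeds$max_intensity[mem])]
    seeds$mask_mrg[setdiff(mem, keep)] <- FALSE
  }
  seeds
}

# connected components of a logical adjacency matrix (union-find)
graph_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) for (j in which(adj[i, ])) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, 0L)
}

#' Initialize spatial footprints from seeds
#'
#' Each active seed becomes a unit whose footprint weight at a pixel within
#' a `wnd`-radius square window is the cosine similarity between that
#' pixel's trace and the seed's trace, zeroed below `thres_corr`; the seed
#' pixel itself gets weight 1.
#'
#' @param video a [video_array()].
#' @param seeds a `seeds` data.frame.
#' @param thres_corr cosine-similarity threshold (default 0.5).
#' @param wnd window radius in pixels (default 10).
#' @return footprint array `A` of shape `(height, width, unit)`.
#' @export
init_spatial <- function(video, seeds, thres_corr = 0.5, wnd = 10) {
  act <- which(seed_active(seeds))
  if (length(act) == 0) stop("no active seeds")
  d <- dim(video)
  mat <- va_matrix(video)
  A <- array(0, c(d[2], d[3], length(act)))
  for (k in seq_along(act)) {
    s <- seeds[act[k], ]
    r0 <- max(0L, s$row_px - wnd); r1 <- min(d[2] - 1L, s$row_px + wnd)
    c0 <- max(0L, s$col_px - wnd); c1 <- min(d[3] - 1L, s$col_px + wnd)
    rows <- (r0:r1) + 1L; cols <- (c0:c1) + 1L
    px <- as.vector(outer(rows, (cols - 1L) * d[2], `+`))
    seed_tr <- mat[, s$row_px + 1L + s$col_px * d[2]]
    sub <- mat[, px, drop = FALSE]
    num <- as.vector(crossprod(sub, seed_tr))
    den <- sqrt(colSums(sub^2)) * sqrt(sum(seed_tr^2))
    sim <- ifelse(den > 0, num / den, 0)
    sim[sim < thres_corr] <- 0
    w <- matrix(sim, length(rows), length(cols))
    w[s$row_px - r0 + 1L, s$col_px - c0 + 1L] <- 1
    A[rows, cols, k] <- w
  }
  A
}

#' Initialize temporal traces from footprints
#'
#' Footprint-weighted projection of the video:
#' `C[t, i] = sum_p A[p, i] Y[t, p] / sum_p A[p, i]^2`.
#'
#' @param video a [video_array()].
#' @param A footprint array `(height, width, unit)`.
#' @return trace matrix `C` of shape `(frame, unit)`.
#' @export
init_temporal <- function(video, A) {
  Af <- flatten_A(A)
  nrm <- colSums(Af^2)
  if (any(nrm == 0)) stop("zero footprint")
  mat <- va_matrix(video)
  sweep(mat %*% Af, 2, nrm, `/`)
}

flatten_A <- function(A) {
  d <- dim(A)
  matrix(A, d[1] * d[2], d[3])
}

#' Initialize the background terms
#'
#' The cell signal `A C` is subtracted from the video (clipped at zero);
#' the background footprint `b` is the temporal mean of the remainder and
#' the background trace `f` its spatial mean per frame.
#'
#' @param video a [video_array()].
#' @param A footprint array `(height, width, unit)`.
#' @param C trace matrix `(frame, unit)`.
#' @return list with `b` (height x width matrix) and `f` (length-frames
#'   vector).
#' @export
init_background <- function(video, A, C) {
  d <- dim(video)
  R <- va_matrix(video) - C %*% t(flatten_A(A))
  R[R < 0] <- 0
  b <- matrix(colMeans(R), d[2], d[3])
  f <- rowMeans(R)
  list(b = b, f = f)
}
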