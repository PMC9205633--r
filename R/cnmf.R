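#' CNMF model container
#'
#' Holds the factorization `Y ~ A C' + b f'`: non-negative spatial
#' footprints `A` (height, width, unit), calcium traces `C` and spike
#' signals `S` (frame, unit), background footprint `b` (height, width) and
#' trace `f` (frame), with stable integer unit labels.  The residual
#' `E = Y - AC - bf'` is derived on demand, never stored.
#'
#' @param A footprint array `(height, width, unit)`.
#' @param C,S matrices `(frame, unit)`; `S` may be `NULL` before the first
#'   temporal update.
#' @param b background footprint matrix; `f` background trace vector.
#' @param unit_ids integer labels, one per unit.
#' @param fps frames per second.
#' @param fits optional per-unit data.frame of temporal-fit diagnostics.
#' @return an object of class `cnmf_model`.
#' @export
cnmf_model <- function(A, C, S = NULL, b = NULL, f = NULL,
                       unit_ids = NULL, fps = 30, fits = NULL) {
  K <- dim(A)[3]
  stopifnot(ncol(C) == K)
  if (is.null(S)) S <- matrix(0, nrow(C), K)
  if (is.null(unit_ids)) unit_ids <- seq_len(K)
  keep <- colSums(flatten_A(A) != 0) > 0
  structure(list(A = A, C = C, S = S, b = b, f = f,
                 unit_ids = as.integer(unit_ids), fps = fps, fits = fits),
            class = "cnmf_model")
}

#' @export
print.cnmf_model <- function(x, ...) {
  cat(sprintf("<cnmf_model> %d units, %d frames, %dx%d px\n",
              dim(x$A)[3], nrow(x$C), dim(x$A)[1], dim(x$A)[2]))
  invisible(x)
}

#' Per-pixel noise level from the high-frequency band
#'
#' The noise standard deviation of each pixel is estimated from the power
#' of its trace above `noise_freq`, rescaled by the fraction of Fourier
#' bins in that band so that i.i.d. white noise of standard deviation
#' `sigma` yields `sn -> sigma`.
#'
#' @param video a [video_array()].
#' @param noise_freq cutoff in Hz, in `(0, fps/2)`.
#' @return matrix `(height, width)` of noise standard deviations.
#' @export
estimate_noise <- function(video, noise_freq = 1) {
  fps <- attr(video, "fps")
  if (noise_freq <= 0 || noise_freq >= fps / 2)
    stop("noise_freq must be in (0, fps/2)")
  d <- dim(video)
  mat <- va_matrix(video)
  n <- d[1]
  hi <- bin_freq(n, fps) > noise_freq
  frac <- mean(hi)
  sn <- numeric(ncol(mat))
  for (b in chunk_starts(ncol(mat), px_chunk(video))) {
    pw <- Mod(stats::mvfft(mat[, b, drop = FALSE]))^2
    sn[b] <- sqrt(colSums(pw * hi) / n^2 / frac)
  }
  matrix(sn, d[2], d[3])
}

# spectral high-band sd of a single trace (same estimator as estimate_noise)
trace_noise_sd <- function(x, noise_freq, fps) {
  n <- length(x)
  hi <- bin_freq(n, fps) > noise_freq
  sqrt(sum(Mod(stats::fft(x))^2 * hi) / n^2 / mean(hi))
}

#' Spatial update: per-pixel non-negative lasso
#'
#' With traces held fixed, every pixel's footprint weights are re-solved:
#' `minimize ||Y(p,:) - A(p,:) C - b(p) f||^2 + lambda_p ||A(p,:)||_1`
#' subject to `A, b >= 0`, with `lambda_p = sparse_penalty * sn(p) * sqrt(T)`.
#' Only units whose previous support, dilated by a disc of diameter
#' `dl_wnd`, covers the pixel enter its problem; the background footprint
#' is updated alongside the cells as one extra (unpenalized) component.
#' Afterwards the background trace is recomputed as the projection of the
#' cell-free residual onto the new background footprint, and units whose
#' footprint became all-zero are dropped.
#'
#' @param video a [video_array()].
#' @param model a [cnmf_model()].
#' @param sn noise map from [estimate_noise()].
#' @param dl_wnd dilation-disc diameter in pixels (default 8).
#' @param sparse_penalty l1 multiplier (default 0.1).
#' @return an updated `cnmf_model`.
#' @export
update_spatial <- function(video, model, sn, dl_wnd = 8,
                           sparse_penalty = 0.1) {
  d <- dim(video)
  TT <- d[1]; P <- d[2] * d[3]
  K <- dim(model$A)[3]
  X <- cbind(model$C, model$f)
  M <- crossprod(X)
  Ymat <- va_matrix(video)
  V <- crossprod(X, Ymat)
  kern <- disc_kernel(dl_wnd)
  cand <- matrix(FALSE, P, K + 1L)
  for (k in seq_len(K)) {
    supp <- model$A[, , k] > 0
    if (length(kern) > 1) supp <- EBImage::dilate(supp * 1, kern) > 0
    cand[, k] <- as.vector(supp)
  }
  cand[, K + 1L] <- TRUE  # background is a candidate everywhere
  cand_list <- lapply(seq_len(P), function(p) which(cand[p, ]))
  lambda_px <- sparse_penalty * as.vector(sn) * sqrt(TT)
  coefs <- cpp_spatial_lasso(M, V, cand_list, lambda_px, K, 1e-5, 500L)
  Anew <- array(t(coefs[seq_len(K), , drop = FALSE]), c(d[2], d[3], K))
  bnew <- matrix(coefs[K + 1L, ], d[2], d[3])
  keep <- colSums(flatten_A(Anew) != 0) > 0
  Anew <- Anew[, , keep, drop = FALSE]
  Cnew <- model$C[, keep, drop = FALSE]
  Snew <- model$S[, keep, drop = FALSE]
  bvec <- as.vector(bnew)
  bb <- sum(bvec^2)
  if (bb > 0) {
    fnew <- as.vector(Ymat %*% bvec - Cnew %*%
                        crossprod(flatten_A(Anew), bvec)) / bb
    fnew[fnew < 0] <- 0
  } else fnew <- model$f * 0
  cnmf_model(Anew, Cnew, Snew, b = bnew, f = fnew,
             unit_ids = model$unit_ids[keep], fps = model$fps,
             fits = model$fits)
}

#' Autoregressive parameters of a calcium trace
#'
#' The AR(p) coefficients of the calcium-transient model are estimated
#' from the empirical autocovariance of the trace through Yule-Walker
#' relations evaluated at lags `p+1 .. 2p`.  White measurement noise only
#' contributes to the lag-0 autocovariance, so using the recursion at
#' higher lags removes the noise bias that otherwise shortens the
#' estimated time constants -- the same end that pre-smoothing the trace
#' serves, without distorting the autocovariance structure.  An unstable
#' estimate is shrunk to spectral radius 0.99.  The per-unit noise
#' standard deviation is taken from the trace's band above `noise_freq`,
#' as in [estimate_noise()].
#'
#' @param trace numeric vector.
#' @param noise_freq noise cutoff in Hz for the noise-sd estimate, or
#'   `NULL` to skip it.
#' @param p AR order, 1 or 2.
#' @param fps sampling rate.
#' @return an object of class `ar_params`: list with `p`, `gamma`, `sd`.
#' @export
estimate_ar_coefs <- function(trace, noise_freq = 1, p = 2, fps = 30) {
  stopifnot(p %in% c(1L, 2L))
  r <- as.vector(stats::acf(trace, lag.max = 2 * p, type = "covariance",
                            plot = FALSE, demean = TRUE)$acf)
  if (r[1] <= 0) stop("constant trace: AR coefficients undefined")
  # r[k + 1] is the empirical autocovariance at lag k; the AR recursion
  # r(k) = sum_j gamma_j r(k - j) holds for every lag k >= 1 and is free
  # of the white-noise term for k > p
  gamma <- tryCatch({
    if (p == 1) {
      if (abs(r[2]) < .Machine$double.eps) stop("degenerate")
      r[3] / r[2]
    } else {
      R <- matrix(c(r[3], r[4], r[2], r[3]), 2)
      as.vector(solve(R, r[4:5]))
    }
  }, error = function(e) rep(0, p))
  gamma <- stabilize_ar(gamma)
  sd_unit <- if (is.null(noise_freq)) NA_real_
             else trace_noise_sd(trace, noise_freq, fps)
  structure(list(p = p, gamma = gamma, sd = sd_unit), class = "ar_params")
}

# clip AR roots to spectral radius 0.99
stabilize_ar <- function(gamma) {
  p <- length(gamma)
  roots <- polyroot(c(1, -gamma))       # roots of 1 - g1 z - g2 z^2
  m <- 1 / min(Mod(roots))              # spectral radius of the AR poles
  if (is.finite(m) && m > 0.99) {
    gamma <- gamma * (0.99 / m)^seq_len(p)
  }
  gamma
}

#' Impulse response of an AR kernel
#'
#' The calcium transient of a single unit spike: `d[0] = 1` and
#' `d[t] = sum_k gamma_k d[t-k]`; satisfies `G d = e_1`.
#'
#' @param ar an `ar_params` object (or numeric vector of coefficients).
#' @param n length in frames.
#' @return numeric vector of length `n`.
#' @export
ar_impulse <- function(ar, n) {
  gamma <- if (inherits(ar, "ar_params")) ar$gamma else ar
  as.vector(stats::filter(c(1, rep(0, n - 1)), gamma, method = "recursive"))
}

#' Spike signal of a calcium trace
#'
#' Applies the AR difference operator: `s_t = c_t - sum_k gamma_k c_{t-k}`
#' (with zero initial conditions), i.e. `s = G c`.
#'
#' @param c_trace numeric vector.
#' @param ar an `ar_params` object or coefficient vector.
#' @return numeric vector of the same length.
#' @export
ar_difference <- function(c_trace, ar) {
  gamma <- if (inherits(ar, "ar_params")) ar$gamma else ar
  n <- length(c_trace)
  s <- c_trace
  for (k in seq_along(gamma)) {
    s <- s - gamma[k] * c(rep(0, k), c_trace[seq_len(n - k)])
  }
  s
}

#' Project the video onto unit footprints
#'
#' Background-subtracted, overlap-corrected raw trace per unit:
#' `y_ra(i) = [A_i . (Y - b f') - sum_{j != i} (A_i . A_j) C(j,:)] / (A_i . A_i)`
#' where `.` is the pixel-wise inner product.
#'
#' @param video a [video_array()].
#' @param model a [cnmf_model()] (uses `A`, `b`, `f`, `C`).
#' @return matrix `(frame, unit)` of projected raw traces.
#' @export
project_traces <- function(video, model) {
  Af <- flatten_A(model$A)
  nrm <- colSums(Af^2)
  if (any(nrm == 0)) {
    warning("dropping zero-norm footprint(s) in projection")
    nrm[nrm == 0] <- NA
  }
  Ymat <- va_matrix(video)
  G <- crossprod(Af)
  YA <- Ymat %*% Af
  if (!is.null(model$b)) {
    bA <- as.vector(crossprod(Af, as.vector(model$b)))
    YA <- YA - outer(model$f, bA)
  }
  Goff <- G; diag(Goff) <- 0
  sweep(YA - model$C %*% Goff, 2, nrm, `/`)
}

#' Constrained deconvolution of one unit's trace
#'
#' Solves
#' `minimize ||y_ra - c - b0 - c0 d||^2 + lambda' * 1'(G c)`
#' subject to `c >= 0, G c >= 0, b0 >= 0, c0 >= 0`, where `G` is the AR
#' difference operator and `d` its impulse response, via coordinate descent
#' on the spike parametrization `s = G c` (the impulse response of a
#' calcium kernel is non-negative, so `c = D s >= 0` holds automatically).
#' `lambda' = sparse_penalty * sd_unit * sqrt(T)`.  A post-hoc scale
#' `alpha = argmin_{a>=0} ||y_ra - a (c + b0 + c0 d)||^2` multiplies all
#' fitted quantities, counteracting the amplitude shrinkage of the l1
#' penalty.
#'
#' @param y_ra projected raw trace (numeric vector).
#' @param ar an `ar_params` object with a valid noise `sd` (or supply
#'   `sd_unit`).
#' @param sparse_penalty l1 multiplier (default 0.008).
#' @param sd_unit override for the unit noise sd.
#' @param tol,max_sweep coordinate-descent convergence controls.
#' @return a `temporal_fit` list: `c`, `s`, `b0`, `c0`, `scale`, `y_ra`.
#' @export
solve_temporal_unit <- function(y_ra, ar, sparse_penalty = 0.008,
                                sd_unit = NULL, tol = 1e-8,
                                max_sweep = 500L) {
  TT <- length(y_ra)
  sd_unit <- sd_unit %||% ar$sd
  if (is.null(sd_unit) || is.na(sd_unit)) sd_unit <- 1
  lambda <- sparse_penalty * sd_unit * sqrt(TT)
  d_full <- ar_impulse(ar, TT)
  keep <- which(abs(d_full) > 1e-8)
  L <- if (length(keep)) max(keep) else 1L
  fit <- cpp_temporal_cd(y_ra, d_full[seq_len(L)], lambda, tol,
                         as.integer(max_sweep), TRUE, TRUE)
  fitted <- fit$c + fit$b0 + fit$c0 * d_full
  den <- sum(fitted^2)
  alpha <- if (den > 0) max(0, sum(y_ra * fitted) / den) else 0
  structure(list(c = alpha * fit$c, s = alpha * fit$s, b0 = alpha * fit$b0,
                 c0 = alpha * fit$c0, scale = alpha, y_ra = y_ra,
                 gamma = ar$gamma),
            class = "temporal_fit")
}

#' Group units that may be updated concurrently
#'
#' Units whose footprint supports have pairwise Jaccard index (intersection
#' over union) at most `jac_thres` are independent enough to be solved in
#' parallel; connected components of the "overlapping" graph are returned.
#' Solving order never changes the result, because each unit's problem
#' depends only on the projected traces computed beforehand.
#'
#' @param A footprint array `(height, width, unit)`.
#' @param jac_thres Jaccard threshold (default 0.2).
#' @return integer vector of group ids, one per unit.
#' @export
jaccard_groups <- function(A, jac_thres = 0.2) {
  Af <- flatten_A(A) > 0
  K <- ncol(Af)
  inter <- crossprod(Af * 1)
  sz <- diag(inter)
  uni <- outer(sz, sz, `+`) - inter
  jac <- ifelse(uni > 0, inter / uni, 0)
  adj <- jac > jac_thres
  diag(adj) <- FALSE
  graph_components(adj)
}

#' Temporal update: deconvolve all units
#'
#' Computes every unit's projected raw trace, estimates its AR parameters,
#' and solves the constrained deconvolution problem unit by unit (units in
#' different Jaccard groups could run concurrently; ordering does not
#' change results).  Units whose fitted calcium trace is all zero are
#' dropped.
#'
#' @param video a [video_array()].
#' @param model a [cnmf_model()].
#' @param p AR order (1 or 2).
#' @param noise_freq noise cutoff in Hz.
#' @param sparse_penalty l1 multiplier (default 0.008).
#' @param jac_thres Jaccard grouping threshold (default 0.2).
#' @return an updated `cnmf_model` with new `C`, `S` and a `fits` table
#'   (`unit_id`, `b0`, `c0`, `scale`, `gamma1`, `gamma2`).
#' @export
update_temporal <- function(video, model, p = 2, noise_freq = 1,
                            sparse_penalty = 0.008, jac_thres = 0.2) {
  fps <- attr(video, "fps")
  yra <- project_traces(video, model)
  K <- ncol(yra)
  Cn <- matrix(0, nrow(yra), K)
  Sn <- matrix(0, nrow(yra), K)
  info <- vector("list", K)
  for (i in seq_len(K)) {
    fit <- tryCatch({
      ar <- estimate_ar_coefs(yra[, i], noise_freq, p, fps)
      solve_temporal_unit(yra[, i], ar, sparse_penalty)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      # solver failure: keep the previous trace, flag the unit
      Cn[, i] <- model$C[, i]
      Sn[, i] <- model$S[, i]
      info[[i]] <- data.frame(unit_id = model$unit_ids[i], b0 = NA, c0 = NA,
                              scale = NA, gamma1 = NA, gamma2 = NA,
                              converged = FALSE)
      next
    }
    Cn[, i] <- fit$c
    Sn[, i] <- fit$s
    g <- c(fit$gamma, 0)[1:2]
    info[[i]] <- data.frame(unit_id = model$unit_ids[i], b0 = fit$b0,
                            c0 = fit$c0, scale = fit$scale,
                            gamma1 = g[1], gamma2 = g[2], converged = TRUE)
  }
  fits <- do.call(rbind, info)
  keep <- colSums(Cn) > 0
  cnmf_model(model$A[, , keep, drop = FALSE], Cn[, keep, drop = FALSE],
             Sn[, keep, drop = FALSE], b = model$b, f = model$f,
             unit_ids = model$unit_ids[keep], fps = model$fps,
             fits = fits[keep, , drop = FALSE])
}

#' Merge duplicated units
#'
#' Units that share at least one nonzero footprint pixel and whose traces
#' correlate above `thres_corr` form connected components; each component
#' is replaced by one unit with the summed footprint and the mean trace
#' (the smallest member id is kept).  Intended between CNMF iterations
#' only, never after the final temporal update.
#'
#' @param model a [cnmf_model()].
#' @param thres_corr trace-correlation threshold.
#' @return a merged `cnmf_model`.
#' @export
unit_merge <- function(model, thres_corr = 0.9) {
  K <- dim(model$A)[3]
  if (K < 2) return(model)
  Af <- flatten_A(model$A) > 0
  overlap <- crossprod(Af * 1) > 0
  cc <- suppressWarnings(stats::cor(model$C))
  cc[is.na(cc)] <- 0
  adj <- overlap & (cc > thres_corr)
  diag(adj) <- FALSE
  comp <- graph_components(adj)
  merge_by_groups(model, comp)
}

merge_by_groups <- function(model, comp) {
  d <- dim(model$A)
  groups <- split(seq_len(d[3]), comp)
  Kn <- length(groups)
  A <- array(0, c(d[1], d[2], Kn))
  C <- matrix(0, nrow(model$C), Kn)
  S <- matrix(0, nrow(model$S), Kn)
  ids <- integer(Kn)
  for (g in seq_along(groups)) {
    mem <- groups[[g]]
    A[, , g] <- apply(model$A[, , mem, drop = FALSE], c(1, 2), sum)
    C[, g] <- rowMeans(model$C[, mem, drop = FALSE])
    S[, g] <- rowMeans(model$S[, mem, drop = FALSE])
    ids[g] <- min(model$unit_ids[mem])
  }
  ord <- order(ids)
  cnmf_model(A[, , ord, drop = FALSE], C[, ord, drop = FALSE],
             S[, ord, drop = FALSE], b = model$b, f = model$f,
             unit_ids = ids[ord], fps = model$fps)
}

#' Apply manual curation labels
#'
#' Labels are `"keep"`, `"drop"`, or an arbitrary merge-group id; units
#' sharing a group id are merged with the same semantics as
#' [unit_merge()].  The input model is not modified.
#'
#' @param model a [cnmf_model()].
#' @param labels character vector, one entry per unit (names or order must
#'   follow `model$unit_ids`).
#' @return a curated `cnmf_model`.
#' @export
apply_unit_labels <- function(model, labels) {
  K <- dim(model$A)[3]
  if (!is.null(names(labels))) {
    if (!all(names(labels) %in% as.character(model$unit_ids)))
      stop("unknown unit id in labels")
    labels <- labels[as.character(model$unit_ids)]
  }
  if (length(labels) != K) stop("one label per unit required")
  keep <- labels != "drop"
  model2 <- cnmf_model(model$A[, , keep, drop = FALSE],
                       model$C[, keep, drop = FALSE],
                       model$S[, keep, drop = FALSE],
                       b = model$b, f = model$f,
                       unit_ids = model$unit_ids[keep], fps = model$fps)
  lab <- labels[keep]
  comp <- match(lab, unique(lab))
  solo <- lab == "keep"
  comp[solo] <- max(comp, 0) + seq_len(sum(solo))  # "keep" units stay alone
  merge_by_groups(model2, match(comp, unique(comp)))
}
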