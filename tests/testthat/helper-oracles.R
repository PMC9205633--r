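# Independent oracles and shared fixtures for the test suite.

# memoised small simulated recording shared across test files
.fixture_env <- new.env(parent = emptyenv())

sim_small <- function() {
  if (is.null(.fixture_env$sim_small)) {
    # spike rate raised so every cell fires several times within the
    # short fixture window (the default rate is tuned to long recordings)
    .fixture_env$sim_small <- simulate_miniscope(
      ncell = 12, dims = c(80, 80), nframes = 900, signal_level = 1,
      spike_rate = 0.5, seed = 11)
  }
  .fixture_env$sim_small
}

mc_small <- function() {
  if (is.null(.fixture_env$mc_small)) {
    sim <- sim_small()
    pp <- preprocess_video(sim$video, denoise_wnd = 5, background_wnd = 8)
    sh <- estimate_motion(pp, chunk_nfm = 3, max_shift = 10)
    .fixture_env$mc_small <- apply_shifts(pp, sh)
  }
  .fixture_env$mc_small
}

# brute-force integer-shift NCC (valid-overlap semantics, no margin)
oracle_shift <- function(frame, templ, max_shift) {
  h <- nrow(frame); w <- ncol(frame)
  best <- -2; bs <- c(0L, 0L)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ri <- max(1, 1 + dy):min(h, h + dy)
    ci <- max(1, 1 + dx):min(w, w + dx)
    a <- frame[ri, ci]; b <- templ[ri - dy, ci - dx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(as.vector(a), as.vector(b))
    better <- r > best ||
      (r == best && max(abs(dy), abs(dx)) < max(abs(bs)))
    if (better) { best <- r; bs <- c(dy, dx) }
  }
  bs
}

# brute-force grayscale opening with an arbitrary flat structuring element
oracle_opening <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  r <- (nrow(kern) - 1) / 2
  offs <- which(kern > 0, arr.ind = TRUE) - r - 1
  erode <- matrix(Inf, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    erode[i, j] <- min(img[cbind(ii[ok], jj[ok])])
  }
  dil <- matrix(-Inf, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    dil[i, j] <- max(erode[cbind(ii[ok], jj[ok])])
  }
  dil
}

# long-run projected-gradient solver for the temporal problem
#   min ||y - D s - b0 - c0 d||^2 + lambda * sum(s),  s, b0, c0 >= 0
# independent of the package's coordinate-descent path
oracle_temporal_qp <- function(y, d, lambda, iters = 50000) {
  TT <- length(y)
  D <- matrix(0, TT, TT)
  for (t in seq_len(TT)) {
    len <- min(length(d), TT - t + 1)
    D[t:(t + len - 1), t] <- d[seq_len(len)]
  }
  X <- cbind(D, 1, d[seq_len(TT)])
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  L <- max(abs(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values))
  pen <- c(rep(lambda, TT), 0, 0)
  z <- rep(0, TT + 2)
  step <- 1 / (2 * L)
  for (it in seq_len(iters)) {
    g <- 2 * (XtX %*% z - Xty) + pen
    z <- pmax(0, z - step * g)
  }
  obj <- sum((y - X %*% z)^2) + lambda * sum(z[seq_len(TT)])
  list(z = z, objective = obj,
       fitted = as.vector(X %*% z))
}

temporal_objective <- function(y, d, lambda, s, b0, c0) {
  TT <- length(y)
  c_tr <- rep(0, TT)
  for (t in which(s != 0)) {
    len <- min(length(d), TT - t + 1)
    c_tr[t:(t + len - 1)] <- c_tr[t:(t + len - 1)] + s[t] * d[seq_len(len)]
  }
  sum((y - c_tr - b0 - c0 * d[seq_len(TT)])^2) + lambda * sum(s)
}

# brute-force one-to-one assignment: maximum matches within max_dist,
# minimum total distance among those (n <= 7 on the smaller side)
oracle_assignment <- function(centA, centB, max_dist) {
  nA <- nrow(centA); nB <- nrow(centB)
  dmat <- sqrt(outer(centA$row, centB$row, `-`)^2 +
                 outer(centA$col, centB$col, `-`)^2)
  best_n <- -1; best_d <- Inf; best_pairs <- NULL
  rec <- function(i, used, pairs, total) {
    if (i > nA) {
      n <- nrow(pairs) %||% 0
      if (n > best_n || (n == best_n && total < best_d)) {
        best_n <<- n; best_d <<- total; best_pairs <<- pairs
      }
      return(invisible())
    }
    rec(i + 1, used, pairs, total)  # leave i unmatched
    for (j in seq_len(nB)) {
      if (!used[j] && dmat[i, j] <= max_dist) {
        used[j] <- TRUE
        rec(i + 1, used, rbind(pairs, data.frame(i = i, j = j)),
            total + dmat[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, nB), NULL, 0)
  list(n = max(best_n, 0), total = ifelse(best_n > 0, best_d, 0),
       pairs = best_pairs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random Gaussian-blob model for property tests
random_model <- function(K, H = 32, W = 32, TT = 60, seed = 1) {
  set.seed(seed)
  A <- array(0, c(H, W, K))
  for (k in seq_len(K)) {
    r0 <- runif(1, 8, H - 8); c0 <- runif(1, 8, W - 8)
    d2 <- outer((seq_len(H) - r0)^2, (seq_len(W) - c0)^2, `+`)
    blob <- exp(-d2 / 8)
    blob[blob < 0.05] <- 0
    A[, , k] <- blob
  }
  C <- matrix(abs(rnorm(TT * K)), TT, K)
  cnmf_model(A, C)
}
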