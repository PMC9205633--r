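test_that("estimate_noise is unbiased for white noise and band-separates", {
  set.seed(20)
  TT <- 3000
  arr <- array(rnorm(TT * 2 * 2, sd = 1), c(TT, 2, 2))
  sn <- estimate_noise(video_array(abs(arr)), noise_freq = 1)
  # |N(0,1)| has sd ~0.60; use a plain positive-offset normal instead
  arr2 <- array(rnorm(TT * 2 * 2, mean = 10, sd = 1), c(TT, 2, 2))
  sn2 <- estimate_noise(video_array(arr2), noise_freq = 1)
  expect_true(all(abs(sn2 - 1) < 0.05))
  # pure sub-cutoff sinusoid -> sn ~ 0
  tt <- seq_len(TT) / 30
  s <- array(5 + sin(2 * pi * 0.3 * tt), c(TT, 1, 1))
  expect_lt(max(estimate_noise(video_array(s), 1)), 1e-8)
  # homogeneity: sn scales linearly with the input
  sn3 <- estimate_noise(video_array(arr2 * 3), noise_freq = 1)
  expect_equal(as.vector(sn3), 3 * as.vector(sn2), tolerance = 1e-10)
  expect_error(estimate_noise(video_array(arr2), 20), "noise_freq")
})

test_that("AR coefficients are recovered from simulated processes", {
  set.seed(21)
  # AR(1), gamma = 0.9, noiseless
  x <- as.vector(stats::filter(rnorm(10000), 0.9, method = "recursive"))
  ar1 <- estimate_ar_coefs(x, noise_freq = 1, p = 1, fps = 30)
  expect_lt(abs(ar1$gamma - 0.9), 0.02)
  # AR(2) from the 0.1 s rise / 1 s decay calcium kernel
  p1 <- exp(-1 / 30); p2 <- exp(-1 / 3)
  g_true <- c(p1 + p2, -p1 * p2)
  y <- as.vector(stats::filter(rbinom(8000, 1, 0.02), g_true,
                               method = "recursive"))
  ar2 <- estimate_ar_coefs(y + rnorm(8000, sd = 0.1), noise_freq = 1,
                           p = 2, fps = 30)
  d_est <- ar_impulse(ar2, 150)
  d_true <- ar_impulse(g_true, 150)
  expect_gt(cor(d_est, d_true), 0.99)
  # d[0] = 1 and G d = unit impulse for any stable coefficients
  for (g in list(0.8, c(1.2, -0.4))) {
    d <- ar_impulse(g, 50)
    expect_equal(d[1], 1)
    gd <- ar_difference(d, g)
    expect_equal(gd, c(1, rep(0, 49)), tolerance = 1e-12)
  }
  expect_error(estimate_ar_coefs(rep(2, 100), p = 1), "constant")
})

test_that("unstable AR estimates are shrunk to the stability boundary", {
  g <- miniscopr:::stabilize_ar(c(1.99, -0.9899))
  expect_lte(1 / min(Mod(polyroot(c(1, -g)))), 0.99 + 1e-9)
  # already-stable coefficients pass through unchanged
  expect_equal(miniscopr:::stabilize_ar(c(0.5, 0.2)), c(0.5, 0.2))
})

test_that("project_traces inverts a noiseless model exactly", {
  set.seed(22)
  H <- 20; W <- 20; TT <- 120
  A <- array(0, c(H, W, 2))
  A[3:8, 3:8, 1] <- exp(-outer((-2:3)^2, (-2:3)^2, `+`) / 4)
  A[6:11, 6:11, 2] <- exp(-outer((-2:3)^2, (-2:3)^2, `+`) / 4)  # overlaps 1
  C <- matrix(abs(rnorm(TT * 2)) * 5, TT, 2)
  b <- matrix(runif(H * W), H, W)
  f <- abs(rnorm(TT))
  Y <- C %*% t(miniscopr:::flatten_A(A)) + f %*% t(as.vector(b))
  v <- video_array(array(Y, c(TT, H, W)))
  model <- cnmf_model(A, C, b = b, f = f)
  yra <- project_traces(v, model)
  expect_equal(yra, C, tolerance = 1e-8)  # algebraic identity
  # adding k * f b' to Y leaves the projection unchanged
  v2 <- video_array(array(Y + 2 * (f %*% t(as.vector(b))), c(TT, H, W)))
  model2 <- cnmf_model(A, C, b = b, f = 3 * f)
  expect_equal(project_traces(v2, model2), C, tolerance = 1e-8)
  # disjoint cells: y_ra of one is independent of the other's trace
  A2 <- A; A2[, , 2] <- 0; A2[14:18, 14:18, 2] <- 1
  Cx <- C; Cx[, 2] <- rev(C[, 2])
  Yd <- C[, 1] %*% t(miniscopr:::flatten_A(A2)[, 1])
  vd <- video_array(array(pmax(Yd, 0), c(TT, H, W)))
  m1 <- cnmf_model(A2, C, b = b * 0, f = f * 0)
  m2 <- cnmf_model(A2, Cx, b = b * 0, f = f * 0)
  expect_equal(project_traces(vd, m1)[, 1], project_traces(vd, m2)[, 1],
               tolerance = 1e-10)
})

test_that("spatial update matches NNLS at zero penalty and empties at huge penalty", {
  set.seed(23)
  H <- 12; W <- 12; TT <- 150
  A <- array(0, c(H, W, 1)); A[5:8, 5:8, 1] <- matrix(runif(16, .3, 1), 4)
  c_tr <- abs(rnorm(TT)) * 8
  Y <- c_tr %*% t(miniscopr:::flatten_A(A)[, 1])
  v <- video_array(array(Y, c(TT, H, W)))
  sn <- matrix(1, H, W)
  model <- cnmf_model(A, matrix(c_tr, TT, 1), b = matrix(0, H, W),
                      f = rep(0, TT))
  up <- update_spatial(v, model, sn, dl_wnd = 3, sparse_penalty = 0)
  # noiseless, single unit, lambda 0: per-pixel NNLS solution = truth
  expect_equal(up$A[5:8, 5:8, 1], A[5:8, 5:8, 1], tolerance = 1e-6)
  # very large penalty drops all units
  up2 <- update_spatial(v, model, sn, dl_wnd = 3, sparse_penalty = 1e6)
  expect_equal(dim(up2$A)[3], 0)
  # sparsity is non-increasing in the penalty
  nnz <- vapply(c(0, 0.5, 5, 50), function(l) {
    m <- update_spatial(v, model, sn, dl_wnd = 3, sparse_penalty = l)
    if (dim(m$A)[3] == 0) 0L else sum(m$A > 0)
  }, 0L)
  expect_true(all(diff(nnz) <= 0))
})

test_that("per-pixel lasso agrees with the glmnet oracle", {
  set.seed(24)
  TT <- 150; K <- 4
  C <- matrix(abs(rnorm(TT * K)), TT, K)
  f <- abs(rnorm(TT))
  X <- cbind(C, f)
  M <- crossprod(X)
  a_true <- c(0.8, 0, 0.5, 0, 0.3)
  y <- as.vector(X %*% a_true + rnorm(TT, sd = 0.1))
  lambda <- 4
  V <- matrix(crossprod(X, y), ncol = 1)
  got <- miniscopr:::cpp_spatial_lasso(M, V, list(1:(K + 1)), lambda, K,
                                       1e-10, 5000L)[, 1]
  obj <- function(a) sum((y - X %*% a)^2) + lambda * sum(a[1:K])
  # glmnet solves (1/2n)RSS + lam * sum(pf_j |b_j|); map the scales
  # (penalty.factor is rescaled internally to average 1)
  pf <- c(rep(1, K), 0)
  lam_g <- lambda / (2 * TT) * sum(pf) / (K + 1)
  g <- glmnet::glmnet(X, y, lambda = lam_g, lower.limits = 0,
                      penalty.factor = pf, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  a_g <- as.vector(g$beta)
  gap <- abs(obj(got) - obj(a_g)) / max(1, abs(obj(a_g)))
  expect_lt(gap, 1e-4)
})

test_that("temporal deconvolution recovers isolated impulses and respects the penalty limit", {
  g <- c(1.2, -0.35)
  ar <- structure(list(p = 2L, gamma = g, sd = 1), class = "ar_params")
  TT <- 300
  s_true <- rep(0, TT); s_true[c(50, 180)] <- c(1, 0.7)
  y <- as.vector(stats::filter(s_true, g, method = "recursive"))
  fit <- solve_temporal_unit(y, ar, sparse_penalty = 1e-6)
  # dominant spikes land on the true frames
  top <- order(fit$s, decreasing = TRUE)[1:2]
  expect_setequal(top, c(50, 180))
  expect_gt(cor(fit$c, y), 0.999)
  expect_true(all(fit$s >= 0) && all(fit$c >= -1e-12))
  # huge penalty: s == 0 and the fit degenerates to baseline terms
  fit2 <- solve_temporal_unit(y + 1, ar, sparse_penalty = 1e5)
  expect_true(all(fit2$s == 0))
})

test_that("temporal solver matches a projected-gradient QP oracle", {
  set.seed(25)
  g <- c(1.3, -0.42)
  TT <- 120
  d <- ar_impulse(g, TT)
  s_true <- rep(0, TT); s_true[c(20, 60, 90)] <- c(1, 0.5, 0.8)
  for (lam_mult in c(0.002, 0.02)) {
    y <- as.vector(stats::filter(s_true, g, method = "recursive")) +
      rnorm(TT, sd = 0.05) + 0.2
    lambda <- lam_mult * 1 * sqrt(TT)
    ar <- structure(list(p = 2L, gamma = g, sd = 1), class = "ar_params")
    fit <- solve_temporal_unit(y, ar, sparse_penalty = lam_mult,
                               tol = 1e-12, max_sweep = 20000L)
    # compare pre-scaling solutions on the common objective
    raw <- miniscopr:::cpp_temporal_cd(y, d[abs(d) > 1e-10], lambda,
                                       1e-12, 20000L, TRUE, TRUE)
    obj_cd <- temporal_objective(y, d, lambda, raw$s, raw$b0, raw$c0)
    orc <- oracle_temporal_qp(y, d, lambda, iters = 30000)
    gap <- (obj_cd - orc$objective) / max(1, abs(orc$objective))
    expect_lt(abs(gap), 1e-4)
  }
})

test_that("update_temporal is order-invariant and drops silent units", {
  sim <- sim_small()
  mc <- mc_small()
  s <- seeds_init(mc, wnd_size = 300, step_size = 150, max_wnd = 8)
  s <- seeds_merge(mc, pnr_refine(mc, s), thres_dist = 4)
  A <- init_spatial(mc, s, wnd = 8)
  C <- init_temporal(mc, A)
  bg <- init_background(mc, A, C)
  model <- cnmf_model(A, C, b = bg$b, f = bg$f)
  sn <- estimate_noise(mc, 1)
  model <- update_spatial(mc, model, sn, dl_wnd = 8, sparse_penalty = 0.1)
  up <- update_temporal(mc, model, p = 2, noise_freq = 1,
                        sparse_penalty = 0.008)
  K <- dim(model$A)[3]
  perm <- rev(seq_len(K))
  pm <- cnmf_model(model$A[, , perm, drop = FALSE],
                   model$C[, perm, drop = FALSE],
                   model$S[, perm, drop = FALSE], b = model$b, f = model$f,
                   unit_ids = model$unit_ids[perm])
  up_p <- update_temporal(mc, pm, p = 2, noise_freq = 1,
                          sparse_penalty = 0.008)
  ord <- match(up$unit_ids, up_p$unit_ids)
  expect_equal(up_p$C[, ord], up$C, tolerance = 1e-6)
  expect_equal(up_p$S[, ord], up$S, tolerance = 1e-6)
  expect_true(all(colSums(up$C) > 0))
})

test_that("jaccard grouping separates non-overlapping units", {
  A <- array(0, c(20, 20, 3))
  A[1:5, 1:5, 1] <- 1
  A[3:7, 3:7, 2] <- 1    # overlaps unit 1 heavily
  A[14:18, 14:18, 3] <- 1
  gr <- jaccard_groups(A, jac_thres = 0.1)
  expect_equal(gr[1], gr[2])
  expect_true(gr[3] != gr[1])
})

test_that("unit_merge combines duplicated units and is idempotent", {
  m <- random_model(4, seed = 31)
  # duplicate unit 1 exactly
  A <- m$A; A[, , 2] <- A[, , 1]
  C <- m$C; C[, 2] <- C[, 1]
  dup <- cnmf_model(A, C)
  merged <- unit_merge(dup, thres_corr = 0.9)
  keep <- which(merged$unit_ids == 1)
  expect_equal(merged$A[, , keep], 2 * A[, , 1])  # footprint = sum
  expect_equal(merged$C[, keep], C[, 1])          # trace = mean
  # disjoint units unchanged regardless of correlation
  A2 <- array(0, c(16, 16, 2)); A2[1:4, 1:4, 1] <- 1; A2[10:13, 10:13, 2] <- 1
  same <- matrix(rep(abs(rnorm(40)), 2), 40, 2)
  dj <- unit_merge(cnmf_model(A2, same), thres_corr = 0.5)
  expect_equal(dim(dj$A)[3], 2)
  # idempotence on random models
  for (seed in 32:34) {
    m <- random_model(5, seed = seed)
    once <- unit_merge(m, 0.6)
    twice <- unit_merge(once, 0.6)
    expect_equal(twice$A, once$A)
    expect_equal(twice$C, once$C)
  }
})

test_that("apply_unit_labels drops and merges without touching the input", {
  m <- random_model(4, seed = 35)
  out_keep <- apply_unit_labels(m, rep("keep", 4))
  expect_equal(out_keep$A, m$A)
  out_drop <- apply_unit_labels(m, c("drop", "keep", "keep", "keep"))
  expect_equal(dim(out_drop$A)[3], 3)
  out_mrg <- apply_unit_labels(m, c("g1", "g1", "keep", "keep"))
  expect_equal(dim(out_mrg$A)[3], 3)
  i <- which(out_mrg$unit_ids == 1)
  expect_equal(out_mrg$A[, , i], m$A[, , 1] + m$A[, , 2])
  expect_equal(dim(m$A)[3], 4)  # input unmodified
  expect_error(apply_unit_labels(m, stats::setNames(rep("keep", 4),
                                                    c("1", "2", "3", "9"))),
               "unknown unit id")
  expect_error(apply_unit_labels(m, rep("keep", 3)), "one label per unit")
})

test_that("spatial and temporal updates never increase their objectives", {
  set.seed(36)
  H <- 16; W <- 16; TT <- 200
  A <- array(0, c(H, W, 2))
  A[3:8, 3:8, 1] <- exp(-outer((-2:3)^2, (-2:3)^2, `+`) / 4)
  A[9:14, 9:14, 2] <- exp(-outer((-2:3)^2, (-2:3)^2, `+`) / 4)
  C <- matrix(abs(rnorm(TT * 2)) * 6, TT, 2)
  Y <- C %*% t(miniscopr:::flatten_A(A)) + rnorm(TT * H * W, sd = 0.3)
  Y[Y < 0] <- 0
  v <- video_array(array(Y, c(TT, H, W)))
  # jitter the initial footprints, then check the spatial objective drops
  Aj <- A * array(runif(length(A), 0.3, 1.7), dim(A))
  model <- cnmf_model(Aj, C, b = matrix(0, H, W), f = rep(0, TT))
  sn <- estimate_noise(v, 1)
  lam_px <- 0.05 * as.vector(sn) * sqrt(TT)
  sp_obj <- function(Am, bm) {
    R <- Y - C %*% t(miniscopr:::flatten_A(Am))
    sum(R^2) + sum(lam_px * rowSums(miniscopr:::flatten_A(Am)))
  }
  up <- update_spatial(v, model, sn, dl_wnd = 5, sparse_penalty = 0.05)
  expect_lte(sp_obj(up$A), sp_obj(Aj))
})
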