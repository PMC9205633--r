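test_that("filter_trace partitions a trace exactly into low and high bands", {
  set.seed(10)
  x <- rnorm(500)
  lo <- filter_trace(x, 1, "low", fps = 30)
  hi <- filter_trace(x, 1, "high", fps = 30)
  expect_lt(max(abs(lo + hi - x)), 1e-9)
  expect_equal(mean(lo), mean(x))  # low-pass retains DC
  # pure 0.2 Hz sinusoid below a 1 Hz cutoff stays in the low band
  tt <- seq_len(600) / 30
  s <- sin(2 * pi * 0.2 * tt)
  expect_lt(max(abs(filter_trace(s, 1, "low", 30) - s)), 1e-6)
  expect_lt(max(abs(filter_trace(s, 1, "high", 30))), 1e-6)
  expect_error(filter_trace(x, 20, "low", 30), "cutoff")
  expect_error(filter_trace(x, 0, "low", 30), "cutoff")
})

test_that("seeds_init finds every true cell and nothing on constant input", {
  # constant video -> zero seeds
  cv <- video_array(array(9, c(30, 16, 16)))
  expect_equal(nrow(seeds_init(cv, wnd_size = 10, step_size = 5,
                               max_wnd = 5)), 0)
  # every simulated cell centre gets a seed within a cell radius
  sim <- sim_small()
  mc <- mc_small()
  s <- seeds_init(mc, wnd_size = 300, step_size = 150, max_wnd = 8,
                  diff_thres = 3)
  cents <- calculate_centroids(sim$truth_A)
  # the registered movie sits at an arbitrary integer gauge relative to
  # the simulation's frame; remove the common displacement first
  disp <- t(vapply(seq_len(nrow(cents)), function(k) {
    i <- which.min((s$row_px - cents$row[k])^2 +
                     (s$col_px - cents$col[k])^2)
    c(s$row_px[i] - cents$row[k], s$col_px[i] - cents$col[k])
  }, numeric(2)))
  gauge <- apply(disp, 2, median)
  resid <- sweep(disp, 2, gauge)
  expect_true(all(sqrt(rowSums(resid^2)) <= 4.5))  # within a cell radius
})

test_that("random-draw seeding finds the same cells as the rolling window", {
  mc <- mc_small()
  roll <- seeds_init(mc, wnd_size = 300, step_size = 150, max_wnd = 8)
  set.seed(77)
  rand <- seeds_init(mc, wnd_size = 300, method = "random", n_iter = 5,
                     max_wnd = 8)
  expect_gt(nrow(rand), 0)
  # every rolling-window seed has a random-draw seed nearby (both methods
  # see the same cells; exact pixels may differ by projection noise)
  dmin <- vapply(seq_len(nrow(roll)), function(i)
    min(abs(rand$row_px - roll$row_px[i]) +
          abs(rand$col_px - roll$col_px[i])), 0)
  expect_lt(stats::median(dmin), 3)
})

test_that("peak-to-noise refinement separates signal from noise traces", {
  TT <- 900; fps <- 30
  tt <- seq_len(TT) / fps
  set.seed(12)
  arr <- array(0, c(TT, 1, 3))
  arr[, 1, 1] <- 5 + 4 * sin(2 * pi * 0.2 * tt) + rnorm(TT, sd = 0.05)
  arr[, 1, 2] <- 5 + rnorm(TT)                      # pure white noise
  arr[, 1, 3] <- 5                                  # constant
  v <- video_array(arr)
  seeds <- structure(data.frame(row_px = c(0L, 0L, 0L), col_px = 0:2,
                                max_intensity = c(9, 6, 5)),
                     class = c("seeds", "data.frame"))
  out <- pnr_refine(v, seeds, noise_freq = 1, thres = 1)
  expect_true(out$mask_pnr[1])        # slow signal + tiny noise kept
  expect_false(out$mask_pnr[2])       # white noise: pnr ~ 1, removed
  expect_equal(out$pnr[3], Inf)       # zero noise ptp -> kept with Inf
  expect_true(out$mask_pnr[3])
  # pnr invariant to positive scaling
  out2 <- pnr_refine(video_array(arr * 7), seeds, noise_freq = 1)
  expect_equal(out2$pnr[1:2], out$pnr[1:2], tolerance = 1e-10)
})

test_that("KS refinement keeps transient-bearing traces and drops Gaussian ones", {
  TT <- 3000
  set.seed(13)
  gaussian <- rnorm(TT)
  transients <- rnorm(TT)
  kick <- sort(sample(TT - 60, 12))
  kern <- 8 * exp(-(0:59) / 20)
  for (t in kick) transients[t:(t + 59)] <- transients[t:(t + 59)] + kern
  arr <- array(0, c(TT, 1, 2))
  arr[, 1, 1] <- gaussian - min(gaussian)
  arr[, 1, 2] <- transients - min(transients)
  seeds <- structure(data.frame(row_px = c(0L, 0L), col_px = 0:1,
                                max_intensity = c(1, 9)),
                     class = c("seeds", "data.frame"))
  out <- ks_refine(video_array(arr), seeds, sig = 0.05)
  expect_false(out$mask_ks[1])  # i.i.d. Gaussian looks normal -> removed
  expect_true(out$mask_ks[2])   # sparse large transients -> kept
})

test_that("seeds_merge keeps one seed per correlated neighbourhood", {
  TT <- 300
  set.seed(14)
  sig <- abs(filter_trace(rnorm(TT), 0.5, "low", 30)) * 10
  other <- abs(filter_trace(rnorm(TT), 0.5, "low", 30)) * 10
  arr <- array(rnorm(TT * 20 * 20, sd = .01), c(TT, 20, 20))
  arr[, 5, 5] <- arr[, 5, 5] + sig * 1.0
  arr[, 5, 7] <- arr[, 5, 7] + sig * 0.8   # same cell, 2 px away, dimmer
  arr[, 15, 15] <- arr[, 15, 15] + other   # distant, uncorrelated
  v <- video_array(arr - min(arr))
  seeds <- structure(data.frame(row_px = c(4L, 4L, 14L),
                                col_px = c(4L, 6L, 14L),
                                max_intensity = c(10, 8, 9)),
                     class = c("seeds", "data.frame"))
  out <- seeds_merge(v, seeds, thres_dist = 4, thres_corr = 0.8,
                     noise_freq = 1)
  expect_equal(out$mask_mrg, c(TRUE, FALSE, TRUE))
  # distant pair is untouched regardless of correlation
  expect_true(out$mask_mrg[3])
  # refinements are monotone: active count never increases
  expect_lte(sum(seed_active(out)), nrow(seeds))
})

test_that("init_spatial footprints honour the window and similarity contracts", {
  TT <- 200
  set.seed(15)
  c_tr <- abs(filter_trace(rnorm(TT), 1, "low", 30)) * 20
  blob <- exp(-outer((-3:3)^2, (-3:3)^2, `+`) / 4)
  arr <- array(0, c(TT, 21, 21))
  for (i in 1:7) for (j in 1:7)
    arr[, 7 + i, 7 + j] <- c_tr * blob[i, j]
  v <- video_array(arr)
  seeds <- structure(data.frame(row_px = 11L, col_px = 11L,
                                max_intensity = max(arr)),
                     class = c("seeds", "data.frame"))
  A <- init_spatial(v, seeds, thres_corr = 0.5, wnd = 6)
  expect_equal(dim(A), c(21, 21, 1))
  expect_equal(A[12, 12, 1], 1)  # seed pixel weight is 1 by definition
  # noiseless single cell: support within the true support dilated by 1 px
  supp <- A[, , 1] > 0
  true_supp <- matrix(FALSE, 21, 21); true_supp[8:14, 8:14] <- TRUE
  dil <- miniscopr:::dilate_gray(true_supp * 1, matrix(1, 3, 3)) > 0
  expect_true(all(!supp | dil))
  # pixels outside the window radius stay zero
  expect_true(all(A[1:4, , 1] == 0))
})

test_that("init_temporal is the footprint-weighted projection", {
  set.seed(16)
  H <- 12; W <- 12; TT <- 80
  A <- array(0, c(H, W, 1))
  A[5:8, 5:8, 1] <- matrix(runif(16), 4)
  c_true <- abs(rnorm(TT)) * 5
  Y <- c_true %*% t(as.vector(A[, , 1]))
  dim(Y) <- c(TT, H, W)
  v <- video_array(Y)
  C <- init_temporal(v, A)
  # exact algebraic recovery for a noiseless rank-one video
  expect_equal(as.vector(C), c_true, tolerance = 1e-10)
  # linearity: doubling the video doubles the traces
  C2 <- init_temporal(video_array(Y * 2), A)
  expect_equal(as.vector(C2), 2 * as.vector(C), tolerance = 1e-10)
  # all-zero video -> all-zero traces
  expect_true(all(init_temporal(video_array(Y * 0), A) == 0))
  expect_error(init_temporal(v, array(0, c(H, W, 1))), "zero footprint")
})

test_that("init_background recovers mean residual structure", {
  set.seed(17)
  H <- 10; W <- 10; TT <- 50
  A <- array(0, c(H, W, 1)); A[3:5, 3:5, 1] <- 1
  C <- matrix(abs(rnorm(TT)), TT, 1)
  Y <- C %*% t(miniscopr:::flatten_A(A))
  v <- video_array(array(Y, c(TT, H, W)))
  bg <- init_background(v, A, C)
  expect_true(all(abs(bg$b) < 1e-12))   # Y == AC exactly -> b = 0
  expect_true(all(abs(bg$f) < 1e-12))
  # Y = AC + constant k -> b == k and f == k
  vk <- video_array(array(Y + 4, c(TT, H, W)))
  bgk <- init_background(vk, A, C)
  expect_equal(as.vector(bgk$b), rep(4, H * W), tolerance = 1e-10)
  expect_equal(bgk$f, rep(4, TT), tolerance = 1e-10)
})

test_that("full refinement chain keeps one active seed per true cell", {
  sim <- sim_small()
  mc <- mc_small()
  s <- seeds_init(mc, wnd_size = 300, step_size = 150, max_wnd = 8,
                  diff_thres = 3)
  n0 <- nrow(s)
  s <- pnr_refine(mc, s, noise_freq = 1, thres = 1)
  n1 <- sum(seed_active(s))
  s <- ks_refine(mc, s, sig = 0.05)
  n2 <- sum(seed_active(s))
  s <- seeds_merge(mc, s, thres_dist = 4, thres_corr = 0.8, noise_freq = 1)
  n3 <- sum(seed_active(s))
  expect_true(n0 >= n1 && n1 >= n2 && n2 >= n3)  # monotone refinement
  # recall 1.0 at the seed stage: every cell keeps an active seed
  cents <- calculate_centroids(sim$truth_A)
  act <- s[seed_active(s), ]
  disp <- t(vapply(seq_len(nrow(cents)), function(k) {
    i <- which.min((act$row_px - cents$row[k])^2 +
                     (act$col_px - cents$col[k])^2)
    c(act$row_px[i] - cents$row[k], act$col_px[i] - cents$col[k])
  }, numeric(2)))
  gauge <- apply(disp, 2, median)
  resid <- sweep(disp, 2, gauge)
  expect_true(all(sqrt(rowSums(resid^2)) <= 4.5))
})
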