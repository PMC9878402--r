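test_that("the canonical HRF peaks at 5 s with a later negative undershoot", {
  h <- canonical_hrf(0.72)
  expect_equal(attr(h, "peak_time"), 5.04, tolerance = 0.01)  # gamma mode (shape-1)*scale
  expect_equal(max(h), 1)
  expect_equal(length(h), floor(32 / 0.72) + 1L)
  expect_lt(min(h), 0)
  expect_gt(which.min(h), which.max(h))
  h1 <- canonical_hrf(1)
  expect_equal(which.max(h1) - 1L, 5L)        # exact 5 s at unit sampling
  expect_error(canonical_hrf(0), "positive")
})

test_that("design matrices place HRF kernels at event frames and trim the run", {
  h <- canonical_hrf(0.72)
  d1 <- build_design(data.frame(frame = 100L, sub_cluster = 1L),
                     n_frames = 300, tr = 0.72, trim = 0)
  expect_equal(d1$X[101:(100 + length(h)), "sc1"], as.numeric(h), tolerance = 1e-8)
  expect_lt(max(abs(d1$X[1:100, "sc1"])), 1e-10)   # FFT convolution leaves fp dust
  expect_true("intercept" %in% colnames(d1$X))
  # linearity: two nearby events superpose
  d2 <- build_design(data.frame(frame = c(100L, 103L), sub_cluster = 1L),
                     n_frames = 300, tr = 0.72, trim = 0)
  manual <- numeric(300)
  manual[100 + seq_along(h)] <- manual[100 + seq_along(h)] + h
  manual[103 + seq_along(h)] <- manual[103 + seq_along(h)] + h
  expect_equal(d2$X[, "sc1"], manual, tolerance = 1e-8)
  # 1,200-frame run -> 1,100 design rows after the 50-frame trims
  d3 <- build_design(data.frame(frame = c(300L, 700L), sub_cluster = c(1L, 2L)),
                     n_frames = 1200, tr = 0.72, trim = 50)
  expect_equal(nrow(d3$X), 1100L)
  expect_warning(
    d4 <- build_design(data.frame(frame = 100L, sub_cluster = 1L),
                       n_frames = 300, tr = 0.72, trim = 0, sub_clusters = 1:3),
    "zero-event")
  expect_equal(d4$dropped, 2:3)
  expect_error(build_design(data.frame(frame = 400L, sub_cluster = 1L),
                            n_frames = 300, tr = 0.72), "outside")
})

test_that("per-voxel OLS matches the normal equations and recovers noiseless betas", {
  set.seed(11)
  des <- build_design(data.frame(frame = c(30L, 90L, 150L), sub_cluster = c(1L, 2L, 1L)),
                      n_frames = 220, tr = 0.72, trim = 10)
  X <- des$X
  b_true <- matrix(rnorm(10 * ncol(X)), 10)
  y0 <- b_true %*% t(X)
  fit0 <- run_glm(y0, des)
  expect_equal(unname(fit0$betas), unname(b_true), tolerance = 1e-8)
  expect_equal(unname(fit0$sigma2), rep(0, 10), tolerance = 1e-10)
  # noisy case: brute-force normal-equations oracle
  y <- y0 + matrix(rnorm(10 * nrow(X)), 10)
  fit <- run_glm(y, des)
  b_ne <- t(solve(t(X) %*% X, t(X) %*% t(y)))
  expect_equal(unname(fit$betas), unname(b_ne), tolerance = 1e-8)
  expect_equal(fit$df, nrow(X) - ncol(X))
  # residuals orthogonal to every design column
  resid <- y - fit$betas %*% t(X)
  expect_lt(max(abs(resid %*% X)), 1e-8 * max(abs(y)))
  # rank deficiency is reported with column names
  des_bad <- des
  des_bad$X <- cbind(des$X, dup = des$X[, 1])
  expect_error(run_glm(y, des_bad), "rank deficient")
})

test_that("shuffling event frames destroys map recovery (negative control)", {
  ps <- fix_patterns40()
  r2v <- split(1:400, rep(1:40, each = 10))
  run <- simulate_voxels(simulate_run(ps, n_frames = 600, snr = 1, seed = 41), r2v, 400)
  des <- suppressWarnings(
    build_design(data.frame(frame = run$log$frame, sub_cluster = run$log$pattern),
                 n_frames = 600, tr = 0.72, trim = 50))
  fit <- run_glm(run$voxel_ts, des)
  r_real <- cor(fit$betas[, "sc1"], pattern_voxel_map(ps$patterns[, 1], r2v, 400))
  set.seed(1)
  sh <- run$log
  sh$frame <- sort(sample(setdiff(60:540, sh$frame), nrow(sh)))
  des_s <- suppressWarnings(
    build_design(data.frame(frame = sh$frame, sub_cluster = sh$pattern),
                 n_frames = 600, tr = 0.72, trim = 50))
  fit_s <- run_glm(run$voxel_ts, des_s)
  r_shuf <- cor(fit_s$betas[, "sc1"], pattern_voxel_map(ps$patterns[, 1], r2v, 400))
  expect_gt(r_real, 0.5)
  expect_lt(abs(r_shuf), 0.35)
})

test_that("group statistics average runs, t-to-z across subjects, and cap degeneracies", {
  set.seed(12)
  n_sub <- 30; n_vox <- 2000
  # null betas: fraction with |z| > 1.96 near 0.05 (t-distribution oracle)
  fracs <- vapply(1:5, function(i) {
    rb <- lapply(1:n_sub, function(s) list(matrix(rnorm(n_vox), n_vox, 1)))
    g <- group_stats(rb)
    mean(abs(g$z) > qnorm(0.975))
  }, 0)
  expect_lt(abs(mean(fracs) - 0.05), 0.015
  )
  # scale invariance: doubling betas doubles means, leaves z unchanged
  rb <- lapply(1:8, function(s) list(matrix(rnorm(50), 50, 1)))
  g1 <- group_stats(rb)
  g2 <- group_stats(lapply(rb, function(r) list(2 * r[[1]])))
  expect_equal(g2$z, g1$z, tolerance = 1e-10)
  expect_equal(g2$mean_beta, 2 * g1$mean_beta, tolerance = 1e-10)
  # near-identical betas across subjects hit the z cap
  rb_id <- lapply(1:8, function(s) list(matrix(1 + rnorm(5, sd = 1e-9), 5, 1)))
  gc <- group_stats(rb_id, z_max = 10)
  expect_true(all(gc$z == 10))
  expect_true(all(gc$capped))
  expect_error(group_stats(rb[1]), "2 subjects")
  # runs are a fixed effect: averaging two runs equals one run of their mean
  two <- lapply(1:8, function(s) list(matrix(rnorm(50), 50, 1), matrix(rnorm(50), 50, 1)))
  one <- lapply(two, function(r) list((r[[1]] + r[[2]]) / 2))
  expect_equal(group_stats(two)$z, group_stats(one)$z, tolerance = 1e-10)
})

test_that("paired sub-clusters yield anti-correlated maps on synthetic voxel data", {
  ps <- fix_patterns40()
  r2v <- split(1:400, rep(1:40, each = 10))
  acc <- matrix(0, 400, 2); cnt <- c(0, 0)
  for (s in 51:60) {
    run <- simulate_voxels(simulate_run(ps, n_frames = 600, snr = 1, seed = s), r2v, 400)
    des <- suppressWarnings(
      build_design(data.frame(frame = run$log$frame, sub_cluster = run$log$pattern),
                   n_frames = 600, tr = 0.72, trim = 50, sub_clusters = 1:12))
    fit <- run_glm(run$voxel_ts, des)
    for (j in 1:2) {
      cn <- paste0("sc", j)
      if (cn %in% colnames(fit$betas)) { acc[, j] <- acc[, j] + fit$betas[, cn]; cnt[j] <- cnt[j] + 1 }
    }
  }
  b <- sweep(acc, 2, cnt, `/`)
  expect_lt(cor(b[, 1], b[, 2]), -0.6)
})
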