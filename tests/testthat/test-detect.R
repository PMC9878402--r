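test_that("sliding windows enumerate stride-1 odd windows with centered frames", {
  w <- sliding_windows(1124, 25)
  expect_equal(nrow(w), 1100L)
  expect_equal(w$center, w$start + 12L)
  expect_equal(nrow(sliding_windows(25, 25)), 1L)
  expect_error(sliding_windows(24, 25), "exceeds")
  expect_error(sliding_windows(100, 24), "odd")
})

test_that("sw-PCA matches a brute-force eigendecomposition of the window correlation matrix", {
  set.seed(7)
  ts <- roi_timeseries(matrix(rnorm(12 * 80), 12), tr = 0.72)
  sw <- swpca(ts, 11)
  for (i in c(1, 25, 70)) {
    win <- ts$data[, i:(i + 10)]
    cm <- cor(t(win))                          # full correlation matrix, independent route
    ev <- eigen(cm, symmetric = TRUE)
    expect_equal(sw$var[i], ev$values[1] / sum(diag(cm)), tolerance = 1e-8)
    expect_equal(abs(sum(sw$loadings[, i] * ev$vectors[, 1])), 1, tolerance = 1e-8)
  }
})

test_that("a rank-one noiseless window explains all variance", {
  s <- sin(seq(0, 3, length.out = 25))
  a <- rnorm(8)
  ts <- roi_timeseries(outer(a, s), tr = 0.72)
  sw <- swpca(ts, 25)
  expect_equal(sw$var[1], 1, tolerance = 1e-8)
})

test_that("white-noise runs give small, stable explained variance", {
  sds <- vapply(1:3, function(s) {
    set.seed(s)
    sw <- swpca(roi_timeseries(matrix(rnorm(264 * 150), 264), tr = 0.72), 25)
    c(mean(sw$var), sd(sw$var))
  }, numeric(2))
  expect_true(all(sds[1, ] < 0.3))
  expect_true(all(sds[2, ] < 0.05))
})

test_that("scale invariance and ROI-permutation equivariance hold", {
  set.seed(3)
  ts <- roi_timeseries(matrix(rnorm(10 * 60), 10), tr = 0.72)
  sw <- swpca(ts, 11)
  ts2 <- ts; ts2$data <- ts$data * 37.5
  sw2 <- swpca(ts2, 11)
  expect_equal(sw2$var, sw$var, tolerance = 1e-10)
  expect_equal(abs(colSums(sw2$loadings * sw$loadings)), rep(1, ncol(sw$loadings)),
               tolerance = 1e-10)
  p <- sample(10)
  ts3 <- ts; ts3$data <- ts$data[p, ]
  sw3 <- swpca(ts3, 11)
  expect_equal(sw3$var, sw$var, tolerance = 1e-10)
  expect_equal(abs(colSums(sw3$loadings * sw$loadings[p, ])),
               rep(1, ncol(sw$loadings)), tolerance = 1e-10)
})

# Fabricate an swpca object with a prescribed variance timecourse.
fake_swpca <- function(v, w = 5L, n_roi = 4L) {
  nw <- length(v)
  structure(list(var = v, starts = 0:(nw - 1), centers = 0:(nw - 1) + (w - 1L) %/% 2L,
                 ends = 0:(nw - 1) + w - 1L,
                 loadings = matrix(1 / sqrt(n_roi), n_roi, nw),
                 scores = matrix(seq_len(w), w, nw), skipped = logical(nw),
                 w = w, tr = 0.72, roi_ids = paste0("r", 1:n_roi),
                 n_frames = nw + w - 1L, frame_offset = 0L,
                 subject_id = NA_character_, run_id = NA_character_),
            class = "swpca")
}

test_that("events are strict local maxima, never endpoints or plateaus", {
  bump <- fake_swpca(c(1, 2, 3, 4, 3, 2, 1) / 10)
  ev <- detect_ts(bump)
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$center, 3 + 2)       # window center of the peak window
  expect_equal(nrow(detect_ts(fake_swpca((1:7) / 10))$events), 0L)
  expect_equal(nrow(detect_ts(fake_swpca(c(1, 2, 3, 3, 2, 1) / 10))$events), 0L)
})

test_that("events overlapping scrubbed frames are dropped", {
  bump <- fake_swpca(c(1, 2, 3, 4, 3, 2, 1) / 10)
  mask <- logical(bump$n_frames)
  mask[6] <- TRUE                             # inside the peak window [3, 7]
  expect_equal(nrow(detect_ts(bump, mask)$events), 0L)
  mask2 <- logical(bump$n_frames)
  mask2[11] <- TRUE                           # outside every candidate window
  expect_equal(nrow(detect_ts(bump, mask2)$events), 1L)
  expect_error(detect_ts(bump, logical(3)), "mask length")
})

test_that("the sign rule follows the score slope and flags zero slopes", {
  l <- rnorm(6); l <- l / sqrt(sum(l^2))
  up <- extract_tsp(l, 1:9)
  expect_equal(up$tsp, l)
  expect_false(up$flipped)
  dn <- extract_tsp(l, 9:1)
  expect_equal(dn$tsp, -l)
  expect_true(dn$flipped)
  flat <- extract_tsp(l, rep(1, 9))
  expect_true(flat$ambiguous)
  expect_equal(flat$tsp, l)
})

test_that("an isolated event's TSP points along its generating pattern", {
  # dual-route check: the generator logs the pattern each detected TSP
  # should match; verify sign and strength for clean isolated transients
  ps <- fix_patterns264()
  run <- simulate_run(ps, n_frames = 800, event_rate = 10 / 800, pair_prob = 0,
                      snr = 2, seed = 21)
  ev <- detect_ts(swpca(trim_frames(bandpass(run$roi_ts), 38, 38), 25))
  g <- crossprod(tsp_matrix_for_tests(ps$patterns), tsp_matrix_for_tests(ev$tsp))
  rs <- vapply(seq_len(ncol(ev$tsp)), function(j) {
    i <- which.min(abs(run$log$frame - ev$events$center[j]))
    if (abs(run$log$frame[i] - ev$events$center[j]) <= 2) g[run$log$pattern[i], j]
    else NA_real_
  }, 0)
  rs <- rs[!is.na(rs)]
  expect_gt(length(rs), 5)
  expect_gte(mean(rs > 0), 0.85)              # sign recovered except at flank boundaries
  expect_gt(median(rs), 0.6)                  # correlation-PCA loadings saturate toward
                                              # the sign pattern, bounding r below 1
})

test_that("synchronization measures agree with their closed forms", {
  # identical timecourses: correlation matrix all ones, Frobenius norm = N
  s <- sin(seq(0, 6, length.out = 60)) + 0.1 * seq(0, 1, length.out = 60)
  ts <- roi_timeseries(matrix(rep(s, each = 6), 6), tr = 0.72)
  sm <- sync_measures(ts, 11, measures = c("frobenius_norm", "phase_sync"))
  expect_equal(sm$frobenius_norm, rep(6, nrow(sm)), tolerance = 1e-8)
  expect_equal(sm$phase_sync, rep(1, nrow(sm)), tolerance = 1e-6)
  # independent phases: Kuramoto order parameter near N^(-1/2)
  set.seed(9)
  low <- replicate(20, {
    x <- matrix(rnorm(264 * 64), 264)
    mean(sync_measures(roi_timeseries(x, tr = 0.72), 11,
                       measures = "phase_sync")$phase_sync)
  })
  expect_gt(mean(low < 0.15), 0.9)
  # point-process counts from the z-scored run
  z <- matrix(rnorm(5 * 30), 5)
  ppa <- sync_measures(roi_timeseries(z, tr = 0.72), 5, measures = "ppa_count")
  zz <- t(scale(t(z)))
  expect_equal(ppa$ppa_count, colSums(zz > 1)[ppa$center + 1])
})

test_that("global efficiency matches a brute-force shortest-path computation", {
  set.seed(4)
  ts <- roi_timeseries(matrix(rnorm(5 * 9), 5), tr = 0.72)
  ge <- sync_measures(ts, 9, measures = "global_efficiency")$global_efficiency
  z <- window_znorm(ts$data)
  r <- tcrossprod(z) / 8; diag(r) <- 1
  len <- pmin(1 - r, 2); diag(len) <- 0
  n <- 5
  d <- len                                    # Floyd-Warshall
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  expect_equal(ge, mean(1 / d[upper.tri(d)]), tolerance = 1e-10)
})

test_that("event timing is stable across window sizes for well-separated events", {
  ps <- fix_patterns40()
  run <- simulate_run(ps, n_frames = 900, event_rate = 8 / 900, pair_prob = 0,
                      snr = 4, seed = 31)
  pre <- trim_frames(bandpass(run$roi_ts), 38, 38)
  # flank-maximum positions drift with the window length, so alignment is
  # asserted at +-5 frames for neighboring sizes
  scan <- window_size_scan(pre, c(15, 25), tol = 5)
  expect_gte(min(scan$alignment$frac_ref_matched), 0.8)
  expect_true(all(scan$alignment$n_maxima > 0))
  one <- window_size_scan(pre, 25)
  expect_equal(one$scans[[1]]$var, swpca(pre, 25)$var)
  expect_error(window_size_scan(pre, integer(0)), "no window sizes")
})
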