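test_that("correlation k-means recovers tight generating clusters exactly", {
  ps <- fix_patterns40()
  set.seed(5)
  truth <- rep(1:6, each = 30)
  tsps <- ps$patterns[, truth] + matrix(rnorm(40 * 180, sd = 0.03), 40)
  m <- fit_kmeans_corr(tsps, k = 6, n_init = 20, seed = 2)
  expect_equal(adjusted_rand(m$labels, truth), 1)
  mm <- match_centroids(m$centroids, ps$patterns)
  expect_true(all(mm$r > 0.99))
})

test_that("k = 1 yields the normalized mean direction and zero inertia for duplicates", {
  set.seed(8)
  x <- matrix(rnorm(20 * 15), 20)
  m1 <- fit_kmeans_corr(x, k = 1, n_init = 3, seed = 1)
  xb <- tsp_matrix_for_tests(x)
  mu <- rowMeans(xb); mu <- mu - mean(mu); mu <- mu / sqrt(sum(mu^2))
  expect_equal(abs(sum(m1$centroids[, 1] * mu)), 1, tolerance = 1e-8)
  same <- matrix(rep(rnorm(20), 7), 20)
  m0 <- fit_kmeans_corr(same, k = 1, n_init = 2, seed = 1)
  expect_equal(m0$inertia, 0, tolerance = 1e-10)
  expect_error(fit_kmeans_corr(x[, 1:3], k = 5), "cannot support")
})

test_that("restart selection is deterministic and minimizes total distance", {
  set.seed(2)
  x <- matrix(rnorm(15 * 60), 15)
  a <- fit_kmeans_corr(x, k = 4, n_init = 10, seed = 7)
  b <- fit_kmeans_corr(x, k = 4, n_init = 10, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(a$inertia, b$inertia)
  # brute-force inertia from the returned assignment (independent route)
  xb <- tsp_matrix_for_tests(x)
  sim <- crossprod(a$centroids, xb)
  expect_equal(a$inertia, sum(1 - sim[cbind(a$labels, seq_len(60))]),
               tolerance = 1e-10)
  # fewer restarts can never beat the selected optimum
  c1 <- fit_kmeans_corr(x, k = 4, n_init = 1, seed = 7)
  expect_gte(c1$inertia, a$inertia - 1e-10)
})

test_that("transition counts respect order and run boundaries", {
  tm <- transition_matrix(c(1, 2, 1, 2, 1), k = 2)
  expect_equal(tm, matrix(c(0L, 2L, 2L, 0L), 2, byrow = TRUE))
  expect_equal(transition_matrix(c(2), k = 3, runs = c(1)), matrix(0L, 3, 3))
  labs <- c(1, 2, 2, 3, 1, 3)
  runs <- c(1, 1, 1, 2, 2, 2)
  tm2 <- transition_matrix(labs, k = 3, runs = runs)
  expect_equal(sum(tm2), 4L)                   # no transition across the boundary
  expect_equal(tm2[2, 3], 0L)
  # row sums = occurrences minus terminal events, per run (counting oracle)
  n_terminal <- vapply(1:3, function(l) sum(c(labs[3], labs[6]) == l), 0L)
  expect_equal(rowSums(tm2), vapply(1:3, function(l) sum(labs == l), 0L) - n_terminal)
})

test_that("sub-cluster pairing recovers the designed anti-correlated pairs", {
  fx <- fix_events40()
  m <- fit_kmeans_corr(fx$tsp, k = 6, n_init = 30, seed = 3)
  tm <- transition_matrix(m$labels, k = 6, runs = fx$run)
  m <- pair_subclusters(m, tm)
  expect_equal(count_recovered_pairs(m, fx$patterns, r_min = 0.85), 3L)
  expect_true(all(m$pairing$centroid_r < 0))
  expect_error(pair_subclusters(fit_kmeans_corr(fx$tsp, k = 5, n_init = 5, seed = 1),
                                matrix(0, 5, 5)), "even")
})

test_that("pairing falls back with a warning when no anti-correlated partner exists", {
  base <- abs(matrix(rnorm(30 * 40), 30)) + 0.5   # all-positive vectors: r > 0 throughout
  m <- fit_kmeans_corr(base, k = 2, n_init = 5, seed = 1)
  if (crossprod(m$centroids)[1, 2] > 0) {
    expect_warning(pair_subclusters(m, matrix(1, 2, 2)), "anti-correlated")
  } else succeed()
})

test_that("cluster partitions are stable across k (pairing-level ARI)", {
  fx <- fix_events40()
  part <- lapply(c(4, 6, 8), function(k) {
    m <- fit_kmeans_corr(fx$tsp, k = k, n_init = 20, seed = 4)
    m <- pair_subclusters(m, transition_matrix(m$labels, k = k, runs = fx$run))
    m$pairing$cluster[m$labels]
  })
  truth_cluster <- fx$patterns$pairing$pair[fx$truth]
  expect_gte(adjusted_rand(part[[2]], truth_cluster), 0.8)
  # neighboring k values agree at the cluster level
  expect_gte(adjusted_rand(part[[1]], part[[2]]), 0.5)
  expect_gte(adjusted_rand(part[[3]], part[[2]]), 0.5)
})

test_that("occurrence timecourses normalize over clusters and match brute-force smoothing", {
  ev <- data.frame(run = rep(1, 6), frame = c(10, 30, 55, 80, 120, 150),
                   sub_cluster = c(1, 1, 2, 1, 2, 1))
  occ <- occurrence_timecourse(ev, 200, smooth_w = 50)
  # brute-force convolution oracle for the smoothing
  ind <- numeric(200); ind[c(10, 30, 80, 150) + 1] <- 1
  box <- rep(1 / 50, 50)
  conv <- stats::convolve(c(numeric(50), ind, numeric(50)), rev(box), type = "open")
  off <- 50 + 25                                # centered boxcar alignment
  expect_equal(occ$rate[1, ], conv[off + (1:200)], tolerance = 1e-10)
  # conditional probabilities sum to 1 where any event mass is present
  s <- colSums(occ$prob)
  expect_true(all(abs(s[s > 0] - 1) < 1e-9))
  # a single occurring cluster has probability 1 at those frames
  ev1 <- data.frame(run = 1, frame = c(20, 60), sub_cluster = 3)
  occ1 <- occurrence_timecourse(ev1, 100, smooth_w = 10)
  expect_true(all(occ1$prob[1, occ1$rate[1, ] > 0] == 1))
  expect_warning(
    occurrence_timecourse(ev1[0, ], 100,
                          pairing = data.frame(sub_cluster = 3, cluster = 1)),
    "no events")
  w0 <- suppressWarnings(
    occurrence_timecourse(ev1[0, ], 100,
                          pairing = data.frame(sub_cluster = 3, cluster = 1)))
  expect_equal(w0$rate, matrix(0, 1, 100))
})

test_that("sub-cluster probabilities are averaged within a paired cluster", {
  ev <- data.frame(run = 1, frame = c(10, 40), sub_cluster = c(1, 2))
  pairing <- data.frame(sub_cluster = 1:2, cluster = c(1, 1))
  occ <- occurrence_timecourse(ev, 100, smooth_w = 1, pairing = pairing)
  expect_equal(sum(occ$rate[1, ]), 1)           # 2 events x 1/2 each
  expect_equal(occ$rate[1, 11], 0.5)
})

test_that("knn classification scores centroids top and gates by the null quantile", {
  ps <- fix_patterns40()
  set.seed(6)
  train <- ps$patterns[, rep(1:6, each = 50)] + matrix(rnorm(40 * 300, sd = 0.1), 40)
  labs <- rep(1:6, each = 50)
  res <- knn_classify(ps$patterns, train, labs, knn_k = 30, n_random = 400, seed = 2)
  expect_equal(res$label, 1:6)
  expect_true(all(res$score > 0.8))
  # by construction, a random query scores below the q-quantile threshold
  # with probability q
  rnd <- matrix(rnorm(40 * 200), 40)
  r05 <- knn_classify(rnd, train, labs, knn_k = 30, n_random = 400,
                      null_quantile = 0.05, seed = 2)
  expect_lt(mean(r05$label == 0), 0.15)
  r95 <- knn_classify(rnd, train, labs, knn_k = 30, n_random = 400,
                      null_quantile = 0.95, seed = 2)
  expect_gte(mean(r95$label == 0), 0.9)
  # determinism under duplicated training data
  dup <- knn_classify(ps$patterns, cbind(train, train), c(labs, labs),
                      knn_k = 30, n_random = 100, seed = 2)
  expect_equal(dup$label, res$label)
  expect_error(knn_classify(ps$patterns, train, labs, knn_k = 1000), "training size")
})

test_that("predict assigns new patterns to the nearest centroid", {
  fx <- fix_events40()
  m <- fit_kmeans_corr(fx$tsp, k = 6, n_init = 10, seed = 3)
  self <- predict(m, m$centroids)
  expect_equal(self, 1:6)
  expect_equal(predict(m, fx$tsp), m$labels)
})
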