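# Shared fixtures, built once per test session and memoized.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# 6-pair pattern set over 264 ROIs (the emulated parcellation scale).
fix_patterns264 <- function() fixture("p264", function() make_pattern_set(264, 6, seed = 1))

# Small 3-pair pattern set for cheap runs.
fix_patterns40 <- function() fixture("p40", function() make_pattern_set(40, 3, seed = 1))

# One default-condition run (264 ROIs, 1200 frames, snr 1) plus its
# preprocessed series and detected events.
fix_run264 <- function() fixture("run264", function() {
  run <- simulate_run(fix_patterns264(), snr = 1, seed = 11)
  pre <- trim_frames(bandpass(run$roi_ts), 38, 38)
  ev <- detect_ts(swpca(pre, 25))
  list(run = run, pre = pre, events = ev)
})

# Pooled events from three cheap runs (40 ROIs, 600 frames, snr 1.5) with
# ground-truth labels, for clustering tests.
fix_events40 <- function() fixture("ev40", function() {
  ps <- fix_patterns40()
  evs <- lapply(1:3, function(s) {
    run <- simulate_run(ps, n_frames = 600, snr = 1.5, seed = s,
                        event_rate = 40 / 600)
    ev <- detect_ts(swpca(trim_frames(bandpass(run$roi_ts), 20, 20), 25))
    g <- crossprod(tsp_matrix_for_tests(ps$patterns), tsp_matrix_for_tests(ev$tsp))
    list(tsp = ev$tsp, truth = apply(g, 2, which.max), run = s,
         frames = ev$events$center)
  })
  list(tsp = do.call(cbind, lapply(evs, `[[`, "tsp")),
       truth = unlist(lapply(evs, `[[`, "truth")),
       run = rep(1:3, vapply(evs, function(e) length(e$truth), 0L)),
       frames = unlist(lapply(evs, `[[`, "frames")),
       patterns = ps)
})

# Center + unit-normalize columns so Pearson r becomes a dot product
# (independent re-implementation of the package's internal normalization).
tsp_matrix_for_tests <- function(x) {
  x <- as.matrix(x)
  x <- sweep(x, 2, colMeans(x))
  sweep(x, 2, sqrt(colSums(x^2)), `/`)
}

# Brute-force adjusted Rand index from the contingency table.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ind <- si * sj / n2
  (sij - exp_ind) / ((si + sj) / 2 - exp_ind)
}

# Map each centroid to its best-matching pattern (signed correlation).
match_centroids <- function(centroids, patterns) {
  g <- crossprod(tsp_matrix_for_tests(patterns), tsp_matrix_for_tests(centroids))
  list(pattern = apply(g, 2, which.max), r = apply(g, 2, max), gram = g)
}

# Count recovered anti-correlated pattern pairs from a paired cluster model:
# a cluster counts when its two centroids match the two distinct members of
# one designed pair, each at r >= r_min.
count_recovered_pairs <- function(model, pattern_set, r_min = 0.9) {
  m <- match_centroids(model$centroids, pattern_set$patterns)
  ok <- 0L
  for (cl in unique(model$pairing$cluster)) {
    scs <- model$pairing$sub_cluster[model$pairing$cluster == cl]
    pa <- m$pattern[scs]
    if (length(unique(pa)) == 2L &&
        pattern_set$pairing$pair[pa[1]] == pattern_set$pairing$pair[pa[2]] &&
        all(m$r[scs] >= r_min)) ok <- ok + 1L
  }
  ok
}
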