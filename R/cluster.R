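# Center and unit-normalize TSP columns so Pearson correlation between
# patterns becomes a plain dot product. Accepts a ts_events object or a
# ROI x n matrix.
tsp_matrix <- function(tsps) {
  x <- if (inherits(tsps, "ts_events")) tsps$tsp else as.matrix(tsps)
  x <- sweep(x, 2L, colMeans(x))
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0)) stop("constant TSP vector has no correlation structure")
  sweep(x, 2L, nrm, `/`)
}

#' k-means clustering of TSPs under correlation distance
#'
#' Clusters temporal synchronization patterns with k-means where the
#' distance between two patterns is `1 - r` (Pearson). Because patterns
#' are centered and unit-normalized this is spherical k-means: assignment
#' maximizes the dot product with the centroid, and the centroid update is
#' the member mean re-centered and renormalized. The algorithm restarts
#' `n_init` times from random event subsets and keeps the solution with the
#' minimum total distance of patterns to their assigned centroids.
#'
#' @param tsps a `ts_events` object or ROI x n matrix of TSPs.
#' @param k number of sub-clusters (default 12).
#' @param n_init random restarts (default 100).
#' @param seed integer seed controlling the whole restart sequence.
#' @param max_iter iteration cap per restart.
#' @return object of class `tsp_kmeans`: `centroids` (ROI x k, unit
#'   mean-zero columns), `labels` (per event), `inertia` (summed `1 - r`
#'   to assigned centroids), `sizes`, `k`, `seed`, and `pairing` (filled by
#'   [pair_subclusters()]).
#' @export
fit_kmeans_corr <- function(tsps, k = 12L, n_init = 100L, seed = 1L, max_iter = 100L) {
  x <- tsp_matrix(tsps)
  n <- ncol(x)
  if (k < 1L) stop("fit_kmeans_corr: k must be at least 1")
  if (n < k) stop(sprintf("fit_kmeans_corr: %d events cannot support k = %d", n, k))
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      cen <- x[, sample.int(n, k), drop = FALSE]
      labels <- integer(n)
      for (iter in seq_len(max_iter)) {
        sim <- crossprod(cen, x)                    # k x n correlations
        new_labels <- max.col(t(sim), ties.method = "first")
        # re-seed empty clusters from the point farthest from its centroid
        for (cl in which(tabulate(new_labels, k) == 0L)) {
          far <- which.min(sim[cbind(new_labels, seq_len(n))])
          cen[, cl] <- x[, far]
          new_labels[far] <- cl
        }
        if (identical(new_labels, labels)) break
        labels <- new_labels
        for (cl in seq_len(k)) {
          v <- rowMeans(x[, labels == cl, drop = FALSE])
          v <- v - mean(v)
          nv <- sqrt(sum(v^2))
          if (nv > 0) cen[, cl] <- v / nv
        }
      }
      sim <- crossprod(cen, x)
      inertia <- sum(1 - sim[cbind(labels, seq_len(n))])
      if (is.null(best) || inertia < best$inertia)
        best <- list(cen = cen, labels = labels, inertia = inertia)
    }
  })
  structure(list(centroids = best$cen, labels = best$labels, inertia = best$inertia,
                 sizes = tabulate(best$labels, k), k = as.integer(k),
                 seed = as.integer(seed), pairing = NULL),
            class = "tsp_kmeans")
}

#' @export
print.tsp_kmeans <- function(x, ...) {
  cat(sprintf("<tsp_kmeans> k = %d sub-clusters over %d events; inertia %.2f\n",
              x$k, length(x$labels), x$inertia))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (!is.null(x$pairing))
    cat(sprintf("  paired into %d clusters\n", length(unique(x$pairing$cluster))))
  invisible(x)
}

#' @export
coef.tsp_kmeans <- function(object, ...) object$centroids

#' Assign new TSPs to the nearest sub-cluster centroid
#'
#' @param object a [fit_kmeans_corr()] model.
#' @param newdata `ts_events` or ROI x n matrix of TSPs.
#' @param ... unused.
#' @return integer vector of sub-cluster labels.
#' @export
predict.tsp_kmeans <- function(object, newdata, ...) {
  x <- tsp_matrix(newdata)
  max.col(t(crossprod(object$centroids, x)), ties.method = "first")
}

#' Event-sequence transition counts
#'
#' Counts consecutive sub-cluster transitions within runs; sequences from
#' different runs are never concatenated, so run boundaries contribute no
#' transitions.
#'
#' @param labels time-ordered sub-cluster labels.
#' @param k number of sub-clusters.
#' @param runs optional run identifier per event (same order as `labels`).
#' @return k x k count matrix; entry (a, b) counts a -> b transitions.
#' @export
transition_matrix <- function(labels, k = max(labels), runs = NULL) {
  if (length(labels) < 2L && is.null(runs))
    stop("transition_matrix: need at least 2 events")
  tm <- matrix(0L, k, k)
  if (is.null(runs)) runs <- rep(1L, length(labels))
  for (r in unique(runs)) {
    l <- labels[runs == r]
    if (length(l) < 2L) next
    for (i in seq_len(length(l) - 1L)) tm[l[i], l[i + 1L]] <- tm[l[i], l[i + 1L]] + 1L
  }
  tm
}

#' Pair sub-clusters into clusters via mutual transitions
#'
#' Sub-clusters that frequently transition into each other and whose
#' centroids are anti-correlated form a cluster. Pairs are selected by
#' greedy maximum-weight matching on the symmetrized transition counts,
#' accepting a pair only if its centroid correlation is negative; sub-
#' clusters left over once no anti-correlated partner remains are paired
#' with their most anti-correlated available partner, with a warning.
#'
#' @param model a [fit_kmeans_corr()] result (`k` even).
#' @param transitions k x k transition count matrix ([transition_matrix()]).
#' @return the model with `pairing` filled in: data.frame `sub_cluster`,
#'   `cluster`, `partner`, `centroid_r` (within-pair centroid correlation).
#' @export
pair_subclusters <- function(model, transitions) {
  stopifnot(inherits(model, "tsp_kmeans"))
  k <- model$k
  if (k %% 2L != 0L) stop("pair_subclusters: k must be even to pair sub-clusters")
  cc <- crossprod(model$centroids)
  sym <- transitions + t(transitions)
  avail <- rep(TRUE, k)
  pairs <- list()
  fallback <- FALSE
  while (sum(avail) > 1L) {
    idx <- which(avail)
    w <- sym[idx, idx, drop = FALSE]
    r <- cc[idx, idx, drop = FALSE]
    cand <- which(upper.tri(w) & r < 0, arr.ind = TRUE)
    if (nrow(cand)) {
      best <- cand[which.max(w[cand]), ]
      a <- idx[best[1L]]; b <- idx[best[2L]]
    } else {
      fallback <- TRUE
      cand <- which(upper.tri(r), arr.ind = TRUE)
      best <- cand[which.min(r[cand]), ]
      a <- idx[best[1L]]; b <- idx[best[2L]]
    }
    pairs[[length(pairs) + 1L]] <- c(a, b)
    avail[c(a, b)] <- FALSE
  }
  if (fallback)
    warning("pair_subclusters: some sub-clusters had no anti-correlated partner; ",
            "fell back to the most anti-correlated available pairing")
  pairing <- data.frame(sub_cluster = integer(0), cluster = integer(0),
                        partner = integer(0), centroid_r = numeric(0))
  for (ci in seq_along(pairs)) {
    p <- pairs[[ci]]
    pairing <- rbind(pairing,
                     data.frame(sub_cluster = p, cluster = ci, partner = rev(p),
                                centroid_r = cc[p[1L], p[2L]]))
  }
  pairing <- pairing[order(pairing$sub_cluster), ]
  rownames(pairing) <- NULL
  model$pairing <- pairing
  model
}

# Zero-padded boxcar moving average of width w (centered; for even w the
# extra tap is forward). Identical to convolution with rep(1/w, w).
boxcar_smooth <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  pad <- c(numeric(w), x, numeric(w))
  sm <- stats::filter(pad, rep(1 / w, w), sides = 2L)
  as.numeric(sm[(w + 1L):(w + n)])
}

#' Cluster occurrence timecourses
#'
#' Converts labeled events into per-cluster occurrence probabilities over
#' time. Per run, the indicator of each cluster's occurrence at each frame
#' (the mean of its sub-cluster indicators) is smoothed with a boxcar moving
#' average (width 50 frames by default); across runs the smoothed
#' indicators are averaged into an occurrence rate, and at frames where any
#' synchronization occurred the rates are normalized across clusters into
#' conditional probabilities summing to 1.
#'
#' @param events data.frame with 0-based `frame`, integer `sub_cluster` and
#'   a `run` identifier.
#' @param n_frames common frame count of the runs.
#' @param smooth_w moving-average width in frames (default 50).
#' @param pairing optional data.frame mapping `sub_cluster` to `cluster`
#'   (e.g. from [pair_subclusters()]); by default each sub-cluster is its
#'   own cluster.
#' @return object of class `occ_tc`: `prob` (cluster x frame conditional
#'   probabilities), `rate` (cluster x frame smoothed occurrence rate),
#'   `by_run` (list of per-run smoothed cluster x frame matrices),
#'   `clusters`, `smooth_w`, `n_frames`.
#' @export
occurrence_timecourse <- function(events, n_frames, smooth_w = 50L, pairing = NULL) {
  if (nrow(events) == 0L) warning("occurrence_timecourse: no events; all-zero timecourse")
  if (is.null(events$run)) events$run <- 1L
  if (is.null(pairing)) {
    subs <- sort(unique(events$sub_cluster))
    pairing <- data.frame(sub_cluster = subs, cluster = seq_along(subs))
  }
  clusters <- sort(unique(pairing$cluster))
  runs <- unique(events$run)
  if (length(runs) == 0L) runs <- 1L
  by_run <- lapply(runs, function(r) {
    ev <- events[events$run == r, , drop = FALSE]
    m <- matrix(0, length(clusters), n_frames)
    for (ci in seq_along(clusters)) {
      subs <- pairing$sub_cluster[pairing$cluster == clusters[ci]]
      ind <- numeric(n_frames)
      for (sc in subs) {
        f <- ev$frame[ev$sub_cluster == sc]
        one <- numeric(n_frames)
        one[f + 1L] <- 1
        ind <- ind + one / length(subs)            # sub-cluster probabilities averaged
      }
      m[ci, ] <- boxcar_smooth(ind, smooth_w)
    }
    m
  })
  names(by_run) <- as.character(runs)
  rate <- Reduce(`+`, by_run) / length(by_run)
  any_occ <- colSums(rate)
  prob <- sweep(rate, 2L, ifelse(any_occ > 0, any_occ, 1), `/`)
  prob[, any_occ <= 0] <- 0
  structure(list(prob = prob, rate = rate, by_run = by_run, clusters = clusters,
                 smooth_w = as.integer(smooth_w), n_frames = as.integer(n_frames)),
            class = "occ_tc")
}

#' k-nearest-neighbor classification of TSPs with a random-pattern null
#'
#' Assigns each query pattern the majority label among its `knn_k` most
#' correlated training TSPs; the classification score is the mean
#' correlation to the neighbors carrying the winning label. Scores are
#' thresholded against random unit patterns: `n_random` uniformly random
#' unit vectors are classified the same way and the `null_quantile` of
#' their scores (the 5th percentile by default) is the floor; queries
#' scoring below it are labeled 0 ("none") with score 0. By construction a
#' random query falls below this floor with probability `null_quantile`,
#' so the default is a lenient junk filter; set `null_quantile = 0.95` for
#' a gate that rejects 95 percent of random patterns.
#'
#' @param query_tsps `ts_events` or ROI x n matrix of query patterns.
#' @param train_tsps training patterns (same ROI space).
#' @param train_labels sub-cluster labels of the training patterns.
#' @param knn_k neighbors (default 100; must not exceed the training size).
#' @param n_random random patterns for the null score distribution.
#' @param null_quantile quantile of the null score distribution used as the
#'   rejection threshold (default 0.05).
#' @param seed integer seed for the random patterns.
#' @return data.frame with `label` (0 = none) and `score` per query, with
#'   the null threshold as attribute `"threshold"`.
#' @export
knn_classify <- function(query_tsps, train_tsps, train_labels, knn_k = 100L,
                         n_random = 10000L, null_quantile = 0.05, seed = 1L) {
  q <- tsp_matrix(query_tsps)
  tr <- tsp_matrix(train_tsps)
  if (knn_k > ncol(tr))
    stop(sprintf("knn_classify: knn_k = %d exceeds training size %d", knn_k, ncol(tr)))
  score_one <- function(v) {
    sim <- as.vector(crossprod(tr, v))
    nb <- order(sim, decreasing = TRUE)[seq_len(knn_k)]
    votes <- table(factor(train_labels[nb], levels = sort(unique(train_labels))))
    win <- as.integer(names(votes)[which.max(votes)])   # ties: smallest label
    c(win, mean(sim[nb[train_labels[nb] == win]]))
  }
  res <- apply(q, 2L, score_one)
  null_scores <- with_seed(seed, {
    rnd <- matrix(stats::rnorm(nrow(tr) * n_random), nrow(tr), n_random)
    apply(tsp_matrix(rnd), 2L, function(v) score_one(v)[2L])
  })
  thr <- stats::quantile(null_scores, null_quantile, names = FALSE)
  label <- as.integer(res[1L, ])
  score <- res[2L, ]
  below <- score < thr
  label[below] <- 0L
  score[below] <- 0
  structure(data.frame(label = label, score = score), threshold = thr)
}
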