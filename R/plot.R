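#' Plot the explained-variance timecourse of a sliding-window PCA
#'
#' Draws the fraction of variance explained by the first PC per window, with
#' detected synchronization events marked if supplied.
#'
#' @param x an [swpca()] result.
#' @param events optional `ts_events` from [detect_ts()] on the same scan.
#' @param ... passed to [graphics::plot()].
#' @export
plot.swpca <- function(x, events = NULL, ...) {
  graphics::plot(x$centers, x$var, type = "l", xlab = "frame (acquisition)",
                 ylab = "explained variance (1st PC)", ...)
  if (!is.null(events) && nrow(events$events)) {
    graphics::points(events$events$center, events$events$explained_variance,
                     col = "red", pch = 16, cex = 0.7)
  }
  invisible(x)
}

#' Plot TSP cluster centroids as an ROI-by-cluster image
#'
#' @param x a [fit_kmeans_corr()] model.
#' @param ... passed to [graphics::image()].
#' @export
plot.tsp_kmeans <- function(x, ...) {
  k <- x$k
  ord <- if (!is.null(x$pairing)) order(x$pairing$cluster, x$pairing$sub_cluster) else seq_len(k)
  z <- x$centroids[, ord, drop = FALSE]
  graphics::image(seq_len(nrow(z)), seq_len(k), z, xlab = "ROI",
                  ylab = "sub-cluster (pair-ordered)",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}

#' Plot cluster occurrence probabilities over the scan
#'
#' @param x an [occurrence_timecourse()] result.
#' @param which `"prob"` (conditional, default) or `"rate"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.occ_tc <- function(x, which = c("prob", "rate"), ...) {
  which <- match.arg(which)
  graphics::matplot(t(x[[which]]), type = "l", lty = 1, xlab = "frame",
                    ylab = sprintf("occurrence %s", which), ...)
  graphics::legend("topright", legend = paste("cluster", x$clusters),
                   col = seq_along(x$clusters), lty = 1, cex = 0.7)
  invisible(x)
}
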