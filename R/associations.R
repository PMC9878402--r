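#' Static resting-state functional connectivity vector
#'
#' Pairwise Pearson correlations between network timecourses over the full
#' (post-trim) run: m networks give `m (m - 1) / 2` values (13 networks
#' give 78). Zero-variance timecourses produce NA for all their pairs and
#' are reported via the `"flagged"` attribute.
#'
#' @param network_ts network x frame matrix (rownames used as labels).
#' @return named numeric vector of upper-triangle correlations
#'   (`"a:b"` names), attribute `"flagged"` listing degenerate networks.
#' @export
static_rsfc <- function(network_ts) {
  m <- as.matrix(network_ts)
  if (nrow(m) < 2L) stop("static_rsfc: need at least 2 networks")
  if (ncol(m) < 3L) stop("static_rsfc: need at least 3 frames")
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("net", seq_len(nrow(m)))
  sds <- apply(m, 1L, stats::sd)
  flagged <- labs[sds == 0]
  r <- suppressWarnings(stats::cor(t(m)))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  out <- r[upper.tri(r)]
  names(out) <- paste(labs[ut[, 1L]], labs[ut[, 2L]], sep = ":")
  attr(out, "flagged") <- flagged
  out
}

#' Predict RSFC strength from cluster occurrence features
#'
#' Per network pair, an OLS regression of across-subject connectivity
#' strength on the cluster features (occurrence frequencies or map betas)
#' plus an intercept, reporting R-squared. A single-feature variant (one
#' regression per cluster feature) is returned alongside.
#'
#' @param rsfc_by_subject subject x pair matrix of connectivity strengths.
#' @param predictors subject x feature matrix (full column rank).
#' @return list with `r2` (per pair, all features jointly) and `r2_single`
#'   (pair x feature matrix of single-feature R-squared).
#' @export
regress_rsfc <- function(rsfc_by_subject, predictors) {
  y <- as.matrix(rsfc_by_subject)
  x <- as.matrix(predictors)
  if (nrow(y) != nrow(x)) stop("regress_rsfc: subject counts differ")
  if (nrow(x) <= ncol(x) + 1L)
    stop("regress_rsfc: need more subjects than predictors + 1")
  X <- cbind(1, x)
  if (qr(X)$rank < ncol(X))
    stop("regress_rsfc: predictor matrix is rank deficient")
  r2_of <- function(Xm, yy) {
    fit <- stats::lm.fit(Xm, yy)
    1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
  }
  r2 <- apply(y, 2L, function(yy) r2_of(X, yy))
  r2_single <- sapply(seq_len(ncol(x)), function(j)
    apply(y, 2L, function(yy) r2_of(cbind(1, x[, j]), yy)))
  colnames(r2_single) <- colnames(x)
  list(r2 = r2, r2_single = r2_single)
}

#' Subject-matched map consistency as Hedges' g
#'
#' Quantifies whether a subject's synchronization map resembles that same
#' subject's task map more than other subjects' maps. Both map sets are
#' demeaned by their cross-subject mean map (removing the shared group
#' topography); the matched distribution holds same-subject spatial
#' correlations, the null all cross-subject correlations, and the effect is
#' their standardized difference with the small-sample correction.
#'
#' @param subject_saps subject x space matrix of synchronization maps.
#' @param subject_taskmaps subject x space matrix of task activation maps.
#' @return list with `g` (Hedges' g), `matched` and `null` correlation
#'   vectors.
#' @export
map_similarity_g <- function(subject_saps, subject_taskmaps) {
  a <- as.matrix(subject_saps)
  b <- as.matrix(subject_taskmaps)
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b))
    stop("map_similarity_g: map sets must share subjects and space")
  n <- nrow(a)
  if (n < 2L) stop("map_similarity_g: need at least 2 subjects")
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  r <- stats::cor(t(a), t(b))                 # r[i, j] = cor(sap_i, task_j)
  matched <- diag(r)
  null <- r[row(r) != col(r)]
  list(g = hedges_g(matched, null), matched = matched, null = null)
}

hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  j <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  j * (mean(x) - mean(y)) / sp
}

#' Rank-based inverse Gaussian (Van der Waerden) transform
#'
#' Maps values to standard-normal quantiles at `rank / (n + 1)` (mean ranks
#' for ties), removing the influence of outliers while preserving order.
#'
#' @param values numeric vector (`>= 3` values, not all identical).
#' @return transformed vector, same length and order.
#' @export
inverse_gaussian_transform <- function(values) {
  if (length(values) < 3L) stop("inverse_gaussian_transform: need at least 3 values")
  if (length(unique(values)) == 1L)
    stop("inverse_gaussian_transform: all values identical; no rank information")
  r <- rank(values, ties.method = "average")
  stats::qnorm(r / (length(values) + 1))
}

#' Regress confounds out of subject measures
#'
#' Per variable, OLS on the confounds plus an intercept; returns the
#' residuals, which are orthogonal to every confound column.
#'
#' @param values subject x variable matrix.
#' @param confounds subject x confound matrix (full column rank).
#' @return residual matrix, same shape as `values`.
#' @export
deconfound <- function(values, confounds) {
  y <- as.matrix(values)
  x <- as.matrix(confounds)
  if (nrow(y) != nrow(x)) stop("deconfound: subject counts differ")
  if (nrow(x) <= ncol(x) + 1L) stop("deconfound: need more subjects than confounds + 1")
  X <- cbind(1, x)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("deconfound: confound matrix is rank deficient")
  y - X %*% qr.coef(qx, y)
}

#' PCA-reduced canonical correlation of maps against subject measures
#'
#' The brain-behavior association pipeline: the image side (subject x pixel
#' maps) is rank-based inverse-Gaussian transformed per pixel, the subject
#' measures are deconfounded and standardized, both sides are PCA-reduced
#' to `n_pcs` components, and canonical correlation analysis links them. Significance
#' per mode is assessed by permuting subjects on the measure side; the null
#' is the per-permutation maximum canonical correlation across modes, so
#' p-values are family-wise-error corrected. Reported weights are the
#' correlations of the original variables with the canonical variates.
#'
#' @param images subject x pixel matrix.
#' @param sms subject x measure matrix.
#' @param confounds optional subject x confound matrix applied to `sms`.
#' @param n_pcs PCA dimensions per side (default 50; `< subjects`).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @return object of class `cca_result`: `cors` (canonical correlations,
#'   non-increasing), `p_fwe`, `image_weights` (pixel x mode),
#'   `sm_weights` (measure x mode), `n_pcs`, `n_perm`, `seed`.
#' @export
cca_pipeline <- function(images, sms, confounds = NULL, n_pcs = 50L,
                         n_perm = 10000L, seed = 1L) {
  img <- as.matrix(images)
  sm <- as.matrix(sms)
  n <- nrow(img)
  if (nrow(sm) != n) stop("cca_pipeline: subject counts differ")
  if (n_pcs >= n) stop("cca_pipeline: n_pcs must be smaller than the subject count")
  const <- apply(img, 2L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning("cca_pipeline: dropping ", sum(const), " constant image columns")
    img <- img[, !const, drop = FALSE]
  }
  img_t <- apply(img, 2L, inverse_gaussian_transform)
  sm_d <- if (is.null(confounds)) scale(sm, scale = FALSE) else deconfound(sm, confounds)
  sm_sd <- apply(sm_d, 2L, stats::sd)
  if (any(sm_sd == 0)) {
    warning("cca_pipeline: dropping ", sum(sm_sd == 0), " constant measure columns")
    sm_d <- sm_d[, sm_sd > 0, drop = FALSE]
    sm_sd <- sm_sd[sm_sd > 0]
  }
  sm_d <- scale(sm_d, center = TRUE, scale = sm_sd)   # unit-variance measures
  kx <- min(n_pcs, ncol(img_t), n - 1L)
  ky <- min(n_pcs, ncol(sm_d), n - 1L)
  px <- stats::prcomp(img_t, rank. = kx)$x
  py <- stats::prcomp(sm_d, rank. = ky)$x
  cc <- stats::cancor(px, py)
  n_modes <- length(cc$cor)
  u <- scale(px, center = cc$xcenter, scale = FALSE) %*% cc$xcoef[, seq_len(n_modes), drop = FALSE]
  v <- scale(py, center = cc$ycenter, scale = FALSE) %*% cc$ycoef[, seq_len(n_modes), drop = FALSE]
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    max(stats::cancor(px, py[sample.int(n), , drop = FALSE])$cor)
  }, 0))
  p_fwe <- vapply(cc$cor, function(r) (1 + sum(null_max >= r)) / (1 + n_perm), 0)
  structure(list(cors = cc$cor, p_fwe = p_fwe,
                 image_weights = stats::cor(img_t, u),
                 sm_weights = stats::cor(sm_d, v),
                 n_pcs = c(image = kx, sm = ky), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> %d modes (PCA dims %d x %d), %d permutations\n",
              length(x$cors), x$n_pcs[1L], x$n_pcs[2L], x$n_perm))
  k <- min(5L, length(x$cors))
  for (i in seq_len(k))
    cat(sprintf("  mode %d: r = %.3f, p_fwe = %.4g\n", i, x$cors[i], x$p_fwe[i]))
  invisible(x)
}
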