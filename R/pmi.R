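#' Pointwise mutual information surface of cluster co-occurrence
#'
#' For an ordered cluster pair (a, b), PMI(t, tau) quantifies in bits how
#' much an occurrence of cluster a at frame t raises the probability of
#' cluster b at frame t + tau:
#' `PMI = log2( Pr(Y_b = 1 at t + tau | X_a = 1 at t) / Pr(Y_b = 1 at t + tau) )`.
#' Probabilities are estimated across runs from the smoothed per-run
#' occurrence indicators of [occurrence_timecourse()] (the smoothing keeps
#' the conditioning probability away from zero), and both t and t + tau are
#' restricted to frames at which a synchronization of any cluster occurred.
#' Cells whose conditioning or marginal probability falls below `floor`, or
#' whose joint probability is zero, are masked rather than imputed.
#'
#' The `"literal"` form replaces the ratio by the product
#' `Pr(Y | X) * Pr(X)` and is provided only for comparison.
#'
#' @param occ an [occurrence_timecourse()] result (smoothed; width 50 by
#'   convention).
#' @param pair length-2 vector: ordered (a, b) cluster ids.
#' @param tau_max largest lag in frames (`< n_frames`).
#' @param floor probability floor below which cells are masked.
#' @param form `"ratio"` (standard PMI, default) or `"literal"`.
#' @return object of class `pmi_surface`: `pmi` (t x tau matrix, bits, NA
#'   where masked), `valid` (logical mask), `t` (0-based frames), `tau`
#'   (1..tau_max), `pair`.
#' @export
pmi_surface <- function(occ, pair, tau_max, floor = 1e-6,
                        form = c("ratio", "literal")) {
  stopifnot(inherits(occ, "occ_tc"))
  form <- match.arg(form)
  n <- occ$n_frames
  if (tau_max >= n) stop("pmi_surface: tau_max must be smaller than the run length")
  ai <- match(pair[1L], occ$clusters)
  bi <- match(pair[2L], occ$clusters)
  if (is.na(ai) || is.na(bi)) stop("pmi_surface: unknown cluster id in pair")
  nr <- length(occ$by_run)
  X <- do.call(rbind, lapply(occ$by_run, function(m) m[ai, ]))   # runs x frames
  Y <- do.call(rbind, lapply(occ$by_run, function(m) m[bi, ]))
  px <- colMeans(X)
  py <- colMeans(Y)
  any_occ <- colSums(occ$rate) > 0
  pmi <- matrix(NA_real_, n, tau_max)
  valid <- matrix(FALSE, n, tau_max)
  for (tau in seq_len(tau_max)) {
    tt <- seq_len(n - tau)
    pxy <- colMeans(X[, tt, drop = FALSE] * Y[, tt + tau, drop = FALSE])
    ok <- px[tt] >= floor & py[tt + tau] >= floor & pxy > 0 &
      any_occ[tt] & any_occ[tt + tau]
    v <- if (form == "ratio") log2(pxy / (px[tt] * py[tt + tau])) else log2(pxy)
    v[!ok] <- NA_real_
    pmi[tt, tau] <- v
    valid[tt, tau] <- ok
  }
  structure(list(pmi = pmi, valid = valid, t = 0:(n - 1L), tau = seq_len(tau_max),
                 pair = pair, floor = floor, form = form, n_runs = nr),
            class = "pmi_surface")
}

#' Decompose a PMI surface into lag, time, and zero-lag effects
#'
#' Multiple linear regression of the valid PMI cells on scan time t, lag
#' tau, and a constant, after discarding the first and last `t_trim` frames
#' (100 by convention) and lags `tau <= tau_min` (100 by convention, to
#' avoid the autocorrelation-dominated short lags). The time coefficient
#' captures monotonic drift of co-occurrence over the run, the lag
#' coefficient its dependence on the interval between the two events, and
#' the constant the zero-lag association.
#'
#' @param surface a [pmi_surface()].
#' @param t_trim frames excluded at each end of the scan (default 100).
#' @param tau_min smallest lag retained, exclusive (default 100).
#' @return named numeric vector `c(const, time, lag)` (bits, bits/frame,
#'   bits/frame) with attribute `"n_cells"`.
#' @export
decompose_pmi <- function(surface, t_trim = 100L, tau_min = 100L) {
  stopifnot(inherits(surface, "pmi_surface"))
  n <- length(surface$t)
  tmax <- surface$t[n]
  sel_t <- surface$t >= t_trim & surface$t <= tmax - t_trim
  sel_tau <- surface$tau > tau_min
  cells <- which(surface$valid & outer(sel_t, sel_tau), arr.ind = TRUE)
  if (nrow(cells) < 9L)
    stop(sprintf("decompose_pmi: only %d valid cells in the fitting region (need >= 9)",
                 nrow(cells)))
  y <- surface$pmi[cells]
  tt <- surface$t[cells[, 1L]]
  tau <- surface$tau[cells[, 2L]]
  fit <- stats::lm.fit(cbind(const = 1, time = tt, lag = tau), y)
  out <- fit$coefficients
  names(out) <- c("const", "time", "lag")
  attr(out, "n_cells") <- nrow(cells)
  out
}

#' Decompose PMI for every ordered cluster pair
#'
#' @param occ an [occurrence_timecourse()] result.
#' @param tau_max largest lag in frames.
#' @param include_self include (a, a) pairs (default FALSE).
#' @inheritParams decompose_pmi
#' @inheritParams pmi_surface
#' @return matrix (ordered pairs x 3) with columns `const`, `time`, `lag`
#'   and rownames `"a>b"`.
#' @export
pmi_decompose_all <- function(occ, tau_max, t_trim = 100L, tau_min = 100L,
                              floor = 1e-6, include_self = FALSE) {
  cl <- occ$clusters
  prs <- expand.grid(a = cl, b = cl)
  if (!include_self) prs <- prs[prs$a != prs$b, ]
  if (nrow(prs) == 0L) {
    warning("pmi_decompose_all: fewer than 2 clusters; nothing to decompose")
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("const", "time", "lag"))))
  }
  out <- t(apply(prs, 1L, function(p) {
    s <- pmi_surface(occ, c(p[["a"]], p[["b"]]), tau_max, floor = floor)
    decompose_pmi(s, t_trim = t_trim, tau_min = tau_min)
  }))
  rownames(out) <- paste0(prs$a, ">", prs$b)
  colnames(out) <- c("const", "time", "lag")
  out
}

#' Permutation-style FWE p-values for PMI coefficients
#'
#' For each coefficient type (constant, time, lag) the null distribution is
#' the per-surrogate maximum of |coefficient| across all cluster pairs, so
#' the resulting p-values are family-wise-error corrected over pairs. The
#' permutation convention `p = (1 + #\{null >= observed\}) / (1 + S)` gives a
#' floor of `1/(S+1)` when the observed value exceeds every surrogate.
#'
#' @param real coefficient matrix from [pmi_decompose_all()] on the real
#'   data (pairs x 3).
#' @param null_coefs list of such matrices, one per surrogate dataset
#'   (>= 100 recommended for alpha = 0.05).
#' @return matrix of FWE-corrected p-values, same shape as `real`.
#' @export
pmi_significance <- function(real, null_coefs) {
  if (length(null_coefs) < 100L)
    warning(sprintf("pmi_significance: only %d surrogates; p-value resolution is %.3g",
                    length(null_coefs), 1 / (length(null_coefs) + 1)))
  s <- length(null_coefs)
  p <- real
  for (j in seq_len(ncol(real))) {
    null_max <- vapply(null_coefs, function(m) max(abs(m[, j])), 0)
    p[, j] <- vapply(abs(real[, j]), function(v) (1 + sum(null_max >= v)) / (1 + s), 0)
  }
  p
}
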