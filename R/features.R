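## Feature engineering: map a (candidate controller set, flux) pair of
## series to a fixed-length numeric vector. Two principles drive the set:
## (i) a flux is expected to be highly rank-correlated with its
## controllers, and (ii) if a metabolite set completely defines a flux,
## each input state can map to only one flux value (functional
## uniqueness). All inputs are rank- or min-max-normalized first, so every
## feature is invariant to positive affine rescaling of any series.

## deterministic thinning of long (pooled) series: evenly spaced indices
thin_index <- function(n, max_points) {
  if (n <= max_points) seq_len(n) else round(seq(1, n, length.out = max_points))
}

minmax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

## Squared Euclidean distances between the rows of X (n x n), via
## tcrossprod; order-equivalent to Euclidean distance, and monotone maps
## keep medians consistent, so neighbour searches and median thresholds
## can work on squared distances throughout.
sqdist <- function(X) {
  X <- as.matrix(X)
  s <- rowSums(X * X)
  d <- outer(s, s, "+") - 2 * tcrossprod(X)
  d[d < 0] <- 0
  d
}

## k-NN regression predictions from a precomputed square distance matrix
## with excluded entries set to Inf; finds the k nearest via repeated
## max.col (C-level, no per-row sort).
knn_predict_dist <- function(d, v, k = 3L) {
  n <- nrow(d)
  k <- min(k, ncol(d) - 1L)
  acc <- numeric(n)
  rows <- seq_len(n)
  for (i in seq_len(k)) {
    j <- max.col(-d, ties.method = "first")
    acc <- acc + v[j]
    d[cbind(rows, j)] <- Inf
  }
  acc / k
}

## Leave-one-out k-NN predictions of v from the rows of X (normalized).
knn_loo <- function(X, v, k = 3L) {
  X <- as.matrix(X)
  if (ncol(X) == 1 && nrow(X) > 4 * (k + 1)) {
    return(knn_loo_1d(X[, 1], v, k))
  }
  d <- sqdist(X)
  diag(d) <- Inf
  knn_predict_dist(d, v, k)
}

## 1-D fast path: after sorting, the k nearest neighbours of a point lie
## within k + 1 positions on either side, so no n x n distance matrix is
## needed.
knn_loo_1d <- function(x, v, k = 3L) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  vs <- v[ord]
  w <- k + 1L
  cand <- outer(seq_len(n), c(-(w:1), 1:w), `+`)
  bad <- cand < 1 | cand > n
  cand[bad] <- 1L
  dmat <- abs(matrix(xs[cand], n, 2 * w) - xs)
  dmat[bad] <- Inf
  vmat <- matrix(vs[cand], n, 2 * w)
  rows <- seq_len(n)
  acc <- numeric(n)
  for (i in seq_len(k)) {
    j <- max.col(-dmat, ties.method = "first")
    acc <- acc + vmat[cbind(rows, j)]
    dmat[cbind(rows, j)] <- Inf
  }
  out <- numeric(n)
  out[ord] <- acc / k
  out
}

r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) return(0)
  1 - sum((obs - pred)^2) / sst
}

abs_spearman <- function(x, v) {
  if (stats::sd(x) == 0 || stats::sd(v) == 0) return(0)
  abs(stats::cor(x, v, method = "spearman"))
}

#' Functional-uniqueness score
#'
#' Quantifies how close a flux series is to being a single-valued function
#' of a set of concentration series. Each series in `X` is min-max
#' normalized; for each timepoint the nearest other timepoint in the
#' normalized input space is found, and among those nearest-neighbour
#' pairs closer than the median of all pairwise distances the mean flux
#' difference `|dv| / range(v)` is returned. Values near 0 mean nearby
#' input states always map to nearby flux values (consistent with `X`
#' completely defining `v`); large values flag multivalued relationships.
#'
#' @param X numeric matrix, one column per concentration series.
#' @param v flux series (same length as `nrow(X)`).
#' @return A scalar in \[0, 1\]; 0 (with a degeneracy attribute) when
#'   `v` is constant.
#' @export
uniqueness_score <- function(X, v) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(v))
  rv <- diff(range(v))
  if (rv <= 0) return(structure(0, degenerate = TRUE))
  Xn <- apply(X, 2, minmax)
  d <- sqdist(Xn)
  med <- stats::median(d[upper.tri(d)])
  diag(d) <- Inf
  nn <- max.col(-d, ties.method = "first")
  dn <- d[cbind(seq_along(nn), nn)]
  keep <- dn < med
  if (!any(keep)) keep <- rep(TRUE, length(nn))
  mean(abs(v - v[nn])[keep]) / rv
}

## lag-1 autocorrelation of the log-linear fit residuals, floored at 0.
## Measurement noise leaves iid residuals (autocorrelation near zero);
## a hidden smooth controller leaves temporally structured residuals.
## Numerically exact fits (noiseless true sets) return 0.
residual_autocorrelation <- function(X, v, floor = 1e-9) {
  lv <- log(pmax(v, floor))
  lx <- log(pmax(X, floor))
  r <- stats::lm.fit(cbind(1, lx), lv)$residuals
  if (stats::sd(r) < 1e-10) return(0)
  max(0, stats::cor(r[-1], r[-length(r)]))
}

## How much of the log-linear fit residual any other metabolite series
## explains: max over context columns of the simple-regression R^2 of
## residual ~ log(z). A hidden controller too weak for the omnibus
## autocorrelation statistic is still found by regressing the residuals
## on it directly; iid noise residuals are explained by nothing.
residual_explained <- function(X, v, context, floor = 1e-9) {
  lv <- log(pmax(v, floor))
  lx <- log(pmax(X, floor))
  r <- stats::lm.fit(cbind(1, lx), lv)$residuals
  if (stats::sd(r) < 1e-10) return(0)
  max(vapply(seq_len(ncol(context)), function(j) {
    lz <- log(pmax(context[, j], floor))
    if (stats::sd(lz) == 0) return(0)
    stats::cor(r, lz)^2
  }, numeric(1)))
}

#' Features for one-controller candidates
#'
#' Five scalar features for the hypothesis that flux `v` is fully
#' determined by the single concentration series `x`:
#' \describe{
#'   \item{f_spearman}{absolute Spearman rank correlation of `x` and
#'     `v`.}
#'   \item{f_loglin_r2}{R-squared of the log-linear regression of `v` on
#'     `x` — exact for a power law of `x` alone, degraded by any hidden
#'     controller.}
#'   \item{f_resid_ac}{lag-1 autocorrelation of that regression's
#'     residuals: measurement noise leaves white residuals, a hidden
#'     smooth controller leaves temporally structured ones.}
#'   \item{f_resid_explained}{maximum over the `context` series (the
#'     other metabolites of the system, when supplied) of the
#'     simple-regression R-squared of the residuals on that series' log —
#'     the targeted test that catches hidden controllers too weak for
#'     the omnibus autocorrelation; 0 when no context is given.}
#'   \item{f_knn_loo_r2}{leave-one-out R-squared of a 3-nearest-
#'     neighbour regression of `v` on `x`, floored at 0 (multivalued
#'     relationships predict poorly).}
#' }
#' Degenerate inputs (constant series) yield all-zero features with a
#' `degenerate` attribute rather than an error, so no candidate is
#' silently dropped.
#'
#' @param x concentration series (length >= 5).
#' @param v flux series on the same grid.
#' @param context optional matrix of other concentration series (one
#'   column per metabolite) used by `f_resid_explained`.
#' @return Named numeric vector of length 5.
#' @export
features_single <- function(x, v, context = NULL) {
  nm <- c("f_spearman", "f_loglin_r2", "f_resid_ac", "f_resid_explained",
          "f_knn_loo_r2")
  stopifnot(length(x) == length(v), length(x) >= 5)
  if (stats::sd(x) == 0 || diff(range(v)) <= 0) {
    return(structure(stats::setNames(numeric(5), nm), degenerate = TRUE))
  }
  xm <- matrix(x, ncol = 1)
  f1 <- abs(stats::cor(x, v, method = "spearman"))
  f2 <- loglinear_r2(xm, v)
  f3 <- residual_autocorrelation(xm, v)
  f4 <- if (is.null(context) || ncol(context) == 0) 0 else
    residual_explained(xm, v, as.matrix(context))
  xn <- minmax(x)
  pred <- knn_loo(matrix(xn, ncol = 1), v, k = 3)
  f5 <- max(0, r_squared(v, pred))
  stats::setNames(c(f1, f2, f3, f4, f5), nm)
}

## R-squared of the log-linear fit log(v) ~ log(X). Under power-law
## kinetics the flux of a true controller set is exactly log-linear in
## the controllers, so this probes the hypothesised functional form
## directly. Values are clamped at a small positive floor so occasional
## negative noisy measurements do not break the logarithm.
loglinear_r2 <- function(X, v, floor = 1e-9) {
  lv <- log(pmax(v, floor))
  lx <- log(pmax(X, floor))
  fit <- stats::lm.fit(cbind(1, lx), lv)
  r_squared(lv, lv - fit$residuals)
}

#' Features for two- and three-controller candidates
#'
#' Seven scalar features for the hypothesis that flux `v` is fully
#' determined by the `n` concentration series in the columns of `X`
#' (n = 2 or 3):
#' \describe{
#'   \item{g_uniqueness}{[uniqueness_score] of the full set (low for true
#'     controller sets).}
#'   \item{g_subset_gap}{minimum over maximal proper subsets of their
#'     uniqueness score minus the full-set score; positive when every
#'     member of the set is needed.}
#'   \item{g_loglin_lackfit}{log10 of (1 - R-squared) of the log-linear
#'     regression of `v` on `X`. Under power-law kinetics the flux of the
#'     true controller set is exactly log-linear, so the lack of fit
#'     collapses toward the numerical floor (-12); the log scale gives
#'     every learner resolution near the R-squared = 1 boundary.}
#'   \item{g_loglin_gain}{log10 of the R-squared improvement of the full
#'     set over its best maximal proper subset (floored at 1e-12).
#'     Near -12 for non-minimal sets whose extra member adds nothing;
#'     clearly higher when every member carries explanatory power, even
#'     when network-driven collinearity makes the raw improvement small.}
#'   \item{g_cor_min, g_cor_max}{minimum and maximum absolute Spearman
#'     correlation between each member and `v`.}
#'   \item{g_partial_min}{minimum over members of the absolute Spearman
#'     correlation between that member and the residuals of 3-NN
#'     regression of `v` on the remaining members; near 0 for decoy
#'     members that explain nothing beyond the rest.}
#' }
#' Degenerate inputs (constant flux or any constant member series) yield
#' all-zero features with a `degenerate` attribute.
#'
#' @param X matrix with `n` columns (concentration series), >= 8 rows.
#' @param v flux series.
#' @return Named numeric vector of length 7.
#' @export
features_multi <- function(X, v) {
  nm <- c("g_uniqueness", "g_subset_gap", "g_loglin_lackfit", "g_loglin_gain",
          "g_cor_min", "g_cor_max", "g_partial_min")
  X <- as.matrix(X)
  n <- ncol(X)
  stopifnot(n %in% 2:3, nrow(X) == length(v), nrow(X) >= 8)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (identical(X[, i], X[, j])) {
        stop(sprintf("duplicate series in candidate set (columns %d and %d)",
                     i, j), call. = FALSE)
      }
    }
  }
  if (diff(range(v)) <= 0 || any(apply(X, 2, stats::sd) == 0)) {
    return(structure(stats::setNames(numeric(7), nm), degenerate = TRUE))
  }
  Xn <- apply(X, 2, minmax)
  g1 <- as.numeric(uniqueness_score(Xn, v))
  # maximal proper subsets suffice: linear-model R-squared can only grow
  # with added regressors, and uniqueness can only shrink with added
  # coordinates, so size n-1 subsets dominate the subset comparisons
  subsets <- utils::combn(n, n - 1, simplify = FALSE)
  sub_uni <- vapply(subsets, function(s) {
    as.numeric(uniqueness_score(Xn[, s, drop = FALSE], v))
  }, numeric(1))
  g2 <- min(sub_uni) - g1
  r2_full <- loglinear_r2(X, v)
  sub_r2 <- vapply(subsets, function(s) {
    loglinear_r2(X[, s, drop = FALSE], v)
  }, numeric(1))
  # log scale: resolution near the exact-fit boundary is what separates
  # true sets from collinear near-misses and from non-minimal supersets
  g3 <- log10(max(0, 1 - r2_full) + 1e-12)
  g4 <- log10(max(0, r2_full - max(sub_r2)) + 1e-12)
  cors <- vapply(seq_len(n), function(j) abs_spearman(Xn[, j], v), numeric(1))
  g5 <- min(cors)
  g6 <- max(cors)
  part <- vapply(seq_len(n), function(j) {
    resid <- v - knn_loo(Xn[, -j, drop = FALSE], v, k = 3)
    if (stats::sd(resid) == 0) 0 else abs_spearman(Xn[, j], resid)
  }, numeric(1))
  g7 <- min(part)
  stats::setNames(c(g1, g2, g3, g4, g5, g6, g7), nm)
}

## Dispatch on candidate order; X is a matrix with one column per
## controller (order-1 candidates use the single-series feature set,
## with the other metabolites' series as context when available).
candidate_features <- function(X, v, context = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 1) features_single(X[, 1], v, context) else
    features_multi(X, v)
}

feature_names <- function(n) {
  if (n == 1) {
    c("f_spearman", "f_loglin_r2", "f_resid_ac", "f_resid_explained",
      "f_knn_loo_r2")
  } else {
    c("g_uniqueness", "g_subset_gap", "g_loglin_lackfit", "g_loglin_gain",
      "g_cor_min", "g_cor_max", "g_partial_min")
  }
}
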