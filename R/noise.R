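#' Subsample a time course to a coarser uniform grid
#'
#' Retains `nT` timepoints spanning the full interval including both
#' endpoints, snapping to the nearest source gridpoints. Emulates a lower
#' experimental sampling frequency.
#'
#' @param tc a [scour_timecourse] on a uniform grid.
#' @param nT number of retained timepoints (at least 2).
#' @return A [scour_timecourse] on the coarser grid.
#' @export
subsample_timecourse <- function(tc, nT) {
  n <- length(tc$times)
  if (nT < 2 || nT > n) {
    stop(sprintf("nT must be between 2 and %d", n), call. = FALSE)
  }
  idx <- round(seq(1, n, length.out = nT))
  scour_timecourse(tc$times[idx],
                   tc$conc[, idx, , drop = FALSE],
                   tc$flux[, idx, , drop = FALSE],
                   noise_applied = tc$noise_applied, collapsed = tc$collapsed)
}

#' Add multiplicative Gaussian measurement noise
#'
#' Replaces each concentration and flux value \eqn{y_i(t_k)} with
#' `replicates` independent draws from
#' \eqn{N(y_i(t_k), (CoV \cdot y_i(t_k))^2)}, mimicking replicate
#' mass-spectrometry measurements whose error scales with signal
#' intensity. Negative draws are retained as-is (downstream features must
#' tolerate them); with `cov = 0` all replicates equal the input.
#'
#' @param tc a noiseless single-replicate [scour_timecourse].
#' @param cov coefficient of variation (e.g. 0.05 or 0.15).
#' @param replicates number of replicates to generate (default 3).
#' @param seed optional integer seed.
#' @return A replicated [scour_timecourse] with `noise_applied = TRUE`.
#' @export
add_noise <- function(tc, cov, replicates = 3L, seed = NULL) {
  stopifnot(cov >= 0, replicates >= 1)
  if (tc$replicates != 1) {
    stop("add_noise expects a single-replicate (noiseless) time course",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  noisify <- function(arr) {
    out <- array(NA_real_, c(dim(arr)[1:2], replicates),
                 dimnames = dimnames(arr))
    base <- arr[, , 1]
    for (r in seq_len(replicates)) {
      out[, , r] <- base + stats::rnorm(length(base), 0, cov * abs(base))
    }
    out
  }
  scour_timecourse(tc$times, noisify(tc$conc), noisify(tc$flux),
                   noise_applied = cov > 0, collapsed = FALSE)
}

#' Collapse replicates by the per-timepoint median
#'
#' Preprocessing used before one-controller classification: each species
#' value is the median across replicates at that timepoint.
#'
#' @param tc a replicated [scour_timecourse].
#' @return A single-replicate [scour_timecourse] with `collapsed = TRUE`.
#' @export
median_collapse <- function(tc) {
  coll <- function(arr) {
    out <- apply(arr, c(1, 2), stats::median)
    dimnames(out) <- dimnames(arr)[1:2]
    out
  }
  scour_timecourse(tc$times, coll(tc$conc), coll(tc$flux),
                   noise_applied = tc$noise_applied, collapsed = TRUE)
}

## Discrete moving-Gaussian filter along a series. The kernel support
## spans `window_pts` gridpoints with SD = window_pts / 4; at the edges
## the kernel is renormalized over the available points.
gaussian_filter <- function(y, window_pts) {
  gaussian_filter_mat(matrix(y, ncol = 1), window_pts)[, 1]
}

## same filter applied down every column of a matrix at once
gaussian_filter_mat <- function(Y, window_pts) {
  n <- nrow(Y)
  if (window_pts <= 1 || n < 3) return(Y)
  h <- max(1L, floor(window_pts / 2))
  off <- (-h):h
  w <- stats::dnorm(off, sd = window_pts / 4)
  out <- Y
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1 & j <= n
    out[i, ] <- (w[ok] %*% Y[j[ok], , drop = FALSE]) / sum(w[ok])
  }
  out
}

#' Collapse replicates by averaging then Gaussian smoothing
#'
#' Preprocessing used before two- and three-controller classification:
#' replicates are combined per timepoint (mean by default, median via
#' `combine`), then each series is smoothed with a moving Gaussian filter
#' whose window spans `fraction` of the total simulation time (default a
#' quarter). The kernel SD is a quarter of the window so +/- 2 SD fits the
#' window; edges are handled by renormalizing the kernel over available
#' points rather than padding.
#'
#' @param tc a replicated [scour_timecourse].
#' @param fraction window width as a fraction of total time (default 1/4).
#' @param combine `"mean"` (default) or `"median"` replicate combination
#'   before smoothing.
#' @return A single-replicate smoothed [scour_timecourse].
#' @export
smooth_collapse <- function(tc, fraction = 0.25, combine = c("mean", "median")) {
  stopifnot(fraction > 0, fraction <= 1)
  combine <- match.arg(combine)
  n <- length(tc$times)
  window_pts <- ceiling(n * fraction)
  coll <- function(arr) {
    fn <- if (combine == "mean") mean else stats::median
    m <- apply(arr, c(1, 2), fn)
    out <- t(apply(m, 1, gaussian_filter, window_pts = window_pts))
    dimnames(out) <- dimnames(arr)[1:2]
    out
  }
  scour_timecourse(tc$times, coll(tc$conc), coll(tc$flux),
                   noise_applied = tc$noise_applied, collapsed = TRUE)
}
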