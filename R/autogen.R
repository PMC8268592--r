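#' Configuration for training-data autogeneration
#'
#' Training interactions are synthesized rather than measured: random
#' damped-sine concentration profiles drive power-law fluxes, giving
#' labelled positive/negative examples in any quantity. Defaults give 1-3
#' visible oscillation periods with decay over a 10-time-unit horizon,
#' mimicking transient metabolite dynamics.
#'
#' @param n_per_class examples per class per stacking level (default 400).
#' @param amplitude,decay,frequency_cycles,phase ranges (length-2 numeric)
#'   for the damped-sine amplitude A, decay rate lambda, number of full
#'   oscillation cycles over the horizon (converted to angular frequency),
#'   and phase.
#' @param offset_margin range for the baseline offset above the amplitude
#'   (C is drawn from A + offset_margin), keeping profiles strictly
#'   positive.
#' @param negative_modes probability weights for the negative-example
#'   constructions `mismatch`, `higher_order` and `superset` (see
#'   [generate_true_negative]); `superset` only applies to orders 2-3 and
#'   its weight is redistributed for order-1 sets.
#' @return A list of class `scour_autogen_config`.
#' @export
autogen_config <- function(n_per_class = 400L,
                           amplitude = c(0.1, 1),
                           decay = c(0, 0.5),
                           frequency_cycles = c(1, 3),
                           phase = c(0, 2 * pi),
                           offset_margin = c(0.1, 2),
                           negative_modes = c(mismatch = 1 / 3,
                                              higher_order = 1 / 3,
                                              superset = 1 / 3)) {
  stopifnot(n_per_class >= 1)
  structure(list(n_per_class = as.integer(n_per_class), amplitude = amplitude,
                 decay = decay, frequency_cycles = frequency_cycles,
                 phase = phase, offset_margin = offset_margin,
                 negative_modes = negative_modes),
            class = "scour_autogen_config")
}

#' Sample a damped-sine concentration profile
#'
#' Draws random parameters and evaluates
#' \eqn{x(t) = C + A e^{-\lambda t} \sin(\omega t + \phi)} on the given
#' grid. The offset C is always at least the amplitude plus a positive
#' margin, so every profile is strictly positive by construction.
#'
#' @param times time grid.
#' @param config an [autogen_config].
#' @return Numeric vector of concentrations, one per timepoint.
#' @export
sample_damped_sine <- function(times, config = autogen_config()) {
  sample_damped_sines(times, config, 1)[, 1]
}

## vectorized batch of m independent damped-sine profiles (columns)
sample_damped_sines <- function(times, config, m) {
  horizon <- max(times) - min(times)
  if (horizon <= 0) horizon <- 1
  A <- stats::runif(m, config$amplitude[1], config$amplitude[2])
  lam <- stats::runif(m, config$decay[1], config$decay[2])
  omega <- 2 * pi * stats::runif(m, config$frequency_cycles[1],
                                 config$frequency_cycles[2]) / horizon
  phi <- stats::runif(m, config$phase[1], config$phase[2])
  C <- A + stats::runif(m, config$offset_margin[1], config$offset_margin[2])
  t0 <- times - min(times)
  decayed <- exp(-outer(t0, lam))
  osc <- sin(outer(times, omega) + rep(phi, each = length(times)))
  sweep(decayed * osc, 2, A, `*`) + rep(C, each = length(times))
}

## power-law flux of a profile matrix (t x n) given k and exponents g
powerlaw_flux <- function(profiles, k, g) {
  k * exp(as.vector(log(profiles) %*% g))
}

## draw n power-law exponents: magnitudes U[0.1,1]; the first (the
## "substrate" exponent) is positive, the rest have random sign.
draw_exponents <- function(n) {
  mag <- stats::runif(n, 0.1, 1)
  sgn <- c(1, sample(c(-1, 1), n - 1, replace = TRUE))
  mag * sgn
}

#' Autogenerate a true-positive training interaction
#'
#' Draws `n` independent damped-sine profiles and computes a power-law
#' flux from exactly those profiles (rate constant from \[0.1, 1\],
#' exponent magnitudes from \[0.1, 1\], first exponent positive, others
#' random sign). The stored profiles therefore completely determine the
#' stored flux — the defining property of a positive example.
#'
#' With `segments > 1` the example emulates a multi-trajectory test
#' dataset: one power law (one `k`, one exponent vector) is applied to
#' `segments` independently drawn profile sets on the same grid, and the
#' segments are concatenated. The stored flux is still an exact pointwise
#' power law of the stored profiles.
#'
#' @param n interaction order (1, 2 or 3).
#' @param times time grid shared by profiles and flux (one segment).
#' @param config an [autogen_config].
#' @param segments number of independent profile segments driven by the
#'   same power law (default 1).
#' @return A list of class `scour_interaction` with `profiles`
#'   (timepoint-by-`n` matrix, segments stacked), `flux`, `label`
#'   (`"true_positive"`), `order`, `mode`, `segments`, `seg_length`, and
#'   `provenance` (generating parameters).
#' @export
generate_true_positive <- function(n, times, config = autogen_config(),
                                   segments = 1L) {
  stopifnot(n %in% 1:3)
  gen_positive(n, times, config, segments)
}

## one independent damped sine per (segment, column), stacked so that
## rows follow the segment layout of example profiles
segmented_sines <- function(times, config, segments, cols) {
  nt <- length(times)
  P <- sample_damped_sines(times, config, segments * cols)
  out <- matrix(NA_real_, segments * nt, cols)
  for (s in seq_len(segments)) {
    out[(s - 1) * nt + seq_len(nt), ] <- P[, (s - 1) * cols + seq_len(cols)]
  }
  out
}

## unchecked generator: higher-order negatives need up to n + 2 profiles
gen_positive <- function(n, times, config, segments = 1L) {
  k <- stats::runif(1, 0.1, 1)
  g <- draw_exponents(n)
  profiles <- segmented_sines(times, config, segments, n)
  structure(list(profiles = profiles,
                 flux = powerlaw_flux(profiles, k, g),
                 label = "true_positive", order = as.integer(n),
                 mode = "positive", segments = as.integer(segments),
                 seg_length = length(times), hidden = NULL,
                 provenance = list(k = k, g = g)),
            class = "scour_interaction")
}

#' Autogenerate a true-negative training interaction
#'
#' Three constructions, all yielding a stored profile set that does NOT
#' coincide with the exact controller set of the stored flux:
#' \describe{
#'   \item{mismatch}{build an order-`n` positive, then replace a uniformly
#'     chosen number (1..n) of its profiles with fresh unrelated damped
#'     sines that took no part in the flux calculation.}
#'   \item{higher_order}{compute the flux from `n+1` or `n+2` damped-sine
#'     controllers but store only the first `n` of them — the stored
#'     profiles are genuine controllers, just not sufficient.}
#'   \item{superset}{compute the flux from fewer than `n` controllers
#'     (1..n-1) and pad the stored set with fresh decoy sines — the
#'     stored set determines the flux but is not minimal, the confuser a
#'     higher-order step meets when a lower-order flux escaped removal.
#'     Only defined for `n >= 2`.}
#' }
#'
#' @inheritParams generate_true_positive
#' @param mode `"mismatch"`, `"higher_order"` or `"superset"`.
#' @return A `scour_interaction` labelled `"true_negative"`.
#' @export
generate_true_negative <- function(n, times, config = autogen_config(),
                                   mode = c("mismatch", "higher_order",
                                            "superset"),
                                   segments = 1L) {
  stopifnot(n %in% 1:3)
  mode <- match.arg(mode)
  if (mode == "superset" && n == 1) {
    stop("superset negatives require n >= 2", call. = FALSE)
  }
  if (mode == "superset") {
    j <- if (n == 2) 1L else sample.int(n - 1, 1)
    ex <- gen_positive(j, times, config, segments)
    ex$profiles <- cbind(ex$profiles,
                         segmented_sines(times, config, segments, n - j))
    ex$order <- as.integer(n)
    ex$provenance$inert_decoys <- n - j
  } else if (mode == "mismatch") {
    ex <- gen_positive(n, times, config, segments)
    n_swap <- if (n == 1) 1L else sample.int(n, 1)
    swap <- sample.int(n, n_swap)
    # the swapped-out series remain true controllers of the flux
    ex$hidden <- ex$profiles[, swap, drop = FALSE]
    ex$profiles[, swap] <- segmented_sines(times, config, segments, n_swap)
    ex$provenance$swapped <- swap
  } else {
    m <- n + sample(1:2, 1)
    full <- gen_positive(m, times, config, segments)
    ex <- full
    ex$profiles <- full$profiles[, seq_len(n), drop = FALSE]
    ex$hidden <- full$profiles[, (n + 1):m, drop = FALSE]
    ex$order <- as.integer(n)
    ex$provenance$hidden_controllers <- m - n
  }
  ex$label <- "true_negative"
  ex$mode <- mode
  ex
}

#' Build the two balanced training sets for one step
#'
#' The stacked classifier needs two independent labelled collections: one
#' to fit the four base learners, one to fit the metamodel on their
#' outputs. Each set holds `config$n_per_class` positives and the same
#' number of negatives (modes mixed per `config$negative_modes`). The two
#' sets are generated from disjoint stretches of the random stream and
#' carry disjoint provenance draw indices.
#'
#' @param n step order (1, 2 or 3).
#' @param times time grid.
#' @param config an [autogen_config].
#' @param segments independent profile segments per example (see
#'   [generate_true_positive]); the stepwise driver uses one segment per
#'   test time course.
#' @param context_size number of bystander concentration series attached
#'   to each example as `context` (used by the one-controller feature
#'   `f_resid_explained`; matched to the number of other metabolites in
#'   the system under test). The context holds the example's hidden true
#'   controllers, padded with fresh unrelated sines — mirroring a test
#'   candidate whose residual structure, if any, is explained by some
#'   other measured metabolite. 0 disables context.
#' @param seed optional integer seed.
#' @return List with elements `level1` and `level2`, each a list of
#'   `scour_interaction` objects.
#' @export
build_training_sets <- function(n, times, config = autogen_config(),
                                segments = 1L, context_size = 0L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counter <- 0L
  mode_w <- config$negative_modes
  if (n == 1) mode_w <- mode_w[names(mode_w) != "superset"]
  add_context <- function(ex) {
    if (context_size > 0) {
      hid <- ex$hidden
      if (!is.null(hid) && ncol(hid) > context_size) {
        hid <- hid[, seq_len(context_size), drop = FALSE]
      }
      pad <- context_size - if (is.null(hid)) 0L else ncol(hid)
      fresh <- if (pad > 0) segmented_sines(times, config, ex$segments, pad)
      ex$context <- cbind(hid, fresh)
    }
    counter <<- counter + 1L
    ex$provenance$draw_index <- counter
    ex
  }
  gen_set <- function() {
    modes <- sample(names(mode_w), config$n_per_class,
                    replace = TRUE, prob = mode_w)
    pos <- lapply(seq_len(config$n_per_class), function(i) {
      add_context(generate_true_positive(n, times, config, segments))
    })
    neg <- lapply(modes, function(md) {
      add_context(generate_true_negative(n, times, config, mode = md,
                                         segments = segments))
    })
    c(pos, neg)
  }
  list(level1 = gen_set(), level2 = gen_set())
}

## Apply the run's noise condition and per-step preprocessing to a single
## autogenerated interaction, so training features see the same
## distortions as test features. Noise and smoothing are applied segment
## by segment (the Gaussian filter never crosses a segment boundary, just
## as it never crosses test time courses). Returns the example with
## profiles/flux replaced by their noisy, collapsed versions.
distort_interaction <- function(ex, cov = 0, replicates = 3L,
                                preprocess = c("none", "median", "smooth"),
                                fraction = 0.25) {
  preprocess <- match.arg(preprocess)
  if (cov <= 0 && preprocess != "smooth") return(ex)
  n_prof <- ncol(ex$profiles)
  n_ctx <- if (is.null(ex$context)) 0L else ncol(ex$context)
  series <- cbind(ex$profiles, ex$context, ex$flux)
  N <- nrow(series)
  C <- ncol(series)
  nt <- if (is.null(ex$seg_length)) N else ex$seg_length
  segments <- N / nt
  if (cov > 0) {
    # all replicate draws at once, then a vectorized per-point collapse
    reps <- array(rep(series, replicates) +
                    stats::rnorm(N * C * replicates, 0,
                                 cov * abs(rep(series, replicates))),
                  c(N, C, replicates))
    if (preprocess == "none") {
      out <- reps[, , 1, drop = FALSE][, , 1]
    } else if (preprocess == "median" && replicates == 3L) {
      a <- reps[, , 1]; b <- reps[, , 2]; d <- reps[, , 3]
      out <- a + b + d - pmax(a, b, d) - pmin(a, b, d)
    } else if (preprocess == "median") {
      out <- apply(reps, c(1, 2), stats::median)
    } else {
      out <- reps[, , 1]
      if (replicates > 1) {
        for (r in 2:replicates) out <- out + reps[, , r]
        out <- out / replicates
      }
    }
    out <- matrix(out, N, C)
  } else {
    out <- series
  }
  if (preprocess == "smooth") {
    # filter every (segment, column) stretch in one matrix pass; the
    # kernel never crosses a segment boundary
    Y <- matrix(out, nt, segments * C)
    Y <- gaussian_filter_mat(Y, ceiling(nt * fraction))
    out <- matrix(Y, N, C)
  }
  ex$profiles <- out[, seq_len(n_prof), drop = FALSE]
  if (n_ctx > 0) {
    ex$context <- out[, n_prof + seq_len(n_ctx), drop = FALSE]
  }
  ex$flux <- out[, C]
  ex
}

#' Compute the feature matrix of a set of training interactions
#'
#' Applies the configured noise condition and per-step preprocessing to
#' every interaction (so training features are computed under the same
#' conditions as test features), then evaluates the step's feature set.
#'
#' @param examples list of `scour_interaction` objects (one step order).
#' @param cov coefficient of variation of added noise (0 = noiseless).
#' @param replicates replicates per noisy draw.
#' @param preprocess `"none"`, `"median"` or `"smooth"`.
#' @param fraction Gaussian-filter window fraction.
#' @param max_points cap on the number of (thinned) timepoints entering
#'   the feature computation for multi-segment examples; keeps the
#'   distance-based features tractable on pooled series (default 120).
#' @return A data.frame of features plus a `label` column (1 = positive).
#' @export
training_feature_matrix <- function(examples, cov = 0, replicates = 3L,
                                    preprocess = "none", fraction = 0.25,
                                    max_points = 120L) {
  n <- examples[[1]]$order
  # order-1 features are linear-cost dominated; allow a denser series
  cap <- if (n == 1) 3L * max_points else max_points
  feats <- lapply(examples, function(ex) {
    ex <- distort_interaction(ex, cov, replicates, preprocess, fraction)
    idx <- thin_index(nrow(ex$profiles), cap)
    ctx <- if (is.null(ex$context)) NULL else ex$context[idx, , drop = FALSE]
    candidate_features(ex$profiles[idx, , drop = FALSE], ex$flux[idx], ctx)
  })
  df <- as.data.frame(do.call(rbind, feats))
  names(df) <- feature_names(n)
  df$label <- as.integer(vapply(examples, `[[`, character(1), "label") ==
                           "true_positive")
  df
}

#' Write training interactions and labels to CSV
#'
#' Emits the tidy time-course schema (`example_id`, `time`, `series`,
#' `value`) plus a labels table (`example_id`, `step`, `label`, `mode`).
#'
#' @param examples list of `scour_interaction` objects.
#' @param profiles_path,labels_path output CSV paths.
#' @return `labels_path`, invisibly.
#' @export
write_training_set <- function(examples, profiles_path, labels_path) {
  rows <- lapply(seq_along(examples), function(i) {
    ex <- examples[[i]]
    nt <- nrow(ex$profiles)
    n <- ncol(ex$profiles)
    data.frame(
      example_id = i,
      time = rep(seq_len(nt), n + 1),
      series = rep(c(paste0("x", seq_len(n)), "v"), each = nt),
      value = c(as.vector(ex$profiles), ex$flux)
    )
  })
  utils::write.csv(do.call(rbind, rows), profiles_path, row.names = FALSE,
                   quote = FALSE)
  labels <- data.frame(
    example_id = seq_along(examples),
    step = vapply(examples, `[[`, integer(1), "order"),
    label = vapply(examples, `[[`, character(1), "label"),
    mode = vapply(examples, `[[`, character(1), "mode")
  )
  utils::write.csv(labels, labels_path, row.names = FALSE, quote = FALSE)
  invisible(labels_path)
}
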