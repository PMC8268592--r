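#' Configuration for a stepwise run
#'
#' Bundles the study conditions of a run: which steps to execute, the
#' noise condition, the per-step preprocessing, training-set sizes and
#' classifier hyperparameters, and how evidence from the multiple test
#' time courses is combined.
#'
#' @param steps which interaction orders to run, in ascending order
#'   (default `1:3`).
#' @param nT number of retained timepoints per test time course (default
#'   50; use 15 for the low-sampling-frequency condition).
#' @param cov coefficient of variation of the measurement noise (0 =
#'   noiseless; 0.05 and 0.15 are the studied noisy conditions).
#' @param replicates noisy replicates per timepoint (default 3,
#'   triplicates).
#' @param n_timecourses number of test time courses simulated from random
#'   initial conditions (default 15).
#' @param horizon,n_points simulation horizon (default 10 time units) and
#'   dense integration grid size before subsampling (default 451).
#' @param x0_range range of the uniform draw for initial concentrations.
#' @param autogen an [autogen_config] for the training data.
#' @param aggregation how evidence from the multiple test time courses is
#'   combined. `"auto"` (default, currently equal to `"pooled"`): the
#'   time courses are concatenated and each candidate is classified once,
#'   with training examples built from matching multi-segment profiles —
#'   cross-trajectory information is what separates true controller sets
#'   from confounded ones. `"vote"` classifies each candidate per time
#'   course and takes the majority.
#' @param max_points cap on thinned pooled-series length entering the
#'   feature computation (default 120).
#' @param smoothing_fraction Gaussian-filter window as a fraction of total
#'   time for the step-2/3 preprocessing (default 1/4).
#' @param ntree,knn_k,nnet_size stack hyperparameters (see [train_stack]).
#' @param seed optional integer master seed.
#' @return A list of class `scour_config`.
#' @export
scour_config <- function(steps = 1:3, nT = 50L, cov = 0, replicates = 3L,
                         n_timecourses = 15L, horizon = 10, n_points = 451L,
                         x0_range = c(0.1, 2),
                         autogen = autogen_config(),
                         aggregation = c("auto", "vote", "pooled"),
                         max_points = 120L,
                         smoothing_fraction = 0.25,
                         ntree = 200L, knn_k = 5L, nnet_size = 10L,
                         seed = NULL) {
  aggregation <- match.arg(aggregation)
  steps <- sort(unique(as.integer(steps)))
  stopifnot(all(steps %in% 1:3), cov >= 0, replicates >= 1)
  structure(list(steps = steps, nT = as.integer(nT), cov = cov,
                 replicates = as.integer(replicates),
                 n_timecourses = as.integer(n_timecourses),
                 horizon = horizon, n_points = as.integer(n_points),
                 x0_range = x0_range, autogen = autogen,
                 aggregation = aggregation, max_points = as.integer(max_points),
                 smoothing_fraction = smoothing_fraction,
                 ntree = ntree, knn_k = knn_k, nnet_size = nnet_size,
                 seed = seed),
            class = "scour_config")
}

## resolve the aggregation mode for a step order
step_aggregation <- function(aggregation, n) {
  if (aggregation == "auto") "pooled" else aggregation
}

## preprocessing rule per step: median collapse before the one-controller
## step, Gaussian smoothing before the two- and three-controller steps;
## noiseless single-replicate data pass through untouched.
step_preprocess_mode <- function(n, noisy) {
  if (!noisy) "none" else if (n == 1) "median" else "smooth"
}

preprocess_timecourse <- function(tc, mode, fraction = 0.25) {
  switch(mode,
         none = tc,
         median = median_collapse(tc),
         smooth = smooth_collapse(tc, fraction = fraction))
}

#' Sample an admissible network instance and its test data
#'
#' Draws power-law kinetics and simulates the test time courses,
#' redrawing the whole parameter set when no admissible initial
#' condition exists for it (some random kinetics inevitably crash a
#' metabolite to zero; such draws are rejected like inadmissible initial
#' conditions).
#'
#' @param net a [scour_network].
#' @param config a [scour_config].
#' @param seed integer seed.
#' @param max_param_draws cap on parameter redraws.
#' @return List with `params` and `test_tcs`.
#' @export
sample_test_system <- function(net, config = scour_config(), seed = 1L,
                               max_param_draws = 20L) {
  for (a in seq_len(max_param_draws)) {
    params <- sample_bst_parameters(net, seed = seed + (a - 1L) * 131L)
    tcs <- tryCatch(
      prepare_testdata(net, params, config, seed = seed + 500000L,
                       max_retries = 15L),
      error = function(e) NULL)
    if (!is.null(tcs)) return(list(params = params, test_tcs = tcs))
  }
  stop("no admissible kinetic parameters found for ", net$name, call. = FALSE)
}

#' Simulate the test dataset for a network
#'
#' Simulates `n_timecourses` time courses from independent random initial
#' conditions (uniform over `x0_range` per metabolite), subsamples each to
#' `nT` uniform timepoints, and — under a noisy condition — adds
#' replicated Gaussian measurement noise. Initial-condition draws whose
#' simulation drives any concentration below the positivity floor are
#' rejected and redrawn (up to `max_retries` per time course).
#'
#' @param net a [scour_network].
#' @param params kinetics from [sample_bst_parameters].
#' @param config a [scour_config].
#' @param seed optional integer seed.
#' @param max_retries redraw cap per time course.
#' @return List of [scour_timecourse] objects (replicated when
#'   `config$cov > 0`).
#' @export
prepare_testdata <- function(net, params, config = scour_config(),
                             seed = NULL, max_retries = 50L) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(net$metabolites)
  lapply(seq_len(config$n_timecourses), function(i) {
    tc <- NULL
    for (try in seq_len(max_retries)) {
      x0 <- stats::setNames(
        stats::runif(m, config$x0_range[1], config$x0_range[2]),
        net$metabolites)
      tc <- tryCatch(
        simulate_timecourse(net, params, x0, horizon = config$horizon,
                            n_points = config$n_points),
        error = function(e) NULL)
      if (!is.null(tc)) break
    }
    if (is.null(tc)) {
      stop(sprintf("no admissible initial condition found for %s after %d draws",
                   net$name, max_retries), call. = FALSE)
    }
    tc <- subsample_timecourse(tc, config$nT)
    if (config$cov > 0) {
      tc <- add_noise(tc, config$cov, config$replicates)
    }
    tc
  })
}

## Feature matrix for a list of candidates over a list of (collapsed)
## test time courses. Returns the matrix plus index vectors mapping rows
## to candidates.
candidate_feature_rows <- function(net, candidates, tcs, pooled = FALSE,
                                   max_points = 120L) {
  n <- candidates[[1]]$order
  cap <- if (n == 1) 3L * max_points else max_points
  all_mets <- rownames(tcs[[1]]$conc)
  pooled_series <- function(ids, rid = NULL) {
    if (!is.null(rid)) {
      return(unlist(lapply(tcs, function(tc) tc_series(tc, "flux", rid))))
    }
    do.call(rbind, lapply(tcs, function(tc) {
      sapply(ids, function(id) tc_series(tc, "metabolite", id))
    }))
  }
  if (pooled) {
    rows <- lapply(candidates, function(cand) {
      X <- pooled_series(cand$controllers)
      v <- pooled_series(NULL, cand$reaction_id)
      idx <- thin_index(nrow(X), cap)
      ctx <- if (n == 1) {
        others <- setdiff(all_mets, cand$controllers)
        pooled_series(others)[idx, , drop = FALSE]
      }
      candidate_features(X[idx, , drop = FALSE], v[idx], ctx)
    })
    idx <- seq_along(candidates)
  } else {
    rows <- list()
    idx <- integer()
    for (ci in seq_along(candidates)) {
      cand <- candidates[[ci]]
      for (tc in tcs) {
        X <- sapply(cand$controllers, function(id) tc_series(tc, "metabolite", id))
        v <- tc_series(tc, "flux", cand$reaction_id)
        ctx <- if (n == 1) {
          sapply(setdiff(all_mets, cand$controllers),
                 function(id) tc_series(tc, "metabolite", id))
        }
        rows[[length(rows) + 1L]] <- candidate_features(as.matrix(X), v, ctx)
        idx <- c(idx, ci)
      }
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- feature_names(n)
  list(features = df, candidate_index = idx)
}

#' Run one step of the stepwise framework
#'
#' Enumerates the order-`n` candidates over the still-active fluxes,
#' computes the step's features for every candidate on every preprocessed
#' test time course, classifies with the trained stack, and combines the
#' per-time-course decisions by majority vote (or classifies pooled
#' series once, per `aggregation`). Fluxes with at least one positively
#' classified candidate are flagged for removal from later steps.
#'
#' @param n step order.
#' @param net a [scour_network].
#' @param tcs list of preprocessed single-replicate test time courses.
#' @param stack a trained `scour_stack` for this step.
#' @param active_fluxes reaction ids still under consideration.
#' @param aggregation `"vote"` or `"pooled"`.
#' @param max_points thinning cap for pooled series.
#' @return A list of class `scour_step_result`: `order`, `candidates`,
#'   `predicted` (logical), `score` (mean metamodel score), `votes`,
#'   `removed_fluxes`.
#' @export
run_step <- function(n, net, tcs, stack, active_fluxes = NULL,
                     aggregation = c("vote", "pooled"), max_points = 120L) {
  aggregation <- match.arg(aggregation)
  candidates <- enumerate_candidates(net, n, active_fluxes)
  if (length(candidates) == 0) {
    return(structure(list(order = n, candidates = list(),
                          predicted = logical(), score = numeric(),
                          votes = numeric(), removed_fluxes = character()),
                     class = "scour_step_result"))
  }
  fr <- candidate_feature_rows(net, candidates, tcs,
                               pooled = aggregation == "pooled",
                               max_points = max_points)
  pred <- stats::predict(stack, fr$features)
  votes <- tapply(pred$label, fr$candidate_index, mean)
  score <- tapply(pred$score, fr$candidate_index, mean)
  predicted <- as.vector(votes > 0.5)
  removed <- unique(vapply(candidates[predicted], `[[`, character(1),
                           "reaction_id"))
  structure(list(order = n, candidates = candidates, predicted = predicted,
                 score = as.vector(score), votes = as.vector(votes),
                 removed_fluxes = removed),
            class = "scour_step_result")
}

#' Run the full stepwise framework
#'
#' For each requested step: autogenerate the two training sets on the
#' test-data time grid under the matched noise condition and per-step
#' preprocessing, train the two-level stack, preprocess the test time
#' courses by the step rule (median collapse before step 1, Gaussian
#' smoothing before steps 2-3, pass-through when noiseless), classify all
#' candidates over the still-active fluxes, and remove positively
#' identified fluxes from later steps. Fully reproducible from
#' `config$seed`.
#'
#' @param net a [scour_network].
#' @param test_tcs list of test time courses as produced by
#'   [prepare_testdata] (replicated when noisy).
#' @param config a [scour_config].
#' @return An object of class `scour_result`: per-step results, the
#'   assembled `predictions` data.frame (step, reaction, controllers,
#'   score) and the config.
#' @export
run_scour <- function(net, test_tcs, config = scour_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  noisy <- test_tcs[[1]]$replicates > 1
  times <- test_tcs[[1]]$times
  active <- reaction_ids(net, constant = FALSE)
  step_results <- list()
  for (n in config$steps) {
    mode <- step_preprocess_mode(n, noisy)
    agg <- step_aggregation(config$aggregation, n)
    segments <- if (agg == "pooled") length(test_tcs) else 1L
    ctx_size <- if (n == 1) length(net$metabolites) - 1L else 0L
    sets <- build_training_sets(n, times, config$autogen,
                                segments = segments,
                                context_size = ctx_size)
    l1 <- training_feature_matrix(sets$level1, cov = config$cov,
                                  replicates = config$replicates,
                                  preprocess = mode,
                                  fraction = config$smoothing_fraction,
                                  max_points = config$max_points)
    l2 <- training_feature_matrix(sets$level2, cov = config$cov,
                                  replicates = config$replicates,
                                  preprocess = mode,
                                  fraction = config$smoothing_fraction,
                                  max_points = config$max_points)
    stack <- train_stack(l1, l2, ntree = config$ntree, knn_k = config$knn_k,
                         nnet_size = config$nnet_size)
    tcs <- lapply(test_tcs, preprocess_timecourse, mode = mode,
                  fraction = config$smoothing_fraction)
    sr <- run_step(n, net, tcs, stack, active_fluxes = active,
                   aggregation = agg, max_points = config$max_points)
    step_results[[as.character(n)]] <- sr
    active <- setdiff(active, sr$removed_fluxes)
  }
  preds <- do.call(rbind, lapply(step_results, function(sr) {
    if (!any(sr$predicted)) return(NULL)
    keep <- which(sr$predicted)
    data.frame(
      step = sr$order,
      reaction = vapply(sr$candidates[keep], `[[`, character(1), "reaction_id"),
      controllers = vapply(sr$candidates[keep], function(cand) {
        paste(cand$controllers, collapse = "+")
      }, character(1)),
      score = sr$score[keep]
    )
  }))
  if (is.null(preds)) {
    preds <- data.frame(step = integer(), reaction = character(),
                        controllers = character(), score = numeric())
  }
  rownames(preds) <- NULL
  structure(list(network = net$name, steps = step_results,
                 predictions = preds, config = config),
            class = "scour_result")
}

#' @export
print.scour_result <- function(x, ...) {
  cat(sprintf("<scour_result> network %s, steps %s\n", x$network,
              paste(names(x$steps), collapse = ",")))
  for (sr in x$steps) {
    cat(sprintf("  step %d: %d candidates, %d predicted positive, %d flux(es) removed\n",
                sr$order, length(sr$candidates), sum(sr$predicted),
                length(sr$removed_fluxes)))
  }
  if (nrow(x$predictions)) {
    cat("predicted interactions:\n")
    print(x$predictions, row.names = FALSE)
  } else cat("no interactions predicted\n")
  invisible(x)
}

#' @export
summary.scour_result <- function(object, ...) {
  df <- do.call(rbind, lapply(object$steps, function(sr) {
    data.frame(step = sr$order, candidates = length(sr$candidates),
               predicted_positive = sum(sr$predicted),
               fluxes_removed = length(sr$removed_fluxes))
  }))
  rownames(df) <- NULL
  df
}
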