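#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, positive predictive value and F1
#' from integer confusion counts. Metrics with a zero denominator are
#' undefined and returned as `NA` (and excluded from replicate averages,
#' matching the convention that runs with no true positives contribute
#' nothing to sensitivity means). F1 propagates undefinedness from either
#' PPV or sensitivity.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `f1` (values in \[0, 1\] or `NA`).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  tp <- as.vector(tp); fp <- as.vector(fp)
  tn <- as.vector(tn); fn <- as.vector(fn)
  total <- tp + fp + tn + fn
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- rate(tp + tn, total)
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp)
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  c(accuracy = acc, sensitivity = sens, specificity = spec, ppv = ppv,
    f1 = f1)
}

#' Score one step's predictions against ground truth
#'
#' A candidate is a ground-truth positive iff its controller set equals
#' the flux's true controller set and the flux's true order equals the
#' step order. Per-interaction scoring: every enumerated candidate counts
#' once in the confusion table.
#'
#' @param step_result a `scour_step_result` from [run_step].
#' @param net the [scour_network] carrying ground truth.
#' @return List with `counts` (tp, fp, tn, fn) and `metrics`
#'   ([confusion_metrics] output).
#' @export
score_step <- function(step_result, net) {
  truth <- vapply(step_result$candidates, candidate_is_true, logical(1),
                  net = net)
  pred <- step_result$predicted
  counts <- c(tp = sum(truth & pred), fp = sum(!truth & pred),
              tn = sum(!truth & !pred), fn = sum(truth & !pred))
  list(counts = counts,
       metrics = confusion_metrics(counts["tp"], counts["fp"],
                                   counts["tn"], counts["fn"]))
}

## active flux set under oracle removal: before step n, all fluxes whose
## true controller order is below n have been removed.
oracle_active_fluxes <- function(net, n) {
  ord <- controller_orders(net)
  names(ord)[ord >= n]
}

#' Random-classifier PPV baseline
#'
#' The comparison baseline: each candidate has a 50% chance of being
#' called positive, independent of the truth, with correct fluxes assumed
#' removed at each step (oracle removal, which favours the baseline by
#' shrinking the candidate pool). Reports the Monte-Carlo mean PPV per
#' step (trials with no predicted positives excluded) alongside the
#' analytic expectation, which is the prevalence of true interactions
#' among the candidates.
#'
#' @param net a [scour_network].
#' @param steps step orders to evaluate (default `1:3`).
#' @param n_trials Monte-Carlo trials (default 10000).
#' @param seed optional integer seed.
#' @return data.frame with columns `step`, `n_candidates`, `n_true`,
#'   `analytic_ppv` (prevalence) and `mc_ppv`.
#' @export
random_baseline <- function(net, steps = 1:3, n_trials = 10000L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(steps, function(n) {
    cands <- enumerate_candidates(net, n, oracle_active_fluxes(net, n))
    truth <- vapply(cands, candidate_is_true, logical(1), net = net)
    k <- length(cands)
    ppvs <- vapply(seq_len(n_trials), function(i) {
      called <- stats::runif(k) < 0.5
      if (!any(called)) return(NA_real_)
      sum(called & truth) / sum(called)
    }, numeric(1))
    data.frame(step = n, n_candidates = k, n_true = sum(truth),
               analytic_ppv = if (k) sum(truth) / k else NA_real_,
               mc_ppv = mean(ppvs, na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Replicate experiment: train repeatedly, test on fixed data
#'
#' The robustness protocol: the test time courses (and network kinetics)
#' are simulated once and held fixed, then the autogenerate-train-
#' classify-score cycle is repeated with independent training seeds.
#' Per-metric means and standard errors of the mean are aggregated across
#' replicates, excluding undefined (NA) values; `n_used` records how many
#' replicates contributed to each mean.
#'
#' @param net a [scour_network].
#' @param config a [scour_config]; its `seed` seeds the kinetics and test
#'   data, while replicate `r` trains with seed `seed + r`.
#' @param n_replicates number of independent training replicates.
#' @return List of class `scour_experiment`: `summary` (data.frame step x
#'   metric with mean, sem, n_used), `replicates` (long per-replicate
#'   metric table), `baseline` ([random_baseline] on the same network),
#'   and `test_data`.
#' @export
run_experiment <- function(net, config = scour_config(), n_replicates = 10L) {
  seed <- if (is.null(config$seed)) 1L else config$seed
  sys <- sample_test_system(net, config, seed = seed)
  test_tcs <- sys$test_tcs
  rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seed + r
    res <- run_scour(net, test_tcs, cfg)
    for (sr in res$steps) {
      sc <- score_step(sr, net)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, step = sr$order,
        metric = names(sc$metrics), value = as.numeric(sc$metrics))
    }
  }
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  agg <- do.call(rbind, lapply(split(long, long[c("step", "metric")]),
    function(d) {
      v <- d$value[!is.na(d$value)]
      data.frame(step = d$step[1], metric = d$metric[1],
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
                 n_used = length(v))
    }))
  agg <- agg[order(agg$step, agg$metric), ]
  rownames(agg) <- NULL
  structure(list(summary = agg, replicates = long,
                 baseline = random_baseline(net, config$steps,
                                            seed = seed + 900000L),
                 network = net$name, n_replicates = n_replicates),
            class = "scour_experiment")
}

#' @export
print.scour_experiment <- function(x, ...) {
  cat(sprintf("<scour_experiment> network %s, %d training replicates\n",
              x$network, x$n_replicates))
  wide <- stats::reshape(x$summary[c("step", "metric", "mean")],
                         idvar = "step", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  cat("random-classifier baseline (analytic PPV):",
      paste(sprintf("step %d: %.3f", x$baseline$step, x$baseline$analytic_ppv),
            collapse = ", "), "\n")
  invisible(x)
}

## convenience accessor: mean of a metric at a step (NA if absent)
experiment_mean <- function(exp, step, metric) {
  s <- exp$summary
  hit <- s$step == step & s$metric == metric
  if (!any(hit)) return(NA_real_)
  s$mean[hit]
}
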