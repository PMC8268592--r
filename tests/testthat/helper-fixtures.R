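# shared fixtures: tiny networks and cheap configs built in code

# one metabolite, constant influx c and linear efflux k*x: the linear
# birth-death system with closed-form solution
linear_network <- function() {
  scour_network(
    metabolites = "x1",
    reactions = list(
      list(id = "v1", substrate = NA, products = "x1", constant = TRUE,
           controllers = numeric()),
      list(id = "v2", substrate = "x1", products = character(),
           constant = FALSE, controllers = c(x1 = 1))
    ),
    name = "linear"
  )
}

linear_params <- function(influx = 0.6, k = 0.4) {
  structure(list(v1 = list(constant = TRUE, value = influx),
                 v2 = list(constant = FALSE, k = k, g = c(x1 = 1))),
            class = "scour_bst_params")
}

# three metabolites, one regulated flux: the smallest enumerable system
toy3_network <- function() {
  scour_network(
    metabolites = c("a", "b", "c"),
    reactions = list(
      list(id = "v1", substrate = NA, products = "a", constant = TRUE,
           controllers = numeric()),
      list(id = "v2", substrate = "a", products = "b", constant = FALSE,
           controllers = c(a = 1, c = -1))
    ),
    name = "toy3"
  )
}

# small run configuration for fast pipeline tests
tiny_config <- function(...) {
  scour_config(autogen = autogen_config(n_per_class = 40L),
               n_timecourses = 3L, nT = 25L, ntree = 60L, ...)
}

# perfectly separable two-feature training frame for stacking tests
separable_frame <- function(n = 40, jitter = 0.05, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  data.frame(
    f_a = c(rnorm(half, 1, jitter), rnorm(n - half, -1, jitter)),
    f_b = rnorm(n, 0, 1),
    label = rep(c(1L, 0L), c(half, n - half))
  )
}

# step/metric mean accessor mirroring the acceptance-script reporting
experiment_mean_tt <- function(ex, step, metric) {
  s <- ex$summary
  hit <- s$step == step & s$metric == metric
  if (!any(hit)) return(NA_real_)
  s$mean[hit]
}

# one key feature value per autogenerated example, computed under the
# pipeline's own conditions (15 pooled segments, thinned series)
key_feature_values <- function(n, n_each, grid, modes) {
  pos <- lapply(seq_len(n_each), function(i) {
    generate_true_positive(n, grid, segments = 15)
  })
  neg <- lapply(seq_len(n_each), function(i) {
    generate_true_negative(n, grid, mode = sample(modes, 1), segments = 15)
  })
  fm <- training_feature_matrix(c(pos, neg))
  key <- if (n == 1) "f_spearman" else "g_uniqueness"
  list(x = fm[[key]], y = fm$label)
}

# balanced accuracy of the best single-feature threshold split
best_threshold_balanced_accuracy <- function(x, y) {
  cuts <- sort(unique(x))
  cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
  best <- 0
  for (cut in cuts) {
    for (dir in c(1, -1)) {
      pred <- if (dir > 0) x > cut else x < cut
      ba <- (mean(pred[y == 1]) + mean(!pred[y == 0])) / 2
      best <- max(best, ba)
    }
  }
  best
}
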