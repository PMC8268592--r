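grid <- seq(0, 10, length.out = 50)

test_that("one-controller features recognise a monotone power law", {
  set.seed(1)
  x <- sort(runif(50, 0.2, 2))
  v <- 0.7 * x^0.8
  f <- features_single(x, v)
  expect_named(f, c("f_spearman", "f_loglin_r2", "f_resid_ac",
                    "f_resid_explained", "f_knn_loo_r2"))
  expect_equal(unname(f["f_spearman"]), 1)
  expect_equal(unname(f["f_loglin_r2"]), 1, tolerance = 1e-8)
  expect_equal(unname(f["f_resid_ac"]), 0)
  expect_gt(f["f_knn_loo_r2"], 0.9)
  # inhibition is captured through the absolute value
  f_neg <- features_single(x, x^-0.5)
  expect_equal(unname(f_neg["f_spearman"]), 1)
})

test_that("independent sequences yield near-zero correlation features", {
  set.seed(2)
  mean_f1 <- mean(replicate(1000, {
    features_single(rnorm(50), rnorm(50))["f_spearman"]
  }))
  expect_lt(mean_f1, 0.15)
})

test_that("multivalued relations score poorly on the neighbour regression", {
  # each x value maps to the full flux range: 3-NN prediction fails
  x <- rep(c(0.5, 1), 6)
  v <- rep(c(0.1, 0.1, 1, 1), 3)
  f <- features_single(x, v)
  expect_equal(unname(f["f_knn_loo_r2"]), 0)
  # while a single-valued staircase predicts well
  f2 <- features_single(rep(1:4, each = 3), rep(c(1, 2, 4, 8), each = 3))
  expect_gt(f2["f_knn_loo_r2"], 0.75)
})

test_that("context series expose hidden controllers through the residuals", {
  set.seed(22)
  grid2 <- seq(0, 10, length.out = 200)
  x <- sample_damped_sine(grid2)
  z <- sample_damped_sine(grid2)
  noise <- function(y) y * (1 + rnorm(length(y), 0, 0.1))
  ctx <- cbind(z, sample_damped_sine(grid2))
  # true one-controller flux: no context series explains the residuals
  f_pos <- features_single(noise(x), noise(0.4 * x^0.8), context = ctx)
  # weak hidden controller z (exponent -0.15, below the noise floor for
  # the omnibus statistics) is still found by the targeted regression
  f_neg <- features_single(noise(x), noise(0.4 * x^0.8 * z^-0.15),
                           context = ctx)
  expect_lt(f_pos["f_resid_explained"], 0.1)
  expect_gt(f_neg["f_resid_explained"],
            3 * f_pos["f_resid_explained"])
})

test_that("residual autocorrelation flags hidden smooth controllers", {
  set.seed(21)
  grid2 <- seq(0, 10, length.out = 200)
  x <- sample_damped_sine(grid2)
  z <- sample_damped_sine(grid2)
  noise <- function(y) y * (1 + rnorm(length(y), 0, 0.1))
  # white-noise residuals: autocorrelation near zero
  f_pos <- features_single(noise(x), noise(0.5 * x^0.7))
  # hidden controller: smooth structured residuals
  f_neg <- features_single(noise(x), noise(0.5 * x^0.7 * z^-0.6))
  expect_lt(f_pos["f_resid_ac"], 0.25)
  expect_gt(f_neg["f_resid_ac"], 0.4)
})

test_that("degenerate series give zero features with a flag, not errors", {
  f <- features_single(rep(1, 50), rnorm(50))
  expect_true(all(f == 0))
  expect_true(attr(f, "degenerate"))
  f2 <- features_multi(cbind(grid, rev(grid)), rep(2, 50))
  expect_true(all(f2 == 0))
  expect_true(attr(f2, "degenerate"))
  expect_error(features_multi(cbind(grid, grid), rnorm(50)), "duplicate")
})

test_that("uniqueness score separates functions from shuffled fluxes", {
  set.seed(3)
  scores <- replicate(30, {
    X <- cbind(sample_damped_sine(grid), sample_damped_sine(grid))
    v <- scour:::powerlaw_flux(X, 0.5, c(0.8, -0.6))
    c(true = as.numeric(uniqueness_score(X, v)),
      perm = as.numeric(uniqueness_score(X, sample(v))))
  })
  expect_lt(mean(scores["true", ]), 0.1)
  expect_gt(mean(scores["perm", ]), 3 * mean(scores["true", ]))
  # identical inputs with identical fluxes contribute zero
  Xd <- cbind(rep(c(1, 2), 10), rep(c(2, 1), 10))
  vd <- rep(c(5, 9), 10)
  expect_equal(as.numeric(uniqueness_score(Xd, vd)), 0)
  expect_true(as.numeric(uniqueness_score(Xd, rep(1, 20))) == 0)
})

test_that("log-linear fit features identify the power-law functional form", {
  set.seed(4)
  X <- cbind(sample_damped_sine(grid), sample_damped_sine(grid))
  v <- scour:::powerlaw_flux(X, 0.3, c(0.5, -0.9))
  f <- features_multi(X, v)
  # exact power law: lack of fit at the numerical floor, clear gain
  expect_lt(f["g_loglin_lackfit"], -8)
  expect_gt(f["g_loglin_gain"], -4)
  # a decoy replacing a controller destroys the exact fit
  Xbad <- X
  Xbad[, 2] <- sample_damped_sine(grid)
  fbad <- features_multi(Xbad, v)
  expect_gt(fbad["g_loglin_lackfit"], -4)
})

test_that("features are invariant to positive rescaling of the input series", {
  set.seed(5)
  x <- sample_damped_sine(grid)
  X <- cbind(x, sample_damped_sine(grid))
  v <- scour:::powerlaw_flux(X, 0.5, c(0.7, 0.4))
  # multiplicative rescaling leaves every feature unchanged (log-linear
  # probes absorb scale factors into the intercept; the rank, bin and
  # neighbour features are additionally shift-invariant)
  f0 <- features_single(x, v)
  f1 <- features_single(2.5 * x, 3 * v)
  expect_equal(f0, f1, tolerance = 1e-8)
  rank_feats <- c("f_spearman", "f_knn_loo_r2")
  f2 <- features_single(2.5 * x + 1, 3 * v + 2)
  expect_equal(f0[rank_feats], f2[rank_feats], tolerance = 1e-10)
  g0 <- features_multi(X, v)
  g1 <- features_multi(X * 4, v * 0.5)
  expect_equal(g0, g1, tolerance = 1e-8)
})

test_that("single features separate autogenerated classes per step", {
  set.seed(6)
  for (n in 1:3) {
    kv <- key_feature_values(n, 200, grid,
                             modes = c("mismatch", "higher_order"))
    ba <- best_threshold_balanced_accuracy(kv$x, kv$y)
    expect_gte(ba, 0.80)
    # permutation null: shuffling the labels destroys the separation
    ba_null <- best_threshold_balanced_accuracy(kv$x, sample(kv$y))
    expect_lte(ba_null, 0.60)
  }
})
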