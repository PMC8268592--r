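grid50 <- seq(0, 10, length.out = 50)

test_that("damped-sine profiles are strictly positive across many draws", {
  set.seed(7)
  mins <- replicate(10000, min(sample_damped_sine(grid50)))
  expect_true(all(mins > 0))
})

test_that("degenerate damped-sine parameters behave analytically", {
  # zero amplitude: constant profile equal to the offset
  cfg0 <- autogen_config(amplitude = c(0, 0), offset_margin = c(0.7, 0.7))
  set.seed(1)
  prof <- sample_damped_sine(grid50, cfg0)
  expect_equal(prof, rep(0.7, 50), ignore_attr = TRUE)
  # no decay, C = 2A: profile confined to [A, 3A] while touching near both
  cfgA <- autogen_config(amplitude = c(0.3, 0.3), decay = c(0, 0),
                         offset_margin = c(0.3, 0.3))
  set.seed(2)
  prof <- replicate(50, sample_damped_sine(grid50, cfgA))
  expect_true(all(prof >= 0.3 - 1e-12 & prof <= 0.9 + 1e-12))
})

test_that("true positives store the exact generators of their flux", {
  set.seed(11)
  for (n in 1:3) {
    ex <- generate_true_positive(n, grid50)
    expect_identical(ex$label, "true_positive")
    expect_identical(ncol(ex$profiles), as.integer(n))
    # pointwise oracle recomputation from the provenance parameters
    oracle <- apply(ex$profiles, 1, function(x) {
      ex$provenance$k * prod(x^ex$provenance$g)
    })
    expect_equal(ex$flux, oracle, tolerance = 1e-12)
    # substrate exponent positive, all magnitudes in [0.1, 1]
    expect_gt(ex$provenance$g[1], 0)
    expect_true(all(abs(ex$provenance$g) >= 0.1 & abs(ex$provenance$g) <= 1))
  }
  # identity power law: flux equals its controller profile
  x <- sample_damped_sine(grid50)
  expect_equal(scour:::powerlaw_flux(matrix(x, ncol = 1), 1, 1), x)
})

test_that("negatives break the stored-profile/flux dependence in the declared way", {
  set.seed(12)
  for (n in 1:3) {
    mm <- generate_true_negative(n, grid50, mode = "mismatch")
    expect_identical(mm$label, "true_negative")
    # at least one stored profile is not a generator of the flux
    oracle <- apply(mm$profiles, 1, function(x) {
      mm$provenance$k * prod(x^mm$provenance$g)
    })
    expect_gt(max(abs(mm$flux - oracle)), 1e-8)
    expect_gte(length(mm$provenance$swapped), 1)

    ho <- generate_true_negative(n, grid50, mode = "higher_order")
    expect_identical(ncol(ho$profiles), as.integer(n))
    expect_true(ho$provenance$hidden_controllers %in% 1:2)
    # stored profiles alone under-determine the flux: full exponent vector
    # is longer than the stored set
    expect_gt(length(ho$provenance$g), n)
  }
  for (n in 2:3) {
    sup <- generate_true_negative(n, grid50, mode = "superset")
    expect_identical(ncol(sup$profiles), as.integer(n))
    expect_lt(length(sup$provenance$g), n)
  }
  expect_error(generate_true_negative(1, grid50, mode = "superset"), "n >= 2")
})

test_that("training sets are balanced, disjoint and of the configured size", {
  cfg <- autogen_config(n_per_class = 25L)
  sets <- build_training_sets(2, grid50, cfg, seed = 5)
  for (s in sets) {
    labels <- vapply(s, `[[`, character(1), "label")
    expect_identical(sum(labels == "true_positive"), 25L)
    expect_identical(sum(labels == "true_negative"), 25L)
    expect_true(all(vapply(s, function(e) ncol(e$profiles), integer(1)) == 2L))
  }
  idx1 <- vapply(sets$level1, function(e) e$provenance$draw_index, integer(1))
  idx2 <- vapply(sets$level2, function(e) e$provenance$draw_index, integer(1))
  expect_length(intersect(idx1, idx2), 0)
  # order-3 positives have exactly three controller profiles
  sets3 <- build_training_sets(3, grid50, autogen_config(n_per_class = 5L),
                               seed = 6)
  expect_true(all(vapply(sets3$level1, function(e) ncol(e$profiles),
                         integer(1)) == 3L))
})

test_that("multi-segment examples keep the single shared power law", {
  set.seed(13)
  ex <- generate_true_positive(2, grid50, segments = 4)
  expect_identical(nrow(ex$profiles), 200L)
  oracle <- apply(ex$profiles, 1, function(x) {
    ex$provenance$k * prod(x^ex$provenance$g)
  })
  expect_equal(ex$flux, oracle, tolerance = 1e-12)
  # segments are genuinely different draws
  expect_false(identical(ex$profiles[1:50, 1], ex$profiles[51:100, 1]))
})

test_that("matched distortion applies noise and per-step collapse to training data", {
  set.seed(14)
  exs <- list(generate_true_positive(1, grid50),
              generate_true_negative(1, grid50, mode = "mismatch"))
  fm <- training_feature_matrix(exs, cov = 0, preprocess = "none")
  expect_identical(dim(fm), c(2L, 6L))
  expect_identical(fm$label, c(1L, 0L))
  # noiseless + none leaves profiles untouched, so features are reproducible
  fm2 <- training_feature_matrix(exs, cov = 0, preprocess = "none")
  expect_identical(fm, fm2)
  # noisy median distortion changes features but keeps them finite
  set.seed(15)
  fm3 <- training_feature_matrix(exs, cov = 0.15, replicates = 3,
                                 preprocess = "median")
  expect_true(all(is.finite(as.matrix(fm3[1:5]))))
  expect_false(identical(fm$f_spearman, fm3$f_spearman))
})

test_that("training sets export to the tidy CSV schema", {
  set.seed(16)
  exs <- build_training_sets(1, grid50, autogen_config(n_per_class = 3L))$level1
  profiles_path <- withr::local_tempfile(fileext = ".csv")
  labels_path <- withr::local_tempfile(fileext = ".csv")
  write_training_set(exs, profiles_path, labels_path)
  labs <- read.csv(labels_path)
  expect_identical(nrow(labs), 6L)
  expect_setequal(unique(labs$label), c("true_positive", "true_negative"))
  profs <- read.csv(profiles_path)
  expect_identical(sort(unique(profs$series)), c("v", "x1"))
})
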