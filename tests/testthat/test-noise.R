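constant_tc <- function(value = 1, n_time = 50, n_rep = 1) {
  conc <- array(value, c(1, n_time, n_rep), dimnames = list("x1", NULL, NULL))
  flux <- array(value, c(1, n_time, n_rep), dimnames = list("v1", NULL, NULL))
  scour_timecourse(seq(0, 10, length.out = n_time), conc, flux)
}

test_that("subsampling retains endpoints on a uniform grid", {
  net <- linear_network()
  tc <- simulate_timecourse(net, linear_params(), c(x1 = 0.5), n_points = 451)
  expect_identical(subsample_timecourse(tc, 451)$times, tc$times)
  sub <- subsample_timecourse(tc, 15)
  # independent arithmetic: nearest grid snap of 15 evenly spaced points
  expect_equal(sub$times, tc$times[round(seq(1, 451, length.out = 15))])
  expect_equal(sub$times[1], 0)
  expect_equal(sub$times[15], 10)
  expect_equal(max(abs(sub$times - seq(0, 10, length.out = 15))), 0,
               tolerance = 0.03)
  expect_error(subsample_timecourse(tc, 452), "between")
  expect_error(subsample_timecourse(tc, 1), "between")
})

test_that("noise model reproduces the target coefficient of variation", {
  # 1e5 draws at CoV 0.15 around value 1.0
  tc <- constant_tc(value = 1, n_time = 33334)
  noisy <- add_noise(tc, cov = 0.15, replicates = 3, seed = 1)
  draws <- as.vector(noisy$conc)
  expect_gte(length(draws), 1e5)
  expect_true(sd(draws) >= 0.148 && sd(draws) <= 0.152)
  # expectation preserved to < 1% relative error
  expect_equal(mean(draws), 1, tolerance = 0.01)
  # zero CoV duplicates the noiseless values
  clean <- add_noise(constant_tc(), cov = 0, replicates = 3)
  expect_true(all(clean$conc == 1))
  expect_identical(clean$replicates, 3L)
  # different seeds give different draws
  n2 <- add_noise(tc, cov = 0.15, replicates = 3, seed = 2)
  expect_false(identical(noisy$conc, n2$conc))
})

test_that("median collapse takes the middle order statistic per timepoint", {
  conc <- array(c(1.0, 1.2, 0.9), c(1, 1, 3), dimnames = list("x1", NULL, NULL))
  flux <- array(c(2.0, 1.8, 2.4), c(1, 1, 3), dimnames = list("v1", NULL, NULL))
  tc <- scour_timecourse(1, conc, flux)
  out <- median_collapse(tc)
  expect_equal(unname(out$conc["x1", 1, 1]), 1.0)
  expect_equal(unname(out$flux["v1", 1, 1]), 2.0)
  # single replicate: identity
  tc1 <- constant_tc(value = 3)
  expect_equal(median_collapse(tc1)$conc, tc1$conc)
})

test_that("Gaussian smoothing preserves constants and the stated window rule", {
  tc <- constant_tc(value = 2.5, n_time = 15, n_rep = 3)
  sm <- smooth_collapse(tc, fraction = 0.25)
  expect_equal(as.vector(sm$conc), rep(2.5, 15))
  # window of a 15-point grid at 1/4 fraction covers ceil(15/4) = 4 points
  expect_identical(ceiling(15 * 0.25), 4)
  y <- c(rep(0, 7), 1, rep(0, 7))
  smoothed <- scour:::gaussian_filter(y, window_pts = 4)
  expect_lt(max(smoothed), 1)            # the spike is spread out
  expect_equal(sum(smoothed > 1e-6), 5)  # support limited to the window
})

test_that("smoothing reduces white-noise variance around a constant", {
  set.seed(42)
  reduced <- replicate(500, {
    y <- rnorm(50, 10, 1)
    var(scour:::gaussian_filter(y, window_pts = 13)) <= var(y)
  })
  expect_true(all(reduced))
})

test_that("smoothing leaves already-smooth reference trajectories nearly unchanged", {
  net <- linear_network()
  tc <- simulate_timecourse(net, linear_params(), c(x1 = 1.35), n_points = 50)
  sm <- smooth_collapse(tc, fraction = 0.25)
  rel <- abs(sm$conc - tc$conc) / abs(tc$conc)
  expect_lt(max(rel), 0.05)
})

test_that("noisy pipeline provenance flags follow subsample-noise-collapse order", {
  net <- linear_network()
  tc <- simulate_timecourse(net, linear_params(), c(x1 = 0.5), n_points = 451)
  sub <- subsample_timecourse(tc, 15)
  noisy <- add_noise(sub, cov = 0.05, replicates = 3, seed = 1)
  expect_true(noisy$noise_applied)
  expect_false(noisy$collapsed)
  coll <- median_collapse(noisy)
  expect_true(coll$collapsed)
  expect_identical(coll$replicates, 1L)
  # noise must be applied to a single-replicate course only
  expect_error(add_noise(noisy, cov = 0.05), "single-replicate")
})
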