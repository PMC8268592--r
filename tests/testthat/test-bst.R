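test_that("sampled parameters respect the stated ranges and signs", {
  net <- reference_network("bigger")
  for (seed in 1:5) {
    p <- sample_bst_parameters(net, seed = seed)
    for (r in net$reactions) {
      pr <- p[[r$id]]
      if (r$constant) {
        expect_true(pr$value >= 0.1 && pr$value <= 1)
      } else {
        expect_true(pr$k >= 0.1 && pr$k <= 1)
        pos <- names(r$controllers)[r$controllers > 0]
        neg <- names(r$controllers)[r$controllers < 0]
        expect_true(all(pr$g[pos] >= 0.1 & pr$g[pos] <= 1))
        expect_true(all(pr$g[neg] >= -1 & pr$g[neg] <= -0.1))
      }
    }
  }
  expect_identical(sample_bst_parameters(net, seed = 99),
                   sample_bst_parameters(net, seed = 99))
})

test_that("power-law flux evaluation matches hand calculation", {
  r <- list(id = "v", substrate = "a", products = "b", constant = FALSE,
            controllers = c(a = 1))
  expect_equal(
    evaluate_flux(r, list(constant = FALSE, k = 0.5, g = c(a = 1)), c(a = 2)),
    1.0)
  r2 <- list(id = "v", substrate = "a", products = character(),
             constant = FALSE, controllers = c(a = 1, b = -1))
  # 1 * 2^0.5 * 4^-0.5
  expect_equal(
    evaluate_flux(r2, list(constant = FALSE, k = 1, g = c(a = 0.5, b = -0.5)),
                  c(a = 2, b = 4)),
    0.70711, tolerance = 1e-5)
  # zero exponent: flux independent of that controller
  p0 <- list(constant = FALSE, k = 2, g = c(a = 1, b = 0))
  expect_equal(evaluate_flux(r2, p0, c(a = 3, b = 10)),
               evaluate_flux(r2, p0, c(a = 3, b = 0.01)))
  # constant reactions ignore concentrations
  expect_equal(evaluate_flux(r, list(constant = TRUE, value = 0.3), c(a = 7)),
               0.3)
  # nonpositive concentration under a fractional exponent is a domain error
  expect_error(
    evaluate_flux(r2, list(constant = FALSE, k = 1, g = c(a = 0.5, b = -0.5)),
                  c(a = -1, b = 4)),
    "nonpositive")
})

test_that("simulation reproduces the closed-form linear birth-death solution", {
  net <- linear_network()
  influx <- 0.6; k <- 0.4; x0 <- 0.25
  tc <- simulate_timecourse(net, linear_params(influx, k),
                            c(x1 = x0), horizon = 10, n_points = 101)
  analytic <- influx / k + (x0 - influx / k) * exp(-k * tc$times)
  expect_equal(tc$conc["x1", , 1], analytic, tolerance = 1e-6,
               ignore_attr = TRUE)
  # stored fluxes are self-consistent with stored concentrations
  expect_equal(tc$flux["v2", , 1], k * tc$conc["x1", , 1],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(tc$flux["v1", , 1] == influx))
})

test_that("stored fluxes equal pointwise power-law evaluation of stored concentrations", {
  net <- reference_network("smaller")
  sys <- sample_test_system(net, scour_config(n_timecourses = 2L), seed = 3)
  for (tc in sys$test_tcs) {
    for (ti in c(1, 10, 25, 50)) {
      x <- tc$conc[, ti, 1]
      for (r in net$reactions) {
        expect_equal(unname(tc$flux[r$id, ti, 1]),
                     evaluate_flux(r, sys$params[[r$id]], x),
                     tolerance = 1e-9)
      }
    }
    expect_true(all(tc$conc > 0))
    expect_true(all(tc$flux > 0))
  }
})

test_that("admissible draws keep concentrations positive across seeds", {
  net <- reference_network("smaller")
  cfg <- scour_config(n_timecourses = 3L)
  for (seed in 1:4) {
    sys <- sample_test_system(net, cfg, seed = seed)
    mins <- vapply(sys$test_tcs, function(tc) min(tc$conc), numeric(1))
    expect_true(all(mins > 0))
  }
})

test_that("tightening the integration tolerance leaves trajectories unchanged", {
  net <- linear_network()
  p <- linear_params()
  tc1 <- simulate_timecourse(net, p, c(x1 = 0.5), n_points = 51)
  # independent verification at much tighter tolerance via deSolve directly
  ref <- deSolve::lsoda(
    y = c(x1 = 0.5), times = tc1$times,
    func = function(t, x, parms) list(0.6 - 0.4 * x), parms = NULL,
    rtol = 1e-11, atol = 1e-13)
  expect_equal(tc1$conc["x1", , 1], ref[, "x1"], tolerance = 1e-6,
               ignore_attr = TRUE)
})
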