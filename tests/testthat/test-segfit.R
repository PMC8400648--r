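# the break-point regression model

test_that("noiseless two-line data is recovered to 1e-3", {
  x <- seq(200, 500, by = 10)
  y <- ifelse(x < 300, 1.5 - 1e-4 * (x - 300), 1.5 - 4e-4 * (x - 300))
  fit <- segfit(x, y)
  expect_equal(coef(fit)[["breakpoint"]], 300, tolerance = 1e-3)
  expect_equal(coef(fit)[["slope_left"]], -1e-4, tolerance = 1e-4)
  expect_equal(coef(fit)[["slope_right"]], -4e-4, tolerance = 1e-4)
  expect_false(fit$no_break)
  expect_equal(unname(predict(fit, 250)), 1.5 - 1e-4 * (250 - 300),
               tolerance = 1e-6)
})

test_that("a single straight line raises the no-break flag", {
  set.seed(5)
  x <- seq(200, 500, by = 10)
  y <- 2 - 3e-4 * x + stats::rnorm(length(x), 0, 1e-3)
  fit <- segfit(x, y)
  expect_true(fit$no_break)
})

test_that("input contracts are enforced", {
  x <- seq(1, 10)
  expect_error(segfit(x, x, min_points_per_side = 2), ">= 3")
  expect_error(segfit(x[1:5], x[1:5]), "at least 6")
  expect_error(segfit(x, seq_len(9)), "equal length")
  expect_error(segfit(x, x, weights = rep(0, 10)), "positive")
})

test_that("hinge optimum matches the exhaustive knot-grid oracle", {
  for (s in 1:8) {
    sc <- generate_thermal_scan(scan_truth(), seed = 400 + s)
    w <- 1 / sc$rho_sd^2
    fit <- segfit(sc$T, sc$rho, weights = w)
    oracle <- brute_force_hinge(sc$T, sc$rho, w, step = 0.1)
    expect_lt(abs(coef(fit)[["breakpoint"]] - oracle$breakpoint), 0.1 + 1e-9)
    wD <- 1 / sc$D_sd^2
    fitD <- segfit(sc$T, sc$D, weights = wD)
    oracleD <- brute_force_hinge(sc$T, sc$D, wD, step = 0.1)
    expect_lt(abs(coef(fitD)[["breakpoint"]] - oracleD$breakpoint), 0.1 + 1e-9)
  }
})

test_that("break point is invariant to y shifts and positive scaling", {
  sc <- generate_thermal_scan(scan_truth(), seed = 77)
  b0 <- coef(segfit(sc$T, sc$rho))[["breakpoint"]]
  b_shift <- coef(segfit(sc$T, sc$rho + 5))[["breakpoint"]]
  expect_equal(b_shift, b0, tolerance = 1e-6)
  d0 <- coef(segfit(sc$T, sc$D))[["breakpoint"]]
  d_scale <- coef(segfit(sc$T, sc$D * 1e4))[["breakpoint"]]
  expect_equal(d_scale, d0, tolerance = 1e-6)
})

test_that("delta-method uncertainty matches the analytic hand fixture", {
  # two lines y = a_i + b_i x with var(a1) = 1e-4 only:
  # x* = (a1 - a2)/(b2 - b1); sd = |dx*/da1| * 1e-2 = 1e-2 / 0.01 = 1
  res <- intersection_sd(a1 = 2, b1 = -0.01, a2 = 5, b2 = -0.02,
                         vcov1 = diag(c(1e-4, 0)), vcov2 = diag(c(0, 0)))
  expect_equal(res$x_star, (2 - 5) / (-0.01))
  expect_equal(res$sd, 1.0)
  # zero parameter variance -> zero sd
  expect_equal(intersection_sd(2, -0.01, 5, -0.02)$sd, 0)
  # doubling all parameter sds (4x covariances) doubles sd(x*)
  v1 <- matrix(c(1e-4, 2e-6, 2e-6, 1e-6), 2)
  v2 <- matrix(c(4e-4, -1e-6, -1e-6, 2e-6), 2)
  s1 <- intersection_sd(2, -0.01, 5, -0.02, v1, v2)$sd
  s2 <- intersection_sd(2, -0.01, 5, -0.02, 4 * v1, 4 * v2)$sd
  expect_equal(s2, 2 * s1)
  expect_error(intersection_sd(1, 1, 2, 1), "parallel")
})

test_that("hinge and two-line propagated uncertainties agree within 10 percent", {
  ok <- 0
  for (s in 1:6) {
    sc <- generate_thermal_scan(scan_truth(), seed = 500 + s)
    sd_h <- propagate_uncertainty(segfit(sc$T, sc$rho, weights = 1 / sc$rho_sd^2))
    sd_t <- propagate_uncertainty(segfit(sc$T, sc$rho, weights = 1 / sc$rho_sd^2,
                                         method = "twolines"))
    if (is.finite(sd_h) && is.finite(sd_t) &&
        abs(sd_h - sd_t) / sd_h < 0.10) ok <- ok + 1
  }
  expect_gte(ok, 4)  # parameterizations differ; most fixtures must agree
})

test_that("twolines places the break at the line intersection", {
  x <- seq(200, 500, by = 10)
  y <- ifelse(x <= 340, 2 + 0.001 * x, 1.32 + 0.003 * x)
  fit <- segfit(x, y, method = "twolines")
  # intersection of the two generating lines: 2+0.001x = 1.32+0.003x -> x = 340
  expect_equal(coef(fit)[["breakpoint"]], 340, tolerance = 0.5)
  expect_equal(coef(fit)[["slope_left"]], 0.001, tolerance = 1e-4)
  expect_equal(coef(fit)[["slope_right"]], 0.003, tolerance = 1e-4)
})

test_that("simulate() reproduces the fitted dispersion", {
  sc <- generate_thermal_scan(scan_truth(), seed = 9)
  fit <- segfit(sc$T, sc$rho)
  sims <- simulate(fit, nsim = 200, seed = 1)
  resid_sd <- apply(sims, 2, function(y) stats::sd(y - fitted(fit)))
  expect_equal(mean(resid_sd), fit$sigma, tolerance = 0.15)
})
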