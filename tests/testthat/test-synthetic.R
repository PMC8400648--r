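# synthetic generators: known dynamics, known break points

test_that("Brownian generator is seed-deterministic and freezes at D = 0", {
  a <- generate_brownian_trajectory(10, 0.05, 1, 20, 10, seed = 42)
  b <- generate_brownian_trajectory(10, 0.05, 1, 20, 10, seed = 42)
  expect_identical(a$coords, b$coords)

  frozen <- generate_brownian_trajectory(5, 0, 1, 10, 10, seed = 1)
  for (fi in 2:10)
    expect_equal(frozen$coords[fi, , ], frozen$coords[1, , ])
  expect_error(generate_brownian_trajectory(5, -1, 1, 10, 10, seed = 1),
               "non-negative")
})

test_that("Brownian increments match the 2 D dt variance law", {
  D <- 0.3; dt <- 2
  tr <- generate_brownian_trajectory(500, D, dt, 201, 50, seed = 7)
  inc <- apply(tr$ground_truth$unwrapped, c(2, 3), diff)
  n_inc <- length(inc)
  expect_gt(n_inc, 1e5)
  v <- mean(inc^2)
  # chi-square standard error of a variance estimate: var * sqrt(2/n)
  se <- 2 * D * dt * sqrt(2 / n_inc)
  expect_lt(abs(v - 2 * D * dt), 3 * se)
})

test_that("ensemble MSD slope over 6 recovers the generator's D", {
  D <- 0.5
  tr <- generate_brownian_trajectory(1000, D, 1, 500, 60, seed = 5)
  # direct oracle: displacement from the first frame of the true paths
  u <- tr$ground_truth$unwrapped
  lags <- c(100, 250, 499)
  for (lag in lags) {
    d <- u[1 + lag, , ] - u[1, , ]
    expect_equal(mean(rowSums(d^2)) / (6 * lag), D, tolerance = 0.05)
  }
})

test_that("caged generator plateaus at its stationary closed form", {
  r_cage <- 1.5
  tr <- generate_caged_trajectory(400, r_cage, 1, 400, 40, seed = 9)
  u <- tr$ground_truth$unwrapped
  # long-lag MSD of the OU walk -> 2 * 3 * var_axis = 2 * cage_radius^2
  lag <- 300
  d <- u[1 + lag, , ] - u[1, , ]
  expect_equal(mean(rowSums(d^2)), 2 * r_cage^2, tolerance = 0.2)
  expect_equal(tr$ground_truth$msd_plateau, 2 * r_cage^2)

  tiny <- generate_caged_trajectory(20, 1e-6, 1, 50, 40, seed = 2)
  spread <- apply(tiny$ground_truth$unwrapped, c(2, 3), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-4)

  expect_error(generate_caged_trajectory(5, -1, 1, 10, 40, seed = 1), "positive")
  expect_error(generate_caged_trajectory(5, 20, 1, 10, 40, seed = 1), "box/4")
})

test_that("caged trajectories fit as statistically zero diffusivity", {
  tr <- generate_caged_trajectory(300, 1.2, 1, 400, 40, seed = 21)
  msd <- compute_msd(unwrap_trajectory(tr))
  fit <- fit_diffusivity(msd, window = c(0.5, 1) * max(msd$lag))
  expect_true(fit$subdiffusive)
  # indistinguishable from zero at the configured tolerance
  expect_lt(fit$D, stats::qnorm(0.975) * fit$D_sd)
})

test_that("thermal-scan generator follows its two-segment laws exactly at zero noise", {
  tr <- scan_truth(true_Tg = 340, rho_noise_sd = 0, D_noise_frac = 0)
  sc <- generate_thermal_scan(tr, seed = 1)
  glass <- sc$T < 340
  rho_expect <- ifelse(glass, tr$rho_at_Tg + tr$glass_slope * (sc$T - 340),
                       tr$rho_at_Tg + tr$liquid_slope * (sc$T - 340))
  expect_equal(sc$rho, rho_expect)
  expect_equal(sc$D[glass], rep(tr$D_floor, sum(glass)))
  expect_equal(sc$D[!glass], tr$D_floor + tr$D_slope * (sc$T[!glass] - 340))
})

test_that("scan generator validates its grid and keeps truth across seeds", {
  expect_error(scan_truth(true_Tg = 600), "interior")
  expect_error(scan_truth(glass_slope = -9e-4, liquid_slope = -1e-4),
               "more negative")
  expect_error(generate_thermal_scan(
    scan_truth(true_Tg = 210, T_grid = seq(200, 500, 10))), "3 grid points")

  a <- generate_thermal_scan(scan_truth(), seed = 1)
  b <- generate_thermal_scan(scan_truth(), seed = 2)
  expect_false(identical(a$rho, b$rho))
  expect_identical(attr(a, "truth"), attr(b, "truth"))
})

test_that("arrhenius diffusivity option is continuous at the break", {
  tr <- scan_truth(D_law = "arrhenius", rho_noise_sd = 0, D_noise_frac = 0)
  sc <- generate_thermal_scan(tr, seed = 1)
  at_tg <- tr$D_scale * exp(-tr$E_act / (8.31446e-3 * tr$true_Tg))
  expect_equal(at_tg, tr$D_floor, tolerance = 1e-10)
  expect_true(all(diff(sc$D[sc$T >= tr$true_Tg]) > 0))
})
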