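# unwrapping, centre reduction, MSD, Einstein fits

test_that("unwrap applies minimum image across boundaries", {
  # no crossing: identity
  path <- cbind(seq(2, 4, length.out = 5), 5, 5)
  tr <- path_trajectory(path, box = 10, wrapped = TRUE)
  tr$wrapped <- TRUE
  expect_equal(unwrap_trajectory(tr)$coords, tr$coords)

  # crossing 9.9 -> 0.1 must unwrap to +0.2, not -9.8
  tr2 <- path_trajectory(cbind(c(9.9, 0.1), 5, 5), box = 10, wrapped = TRUE)
  out <- unwrap_trajectory(tr2)
  expect_equal(out$coords[2, 1, 1] - out$coords[1, 1, 1], 0.2)
  expect_false(out$wrapped)

  # a jump of exactly L/2 is ambiguous -> error
  tr3 <- path_trajectory(cbind(c(0, 5), 1, 1), box = 10, wrapped = TRUE)
  expect_error(unwrap_trajectory(tr3), "undersampled")
})

test_that("unwrap recovers the Brownian generator's true paths", {
  tr <- generate_brownian_trajectory(50, 0.02, 1, 100, 8, seed = 13)
  un <- unwrap_trajectory(tr)
  truth <- tr$ground_truth$unwrapped
  # continuous paths agree up to the wrap offset of the first frame
  offset <- truth[1, , ] - un$coords[1, , ]
  for (fi in c(2, 50, 100))
    expect_equal(un$coords[fi, , ] + offset, truth[fi, , ], tolerance = 1e-9)
})

test_that("molecular centres are mass-weighted and translation-equivariant", {
  top <- topology(1:4, c("C", "C", "O", "O"), mass = c(1, 1, 16, 16),
                  molecule_id = c(1, 1, 2, 2), molecule_name = c("m", "m", "n", "n"))
  co <- array(0, c(1, 4, 3))
  co[1, 1, ] <- c(0, 0, 0); co[1, 2, ] <- c(2, 0, 0)
  co[1, 3, ] <- c(5, 5, 5); co[1, 4, ] <- c(5, 7, 5)
  tr <- trajectory(co, rep(50, 3), 0, topology = top, wrapped = FALSE)
  cen <- molecular_centers(tr)
  expect_equal(n_atoms(cen), 2)
  expect_equal(cen$coords[1, 1, ], c(1, 0, 0))
  expect_equal(cen$coords[1, 2, ], c(5, 6, 5))

  shifted <- tr
  shifted$coords <- tr$coords + 5
  cen2 <- molecular_centers(shifted)
  expect_equal(cen2$coords, cen$coords + 5)

  # single-atom molecules: identity
  tr1 <- generate_brownian_trajectory(6, 0.01, 1, 5, 10, seed = 1)
  un <- unwrap_trajectory(tr1)
  expect_equal(molecular_centers(un)$coords, un$coords)

  expect_error(molecular_centers(tr1), "unwrapped")
})

test_that("MSD is zero for static input and exact for uniform drift", {
  static <- path_trajectory(matrix(rep(c(1, 2, 3), 10), 10, 3, byrow = TRUE))
  expect_true(all(compute_msd(static)$msd == 0))

  v <- 0.01
  drift <- path_trajectory(cbind(v * (0:99), 0, 0))
  msd <- compute_msd(drift, max_lag_fraction = 1)
  expect_equal(msd$msd, (v * msd$lag)^2)
  expect_equal(msd$n_origins, 99:1)
})

test_that("MSD is invariant under translation and particle relabeling", {
  tr <- unwrap_trajectory(generate_brownian_trajectory(20, 0.05, 1, 60, 12, seed = 3))
  m0 <- compute_msd(tr)
  tr_shift <- tr
  tr_shift$coords <- tr$coords + 7.7
  expect_equal(compute_msd(tr_shift)$msd, m0$msd)
  perm <- sample(20)
  tr_perm <- tr
  tr_perm$coords <- tr$coords[, perm, , drop = FALSE]
  expect_equal(compute_msd(tr_perm)$msd, m0$msd)
})

test_that("species selection requires topology entries that exist", {
  tr <- unwrap_trajectory(generate_brownian_trajectory(5, 0.01, 1, 10, 10, seed = 1))
  expect_error(compute_msd(tr, species = "ghost"), "no sites")
})

test_that("Einstein fit returns slope/6 and flags flat curves", {
  msd <- structure(data.frame(lag = 1:100, msd = 0.6 * (1:100),
                              n_origins = 100:1),
                   class = c("msd_curve", "data.frame"))
  fit <- fit_diffusivity(msd, window = c(10, 90))
  expect_equal(fit$D, 0.1, tolerance = 1e-12)
  expect_false(fit$subdiffusive)
  expect_equal(fit$D_m2s, fit$D * 1e-5)

  flat <- structure(data.frame(lag = 1:50, msd = rep(2, 50), n_origins = 50:1),
                    class = c("msd_curve", "data.frame"))
  ffit <- fit_diffusivity(flat, window = c(5, 45))
  expect_equal(ffit$D, 0)
  expect_true(ffit$subdiffusive)

  expect_error(fit_diffusivity(msd, window = c(90, 200)), "window")
})

test_that("fitted D on 1000-particle Brownian input is within 5 percent", {
  D <- 0.5
  tr <- generate_brownian_trajectory(1000, D, 1, 300, 60, seed = 17)
  msd <- compute_msd(unwrap_trajectory(tr))
  fit <- fit_diffusivity(msd)
  expect_equal(fit$D, D, tolerance = 0.05)
  expect_false(fit$subdiffusive)
})

test_that("fitted D is unbiased over seeds within two standard errors", {
  D <- 0.2
  ds <- vapply(1:20, function(s) {
    tr <- generate_brownian_trajectory(80, D, 1, 120, 30, seed = 100 + s)
    fit_diffusivity(compute_msd(unwrap_trajectory(tr)))$D
  }, numeric(1))
  se <- stats::sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - D), 2 * se + 1e-12)
})

test_that("diffusion exponent separates Fickian from caged dynamics", {
  dif <- generate_brownian_trajectory(200, 0.1, 1, 300, 30, seed = 4)
  caged <- generate_caged_trajectory(200, 1.0, 1, 300, 30, seed = 4)
  a_dif <- msd_exponent(compute_msd(unwrap_trajectory(dif)))
  a_caged <- msd_exponent(compute_msd(unwrap_trajectory(caged)),
                          window = c(0.5, 1) * 149)
  expect_gt(a_dif, 0.8)
  expect_lt(a_caged, 0.2)
})
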