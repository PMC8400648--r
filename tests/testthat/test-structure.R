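# densities, volumes, RDF, hydrogen-bond contacts

test_that("mass density reproduces the hand-converted value", {
  # 100 atoms of 18 u in a (10 A)^3 box:
  # 1800 u * 1.66054e-24 g / 1e-21 cm^3 = 2.989 g/cm^3
  top <- topology(1:100, rep("O", 100), mass = rep(18, 100),
                  molecule_id = 1:100, molecule_name = "w")
  co <- array(stats::runif(100 * 3, 0, 10), c(1, 100, 3))
  tr <- trajectory(co, rep(10, 3), 0, topology = top)
  sp <- mass_density(tr)
  expect_equal(sp$rho, 2.989, tolerance = 1e-3)

  # doubling the masses doubles the density
  sp2 <- mass_density(tr, masses = rep(36, 100))
  expect_equal(sp2$rho, 2 * sp$rho)

  # constant volume -> zero spread
  co2 <- array(stats::runif(3 * 100 * 3, 0, 10), c(3, 100, 3))
  tr3 <- trajectory(co2, rep(10, 3), 0:2, topology = top)
  expect_equal(mass_density(tr3)$rho_sd, 0)
})

test_that("molar and excess volumes follow their defining arithmetic", {
  expect_equal(molar_volume(1.0, 100), 100)
  expect_equal(molar_volume(2.0, 100), 50)
  expect_equal(molar_volume(1.5, c(100, 200), c(0.5, 0.5)), 150 / 1.5)

  ex <- excess_volume(100, c(0.5, 0.5), c(100, 100))
  expect_equal(ex$V_E, 0)
  ex2 <- excess_volume(99, c(0.5, 0.5), c(100, 100))
  expect_equal(ex2$V_E, -1)
  expect_equal(ex2$percent, 100 * (-1) / 99, tolerance = 1e-12)
  ex3 <- excess_volume(97, c(1, 0), c(100, 120))
  expect_equal(ex3$V_E, -3)
  expect_error(excess_volume(100, c(0.6, 0.5), c(100, 100)), "sum to 1")
})

test_that("two isolated particles give a single nonzero RDF bin", {
  co <- array(0, c(1, 2, 3))
  co[1, 2, ] <- c(5, 0, 0)
  tr <- trajectory(co, rep(40, 3), 0, topology = point_topology(2))
  rdf <- compute_rdf(tr, r_max = 10, bin_width = 0.1)
  nz <- which(rdf$g > 0)
  expect_length(nz, 1)
  expect_equal(rdf$r[nz], 5.05, tolerance = 0.1)
})

test_that("uniform-random configurations give g(r) = 1 within counting noise", {
  set.seed(31)
  n <- 800; L <- 20
  co <- array(stats::runif(n * 3, 0, L), c(1, n, 3))
  tr <- trajectory(co, rep(L, 3), 0, topology = point_topology(n))
  rdf <- compute_rdf(tr, r_max = 8, bin_width = 0.25)
  # Poisson counting: sd(g) ~ g / sqrt(expected count per bin)
  shell <- 4 / 3 * pi * ((rdf$r + 0.125)^3 - (rdf$r - 0.125)^3)
  expected <- n * (n - 1) / 2 * shell / L^3
  z <- (rdf$g - 1) * sqrt(expected)
  keep <- expected > 30
  expect_gt(mean(abs(z[keep]) < 3), 0.97)
  expect_true(all(abs(z[keep]) < 5))
})

test_that("simple-cubic lattice: first peak at the spacing, coordination 6", {
  a <- 2.0; per <- 6
  g <- (seq_len(per) - 1) * a
  pos <- as.matrix(expand.grid(g, g, g))
  n <- nrow(pos)
  co <- array(0, c(1, n, 3)); co[1, , ] <- pos
  tr <- trajectory(co, rep(per * a, 3), 0, topology = point_topology(n))
  rdf <- compute_rdf(tr, r_max = 5, bin_width = 0.05)
  pk <- first_peak(rdf, range = c(1, 3))
  expect_true(pk$is_peak)
  expect_equal(pk$r_peak, a, tolerance = 0.05)
  # integrate through the first shell: 6 nearest neighbours
  expect_equal(coordination_number(rdf, r_cut = 2.5), 6, tolerance = 0.01)
})

test_that("RDF is invariant under periodic shifts of all coordinates", {
  tr <- generate_brownian_trajectory(100, 0.05, 1, 3, 15, seed = 8)
  r0 <- compute_rdf(tr, r_max = 7, bin_width = 0.2)
  tr2 <- tr
  tr2$coords <- (tr$coords + 9.3) %% 15
  r1 <- compute_rdf(tr2, r_max = 7, bin_width = 0.2)
  expect_equal(r1$g, r0$g, tolerance = 1e-12)
})

test_that("RDF rejects r_max beyond the minimum-image radius and empty selections", {
  tr <- generate_brownian_trajectory(10, 0.05, 1, 2, 10, seed = 1)
  expect_error(compute_rdf(tr, r_max = 6), "half the smallest")
  expect_error(compute_rdf(tr, site_pair = c("Q", "P"), r_max = 4), "empty site")
})

test_that("first_peak refines constructed bumps and flags monotone curves", {
  r <- seq(0.025, 5, by = 0.05)
  bump <- function(mu) exp(-(r - mu)^2 / (2 * 0.09))
  mk <- function(g) structure(data.frame(r = r, g = g, count = g),
                              bin_width = 0.05, site_pair = c("a", "b"),
                              class = c("rdf_curve", "data.frame"))
  pk <- first_peak(mk(bump(1.75)), range = c(0.5, 3))
  expect_equal(pk$r_peak, 1.75, tolerance = 0.025)

  two <- mk(bump(1.5) + 1.4 * bump(2.25))
  expect_equal(first_peak(two, range = c(0.5, 3))$r_peak, 2.25, tolerance = 0.03)

  mono <- mk(r)  # strictly increasing: boundary maximum is not a peak
  expect_false(first_peak(mono, range = c(1, 3))$is_peak)
  zero <- mk(rep(0, length(r)))
  expect_false(first_peak(zero)$is_peak)
  expect_equal(first_peak(zero)$amplitude, 0)
})

test_that("hydrogen-bond counting honors cutoff and excludes intramolecular pairs", {
  top <- topology(1:4, c("H_d", "O_a", "H_d", "O_a"),
                  mass = c(1, 16, 1, 16),
                  molecule_id = c(1, 1, 2, 2), molecule_name = "m",
                  donor = c(TRUE, FALSE, TRUE, FALSE),
                  acceptor = c(FALSE, TRUE, FALSE, TRUE))
  co <- array(0, c(1, 4, 3))
  co[1, 1, ] <- c(0, 0, 0)     # donor H, mol 1
  co[1, 2, ] <- c(0.9, 0, 0)   # acceptor, mol 1 (intramolecular: excluded)
  co[1, 3, ] <- c(10, 0, 0)    # donor H, mol 2
  co[1, 4, ] <- c(1.8, 0, 0)   # acceptor, mol 2; 1.8 A from donor 1
  tr <- trajectory(co, rep(30, 3), 0, topology = top)
  cs <- hbond_contacts(tr, cutoff = 2.5)
  expect_equal(cs$n_contacts, 1)
  expect_equal(cs$mean_per_donor, 0.5)

  co[1, 4, ] <- c(3.0, 0, 0)   # beyond cutoff
  tr2 <- trajectory(co, rep(30, 3), 0, topology = top)
  expect_equal(hbond_contacts(tr2, cutoff = 2.5)$n_contacts, 0)
  expect_error(hbond_contacts(tr2, cutoff = -1), "positive")
})

test_that("lattice contact counts equal the brute-force enumeration", {
  # 4x4x4 alternating donor/acceptor lattice, spacing 2 A
  a <- 2.0; per <- 4
  g <- (seq_len(per) - 1) * a
  pos <- as.matrix(expand.grid(g, g, g))
  n <- nrow(pos)
  parity <- (rowSums(pos / a) %% 2) == 0
  top <- topology(1:n, ifelse(parity, "H_d", "O_a"), mass = rep(1, n),
                  molecule_id = 1:n, molecule_name = "site",
                  donor = parity, acceptor = !parity)
  co <- array(0, c(1, n, 3)); co[1, , ] <- pos
  tr <- trajectory(co, rep(per * a, 3), 0, topology = top)
  for (cutoff in c(2.1, 3.0, 3.6)) {
    got <- hbond_contacts(tr, cutoff = cutoff)$n_contacts
    want <- brute_force_hbonds(pos, rep(per * a, 3), 1:n, parity, !parity, cutoff)
    expect_equal(got, want)
  }
})
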