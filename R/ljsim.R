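#' Parameters of the toy binary LJ glass former
#'
#' A canonical 80:20 binary Lennard-Jones mixture with non-additive cross
#' interaction — a desk-scale system that vitrifies on cooling instead of
#' crystallising.  Reduced units throughout (species A mass 1, sigma_AA 1,
#' eps_AA 1); the conversion to laboratory units is declared by
#' \code{\link{lj_units}}.
#'
#' @param n_A,n_B particle counts per species (> 0; total <= ~500 keeps
#'   desk-scale run times).
#' @param eps pair well depths \code{c(AA, AB, BB)}, reduced.
#' @param sigma pair diameters \code{c(AA, AB, BB)}, reduced.
#' @param mass species masses \code{c(A, B)}, reduced (the integrator
#'   assumes equal masses; unequal masses are rejected).
#' @param dt time step, reduced (> 0).
#' @param cutoff_factor cutoff radius as a multiple of the pair sigma;
#'   potential shifted to zero at the cutoff.
#' @param T_target,P_target thermostat/barostat set points, reduced.
#' @param tau_T,tau_P coupling times, reduced.
#' @param density initial number density, reduced.
#' @param seed integer seed (initial placement and velocities).
#' @return A list of class \code{"toy_system_params"}.
#' @export
toy_system_params <- function(n_A = 120, n_B = 30,
                              eps = c(AA = 1.0, AB = 1.5, BB = 0.5),
                              sigma = c(AA = 1.0, AB = 0.8, BB = 0.88),
                              mass = c(A = 1, B = 1),
                              dt = 0.002, cutoff_factor = 2.5,
                              T_target = 1.0, P_target = 1.0,
                              tau_T = 0.2, tau_P = 2.0,
                              density = 1.2, seed = 1) {
  if (n_A <= 0 || n_B <= 0) stop("particle counts must be positive")
  if (dt <= 0) stop("time step must be positive")
  if (length(eps) != 3 || length(sigma) != 3)
    stop("eps and sigma must give the AA, AB, BB pair values")
  if (mass[1] != mass[2])
    stop("the integrator assumes equal species masses")
  structure(list(n_A = as.integer(n_A), n_B = as.integer(n_B),
                 eps = unname(eps), sigma = unname(sigma),
                 mass = unname(mass), dt = dt,
                 cutoff_factor = cutoff_factor,
                 T_target = T_target, P_target = P_target,
                 tau_T = tau_T, tau_P = tau_P,
                 density = density, seed = as.integer(seed)),
            class = "toy_system_params")
}

#' Reduced-to-laboratory unit system for the toy LJ fluid
#'
#' Declares the mapping applied at the analysis boundary: an argon-like
#' parameterisation by default.  \code{sigma_A} converts reduced lengths
#' to \enc{Å}{A}, \code{epsilon_K} reduced temperature to K,
#' \code{mass_u} reduced mass to u; the derived time unit is
#' \eqn{\tau = \sigma \sqrt{m / \epsilon}} in fs.
#'
#' @param sigma_A length unit, \enc{Å}{A}.
#' @param epsilon_K energy unit over Boltzmann's constant, K.
#' @param mass_u mass unit, u.
#' @return List of class \code{"lj_units"} with conversion factors:
#'   \code{length_A}, \code{temp_K}, \code{mass_u}, \code{time_fs},
#'   \code{pressure_kPa}, \code{energy_kJmol}, \code{diffusivity_A2fs}.
#' @export
lj_units <- function(sigma_A = 3.405, epsilon_K = 119.8, mass_u = 39.948) {
  kB <- 1.380649e-23                     # J/K
  eps_J <- kB * epsilon_K
  m_kg <- mass_u * 1.66053906660e-27
  tau_s <- sigma_A * 1e-10 * sqrt(m_kg / eps_J)
  structure(list(
    length_A = sigma_A,
    temp_K = epsilon_K,
    mass_u = mass_u,
    time_fs = tau_s * 1e15,
    pressure_kPa = eps_J / (sigma_A * 1e-10)^3 / 1e3,
    energy_kJmol = eps_J * 6.02214076e23 / 1e3,
    diffusivity_A2fs = sigma_A^2 / (tau_s * 1e15)
  ), class = "lj_units")
}

# lattice or random initial placement, reduced units
.lj_init_coords <- function(n, L, sigma_min, init, max_tries = 200L) {
  if (init == "lattice") {
    per_side <- ceiling(n^(1 / 3))
    a <- L / per_side
    g <- (seq_len(per_side) - 0.5) * a
    grid <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(n), ]
    jitter <- matrix(stats::runif(3 * n, -0.05 * a, 0.05 * a), n, 3)
    grid + jitter
  } else {
    # random sequential placement with a repulsion threshold
    rmin <- 0.85 * sigma_min
    out <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        p <- stats::runif(3, 0, L)
        if (i == 1) { out[i, ] <- p; placed <- TRUE; break }
        d <- sweep(out[seq_len(i - 1), , drop = FALSE], 2, p)
        d <- d - round(d / L) * L
        if (min(sqrt(rowSums(d^2))) > rmin) { out[i, ] <- p; placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf(
          "could not place particle %d without overlap after %d tries (density too high for random init)",
          i, max_tries))
    }
    out
  }
}

#' Run the toy LJ glass former
#'
#' Velocity-Verlet MD of the binary mixture in NVE, NVT or NPT mode.
#' NVE (couplings off) conserves total energy and momentum; NVT holds the
#' mean temperature at the set point; NPT additionally holds the mean
#' pressure.  Thermo records are sampled per \code{sample_every} steps;
#' coordinate frames per \code{frame_every}.
#'
#' @param params a \code{\link{toy_system_params}}.
#' @param n_steps number of MD steps (>= 0).
#' @param mode \code{"NVE"}, \code{"NVT"} or \code{"NPT"}.
#' @param state optional continuation state (\code{$coords}, \code{$vel},
#'   \code{$L}, reduced) from a previous run; fresh initialisation when
#'   missing.
#' @param init \code{"lattice"} (jittered grid, default) or
#'   \code{"random"} (sequential placement with a repulsion threshold;
#'   errors after exhausting retries).
#' @param sample_every,frame_every sampling strides (steps); 0 disables
#'   frame storage.
#' @return List of class \code{"lj_run"}: \code{trajectory} (reduced
#'   units, species topology), \code{thermo} (\code{\link{thermo_series}}
#'   in reduced units plus reduced pressure/energy columns), \code{state}
#'   (for continuation), \code{params}.
#' @export
simulate_lj_glassformer <- function(params, n_steps,
                                    mode = c("NVT", "NVE", "NPT"),
                                    state = NULL, init = "lattice",
                                    sample_every = 10L, frame_every = 0L) {
  stopifnot(inherits(params, "toy_system_params"))
  mode <- match.arg(mode)
  n <- params$n_A + params$n_B
  type <- c(rep(0L, params$n_A), rep(1L, params$n_B))
  if (is.null(state)) {
    set.seed(params$seed)
    L <- (n / params$density)^(1 / 3)
    coords <- .lj_init_coords(n, L, min(params$sigma), init)
    vel <- matrix(stats::rnorm(3 * n, 0, sqrt(params$T_target)), n, 3)
    vel <- sweep(vel, 2, colMeans(vel))  # zero total momentum
  } else {
    coords <- state$coords; vel <- state$vel; L <- state$L
  }
  mode_i <- match(mode, c("NVE", "NVT", "NPT")) - 1L
  res <- .lj_run_cpp(coords, vel, type, L, as.integer(n_steps), params$dt,
                     params$eps, params$sigma, params$cutoff_factor,
                     mode_i, params$T_target, params$P_target,
                     params$tau_T, params$tau_P,
                     as.integer(sample_every), as.integer(frame_every))
  top <- topology(seq_len(n), ifelse(type == 0L, "A", "B"),
                  mass = rep(params$mass[1], n),
                  molecule_id = seq_len(n),
                  molecule_name = ifelse(type == 0L, "A", "B"))
  traj <- NULL
  if (frame_every > 0 && res$n_frames > 0) {
    nf <- res$n_frames
    co <- res$frames[seq_len(nf), , , drop = FALSE]
    traj <- trajectory(co, box = cbind(res$frame_box[seq_len(nf)],
                                       res$frame_box[seq_len(nf)],
                                       res$frame_box[seq_len(nf)]),
                       times = res$frame_step[seq_len(nf)] * params$dt,
                       topology = top, wrapped = TRUE, units = "reduced")
  }
  th <- res$thermo
  thermo <- if (nrow(th) > 0)
    thermo_series(time = th$step * params$dt, T = th$T, P = th$P, V = th$V,
                  U = th$U, H = th$H) else
    thermo_series(time = numeric(0), T = numeric(0))
  thermo$E <- if (nrow(th) > 0) th$E else numeric(0)
  structure(list(trajectory = traj, thermo = thermo,
                 state = list(coords = res$coords, vel = res$vel, L = res$L),
                 mode = mode, params = params),
            class = "lj_run")
}

#' Temperature-scan protocol on the toy glass former
#'
#' Runs the sequential cooling (or heating) protocol: at each grid
#' temperature, an equilibration then a production NPT run, the final
#' configuration carried to the next temperature.  Per temperature, the
#' mean density (with sd) comes from the production volumes and the
#' self-diffusivity (with sd) from an Einstein fit to the production MSD.
#' Results are converted to laboratory units through \code{units}.
#'
#' @param params a \code{\link{toy_system_params}}; its \code{T_target}
#'   is overridden along the grid.
#' @param T_grid temperatures in K (converted via \code{units}), sorted
#'   descending for cooling or ascending for heating.
#' @param equil_steps,prod_steps steps per phase (> 0).
#' @param units an \code{\link{lj_units}} declaration.
#' @param frame_every production frame stride for the MSD; by default
#'   chosen so about 250 frames are stored regardless of run length.
#' @return A \code{\link{thermal_scan}} (T ascending, K; rho in g/cm^3;
#'   D in \enc{Å}{A}^2/fs) with the per-temperature runs in
#'   \code{attr(, "runs")}.
#' @export
run_thermal_protocol <- function(params, T_grid, equil_steps, prod_steps,
                                 units = lj_units(), frame_every = NULL) {
  stopifnot(inherits(params, "toy_system_params"))
  if (equil_steps <= 0 || prod_steps <= 0) stop("step counts must be positive")
  if (is.null(frame_every)) frame_every <- max(1L, prod_steps %/% 250L)
  dT <- diff(T_grid)
  if (length(T_grid) > 1 && !(all(dT > 0) || all(dT < 0)))
    stop("T_grid must be sorted (cooling or heating)")
  n <- params$n_A + params$n_B
  mass_total_u <- n * units$mass_u
  state <- NULL
  rows <- vector("list", length(T_grid))
  for (i in seq_along(T_grid)) {
    T_red <- T_grid[i] / units$temp_K
    p <- params
    p$T_target <- T_red
    r <- tryCatch({
      eq <- simulate_lj_glassformer(p, equil_steps, mode = "NPT",
                                    state = state, sample_every = 0L)
      pr <- simulate_lj_glassformer(p, prod_steps, mode = "NPT",
                                    state = eq$state,
                                    sample_every = max(10L, prod_steps %/% 500L),
                                    frame_every = frame_every)
      pr
    }, error = function(e)
      stop(sprintf("thermal protocol failed at T = %g K: %s",
                   T_grid[i], conditionMessage(e)), call. = FALSE))
    state <- r$state
    V_red <- r$thermo$V
    V_A3 <- V_red * units$length_A^3
    rho <- mass_total_u * 1.66053906660e-24 / (V_A3 * 1e-24)
    # Einstein fit on the production trajectory, converted to A^2/fs
    tr <- r$trajectory
    tr$box <- tr$box * units$length_A
    tr$coords <- tr$coords * units$length_A
    tr$times <- tr$times * units$time_fs
    tr$units <- "real"
    dfit <- fit_diffusivity(compute_msd(unwrap_trajectory(tr)))
    rows[[i]] <- c(T = T_grid[i], rho = mean(rho), rho_sd = stats::sd(rho),
                   D = dfit$D, D_sd = dfit$D_sd)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- tab[order(tab$T), ]
  scan <- thermal_scan(tab$T, rho = tab$rho, rho_sd = tab$rho_sd,
                       D = tab$D, D_sd = tab$D_sd)
  attr(scan, "units") <- units
  scan
}
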