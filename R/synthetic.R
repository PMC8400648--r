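#' Brownian (freely diffusive) test trajectory
#'
#' Ideal liquid-regime dynamics: per-axis position increments are
#' independent zero-mean Gaussians with variance \eqn{2 D \Delta t}, so
#' the ensemble MSD is exactly \eqn{6 D \tau} in expectation.  Both the
#' wrapped coordinates (as an MD dump would hold) and the true unwrapped
#' paths are stored; the seed fully determines the output.
#'
#' @param n_particles number of particles.
#' @param true_D self-diffusivity, \enc{Å}{A}^2/fs (>= 0).
#' @param dt frame spacing, fs.
#' @param n_frames number of frames.
#' @param box cubic box edge, \enc{Å}{A}.
#' @param seed integer RNG seed.
#' @return A wrapped \code{\link{trajectory}} with single-atom "molecules"
#'   and \code{ground_truth = list(true_D, unwrapped)}.
#' @export
generate_brownian_trajectory <- function(n_particles, true_D, dt, n_frames,
                                         box, seed) {
  if (true_D < 0) stop("true_D must be non-negative")
  set.seed(seed)
  sd_step <- sqrt(2 * true_D * dt)
  unwrapped <- array(0, c(n_frames, n_particles, 3))
  unwrapped[1, , ] <- matrix(stats::runif(n_particles * 3, 0, box),
                             n_particles, 3)
  if (n_frames > 1) {
    for (fi in 2:n_frames) {
      step <- matrix(stats::rnorm(n_particles * 3, 0, sd_step), n_particles, 3)
      unwrapped[fi, , ] <- unwrapped[fi - 1, , ] + step
    }
  }
  top <- topology(seq_len(n_particles), rep("P", n_particles),
                  mass = rep(1, n_particles),
                  molecule_id = seq_len(n_particles),
                  molecule_name = rep("tracer", n_particles))
  trajectory(.wrap_coords(unwrapped, matrix(box, n_frames, 3)),
             box = rep(box, 3), times = (seq_len(n_frames) - 1) * dt,
             topology = top, wrapped = TRUE,
             ground_truth = list(true_D = true_D, unwrapped = unwrapped))
}

#' Caged (glassy) test trajectory
#'
#' Sub-diffusive reference dynamics: each particle performs a discrete
#' Ornstein--Uhlenbeck walk reverting to a fixed cage site,
#' \deqn{x_{t+1} = s + \phi (x_t - s) + \epsilon, \quad
#'       \epsilon \sim N(0, \sigma_\epsilon^2),}
#' with the stationary per-axis variance set to \code{cage_radius^2 / 3}
#' so the long-lag MSD plateaus at \eqn{2 \cdot cage\_radius^2}
#' (\eqn{MSD(\infty) = 2 \times 3 \sigma_{axis}^2}).
#'
#' @param n_particles number of particles.
#' @param cage_radius cage size, \enc{Å}{A} (> 0, < box/4).
#' @param dt frame spacing, fs.
#' @param n_frames number of frames.
#' @param box cubic box edge, \enc{Å}{A}.
#' @param seed integer RNG seed.
#' @param phi per-frame reversion factor in [0, 1). Default 0.8.
#' @return A wrapped \code{\link{trajectory}} with
#'   \code{ground_truth = list(msd_plateau, unwrapped)}.
#' @export
generate_caged_trajectory <- function(n_particles, cage_radius, dt, n_frames,
                                      box, seed, phi = 0.8) {
  if (cage_radius <= 0) stop("cage_radius must be positive")
  if (cage_radius >= box / 4) stop("cage_radius must be below box/4")
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  set.seed(seed)
  var_axis <- cage_radius^2 / 3
  sd_eps <- sqrt(var_axis * (1 - phi^2))
  sites <- matrix(stats::runif(n_particles * 3, 0, box), n_particles, 3)
  unwrapped <- array(0, c(n_frames, n_particles, 3))
  # start in the stationary distribution so the plateau holds at all lags
  unwrapped[1, , ] <- sites + matrix(stats::rnorm(n_particles * 3, 0, sqrt(var_axis)),
                                     n_particles, 3)
  if (n_frames > 1) {
    for (fi in 2:n_frames) {
      eps <- matrix(stats::rnorm(n_particles * 3, 0, sd_eps), n_particles, 3)
      unwrapped[fi, , ] <- sites + phi * (unwrapped[fi - 1, , ] - sites) + eps
    }
  }
  top <- topology(seq_len(n_particles), rep("P", n_particles),
                  mass = rep(1, n_particles),
                  molecule_id = seq_len(n_particles),
                  molecule_name = rep("tracer", n_particles))
  trajectory(.wrap_coords(unwrapped, matrix(box, n_frames, 3)),
             box = rep(box, 3), times = (seq_len(n_frames) - 1) * dt,
             topology = top, wrapped = TRUE,
             ground_truth = list(msd_plateau = 2 * cage_radius^2,
                                 unwrapped = unwrapped, phi = phi))
}

#' Ground truth of a synthetic thermal scan
#'
#' Parameters of the two-regime laws a generated scan follows: a
#' continuous piecewise-linear density with a slope change at the true Tg
#' (the liquid branch steeper — larger expansion above Tg), and a
#' diffusivity that sits at a small constant floor in the glass and rises
#' in an activation (Arrhenius) fashion above Tg.
#'
#' @param true_Tg glass transition, K; must be interior to \code{T_grid}.
#' @param T_grid temperature grid, K (default 200--500 K in 10 K steps,
#'   the scan protocol the analysis is designed around).
#' @param rho_at_Tg density at the break, g/cm^3.
#' @param glass_slope,liquid_slope density slopes, g/cm^3/K
#'   (liquid more negative).
#' @param D_floor glass-branch diffusivity floor, \enc{Å}{A}^2/fs.
#' @param D_law liquid-branch diffusivity law: \code{"linear"} (default)
#'   rises linearly from the floor at Tg with slope \code{D_slope} — the
#'   piecewise form a linear-scale trend-shift fit is consistent for;
#'   \code{"arrhenius"} uses the activation law
#'   \code{D = D_scale * exp(-E_act/(R T))} anchored to the floor at Tg,
#'   which is convex in T and biases a linear-scale hinge fit upward
#'   (kept for realism studies, not for estimator calibration).
#' @param D_slope linear-law slope above Tg, \enc{Å}{A}^2/fs/K.
#' @param D_scale,E_act activation-law parameters; \code{E_act} in kJ/mol,
#'   \code{D_scale} defaults to anchoring the law at the floor at Tg.
#' @param rho_noise_sd,D_noise_frac observation noise: absolute sd on
#'   density; fractional sd on diffusivity (floored at the floor's scale).
#' @return A list of class \code{"scan_truth"}.
#' @export
scan_truth <- function(true_Tg = 350, T_grid = seq(200, 500, by = 10),
                       rho_at_Tg = 1.20,
                       glass_slope = -2e-4, liquid_slope = -8e-4,
                       D_floor = 2e-7, D_law = c("linear", "arrhenius"),
                       D_slope = 2e-8, D_scale = NULL, E_act = 45,
                       rho_noise_sd = 1.5e-3, D_noise_frac = 0.15) {
  D_law <- match.arg(D_law)
  if (true_Tg <= min(T_grid) || true_Tg >= max(T_grid))
    stop("true_Tg must be interior to the temperature grid")
  if (liquid_slope >= glass_slope)
    stop("liquid density slope must be more negative than the glass slope")
  if (D_slope <= 0) stop("D_slope must be positive")
  if (is.null(D_scale))  # anchor the activation law to the floor at Tg
    D_scale <- D_floor * exp(E_act / (.R_KJ * true_Tg))
  structure(list(true_Tg = true_Tg, T_grid = T_grid, rho_at_Tg = rho_at_Tg,
                 glass_slope = glass_slope, liquid_slope = liquid_slope,
                 D_floor = D_floor, D_law = D_law, D_slope = D_slope,
                 D_scale = D_scale, E_act = E_act,
                 rho_noise_sd = rho_noise_sd, D_noise_frac = D_noise_frac),
            class = "scan_truth")
}

#' Generate a thermal scan with a known break point
#'
#' Evaluates the \code{\link{scan_truth}} laws on the grid and adds
#' Gaussian observation noise; the ground truth travels with the scan as
#' a sidecar attribute.  At least 3 grid points are required on each side
#' of the true Tg.
#'
#' @param truth a \code{\link{scan_truth}}.
#' @param seed integer RNG seed.
#' @return A \code{\link{thermal_scan}} with \code{rho}, \code{rho_sd},
#'   \code{D}, \code{D_sd} columns and the truth attached.
#' @export
generate_thermal_scan <- function(truth = scan_truth(), seed = 1) {
  stopifnot(inherits(truth, "scan_truth"))
  Tg <- truth$true_Tg
  Tv <- truth$T_grid
  if (sum(Tv < Tg) < 3 || sum(Tv > Tg) < 3)
    stop("need at least 3 grid points on each side of true_Tg")
  set.seed(seed)
  rho_true <- ifelse(Tv < Tg,
                     truth$rho_at_Tg + truth$glass_slope * (Tv - Tg),
                     truth$rho_at_Tg + truth$liquid_slope * (Tv - Tg))
  D_true <- if (truth$D_law == "linear") {
    ifelse(Tv < Tg, truth$D_floor, truth$D_floor + truth$D_slope * (Tv - Tg))
  } else {
    ifelse(Tv < Tg, truth$D_floor,
           truth$D_scale * exp(-truth$E_act / (.R_KJ * Tv)))
  }
  rho_sd <- rep(truth$rho_noise_sd, length(Tv))
  D_sd <- pmax(truth$D_noise_frac * D_true, truth$D_noise_frac * truth$D_floor)
  zero_noise <- truth$rho_noise_sd == 0 && truth$D_noise_frac == 0
  rho <- rho_true + if (zero_noise) 0 else stats::rnorm(length(Tv), 0, rho_sd)
  D <- D_true + if (zero_noise) 0 else stats::rnorm(length(Tv), 0, D_sd)
  thermal_scan(Tv, rho = rho,
               rho_sd = if (zero_noise) NULL else rho_sd,
               D = D,
               D_sd = if (zero_noise) NULL else D_sd,
               truth = truth)
}
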