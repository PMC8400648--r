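#' Unwrap periodic coordinates
#'
#' Accumulates minimum-image frame-to-frame displacements so particle paths
#' become continuous across box boundaries — the prerequisite of any MSD
#' analysis.  Fails loudly if any single-frame displacement reaches half a
#' box edge (undersampled trajectory: the image convention is ambiguous).
#'
#' @param traj a wrapped \code{\link{trajectory}}.
#' @return The trajectory with continuous coordinates and
#'   \code{wrapped = FALSE}.
#' @export
unwrap_trajectory <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (!traj$wrapped) return(traj)
  nf <- n_frames(traj)
  out <- traj$coords
  if (nf > 1) {
    for (fi in 2:nf) {
      L <- traj$box[fi, ]
      d <- traj$coords[fi, , , drop = FALSE] - traj$coords[fi - 1, , , drop = FALSE]
      d <- d[1, , , drop = TRUE]
      if (n_atoms(traj) == 1L) d <- matrix(d, 1, 3)
      for (k in 1:3) {
        if (any(abs(d[, k] - round(d[, k] / L[k]) * L[k]) >= L[k] / 2 - 1e-12))
          stop(sprintf(
            "displacement >= L/2 between frames %d and %d on axis %d: undersampled trajectory",
            fi - 1, fi, k))
        d[, k] <- d[, k] - round(d[, k] / L[k]) * L[k]
      }
      prev <- out[fi - 1, , , drop = TRUE]
      if (n_atoms(traj) == 1L) prev <- matrix(prev, 1, 3)
      out[fi, , ] <- prev + d
    }
  }
  traj$coords <- out
  traj$wrapped <- FALSE
  traj
}

#' Reduce a trajectory to molecular centres of mass
#'
#' One site per molecule: the mass-weighted centre of its atoms.  Removes
#' intramolecular vibration from subsequent displacement analysis.
#' Requires unwrapped coordinates (a centre of mass computed from wrapped
#' coordinates is meaningless when a molecule straddles a boundary).
#'
#' @param traj an unwrapped \code{\link{trajectory}} with a topology.
#' @param top optional \code{\link{topology}} overriding \code{traj$topology}.
#' @return A \code{\link{trajectory}} with one site per molecule; its
#'   topology has one row per molecule (mass = molecular mass).
#' @export
molecular_centers <- function(traj, top = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$wrapped) stop("molecular_centers requires an unwrapped trajectory")
  if (is.null(top)) top <- traj$topology
  if (is.null(top)) stop("a topology is required to group atoms into molecules")
  if (any(!is.finite(top$mass))) stop("topology contains atoms without a mass")
  mol_ids <- sort(unique(top$molecule_id))
  nmol <- length(mol_ids)
  nf <- n_frames(traj)
  centers <- array(0, c(nf, nmol, 3))
  w <- top$mass
  grp <- match(top$molecule_id, mol_ids)
  wsum <- as.numeric(tapply(w, grp, sum))
  for (k in 1:3) {
    # coords[, atom, k] weighted row-sums per molecule
    xk <- traj$coords[, , k, drop = FALSE][, , 1, drop = TRUE]
    if (nf == 1L) xk <- matrix(xk, 1)
    wx <- sweep(xk, 2, w, `*`)
    acc <- matrix(0, nf, nmol)
    for (g in seq_len(nmol)) {
      cols <- which(grp == g)
      acc[, g] <- if (length(cols) == 1L) wx[, cols] else rowSums(wx[, cols, drop = FALSE])
    }
    centers[, , k] <- sweep(acc, 2, wsum, `/`)
  }
  first <- !duplicated(top$molecule_id)
  mol_top <- topology(
    atom_id = seq_len(nmol),
    atom_type = paste0(top$molecule_name[first], "_com"),
    mass = wsum,
    molecule_id = seq_len(nmol),
    molecule_name = top$molecule_name[first]
  )
  trajectory(centers, traj$box, traj$times, topology = mol_top,
             wrapped = FALSE, ground_truth = traj$ground_truth,
             units = traj$units)
}

#' Mean-squared displacement
#'
#' Time-origin-averaged MSD per species:
#' \deqn{MSD(\tau) = \langle |r(t+\tau) - r(t)|^2 \rangle}
#' averaged over all particles of the species and all origins at the frame
#' stride.  The number of origins entering each lag is recorded for use as
#' fit weights.
#'
#' @param traj an unwrapped (ideally centre-reduced) \code{\link{trajectory}}.
#' @param species molecule name to select; \code{NULL} selects all sites.
#' @param max_lag_fraction largest lag as a fraction of the trajectory
#'   length, in (0, 1].
#' @param origin_stride frame stride between time origins. Default 1
#'   (all origins; overlap is accounted through \code{n_origins} weights).
#' @return A \code{data.frame} of class \code{"msd_curve"} with columns
#'   \code{lag} (fs), \code{msd} (\enc{Å}{A}^2), \code{n_origins}.
#' @export
compute_msd <- function(traj, species = NULL, max_lag_fraction = 0.5,
                        origin_stride = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$wrapped) stop("compute_msd requires an unwrapped trajectory")
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("max_lag_fraction must lie in (0, 1]")
  sel <- seq_len(n_atoms(traj))
  if (!is.null(species)) {
    if (is.null(traj$topology)) stop("species selection requires a topology")
    sel <- which(traj$topology$molecule_name == species)
    if (length(sel) == 0) stop("no sites of species '", species, "' in the trajectory")
  }
  nf <- n_frames(traj)
  if (nf < 2) stop("at least two frames required")
  dtimes <- diff(traj$times)
  if (diff(range(dtimes)) > 1e-9 * mean(dtimes))
    stop("compute_msd requires uniformly spaced frames")
  dt <- mean(dtimes)
  max_lag <- max(1L, floor((nf - 1L) * max_lag_fraction))
  lags <- seq_len(max_lag)
  msd <- numeric(max_lag)
  se <- numeric(max_lag)
  nor <- integer(max_lag)
  x <- traj$coords[, sel, , drop = FALSE]
  np <- length(sel)
  pp <- matrix(NA_real_, max_lag, np)   # origin-averaged MSD per particle
  for (li in lags) {
    orig <- seq.int(1L, nf - li, by = origin_stride)
    d <- x[orig + li, , , drop = FALSE] - x[orig, , , drop = FALSE]
    d2 <- matrix(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2,
                 nrow = length(orig), ncol = np)
    pp[li, ] <- colMeans(d2)
    msd[li] <- mean(pp[li, ])
    # ensemble standard error: particles are the independent unit, origins
    # of one particle are strongly correlated
    se[li] <- if (np > 1) stats::sd(pp[li, ]) / sqrt(np) else NA_real_
    nor[li] <- length(orig)
  }
  out <- data.frame(lag = lags * dt, msd = msd, se = se, n_origins = nor)
  attr(out, "per_particle") <- pp
  attr(out, "species") <- if (is.null(species)) "all" else species
  attr(out, "n_particles") <- length(sel)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Einstein-relation self-diffusivity
#'
#' Weighted least-squares line through MSD versus lag on a fit window;
#' the self-diffusivity is slope/6 (three dimensions).  A negative fitted
#' slope is reported as \code{D = 0} with a sub-diffusive flag, as is a
#' slope statistically indistinguishable from zero.
#'
#' @param msd an \code{"msd_curve"} from \code{\link{compute_msd}}.
#' @param window lag range \code{c(lo, hi)} in fs; default the 10--50\%
#'   span of the available lags (excludes the short-time ballistic/cage
#'   regime and the noisy long-lag tail).
#' @param weights per-point fit weights; default \code{1/se^2} from the
#'   curve's ensemble standard errors when present, else \code{n_origins}.
#' @param zero_alpha significance level for the statistically-zero call.
#'
#' @details When the curve carries its per-particle MSD matrix (attribute
#'   \code{"per_particle"}, attached by \code{\link{compute_msd}}), the
#'   slope uncertainty comes from the dispersion of per-particle slopes:
#'   each particle's origin-averaged curve is fitted with the same window
#'   and weights, and \code{sd(slope) = sd(slope_i)/sqrt(n)}.  Particles
#'   are the independent unit; both residual-based and per-lag-error-based
#'   estimates are badly optimistic because overlapping time origins
#'   correlate neighbouring lags of a pooled curve.
#' @return A list of class \code{"diffusivity_fit"}: \code{D} and
#'   \code{D_sd} (\enc{Å}{A}^2/fs), \code{D_m2s} (m^2/s), \code{window},
#'   \code{r_squared}, \code{subdiffusive}, \code{fit} (the \code{lm}).
#' @export
fit_diffusivity <- function(msd, window = NULL, weights = NULL,
                            zero_alpha = 0.05) {
  stopifnot(inherits(msd, "msd_curve"))
  if (is.null(window)) window <- c(0.1, 0.5) * max(msd$lag)
  if (window[1] < 0 || window[2] > max(msd$lag) || window[1] >= window[2])
    stop("fit window outside the available lag range")
  keep <- msd$lag >= window[1] & msd$lag <= window[2]
  if (sum(keep) < 5) stop("fit window must contain at least 5 lag points")
  d <- msd[keep, ]
  w <- if (!is.null(weights)) weights[keep] else d$n_origins
  fit <- stats::lm(msd ~ lag, data = d, weights = w)
  slope <- unname(stats::coef(fit)["lag"])
  pp <- attr(msd, "per_particle")
  if (!is.null(pp) && ncol(pp) > 1) {
    # per-particle slope dispersion: the pooled WLS slope is the mean of
    # the per-particle slopes (linearity), so sd(mean) = sd_i / sqrt(n)
    X <- cbind(1, d$lag)
    XtWXi <- solve(crossprod(X * sqrt(w)))
    hat <- XtWXi %*% t(X * w)          # 2 x n_points projector
    slopes_i <- drop(hat[2, ] %*% pp[keep, , drop = FALSE])
    slope_sd <- stats::sd(slopes_i) / sqrt(ncol(pp))
    zcrit <- stats::qnorm(1 - zero_alpha / 2)
  } else {
    slope_sd <- suppressWarnings(unname(sqrt(stats::vcov(fit)["lag", "lag"])))
    zcrit <- stats::qt(1 - zero_alpha / 2, df = stats::df.residual(fit))
  }
  sub <- slope <= 0 || slope < zcrit * slope_sd
  D <- max(slope, 0) / 6
  structure(list(
    D = D,
    D_sd = slope_sd / 6,
    D_m2s = D * 1e-20 / 1e-15,   # A^2/fs -> m^2/s
    window = window,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    subdiffusive = sub,
    n_points = sum(keep),
    fit = fit
  ), class = "diffusivity_fit")
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf("<diffusivity_fit> D = %.4g +/- %.2g A^2/fs (%.4g m^2/s)\n",
              x$D, x$D_sd, x$D_m2s))
  cat(sprintf("  window %.4g .. %.4g fs, %d points, R^2 = %.4f%s\n",
              x$window[1], x$window[2], x$n_points, x$r_squared,
              if (x$subdiffusive) ", flagged sub-diffusive (D ~ 0)" else ""))
  invisible(x)
}

#' Diffusion exponent of an MSD curve
#'
#' Log--log slope of MSD versus lag over a window:
#' \eqn{MSD \propto \tau^\alpha} with \eqn{\alpha = 1} for Fickian
#' diffusion and \eqn{\alpha \ll 1} for caged (plateaued, sub-diffusive)
#' dynamics.  A sharper regime classifier than the significance of the
#' Einstein slope, which overlapping-origin correlations distort.
#'
#' @param msd an \code{"msd_curve"}.
#' @param window lag range, fs; default the 10--50\% span.
#' @return The exponent \eqn{\alpha} (dimensionless).
#' @export
msd_exponent <- function(msd, window = NULL) {
  stopifnot(inherits(msd, "msd_curve"))
  if (is.null(window)) window <- c(0.1, 0.5) * max(msd$lag)
  keep <- msd$lag >= window[1] & msd$lag <= window[2] & msd$msd > 0
  if (sum(keep) < 3) stop("window must contain at least 3 positive MSD points")
  unname(stats::coef(stats::lm(log(msd$msd[keep]) ~ log(msd$lag[keep])))[2])
}

#' @export
plot.msd_curve <- function(x, ..., log = "") {
  graphics::plot(x$lag, x$msd, type = "l", log = log,
                 xlab = "lag (fs)", ylab = expression(MSD ~ (ring(A)^2)),
                 main = paste("MSD,", attr(x, "species")), ...)
  invisible(x)
}
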