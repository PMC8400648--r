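#' Atomistic topology table
#'
#' Builds the per-atom topology used throughout the analysis layer: atom
#' identities, masses, charges, molecule membership and hydrogen-bond site
#' roles.  Atom type labels follow the site-naming convention of the systems
#' under study (e.g. \code{"O_Z"}, \code{"H_A/C1"}).
#'
#' @param atom_id integer atom indices (unique).
#' @param atom_type character site labels.
#' @param mass atomic masses in unified atomic mass units (u).
#' @param molecule_id integer molecule index each atom belongs to.
#' @param molecule_name character molecule (species) name per atom.
#' @param charge partial charges in elementary-charge units. Default 0.
#' @param donor logical; is this site a hydrogen-bond donor hydrogen?
#' @param acceptor logical; is this site a hydrogen-bond acceptor?
#'
#' @return A \code{data.frame} of class \code{"topology"} with one row per
#'   atom.  Per-molecule molar masses are available via
#'   \code{\link{molar_masses}}.
#' @export
topology <- function(atom_id, atom_type, mass, molecule_id, molecule_name,
                     charge = 0, donor = FALSE, acceptor = FALSE) {
  n <- length(atom_id)
  if (anyDuplicated(atom_id)) stop("atom_id values must be unique")
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("masses must be positive and finite")
  top <- data.frame(
    atom_id       = as.integer(atom_id),
    atom_type     = as.character(atom_type),
    mass          = as.numeric(mass),
    charge        = rep_len(as.numeric(charge), n),
    molecule_id   = as.integer(rep_len(molecule_id, n)),
    molecule_name = as.character(rep_len(molecule_name, n)),
    donor         = rep_len(as.logical(donor), n),
    acceptor      = rep_len(as.logical(acceptor), n),
    stringsAsFactors = FALSE
  )
  # each atom belongs to exactly one molecule by construction; check that a
  # molecule_id never spans two molecule names
  spans <- tapply(top$molecule_name, top$molecule_id, function(x) length(unique(x)))
  if (any(spans > 1L)) stop("a molecule_id maps to more than one molecule_name")
  top <- top[order(top$atom_id), , drop = FALSE]
  rownames(top) <- NULL
  class(top) <- c("topology", "data.frame")
  top
}

#' Molar mass per molecule name
#'
#' Sums atom masses of one representative molecule of each species.  All
#' molecules sharing a name must have identical composition (checked to
#' 1e-6 u).
#'
#' @param top a \code{\link{topology}}.
#' @return Named numeric vector, g/mol per molecule name.
#' @export
molar_masses <- function(top) {
  stopifnot(inherits(top, "topology"))
  per_mol <- tapply(top$mass, top$molecule_id, sum)
  name_of <- tapply(top$molecule_name, top$molecule_id, function(x) x[[1L]])
  out <- vapply(split(as.numeric(per_mol), as.character(name_of)), function(m) {
    if (diff(range(m)) > 1e-6)
      stop("molecules sharing a name differ in molar mass by more than 1e-6 u")
    m[[1L]]
  }, numeric(1))
  out
}

#' Trajectory container
#'
#' Time-ordered frames of particle coordinates in an orthogonal periodic box.
#' Coordinates are stored as read (wrapped or not); unwrapping is an explicit
#' step (\code{\link{unwrap_trajectory}}), never implicit.
#'
#' @param coords numeric array \code{[n_frames, n_atoms, 3]}, \enc{Å}{A}.
#' @param box per-frame orthogonal box edge lengths: either a length-3 vector
#'   (constant box) or an \code{n_frames x 3} matrix, \enc{Å}{A}.
#' @param times frame times, fs (reduced time for toy systems); strictly
#'   increasing.
#' @param topology optional \code{\link{topology}}.
#' @param wrapped logical; are coordinates wrapped into \code{[0, L)}?
#' @param ground_truth optional list attached by the synthetic generators
#'   (e.g. \code{true_D}, true unwrapped coordinates).
#' @param units \code{"real"} (\enc{Å}{A}/fs) or \code{"reduced"}.
#'
#' @return An object of class \code{"trajectory"}.
#' @export
trajectory <- function(coords, box, times, topology = NULL, wrapped = TRUE,
                       ground_truth = NULL, units = "real") {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an [n_frames, n_atoms, 3] array")
  nf <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != nf || ncol(box) != 3)
    stop("box must be a 3-vector or an n_frames x 3 matrix")
  if (any(box <= 0)) stop("box edge lengths must be strictly positive")
  times <- as.numeric(times)
  if (length(times) != nf) stop("times length must equal the number of frames")
  if (nf > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (!is.null(topology) && nrow(topology) != dim(coords)[2])
    stop("topology row count must equal the atom count")
  structure(
    list(coords = coords, box = box, times = times, topology = topology,
         wrapped = isTRUE(wrapped), ground_truth = ground_truth,
         units = units),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d atoms, %s coordinates (%s units)\n",
              n_frames(x), n_atoms(x),
              if (x$wrapped) "wrapped" else "unwrapped", x$units))
  cat(sprintf("  time %g .. %g, box (last frame) %.4g x %.4g x %.4g\n",
              x$times[1], x$times[n_frames(x)],
              x$box[n_frames(x), 1], x$box[n_frames(x), 2], x$box[n_frames(x), 3]))
  if (!is.null(x$topology))
    cat(sprintf("  topology: %d molecules (%s)\n",
                length(unique(x$topology$molecule_id)),
                paste(unique(x$topology$molecule_name), collapse = ", ")))
  invisible(x)
}

#' @rdname trajectory
#' @param x a trajectory.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(x) dim(x$coords)[2]

#' Per-state-point thermodynamic series
#'
#' Sampled records of temperature, pressure, volume and energies from one
#' simulation state point.  Optional columns are absent (\code{NULL}), never
#' silently zero.
#'
#' @param time record times, fs.
#' @param T temperature, K.
#' @param P pressure, kPa (optional).
#' @param V box volume, \enc{Å}{A}^3 (optional).
#' @param U potential energy per box, kJ/mol (optional).
#' @param H total enthalpy per box, kJ/mol (optional).
#' @return A \code{data.frame} of class \code{"thermo_series"}.
#' @export
thermo_series <- function(time, T, P = NULL, V = NULL, U = NULL, H = NULL) {
  n <- length(time)
  cols <- list(time = as.numeric(time), T = as.numeric(T))
  for (nm in c("P", "V", "U", "H")) {
    val <- switch(nm, P = P, V = V, U = U, H = H)
    if (!is.null(val)) {
      if (length(val) != n) stop(sprintf("column %s has length %d, expected %d",
                                         nm, length(val), n))
      cols[[nm]] <- as.numeric(val)
    }
  }
  if (length(cols$T) != n) stop("temperature column length mismatch")
  if (!is.null(cols$V) && any(cols$V <= 0)) stop("volumes must be positive")
  out <- as.data.frame(cols)
  class(out) <- c("thermo_series", "data.frame")
  out
}

#' Per-temperature thermal scan
#'
#' Aggregated density and self-diffusivity (with uncertainties) on a
#' temperature grid — the input of the trend-shift glass transition
#' estimator.
#'
#' @param T temperature grid, K, strictly increasing.
#' @param rho mean mass density, g/cm^3.
#' @param rho_sd standard deviation of \code{rho}.
#' @param D self-diffusivity, \enc{Å}{A}^2/fs.
#' @param D_sd standard deviation of \code{D}.
#' @param composition optional mixture description (see
#'   \code{\link{mixture_spec}}).
#' @param truth optional \code{\link{scan_truth}} sidecar attached by
#'   generators.
#' @return A \code{data.frame} of class \code{"thermal_scan"}.
#' @export
thermal_scan <- function(T, rho = NULL, rho_sd = NULL, D = NULL, D_sd = NULL,
                         composition = NULL, truth = NULL) {
  T <- as.numeric(T)
  if (length(T) > 1 && any(diff(T) <= 0)) stop("temperature grid must be strictly increasing")
  n <- length(T)
  out <- data.frame(T = T)
  for (nm in c("rho", "rho_sd", "D", "D_sd")) {
    val <- switch(nm, rho = rho, rho_sd = rho_sd, D = D, D_sd = D_sd)
    if (!is.null(val)) {
      if (length(val) != n) stop(sprintf("column %s length mismatch", nm))
      out[[nm]] <- as.numeric(val)
    }
  }
  attr(out, "composition") <- composition
  attr(out, "truth") <- truth
  class(out) <- c("thermal_scan", "data.frame")
  out
}

#' @export
print.thermal_scan <- function(x, ...) {
  cat(sprintf("<thermal_scan> %d temperatures, %g .. %g K; observables: %s\n",
              nrow(x), min(x$T), max(x$T),
              paste(setdiff(names(x), "T"), collapse = ", ")))
  if (!is.null(attr(x, "truth")))
    cat(sprintf("  ground truth attached (true Tg = %g K)\n", attr(x, "truth")$true_Tg))
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

# internal: wrap coordinates into [0, L) per axis
.wrap_coords <- function(coords, box) {
  nf <- dim(coords)[1]
  for (k in 1:3) {
    L <- box[, k]
    coords[, , k] <- coords[, , k] - floor(coords[, , k] / L) * L
  }
  coords
}
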