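#' Vaporization energy and enthalpy
#'
#' Cohesion estimator under the ideal-vapor assumption:
#' \deqn{U_{vap} = \langle U_{gas} \rangle - \langle U_{liq} \rangle / n}
#' where the gas reference is a single-molecule (intramolecular-only)
#' potential-energy average and the liquid series is per simulation box of
#' \code{n} molecules.  \eqn{\Delta H_{vap} = U_{vap} + RT} exactly, with
#' R = 8.31446e-3 kJ/(mol K).  Uncertainties combine the two series'
#' standard errors in quadrature.
#'
#' @param liquid \code{\link{thermo_series}} of the bulk liquid (column
#'   \code{U}, kJ/mol per box).
#' @param gas \code{\link{thermo_series}} of the isolated molecule (column
#'   \code{U}, kJ/mol per molecule).
#' @param n_molecules number of molecules in the liquid box.
#' @param T temperature, K; defaults to the liquid series mean.  The two
#'   series must agree in mean temperature within 1 K.
#' @return A list of class \code{"vaporization_result"}: \code{U_vap},
#'   \code{U_vap_sd}, \code{dH_vap}, \code{dH_vap_sd} (kJ/mol), \code{T}.
#' @export
vaporization_energy <- function(liquid, gas, n_molecules, T = NULL) {
  for (s in list(liquid, gas))
    if (is.null(s$U)) stop("both series need a potential-energy column U")
  if (n_molecules <= 0) stop("n_molecules must be positive")
  Tl <- mean(liquid$T); Tg <- mean(gas$T)
  if (abs(Tl - Tg) > 1) stop(sprintf(
    "temperature mismatch between liquid (%.1f K) and gas (%.1f K) series", Tl, Tg))
  if (is.null(T)) T <- Tl
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  U_vap <- mean(gas$U) - mean(liquid$U) / n_molecules
  U_sd <- sqrt(se(gas$U)^2 + (se(liquid$U) / n_molecules)^2)
  structure(list(U_vap = U_vap, U_vap_sd = U_sd,
                 dH_vap = U_vap + .R_KJ * T, dH_vap_sd = U_sd, T = T),
            class = "vaporization_result")
}

#' @export
print.vaporization_result <- function(x, ...) {
  cat(sprintf("<vaporization_result> at %.1f K\n", x$T))
  cat(sprintf("  U_vap  = %.2f +/- %.2f kJ/mol\n", x$U_vap, x$U_vap_sd))
  cat(sprintf("  dH_vap = %.2f +/- %.2f kJ/mol (U_vap + RT, ideal vapor)\n",
              x$dH_vap, x$dH_vap_sd))
  invisible(x)
}

#' Specific (per-mass) vaporization energy
#'
#' Converts a molar vaporization energy to a per-mass cohesion measure.
#' Two unit scales are in circulation for this quantity; both are returned:
#' \code{kJ_g} (kJ/g, i.e. U_vap/M directly) and \code{J_g}
#' (J/g = 1000 U_vap/M).  For U_vap ~ 100 kJ/mol and M ~ 135 g/mol the
#' kJ/g scale gives ~0.74 — the magnitude at which such comparisons are
#' typically quoted.
#'
#' @param U_vap molar vaporization energy, kJ/mol.
#' @param M molar mass, g/mol.
#' @return List: \code{kJ_g}, \code{J_g}.
#' @export
specific_energy <- function(U_vap, M) {
  if (any(M <= 0)) stop("molar mass must be positive")
  list(kJ_g = U_vap / M, J_g = 1000 * U_vap / M)
}

#' Fusion enthalpy as a two-phase enthalpy difference
#'
#' Plain per-molecule enthalpy difference between a liquid and a crystal
#' series at the same temperature and pressure:
#' \deqn{\Delta_{fus} H = \langle H_{liq} \rangle / n_{liq} -
#'       \langle H_{cryst} \rangle / n_{cryst}.}
#' No superheating or finite-size correction is applied; reports label the
#' estimator accordingly.
#'
#' @param crystal,liquid \code{\link{thermo_series}} with enthalpy column
#'   \code{H} (kJ/mol per box).
#' @param n_crystal,n_liquid molecules per box in each phase.
#' @param T stated temperature, K; the two series must agree within 1 K.
#' @return A list of class \code{"fusion_result"}: \code{dH_fus} (kJ/mol),
#'   \code{T}.
#' @export
fusion_enthalpy <- function(crystal, liquid, n_crystal, n_liquid, T = NULL) {
  for (s in list(crystal, liquid))
    if (is.null(s$H)) stop("both series need an enthalpy column H")
  Tc <- mean(crystal$T); Tl <- mean(liquid$T)
  if (abs(Tc - Tl) > 1) stop(sprintf(
    "temperature mismatch between crystal (%.1f K) and liquid (%.1f K) series", Tc, Tl))
  if (is.null(T)) T <- (Tc + Tl) / 2
  structure(list(dH_fus = mean(liquid$H) / n_liquid - mean(crystal$H) / n_crystal,
                 T = T, phases = c("crystal", "liquid")),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(
    "<fusion_result> dH_fus = %.2f kJ/mol at %.1f K (liquid - crystal enthalpy difference)\n",
    x$dH_fus, x$T))
  invisible(x)
}
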