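# 1/sd^2 weights when every uncertainty is usable, else unweighted
.scan_weights <- function(sd) {
  if (is.null(sd) || any(!is.finite(sd)) || any(sd <= 0)) NULL else 1 / sd^2
}

#' Glass transition from a density scan
#'
#' Trend-shift estimate: fits the two-segment model to density versus
#' temperature (weights \code{1/sd^2} where uncertainties are available)
#' and takes the break point as Tg.  The liquid branch is expected to be
#' the steeper one (larger thermal expansion above Tg).
#'
#' @param scan a \code{\link{thermal_scan}} with a \code{rho} column.
#' @param method passed to \code{\link{segfit}}.
#' @param min_points_per_side passed to \code{\link{segfit}}.
#' @return List of class \code{"tg_branch"}: \code{Tg}, \code{sd},
#'   \code{fit} (the \code{segfit}), \code{observable}, \code{no_break}.
#' @export
tg_from_density <- function(scan, method = "hinge", min_points_per_side = 3) {
  stopifnot(inherits(scan, "thermal_scan"))
  if (is.null(scan$rho)) stop("scan has no density column")
  fit <- segfit(scan$T, scan$rho, weights = .scan_weights(scan$rho_sd),
                min_points_per_side = min_points_per_side, method = method)
  structure(list(Tg = unname(coef(fit)[["breakpoint"]]),
                 sd = propagate_uncertainty(fit),
                 fit = fit, observable = "density",
                 no_break = fit$no_break),
            class = "tg_branch")
}

#' Glass transition from a self-diffusivity scan
#'
#' Trend-shift estimate on the linear D scale: the glass branch is a
#' near-zero floor, the liquid branch rises with temperature; Tg is the
#' break point.  The fit is on linear D (not log D) because glass-phase
#' diffusivities are statistically zero.
#'
#' @inheritParams tg_from_density
#' @return A \code{"tg_branch"} (see \code{\link{tg_from_density}}).
#' @export
tg_from_diffusivity <- function(scan, method = "hinge", min_points_per_side = 3) {
  stopifnot(inherits(scan, "thermal_scan"))
  if (is.null(scan$D)) stop("scan has no diffusivity column")
  if (all(scan$D == 0)) stop("all-zero diffusivities: insufficient signal for a trend shift")
  fit <- segfit(scan$T, scan$D, weights = .scan_weights(scan$D_sd),
                min_points_per_side = min_points_per_side, method = method)
  structure(list(Tg = unname(coef(fit)[["breakpoint"]]),
                 sd = propagate_uncertainty(fit),
                 fit = fit, observable = "diffusivity",
                 no_break = fit$no_break),
            class = "tg_branch")
}

#' @export
print.tg_branch <- function(x, ...) {
  cat(sprintf("<tg_branch: %s> Tg = %.1f +/- %.1f K%s\n", x$observable,
              x$Tg, x$sd,
              if (isTRUE(x$no_break)) "  [no-break flag]" else ""))
  invisible(x)
}

#' Combine density- and diffusivity-derived Tg
#'
#' The final Tg is the arithmetic mean of the two branch estimates, with
#' the uncertainty combined in quadrature (halved).  A consistency gap
#' above 25 K between the branches raises a flag — within the method's
#' expected branch agreement the two estimates should not differ by more.
#'
#' @param tg_rho density branch: a \code{"tg_branch"} or \code{c(Tg, sd)}.
#' @param tg_D diffusivity branch, same forms; \code{NULL} for a
#'   single-branch (uncombined) result.
#' @param gap_limit consistency threshold, K. Default 25.
#' @return An object of class \code{"tg_estimate"}: \code{Tg_rho},
#'   \code{Tg_D}, \code{Tg_avg} (each with \code{*_sd}),
#'   \code{consistency_gap}, \code{consistency_flag}, \code{combined}.
#' @export
combine_tg <- function(tg_rho, tg_D = NULL, gap_limit = 25) {
  as_pair <- function(b) {
    if (inherits(b, "tg_branch")) c(b$Tg, b$sd)
    else if (is.numeric(b) && length(b) >= 1) c(b[1], if (length(b) > 1) b[2] else NA_real_)
    else stop("branch must be a tg_branch or c(Tg, sd)")
  }
  r <- as_pair(tg_rho)
  if (is.null(tg_D)) {
    return(structure(list(Tg_rho = r[1], Tg_rho_sd = r[2],
                          Tg_D = NA_real_, Tg_D_sd = NA_real_,
                          Tg_avg = r[1], Tg_avg_sd = r[2],
                          consistency_gap = NA_real_,
                          consistency_flag = FALSE, combined = FALSE),
                     class = "tg_estimate"))
  }
  d <- as_pair(tg_D)
  gap <- abs(r[1] - d[1])
  structure(list(Tg_rho = r[1], Tg_rho_sd = r[2],
                 Tg_D = d[1], Tg_D_sd = d[2],
                 Tg_avg = (r[1] + d[1]) / 2,
                 Tg_avg_sd = sqrt(r[2]^2 + d[2]^2) / 2,
                 consistency_gap = gap,
                 consistency_flag = gap > gap_limit,
                 combined = TRUE),
            class = "tg_estimate")
}

#' Full trend-shift Tg estimation from a thermal scan
#'
#' Runs the density and diffusivity branch fits and combines them — the
#' complete glass-transition determination from one scan.
#'
#' @inheritParams tg_from_density
#' @return A \code{"tg_estimate"} carrying both branch fits
#'   (\code{$branch_rho}, \code{$branch_D}).
#' @export
estimate_tg <- function(scan, method = "hinge", min_points_per_side = 3) {
  stopifnot(inherits(scan, "thermal_scan"))
  br <- if (!is.null(scan$rho))
    tg_from_density(scan, method, min_points_per_side) else NULL
  bd <- if (!is.null(scan$D))
    tg_from_diffusivity(scan, method, min_points_per_side) else NULL
  if (is.null(br) && is.null(bd)) stop("scan carries neither density nor diffusivity")
  est <- if (is.null(bd)) combine_tg(br)
  else if (is.null(br)) {
    structure(list(Tg_rho = NA_real_, Tg_rho_sd = NA_real_,
                   Tg_D = bd$Tg, Tg_D_sd = bd$sd,
                   Tg_avg = bd$Tg, Tg_avg_sd = bd$sd,
                   consistency_gap = NA_real_, consistency_flag = FALSE,
                   combined = FALSE), class = "tg_estimate")
  } else combine_tg(br, bd)
  est$branch_rho <- br
  est$branch_D <- bd
  est$scan <- scan
  est
}

#' @export
print.tg_estimate <- function(x, ...) {
  cat("<tg_estimate>\n")
  if (is.finite(x$Tg_rho))
    cat(sprintf("  density branch:     Tg = %.1f +/- %.1f K\n", x$Tg_rho, x$Tg_rho_sd))
  if (is.finite(x$Tg_D))
    cat(sprintf("  diffusivity branch: Tg = %.1f +/- %.1f K\n", x$Tg_D, x$Tg_D_sd))
  cat(sprintf("  averaged:           Tg = %.1f +/- %.1f K\n", x$Tg_avg, x$Tg_avg_sd))
  if (isTRUE(x$combined))
    cat(sprintf("  branch gap %.1f K%s\n", x$consistency_gap,
                if (x$consistency_flag) "  [exceeds 25 K consistency limit]" else ""))
  for (b in list(x$branch_rho, x$branch_D))
    if (!is.null(b) && isTRUE(b$no_break))
      cat(sprintf("  note: %s branch carries a no-break flag\n", b$observable))
  invisible(x)
}

#' @export
summary.tg_estimate <- function(object, ...) {
  df <- data.frame(
    branch = c("density", "diffusivity", "averaged"),
    Tg = c(object$Tg_rho, object$Tg_D, object$Tg_avg),
    sd = c(object$Tg_rho_sd, object$Tg_D_sd, object$Tg_avg_sd))
  df[is.finite(df$Tg), ]
}

#' @export
plot.tg_estimate <- function(x, ...) {
  has_rho <- !is.null(x$branch_rho)
  has_D <- !is.null(x$branch_D)
  if (has_rho && has_D) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (has_rho) plot(x$branch_rho$fit, xlab = "T (K)",
                    ylab = expression(rho ~ (g ~ cm^-3)),
                    main = "density branch")
  if (has_D) plot(x$branch_D$fit, xlab = "T (K)",
                  ylab = expression(D ~ (ring(A)^2 ~ fs^-1)),
                  main = "diffusivity branch")
  invisible(x)
}
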