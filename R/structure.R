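# unit constants
.AMU_G <- 1.66053906660e-24   # g per unified atomic mass unit
.A3_CM3 <- 1e-24              # cm^3 per A^3
.R_KJ <- 8.31446e-3           # gas constant, kJ/(mol K)

#' Mass density of a trajectory
#'
#' Per-frame mass density (total mass over box volume, converted to
#' g/cm^3), averaged across frames with a standard deviation.
#'
#' @param traj a \code{\link{trajectory}} with a topology (or supply
#'   \code{masses}).
#' @param masses optional per-atom masses (u) overriding the topology.
#' @return A list of class \code{"state_point"}: \code{rho}, \code{rho_sd}
#'   (g/cm^3), \code{per_frame}, \code{volume} (mean, \enc{Å}{A}^3).
#' @export
mass_density <- function(traj, masses = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(masses)) {
    if (is.null(traj$topology)) stop("mass_density needs a topology or masses")
    masses <- traj$topology$mass
  }
  if (length(masses) != n_atoms(traj)) stop("one mass per atom required")
  V <- traj$box[, 1] * traj$box[, 2] * traj$box[, 3]
  if (any(V <= 0)) stop("non-positive box volume")
  m_g <- sum(masses) * .AMU_G
  rho <- m_g / (V * .A3_CM3)
  structure(list(rho = mean(rho),
                 rho_sd = if (length(rho) > 1) stats::sd(rho) else 0,
                 per_frame = rho,
                 volume = mean(V)),
            class = "state_point")
}

#' Molar volume from density
#'
#' \eqn{V_m = \bar{M} / \rho} per mole of molecules, with the mixture-mean
#' molar mass \eqn{\bar{M} = \sum_i x_i M_i}.
#'
#' @param rho mass density, g/cm^3.
#' @param M molar masses, g/mol: a scalar for a pure compound or a vector
#'   with mole fractions \code{x} for a mixture.
#' @param x mole fractions (same length as \code{M}); default equimolar.
#' @return Molar volume, cm^3/mol.
#' @export
molar_volume <- function(rho, M, x = NULL) {
  if (any(rho <= 0)) stop("density must be positive")
  if (length(M) > 1) {
    if (is.null(x)) x <- rep(1 / length(M), length(M))
    if (abs(sum(x) - 1) > 1e-9) stop("mole fractions must sum to 1")
    M <- sum(x * M)
  }
  M / rho
}

#' Excess molar volume of a mixture
#'
#' \eqn{V^E = V_{m,mix} - \sum_i x_i V_{m,i}}; negative values indicate
#' packing more efficient than the ideal (mole-fraction-weighted) mixture.
#'
#' @param V_m_mix mixture molar volume, cm^3/mol.
#' @param x mole fractions (sum to 1 within 1e-9).
#' @param V_m_pure pure-component molar volumes, cm^3/mol.
#' @return List: \code{V_E} (cm^3/mol) and \code{percent}
#'   (\eqn{100 V^E / V_{m,mix}}).
#' @export
excess_volume <- function(V_m_mix, x, V_m_pure) {
  if (abs(sum(x) - 1) > 1e-9) stop("mole fractions must sum to 1 within 1e-9")
  if (length(x) != length(V_m_pure)) stop("one pure molar volume per component")
  V_E <- V_m_mix - sum(x * V_m_pure)
  list(V_E = V_E, percent = 100 * V_E / V_m_mix)
}

# minimum-image distances between site sets (orthogonal box)
.pair_distances <- function(A, B, L, same) {
  dx <- outer(A[, 1], B[, 1], `-`)
  dy <- outer(A[, 2], B[, 2], `-`)
  dz <- outer(A[, 3], B[, 3], `-`)
  dx <- dx - round(dx / L[1]) * L[1]
  dy <- dy - round(dy / L[2]) * L[2]
  dz <- dz - round(dz / L[3]) * L[3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  if (same) d[upper.tri(d)] else as.vector(d)
}

#' Site--site radial distribution function
#'
#' Histogram of minimum-image pair distances, normalised by the ideal-gas
#' pair density of the selected site populations and the spherical shell
#' volumes, averaged over frames with the per-frame box volume
#' (NPT-compatible).
#'
#' @param traj a \code{\link{trajectory}} (wrapped or unwrapped; minimum
#'   image is applied).
#' @param site_pair character pair of topology \code{atom_type} labels
#'   (e.g. \code{c("O_Z", "H_A/C1")}); \code{NULL} uses all sites.
#' @param r_max largest separation, \enc{Å}{A}; must not exceed half the
#'   smallest box edge.
#' @param bin_width histogram bin width, \enc{Å}{A}. Default 0.05.
#' @param frames frame indices to average; default all.
#' @return A \code{data.frame} of class \code{"rdf_curve"}: \code{r} (bin
#'   centres), \code{g}, \code{count} (mean raw pair count per frame);
#'   attributes \code{site_pair}, \code{bin_width}, \code{n_frames},
#'   \code{pair_density} (N_pairs/V, for coordination integrals).
#' @export
compute_rdf <- function(traj, site_pair = NULL, r_max = NULL,
                        bin_width = 0.05, frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  Lmin <- min(traj$box[frames, ])
  if (is.null(r_max)) r_max <- Lmin / 2
  if (r_max > Lmin / 2 + 1e-9)
    stop("r_max exceeds half the smallest box edge (minimum image invalid)")
  types <- if (!is.null(traj$topology)) traj$topology$atom_type else
    rep("X", n_atoms(traj))
  if (is.null(site_pair)) {
    selA <- selB <- seq_len(n_atoms(traj))
  } else {
    selA <- which(types == site_pair[1])
    selB <- which(types == site_pair[2])
    if (length(selA) == 0 || length(selB) == 0)
      stop("empty site selection for pair ", paste(site_pair, collapse = "..."))
  }
  same <- is.null(site_pair) || site_pair[1] == site_pair[2]
  n_bins <- ceiling(r_max / bin_width)
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  counts <- numeric(n_bins)
  g_acc <- numeric(n_bins)
  shell_vol <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  n_pairs <- if (same) length(selA) * (length(selA) - 1) / 2 else
    length(selA) * length(selB)
  if (n_pairs == 0) stop("selection yields no pairs")
  for (fi in frames) {
    L <- traj$box[fi, ]
    V <- prod(L)
    d <- .pair_distances(traj$coords[fi, selA, , drop = TRUE],
                         traj$coords[fi, selB, , drop = TRUE], L, same)
    h <- graphics::hist(d[d < n_bins * bin_width], breaks = breaks,
                        plot = FALSE)$counts
    counts <- counts + h
    g_acc <- g_acc + h / (n_pairs * shell_vol / V)
  }
  nf <- length(frames)
  out <- data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    g = g_acc / nf, count = counts / nf)
  attr(out, "site_pair") <- if (is.null(site_pair)) c("all", "all") else site_pair
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- nf
  attr(out, "n_A") <- length(selA)
  attr(out, "n_B") <- length(selB)
  attr(out, "pair_density") <- n_pairs / mean(traj$box[frames, 1] *
                                                traj$box[frames, 2] *
                                                traj$box[frames, 3])
  class(out) <- c("rdf_curve", "data.frame")
  out
}

#' @export
plot.rdf_curve <- function(x, ...) {
  sp <- attr(x, "site_pair")
  graphics::plot(x$r, x$g, type = "l",
                 xlab = expression(r ~ (ring(A))), ylab = "g(r)",
                 main = paste(sp[1], "...", sp[2]), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' First peak of an RDF
#'
#' Position and amplitude of the maximum bin on a search range, refined by
#' a parabola through the three bins around the maximum.  A maximum sitting
#' on a range boundary (monotone g on the range) or an all-zero range is
#' flagged as no peak.
#'
#' @param rdf an \code{"rdf_curve"}.
#' @param range r range \code{c(lo, hi)} to search, \enc{Å}{A}; default all.
#' @return List: \code{r_peak}, \code{amplitude}, \code{is_peak}.
#' @export
first_peak <- function(rdf, range = NULL) {
  stopifnot(inherits(rdf, "rdf_curve"))
  if (is.null(range)) range <- c(min(rdf$r), max(rdf$r))
  idx <- which(rdf$r >= range[1] & rdf$r <= range[2])
  if (length(idx) == 0) stop("empty search range")
  g <- rdf$g[idx]
  if (all(g == 0)) return(list(r_peak = NA_real_, amplitude = 0, is_peak = FALSE))
  imax <- idx[which.max(g)]
  boundary <- imax == idx[1] || imax == idx[length(idx)]
  r_peak <- rdf$r[imax]
  amp <- rdf$g[imax]
  if (!boundary) {
    # parabolic refinement across the three bins around the maximum
    y1 <- rdf$g[imax - 1]; y2 <- rdf$g[imax]; y3 <- rdf$g[imax + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 0) {
      delta <- 0.5 * (y1 - y3) / denom
      delta <- max(min(delta, 0.5), -0.5)
      h <- attr(rdf, "bin_width")
      r_peak <- r_peak + delta * h
      amp <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  list(r_peak = r_peak, amplitude = amp, is_peak = !boundary)
}

#' Coordination number by RDF integration
#'
#' Integrates \eqn{\rho_{pair} 4 \pi r^2 g(r)} over \code{[0, r_cut]} with
#' the partner-site number density, giving the mean number of partner sites
#' within \code{r_cut} of a central site.
#'
#' @param rdf an \code{"rdf_curve"} (same- or cross-pair).
#' @param r_cut integration limit, \enc{Å}{A} (typically the first minimum).
#' @return Coordination number (partner sites per central site).
#' @export
coordination_number <- function(rdf, r_cut) {
  stopifnot(inherits(rdf, "rdf_curve"))
  keep <- rdf$r <= r_cut
  # mean raw pair count within r_cut per frame, converted per central site
  pairs_in <- sum(rdf$count[keep])
  sp <- attr(rdf, "site_pair")
  nA <- attr(rdf, "n_A")
  if (identical(sp[1], sp[2])) 2 * pairs_in / nA else pairs_in / nA
}

#' Hydrogen-bond contact statistics
#'
#' Distance-only criterion: a contact is a donor hydrogen within
#' \code{cutoff} of an acceptor site under minimum image, intramolecular
#' pairs excluded.  No angular term — contacts here mirror the short-range
#' donor...acceptor structure that site--site RDFs resolve.
#'
#' @param traj a \code{\link{trajectory}} with donor/acceptor flags in its
#'   topology.
#' @param cutoff H...acceptor distance cutoff, \enc{Å}{A}. Default 2.5.
#' @param frames frame indices; default all.
#' @return A list of class \code{"contact_stats"}: \code{n_contacts} (mean
#'   per frame), \code{mean_per_donor}, \code{n_donors}, \code{n_acceptors},
#'   \code{by_pair} (mean contact count per donor-type/acceptor-type
#'   combination, ranked), \code{cutoff}.
#' @export
hbond_contacts <- function(traj, cutoff = 2.5, frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  if (is.null(top)) stop("hbond_contacts requires a topology with site flags")
  don <- which(top$donor)
  acc <- which(top$acceptor)
  if (length(don) == 0 || length(acc) == 0)
    stop("topology has no donor or no acceptor sites")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  same_mol <- outer(top$molecule_id[don], top$molecule_id[acc], `==`)
  tot <- 0
  pair_keys <- character(0)
  pair_counts <- numeric(0)
  for (fi in frames) {
    L <- traj$box[fi, ]
    dmat <- matrix(.pair_distances(traj$coords[fi, don, , drop = TRUE],
                                   traj$coords[fi, acc, , drop = TRUE],
                                   L, same = FALSE),
                   nrow = length(don))
    hit <- dmat <= cutoff & !same_mol
    tot <- tot + sum(hit)
    if (any(hit)) {
      idx <- which(hit, arr.ind = TRUE)
      keys <- paste(top$atom_type[don[idx[, 1]]],
                    top$atom_type[acc[idx[, 2]]], sep = "...")
      tb <- table(keys)
      for (k in names(tb)) {
        j <- match(k, pair_keys)
        if (is.na(j)) {
          pair_keys <- c(pair_keys, k)
          pair_counts <- c(pair_counts, tb[[k]])
        } else pair_counts[j] <- pair_counts[j] + tb[[k]]
      }
    }
  }
  nf <- length(frames)
  by_pair <- if (length(pair_keys)) {
    parts <- strsplit(pair_keys, "...", fixed = TRUE)
    df <- data.frame(donor = vapply(parts, `[[`, "", 1),
                     acceptor = vapply(parts, `[[`, "", 2),
                     mean_count = pair_counts / nf)
    df[order(-df$mean_count), ]
  } else data.frame(donor = character(0), acceptor = character(0),
                    mean_count = numeric(0))
  structure(list(n_contacts = tot / nf,
                 mean_per_donor = tot / nf / length(don),
                 n_donors = length(don), n_acceptors = length(acc),
                 by_pair = by_pair, cutoff = cutoff),
            class = "contact_stats")
}

#' @export
print.contact_stats <- function(x, ...) {
  cat(sprintf("<contact_stats> %.3g contacts/frame (%.3g per donor), cutoff %.2f A\n",
              x$n_contacts, x$mean_per_donor, x$cutoff))
  if (nrow(x$by_pair)) {
    cat("  leading donor...acceptor pairs:\n")
    print(utils::head(x$by_pair, 5), row.names = FALSE)
  }
  invisible(x)
}
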