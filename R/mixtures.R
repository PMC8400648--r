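#' Binary/multinary mixture specification
#'
#' Composition record for drug--excipient mixtures: component names, mole
#' fractions, molar masses, and optional per-component glass-transition
#' temperatures, densities and fusion temperatures for the empirical
#' mixing rules.  Mass fractions are derived, never stored independently.
#'
#' @param names component names.
#' @param x mole fractions, summing to 1 within 1e-9.
#' @param M molar masses, g/mol.
#' @param Tg per-component glass transition temperatures, K (optional).
#' @param rho per-component amorphous densities, g/cm^3 (optional).
#' @param Tf per-component fusion temperatures, K (optional).
#' @return A list of class \code{"mixture_spec"} with derived mass
#'   fractions \code{w}.
#' @export
mixture_spec <- function(names, x, M, Tg = NULL, rho = NULL, Tf = NULL) {
  if (abs(sum(x) - 1) > 1e-9) stop("mole fractions must sum to 1 within 1e-9")
  if (length(names) != length(x) || length(M) != length(x))
    stop("names, x and M must have equal length")
  structure(list(names = as.character(names), x = as.numeric(x),
                 M = as.numeric(M), w = mole_to_mass_fraction(x, M),
                 Tg = Tg, rho = rho, Tf = Tf),
            class = "mixture_spec")
}

#' Mole to mass fractions
#'
#' \eqn{w_i = x_i M_i / \sum_j x_j M_j}.
#'
#' @param x mole fractions (sum to 1 within 1e-9).
#' @param M molar masses, g/mol (positive).
#' @return Mass fractions (sum to 1).
#' @export
mole_to_mass_fraction <- function(x, M) {
  if (any(M <= 0)) stop("molar masses must be positive")
  if (abs(sum(x) - 1) > 1e-9) stop("mole fractions must sum to 1 within 1e-9")
  x * M / sum(x * M)
}

#' Gordon--Taylor mixture Tg
#'
#' \deqn{T_g = \frac{w_1 T_{g1} + K w_2 T_{g2}}{w_1 + K w_2}}
#' with mass fractions \eqn{w_1 = 1 - w_2}.  \code{K = 1} reduces to the
#' mass-weighted linear blend; the density-based Simha--Boyer form of
#' \code{K} is available via \code{\link{k_simha_boyer}}.
#'
#' @param Tg1,Tg2 pure-component glass transitions, K.
#' @param w2 mass fraction of component 2, in [0, 1].
#' @param K_gt Gordon--Taylor constant (> 0).
#' @return Mixture Tg, K.
#' @export
gordon_taylor <- function(Tg1, Tg2, w2, K_gt) {
  if (any(w2 < 0 | w2 > 1)) stop("w2 must lie in [0, 1]")
  if (any(K_gt <= 0)) stop("K_gt must be positive")
  w1 <- 1 - w2
  (w1 * Tg1 + K_gt * w2 * Tg2) / (w1 + K_gt * w2)
}

#' Simha--Boyer estimate of the Gordon--Taylor constant
#'
#' \eqn{K = \rho_1 T_{g1} / (\rho_2 T_{g2})} — the density-based form,
#' requiring only the pure-component densities and glass transitions.
#'
#' @param rho1,Tg1 density (g/cm^3) and Tg (K) of component 1.
#' @param rho2,Tg2 density and Tg of component 2.
#' @return The constant K (dimensionless).
#' @export
k_simha_boyer <- function(rho1, Tg1, rho2, Tg2) {
  vals <- c(rho1, Tg1, rho2, Tg2)
  if (any(vals <= 0)) stop("densities and temperatures must be positive")
  (rho1 * Tg1) / (rho2 * Tg2)
}

#' Fox mixture Tg
#'
#' \deqn{\frac{1}{T_g} = \frac{1 - w_2}{T_{g1}} + \frac{w_2}{T_{g2}}}
#' — the parameter-free harmonic blend; always at or below the
#' mass-weighted arithmetic mean when the components differ.
#'
#' @inheritParams gordon_taylor
#' @return Mixture Tg, K.
#' @export
fox <- function(Tg1, Tg2, w2) {
  if (any(w2 < 0 | w2 > 1)) stop("w2 must lie in [0, 1]")
  1 / ((1 - w2) / Tg1 + w2 / Tg2)
}

#' Fusion-temperature fraction rule
#'
#' The empirical band \eqn{T_g \in (0.6 T_f, 0.8 T_f)} holding for most
#' small-molecule pharmaceuticals.
#'
#' @param Tf fusion temperature, K (> 0).
#' @return Named vector \code{c(low, high)} in K.
#' @export
tf_rule <- function(Tf) {
  if (any(Tf <= 0)) stop("Tf must be positive")
  c(low = 0.6 * Tf, high = 0.8 * Tf)
}

#' Tg versus composition trend
#'
#' Orders Tg estimates of one component pair by the excipient mole
#' fraction and reports a rank-concordance statistic (Spearman rho between
#' composition and averaged Tg) quantifying the monotone trend.
#'
#' @param estimates list of \code{"tg_estimate"} objects.
#' @param specs list of matching \code{\link{mixture_spec}}s (same length).
#' @param excipient name of the excipient component whose mole fraction
#'   orders the series; default the second component of the first spec.
#' @return A list of class \code{"tg_trend"}: \code{table} (data.frame
#'   ordered by excipient fraction: \code{x_excipient}, \code{Tg_avg},
#'   \code{sd}), \code{concordance} (Spearman rho; 0 when Tg is constant),
#'   \code{excipient}.
#' @export
tg_vs_composition <- function(estimates, specs, excipient = NULL) {
  if (length(estimates) < 2) stop("need at least two compositions")
  if (length(estimates) != length(specs)) stop("one spec per estimate required")
  pairs <- lapply(specs, function(s) sort(s$names))
  if (length(unique(vapply(pairs, paste, "", collapse = "|"))) != 1)
    stop("all compositions must share the same component pair")
  if (is.null(excipient)) excipient <- specs[[1]]$names[2]
  xs <- vapply(specs, function(s) {
    i <- match(excipient, s$names)
    if (is.na(i)) stop("excipient '", excipient, "' not in mixture spec")
    s$x[i]
  }, numeric(1))
  tg <- vapply(estimates, function(e) e$Tg_avg, numeric(1))
  sd <- vapply(estimates, function(e) e$Tg_avg_sd, numeric(1))
  o <- order(xs)
  tab <- data.frame(x_excipient = xs[o], Tg_avg = tg[o], sd = sd[o])
  conc <- if (stats::sd(tg) == 0 || stats::sd(xs) == 0) 0
  else suppressWarnings(stats::cor(xs, tg, method = "spearman"))
  structure(list(table = tab, concordance = conc, excipient = excipient),
            class = "tg_trend")
}

#' @export
print.tg_trend <- function(x, ...) {
  cat(sprintf("<tg_trend> Tg vs x(%s), rank concordance %.2f\n",
              x$excipient, x$concordance))
  print(x$table, row.names = FALSE)
  invisible(x)
}
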