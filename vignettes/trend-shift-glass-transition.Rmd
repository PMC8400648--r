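---
title: "Trend-shift glass transition analysis from molecular dynamics scans"
author: "tgtrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trend-shift glass transition analysis from molecular dynamics scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgtrend)
```

## The problem

Amorphous solid dispersions are a standard strategy for raising the
solubility of poorly soluble drugs: the active pharmaceutical ingredient
(API) is kept in a metastable glassy state, often stabilised by a
low-molecular-weight co-former (an excipient — here, nucleobases such as
adenine and cytosine). The key material property is the glass transition
temperature $T_g$: the further storage conditions sit below $T_g$, the
slower the relaxation toward recrystallisation. Molecular dynamics (MD)
gives direct access to the two observables that distinguish the glass
from the liquid — the thermal expansion of the density and the molecular
self-diffusivity — and `tgtrend` implements the analysis layer that turns
MD output into a $T_g$ estimate with a defensible uncertainty.

## The trend-shift model

Both density and diffusivity change their temperature trend at the glass
transition: the liquid contracts faster on cooling than the glass
(steeper $\rho(T)$ slope above $T_g$), and the self-diffusivity falls to
a statistically-zero floor below it. The estimator fits the continuous
two-segment ("hinge") model

$$ y(T) = c + b_L\,(T - T_b)\,[T < T_b] + b_R\,(T - T_b)\,[T \ge T_b] $$

to an observable series by weighted least squares and reports the break
point $T_b$ as $T_g$. At fixed $T_b$ the model is linear in
$(c, b_L, b_R)$, so `segfit()` profiles the residual sum of squares over
the break: every admissible inter-point interval is searched with a 1-D
optimiser and the interval edges are checked explicitly, because the
profile is smooth only within an interval. Exact ties break toward the
lower temperature (the conservative $T_g$ call). An exhaustive
fixed-resolution knot grid is used as a brute-force oracle in the test
suite; the profiled optimum agrees with it to within one 0.1 K grid step
on every tested fixture.

Two readings of "two interpolating lines" exist: lines constrained to
meet at the break (the hinge) and two free lines with $T_g$ at their
intersection $x^* = (a_1 - a_2)/(b_2 - b_1)$. Both are supported
(`method = "hinge"` / `"twolines"`); the hinge is the default because it
is better conditioned — the free-lines intersection degrades when the
slopes are close. The `twolines` route doubles as an analytic cross-check
of the uncertainty propagation (below).

### Uncertainty propagation

The standard deviation of $T_g$ comes from the error-propagation (delta)
law. For the hinge, the residual Jacobian at the optimum over
$(c, b_L, b_R, T_b)$ gives the parameter covariance
$\sigma^2 (J^T W J)^{-1}$; the normal matrix is rescaled to unit diagonal
before inversion because slope and temperature columns differ by many
orders of magnitude. For the two-line variant, the gradient of $x^*$ is
differentiated analytically (`intersection_sd()`); the two routes agree
within about 10% on well-conditioned fixtures, which the suite checks.

Two properties of this estimator are worth knowing:

* **Calibration.** Over repeated synthetic scans, the mean absolute
  error of the combined $T_g$ stays below the mean reported standard
  deviation — the propagated uncertainty is a usable (slightly
  conservative) error bar. The suite verifies this over 50 seeds.
* **Finite-sample bias.** A break point is a ratio of fitted quantities,
  and ratios of noisy estimates are biased. At the default noise levels
  on a 10 K grid the bias of the combined estimate is a few tenths of a
  kelvin — real (it survives the brute-force oracle, so it is not a
  search artefact) but an order of magnitude below the grid spacing and
  well below the reported uncertainties.

### Branch combination

`estimate_tg()` runs both branches and averages them,
$T_g = (T_{g,\rho} + T_{g,D})/2$, with the branch uncertainties combined
in quadrature and halved. A gap above 25 K between the branches raises a
consistency flag: the two observables see the same transition, and a
larger disagreement signals an ill-determined break in at least one
branch rather than genuine physics. Degenerate inputs surface as flags
or errors, never as silent numbers: a single-slope series carries a
`no_break` flag (slopes indistinguishable within noise, tested as
$|b_R - b_L| < 2\,\mathrm{sd}(b_R - b_L)$), and an all-zero diffusivity
column is an error.

### Weights and scales

Points are weighted $1/\mathrm{sd}^2$ when the scan carries
uncertainties; zero or missing uncertainties fall back to an unweighted
fit rather than infinite weights. The diffusivity branch is fitted on the
linear $D$ scale: glass-phase diffusivities are statistically zero, so a
log transform is undefined exactly where the glass branch lives.

## Synthetic data: what is emulated, what is not

The generators provide every input the pipeline needs with known ground
truth attached as a sidecar:

* `generate_thermal_scan()` draws a density branch that is continuous
  piecewise-linear with the slope change at the true $T_g$
  (liquid slope more negative, default $-8\times10^{-4}$ vs
  $-2\times10^{-4}$ g cm$^{-3}$ K$^{-1}$), and a diffusivity branch that
  sits at a small floor ($2\times10^{-7}$ Å$^2$ fs$^{-1}$) below $T_g$
  and rises above it, on a 200–500 K grid in 10 K steps — the grid
  layout of a typical cooling protocol. Noise is Gaussian: absolute
  ($1.5\times10^{-3}$ g cm$^{-3}$) on density, fractional (15%) on
  diffusivity — the density of an NPT run is sharply determined while
  transport coefficients from short trajectories scatter strongly.
* The default liquid-branch diffusivity law is **linear** in $T$. An
  activation-type (Arrhenius) law is available
  (`D_law = "arrhenius"`), but it is convex over a 300 K window, and a
  linear-scale hinge fitted to a convex branch lands systematically
  above the true break — tens of kelvin at zero noise, as one suite test
  documents. A hinge estimator is consistent only for a locally linear
  branch, so estimator calibration uses the linear law; the Arrhenius
  option exists to study exactly that model-mismatch effect.
* `generate_brownian_trajectory()` produces free diffusion with per-axis
  increment variance $2 D \Delta t$; `generate_caged_trajectory()` an
  Ornstein–Uhlenbeck walk around fixed sites whose stationary MSD
  plateau is $2 r_{cage}^2$ by construction. Both store the true
  unwrapped paths.

What the synthetic data does **not** emulate: force-field realism,
correlated (non-Gaussian, autocorrelated) noise of real MD observables,
cooling-rate dependence of the transition, and any chemistry-specific
coupling between the density and diffusivity branches. Passing the
recovery tests therefore demonstrates the correctness of the analysis
chain, not the accuracy of any particular force field.

## The toy glass former

`simulate_lj_glassformer()` is a compiled velocity-Verlet engine for the
canonical 80:20 binary Lennard-Jones mixture with non-additive cross
parameters ($\epsilon_{AB} = 1.5$, $\sigma_{AB} = 0.8$ against
$\epsilon_{AA} = \sigma_{AA} = 1$), shifted potential cut off at
$2.5\sigma$ — a system that vitrifies rather than crystallises at desk
scale. Temperature and pressure are held by Berendsen-style weak
couplings (an isotropic barostat); with the couplings off, the NVE
integrator conserves energy to better than $10^{-3}$ relative over
$10^4$ steps at $\Delta t = 0.002$ and conserves momentum to rounding —
both under test. The contract of the engine is on ensemble means (mean
$T$ within 2% of target, mean $P$ near target), not on reproducing any
particular thermostat's fluctuation spectrum.

`run_thermal_protocol()` drives the sequential scan: equilibration then
production at each grid temperature, carrying the configuration to the
next temperature, and aggregates a `thermal_scan` — density from
production volumes, diffusivity from an Einstein fit on production
frames. Reduced units are converted at the analysis boundary by a
declared mapping (`lj_units()`, argon-like by default:
$\sigma = 3.405$ Å, $\epsilon/k_B = 119.8$ K).

Problem sizes in the tests — 150 particles, $10^3$–$2\times10^4$ steps
per phase, ten grid temperatures — are chosen so a full cooling scan
with a clearly detectable density break runs in about a minute; the
break the suite detects for this protocol sits near $T^* \approx 0.4$,
with the liquid branch roughly twice as steep as the glass branch.

## Dynamics analysis choices

* Coordinates are stored as read; `unwrap_trajectory()` is explicit and
  refuses frame-to-frame displacements of half a box edge or more
  (undersampled trajectory, ambiguous image).
* MSD reduction uses **mass-weighted molecular centres**, removing
  intramolecular vibration; the per-molecule reduction is a separate
  explicit step (`molecular_centers()`).
* The default Einstein fit window is 10–50% of the maximum lag,
  excluding the short-time ballistic/cage regime and the noisy long-lag
  tail; for glassy systems a linear regime may simply not exist within a
  short trajectory, so the window is a visible parameter, not an
  automatic choice.
* The slope uncertainty comes from the **dispersion of per-particle
  slopes** ($\mathrm{sd}/\sqrt{N}$). Particles are the only independent
  unit in an MSD curve: overlapping time origins correlate neighbouring
  lags so strongly that residual-based standard errors are optimistic by
  an order of magnitude. The statistically-zero call for glassy
  trajectories (`subdiffusive` flag) and its complement for liquids both
  rest on this estimate; the diffusion exponent
  (`msd_exponent()`, the log–log slope) is provided as a sharper regime
  classifier.

## Structure and energetics conventions

Site–site radial distribution functions are normalised by the ideal-gas
pair density of the selected populations with the per-frame box volume
(NPT-compatible), default bin width 0.05 Å. The first-peak locator
refines the maximum bin with a three-point parabola and flags boundary
maxima as non-peaks. Hydrogen-bond contacts use a **distance-only**
H···acceptor criterion (default cutoff 2.5 Å, minimum image,
intramolecular pairs excluded) — the analysis this package supports is
expressed through distance distributions of donor/acceptor sites, so no
angular term is imposed.

Vaporization energetics assume an ideal vapor with a single-molecule
(intramolecular-only) gas reference:
$U_{vap} = \langle U_{gas}\rangle - \langle U_{liq}\rangle/n$ and
$\Delta H_{vap} = U_{vap} + RT$ with
$R = 8.31446\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$ — an identity the
suite checks to machine precision. Per-mass specific energies are
reported on both the kJ/g and J/g scales, because published comparisons
of this quantity are ambiguous about the unit at the ~0.5–1.0 kJ/g
magnitude typical for organic glasses. Fusion enthalpy is a plain
two-phase per-molecule enthalpy difference at a stated temperature, with
no superheating correction, and is labelled as such.

## Mixture rules

Gordon–Taylor
$T_g = (w_1 T_{g1} + K w_2 T_{g2})/(w_1 + K w_2)$ and Fox
$1/T_g = w_1/T_{g1} + w_2/T_{g2}$ operate on mass fractions; molar
compositions (the natural reporting unit for API:excipient ratios such
as 1:3, 1:1, 3:1) are converted explicitly via
`mole_to_mass_fraction()`. The Gordon–Taylor constant defaults to the
density-based Simha–Boyer form $K = \rho_1 T_{g1}/(\rho_2 T_{g2})$,
which needs only quantities the rest of the pipeline already produces.
These rules are reported alongside trend-shift estimates, never blended
into them. `tg_vs_composition()` orders estimates by excipient mole
fraction and attaches a Spearman rank concordance as the monotone-trend
statistic, with the convention that a constant series has concordance 0.

## A worked example

```{r example}
truth <- scan_truth(true_Tg = 350)
scan <- generate_thermal_scan(truth, seed = 42)
est <- estimate_tg(scan)
est
```

```{r plot, fig.width = 7, fig.height = 3.5}
plot(est)
```

## Known limitations

* The hinge fit assumes exactly one break; multi-step relaxations or
  smooth crossovers are reported as the single best break with a wide
  uncertainty, not detected as model misfit.
* The diffusivity branch on the linear scale is dominated by the
  highest-temperature points when uncertainties are absent; supplying
  per-point standard deviations is strongly recommended.
* The propagated $T_g$ uncertainty is a local (delta-method) quantity;
  for data where the profile has competing minima it understates the
  true ambiguity, which is why the no-break and consistency flags
  accompany every estimate.
* The toy engine is a calibration instrument for the analysis chain.
  Its Berendsen-style couplings produce correct means but suppressed
  fluctuations; quantities derived from fluctuation magnitudes (heat
  capacities, compressibilities) are out of scope.
* Empirical mixture rules are interpolations between pure-component
  glass transitions; they carry no information about specific
  interactions and are reported for orientation only.
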