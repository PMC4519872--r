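---
title: "Models and methods behind quenchbind"
author: "quenchbind authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quenchbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

`quenchbind` analyses steady-state fluorescence titrations of a protein by a
small-molecule ligand that quenches the protein's intrinsic (tryptophan)
emission. The running example throughout the package is the gallic
acid-lysozyme pair — a protein emitting at about 341 nm under 282 nm
excitation, titrated with a phenolic ligand that absorbs at both wavelengths —
but every routine is generic. This vignette states each model, its
assumptions, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## Inner-filter correction

A ligand that absorbs at the excitation or emission wavelength attenuates
the measured fluorescence for purely optical reasons. Before any fitting,
observed intensities are corrected with the standard factor

$$F_\mathrm{corr} = F_\mathrm{obs}\,10^{(A_\mathrm{ex}+A_\mathrm{em})/2},$$

where $A_\mathrm{ex}$ and $A_\mathrm{em}$ are the solution absorbances (AU,
1 cm path) at the two wavelengths. The half-power form assumes fluorescence
is collected from the cuvette centre. The correction factor is $\ge 1$ and
monotone in each absorbance; negative absorbances are rejected. All
downstream analyses use the corrected band maximum as the scalar intensity
$F$ — band maxima are what titration studies plot, and the peak is located
before correction does not matter because the correction is multiplicative
at fixed wavelengths.

## Stern-Volmer analysis and mechanism classification

Collisional (dynamic) quenching follows

$$F_0/F = 1 + K_\mathrm{sv}[Q],$$

and `stern_volmer_fit()` estimates $K_\mathrm{sv}$ by ordinary least squares
of $F_0/F$ on $[Q]$ with a *free* intercept: the reported correlation
coefficient, residual standard deviation and slope p-value presuppose an
unconstrained regression, and an intercept far from 1 is itself a useful
diagnostic of curvature or a bad reference point. The bimolecular quenching
rate constant is $K_q = K_\mathrm{sv}/\tau_0$, with the unquenched lifetime
defaulting to $\tau_0 = 10^{-8}$ s, the usual biopolymer value; it is a
parameter, not a constant, because lifetime-resolved values are better when
available.

`classify_mechanism()` encodes the standard argument: collisional quenching
cannot exceed the diffusion-controlled encounter rate, about
$2\times10^{10}$ L mol$^{-1}$ s$^{-1}$ for quenchers of biopolymers, so
$K_q$ above that limit (with a significant slope, default $\alpha = 0.05$)
implies ground-state complex formation — static quenching. A slope that is
not significantly positive yields `"none"`. The package deliberately fits
no mixed static+dynamic (quadratic) model: when the Stern-Volmer plot is
linear, the data cannot identify two mechanisms at once.

## Binding constant and stoichiometry

For static quenching with $n$ equivalent independent sites,

$$\log_{10}\frac{F_0-F}{F} = \log_{10} K + n \log_{10}[Q],$$

fit by OLS over the nonzero-concentration points (`double_log_fit()`).
Logarithms are base 10 — the convention of this literature; misreading the
base changes $K$ by orders of magnitude, so the convention is pinned in the
test suite. Two approximations are inherited from the model itself: the free
ligand concentration is approximated by the total added concentration, and
$(F_0-F)/F$ is taken as the bound/free ratio. Points where noise pushes
$F \ge F_0$ have no defined log-ratio; the fit refuses such series rather
than silently dropping points.

Confidence intervals (`confint()`) use a parametric bootstrap at the
*intensity* level. The naive choice — resampling the residuals of the
log-log regression — is badly wrong here, because the reference intensity
$F_0$ enters every log-ratio: a single multiplicative error in $F_0$ tilts
all points coherently, inflating the true sampling variance far beyond the
within-fit scatter. The bootstrap therefore estimates the relative noise from the
scatter of intensities around the fitted isotherm $F = F_0/(1+K[Q]^n)$,
simulates whole intensity vectors including $F_0$, and refits; percentile
intervals of the replicates are returned. Replicates in which noise erases
the quenching signal at all but fewer than three points are dropped, mirroring
what an experimenter would do with such a titration.

## Van't Hoff thermodynamics and force classification

`vant_hoff_fit()` regresses $\ln K$ on $1/T$ (an exact solve for two
temperatures): $\Delta H^\circ = -R\,\mathrm{slope}$,
$\Delta S^\circ = R\,\mathrm{intercept}$, assuming both are constant over
the temperature range — with only two temperatures this is untestable, and
results should be read accordingly. Free energies are reported as
$\Delta G^\circ(T) = -RT\ln K(T)$ from the *unrounded* K values rather than
as $\Delta H^\circ - T\Delta S^\circ$ on rounded estimates: the two forms
are algebraically identical for a two-point fit, but the latter amplifies
rounding (with three-significant-figure K values the difference reaches
several percent). $R = 8.314$ J mol$^{-1}$ K$^{-1}$; energies are kJ/mol
throughout.

The force classification follows the standard sign rules for protein-ligand
association: $\Delta H^\circ>0,\Delta S^\circ>0$ hydrophobic;
$\Delta H^\circ<0,\Delta S^\circ<0$ van der Waals plus hydrogen bonding;
$\Delta S^\circ>0$ with $\Delta H^\circ\le 0$ electrostatic or hydrophobic.
Exact zeros — and the $\Delta H^\circ>0,\Delta S^\circ<0$ quadrant, which
the rules do not cover — return `"indeterminate"` with a warning rather than
silently picking a label.

## FRET parameters

Transfer efficiency is measured as $E = 1 - F/F_0$ at (conventionally)
equimolar donor and acceptor. The overlap integral

$$J = \frac{\int F(\lambda)\,\varepsilon(\lambda)\,\lambda^4\,d\lambda}
           {\int F(\lambda)\,d\lambda}$$

is computed by trapezoidal quadrature on the donor's native grid after
linearly interpolating the acceptor absorptivity onto it, with $\lambda$
converted to cm inside the integrand so that, with $\varepsilon$ in
L mol$^{-1}$ cm$^{-1}$, $J$ carries cm$^3$ L mol$^{-1}$. The critical
distance uses

$$R_0^6 = 8.8\times10^{-25}\,\kappa^2 N^{-4}\Phi\,J$$

with $R_0$ in cm (returned in nm). That numeric constant is tied to exactly
this unit convention — the single most error-prone step in a FRET
calculation — and is pinned by a dedicated unit test. Defaults
$\kappa^2 = 2/3$ (random orientation), $N = 1.336$ (aqueous buffer),
$\Phi = 0.118$ (tryptophan donor); all overridable. The distance inverts
$E = R_0^6/(R_0^6+r^6)$, and two admissibility diagnostics are reported
separately rather than fused into one rule: $r < 6$ nm (practical range of
the dipole-dipole mechanism) and $0.5R_0 < r < 1.5R_0$ (the window where
$E$ is sensitive to $r$).

A note on the reference system: recomputing $R_0$ from the published inputs
of the gallic acid-lysozyme pair ($J = 1.15\times10^{-15}$ cm$^3$ L
mol$^{-1}$ and the defaults above) gives 1.71 nm where 1.69 nm was printed,
a ~1.2% difference not explained by rounding of $J$; the published
$r = 2.12$ nm is, however, exactly consistent with $E = 0.203$ and
$R_0 = 1.69$ nm. The package reports its computed values and the test suite
asserts the recomputed $R_0$ agrees with the printed one only to within
1.5%, while the $r$-from-$(E, R_0)$ inversion is held to the printed
precision.

## Conformational analysis

Synchronous scans (fixed offset $\Delta\lambda$ between excitation and
emission; 15 nm reports the tyrosine microenvironment, 60 nm the tryptophan
one) are summarized by the shift of the band maximum across the titration.
Peak positions come from a three-point parabolic interpolation through the
maximum sample and its neighbours: shifts of interest (~1.6 nm) are close to
typical 1 nm sampling steps, so nearest-sample peak picking cannot resolve
them. A maximum on the grid boundary raises an error — the band was not
fully captured. The shift is last-minus-first, so red shifts are positive,
and it is invariant under uniform intensity scaling.

The fluorescence phase diagram plots $I(\lambda_1)$ against $I(\lambda_2)$
across the perturbation series. If the system interconverts between exactly
two spectral states every spectrum is an affine mixture of the endpoints, so
the points are collinear for *any* wavelength pair; curvature indicates
populated intermediates. `phase_diagram_fit()` reports the OLS intercept
$a$, slope $b$, and $R^2$, with a `two_state` verdict at $R^2 \ge 0.98$ by
default — the linearity criterion is qualitative in the literature, so the
threshold is explicit and configurable, and the verdict should be read
together with the $R^2$ itself. Intensities are linearly interpolated, so
analysis wavelengths (default pair 320/365 nm, bracketing the tryptophan
band) need not sit on the sampling grid. No selection statistic for the
pair is established in the literature; `phase_pair_scan()` reports $R^2$
for every candidate pair and leaves the choice to the user.

## MM-PBSA bookkeeping

`read_energy_table()` and `aggregate_energy()` audit externally produced
MM-PBSA decompositions; the package computes no solvation energies itself.
The identities

$$\Delta G_\mathrm{solv} = \Delta G_\mathrm{pol} + \Delta G_\mathrm{nonpol},
\quad \Delta G_\mathrm{gas} = \Delta G_\mathrm{vdw} + \Delta G_\mathrm{elec},
\quad \Delta G = \Delta G_\mathrm{gas} + \Delta G_\mathrm{solv} - T\Delta S$$

are recomputed from the component columns, and any aggregate columns present
in the input are compared against the recomputed values with a 0.02 kJ/mol
rounding tolerance — published tables round components to two decimals, so
sums can disagree with printed totals by up to that much without being
wrong. $T\Delta S$ defaults to zero because tabulated summaries commonly
omit the entropy term. Units are fixed to kJ/mol; kcal tables must be
converted explicitly, a deliberate refusal to auto-detect that guards
against silent 4.184-fold errors.

## The synthetic-data generator

`generate_titration()` inverts the double-log fitting equation into a
forward model: the fraction of protein still emitting at $[Q]$ is
$1/(1+K(T)[Q]^n)$ (the fitting equation itself is only ever written in
linearized form in the literature, so the isotherm is the model it implies).
Its defaults are the reference study's conditions: eight points at 0 to
$4\times10^{-5}$ mol/L quencher, protein at $10^{-5}$ mol/L, a Gaussian
emission band centred at 341 nm under 282 nm excitation, $K = 3.93\times10^5$
L/mol and $n = 1.3985$ at 298 K, and a 1.6 nm red shift of the band centre
at full saturation. The band width (s.d. 18 nm) is chosen to visually match
a tryptophan emission band; published figures show but do not parameterize
band shapes. When $\Delta H$/$\Delta S$ are supplied, $K(T)$ follows the
Van't Hoff relation, giving exact round-trip tests of the thermodynamic
stage. Ligand absorbance produces inner-filter attenuation
$10^{-(A_\mathrm{ex}+A_\mathrm{em})/2}$ with $A = \varepsilon c$ (1 cm
path); the ligand itself is non-fluorescent. Noise is multiplicative
Gaussian — detector noise on these instruments is closer to relative than
additive — with magnitude free and zero by default, and is drawn from a
private RNG stream under the ground-truth seed, leaving the caller's RNG
state untouched.

What the generator does **not** emulate: photobleaching, scattering and
Raman bands, instrument baseline drift, excited-state lifetimes, ligand
depletion (free ligand is approximated by total ligand, as the fitting
equations implicitly do), and any coupling between quenching and band
shape beyond the linear centre shift. Passing recovery tests on this
generator therefore demonstrates the correctness of the estimators under
the model's own assumptions, not robustness to every artifact of real
spectra.

A note on one study condition: with the reference thermodynamics
($\Delta H = -388.81$ kJ/mol, $\Delta S = -1.20$ kJ/(mol K)) the binding
constant at 310 K is ~$9\times10^2$ L/mol, which quenches under 0.1% of the
emission over this concentration range — less than any realistic noise
level. End-to-end pipeline tests therefore run that configuration
noiseless; the bootstrap-coverage test instead uses a deliberately
well-conditioned design ($K = 5\times10^6$ L/mol, quenched fraction
spanning ~12-78%) because the log-ratio response must be defined at every
point for 200 replicates at 1% noise to be fittable at all.

## Problem sizes and determinism

All tests and examples run on small problems chosen for statistical
adequacy: titrations of 8 points on 181-point wavelength grids, 200-replicate
coverage studies with 299 bootstrap resamples each, and fine-grid (0.001 nm)
Riemann oracles for the overlap integral. Every stochastic component takes
an explicit seed; pipeline reports and TSV serializations are byte-identical
across repeated runs on the same inputs.

## Known limitations

- Per-temperature linearized fits only; no global nonlinear fit of the
  isotherm across temperatures.
- The Stern-Volmer stage assumes a single quenching mechanism; upward
  curvature from mixed quenching is visible in the intercept/R diagnostics
  but not modelled.
- The apparent stoichiometry $n$ from the double-log plot is a fit
  parameter, not a site count; it can change with temperature without a
  structural interpretation, and the package reports it per temperature
  without further claims.
- Two-temperature Van't Hoff analysis cannot detect heat-capacity effects.
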