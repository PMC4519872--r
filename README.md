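# quenchbind

Analysis of steady-state fluorescence titrations of a protein by a
small-molecule quencher, for spectroscopists and biophysical chemists who
study protein–ligand binding. From a titration series of emission spectra
(plus absorbances for the inner-filter correction), the package estimates:

- the **Stern–Volmer constant** from F₀/F = 1 + K_sv[Q] and the bimolecular
  rate constant K_q = K_sv/τ₀, with mechanism classification (static vs.
  dynamic quenching) against the diffusion-controlled limit of
  2×10¹⁰ L mol⁻¹ s⁻¹;
- the **binding constant K and stoichiometry n** from the double-logarithmic
  isotherm log₁₀[(F₀−F)/F] = log₁₀K + n·log₁₀[Q], with intensity-level
  bootstrap confidence intervals;
- **Van't Hoff thermodynamics** (ΔH°, ΔS° from ln K vs. 1/T;
  ΔG°(T) = −RT ln K) with the standard sign-rule classification of the
  dominant intermolecular force;
- **FRET parameters**: efficiency E = 1 − F/F₀, overlap integral
  J = ∫F(λ)ε(λ)λ⁴dλ / ∫F(λ)dλ, critical distance
  R₀⁶ = 8.8×10⁻²⁵ κ²N⁻⁴ΦJ, and donor–acceptor distance
  r = R₀((1−E)/E)^(1/6);
- **conformational diagnostics**: synchronous-fluorescence peak shifts
  (sub-grid parabolic peak location) and the fluorescence phase-diagram
  two-state test I(λ₁) = a + b·I(λ₂);
- **MM-PBSA bookkeeping**: parsing, decomposition-identity checking and
  cross-temperature comparison of externally produced energy-component
  tables (ΔG = ΔG_gas + ΔG_solv − TΔS).

A seedable synthetic-titration generator with known ground truth
(`ground_truth()`, `generate_titration()`, `generate_synchronous()`,
`generate_two_state_series()`) makes the whole pipeline testable end to end;
its defaults emulate the gallic acid–lysozyme system (emission maximum
341 nm at λ_ex = 282 nm, eight titration points from 0 to 4×10⁻⁵ mol/L).

## Worked example

Simulate a two-temperature titration with the reference thermodynamics and
run the full pipeline:

```r
library(quenchbind)

concs <- c(0, 0.4, 0.8, 1, 1.6, 2.4, 3.2, 4) * 1e-5   # mol/L
eps <- example_ligand_eps()                            # quencher absorptivity
series <- lapply(c(298, 310), function(Tk) {
  gt <- ground_truth(dH_kJ = -388.81, dS_kJ = -1.20,
                     shift_per_sat_nm = 1.6, ligand_eps = eps)
  generate_titration(gt, concs, Tk, seq(260, 440))
})
report <- run_pipeline(series, acceptor_eps = eps)
report
```

Excerpts of the printed report:

```
Stern-Volmer quenching fit
  T = 298 K, n = 8 points
  Ksv = 5315 L/mol   Kq = 5.315e+11 L/(mol s)  (tau0 = 1e-08 s)
  intercept = 0.9839  R = 0.9912  SD = 0.01081  p(slope) = 1.689e-06
  mechanism: static
...
Van't Hoff thermodynamic analysis
  dH = -389 kJ/mol   dS = -1.201 kJ/(mol K)
  dG(298 K) = -31.22 kJ/mol   (K = 296677 L/mol)
  dG(310 K) = -16.81 kJ/mol   (K = 680.1 L/mol)
  dominant forces: vdw_hbond
```

K_q is far above the 2×10¹⁰ L mol⁻¹ s⁻¹ collisional ceiling, so the 298 K
quenching is static (complex formation); the fitted ΔH and ΔS recover the
generator's ground truth, both negative, classifying the driving forces as
van der Waals interactions plus hydrogen bonding; ΔG is negative and rises
with temperature — binding weakens on warming.

Desk-scale calculations work directly on published numbers:

```r
donor_acceptor_distance(E = 0.203, R0_nm = 1.69)$r_nm
#> [1] 2.12266            # nm; inside the r < 6 nm FRET window

rows <- read_energy_table(system.file("extdata", "ga_lys_mmpbsa.tsv",
                                      package = "quenchbind"))
rows[[1]]
#> MM-PBSA components at 298 K (kJ/mol): vdw -44.92, elec -24.22, pol 58.98, nonpol -1.79, TdS 0.00
#>   gas -69.14 + solv 57.19 - TdS = total -11.95
compare_temperatures(rows)
#>   T_from T_to ddG_kJ                direction
#> 1    298  310   4.39 weaker at higher index T
```

The consistency audit attached to each parsed row
(`attr(rows[[1]], "consistency")`) compares any aggregate columns present in
the file against the recomputed decomposition with a 0.02 kJ/mol rounding
tolerance.

See `vignettes/quenchbind-methods.Rmd` for the models, assumptions and
numerical choices, and what the synthetic generator does and does not
emulate.

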