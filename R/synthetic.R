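#' Ground truth for synthetic quenching titrations
#'
#' Parameter set of the forward model used by [generate_titration()] and
#' friends. Static quenching by ground-state complex formation is modelled
#' through the binding isotherm: with binding constant `K` and apparent
#' stoichiometry `n`, the fraction of protein still emitting at quencher
#' concentration `[Q]` is `1 / (1 + K [Q]^n)`, so the quenched intensity is
#' `F = F0 / (1 + K [Q]^n)`. When `dH_kJ`/`dS_kJ` are supplied, the binding
#' constant at temperature T follows the Van't Hoff relation
#' `K(T) = exp(-dH/(R T) + dS/R)`; otherwise `K_bind` is used as given.
#'
#' The emission band is Gaussian (centre `band_center_nm`, s.d.
#' `band_width_nm`); its centre red-shifts linearly with the bound fraction,
#' reaching `shift_per_sat_nm` at full saturation. If a ligand molar
#' absorptivity spectrum is supplied, the observed intensity is attenuated by
#' the inner-filter factor `10^-((A_ex + A_em)/2)` with `A = eps * conc * 1 cm`.
#' Noise is multiplicative Gaussian with relative s.d. `noise_sd_rel`,
#' reproducible under `seed`. The defaults reproduce the gallic acid-lysozyme
#' study conditions: emission maximum 341 nm under 282 nm excitation,
#' K = 3.93e5 L/mol and n = 1.3985 at 298 K, and a 1.6 nm red shift at
#' saturation.
#'
#' @param K_bind binding constant, L/mol (per the `n`-th power isotherm).
#' @param n_sites apparent number of binding sites (isotherm exponent).
#' @param dH_kJ,dS_kJ optional binding enthalpy (kJ/mol) and entropy
#'   (kJ/(mol K)); when both given they override `K_bind` via Van't Hoff.
#' @param Ksv_dynamic additional collisional (dynamic) quenching constant,
#'   L/mol; 0 for purely static quenching.
#' @param band_center_nm,band_width_nm Gaussian emission band centre and
#'   standard deviation, nm.
#' @param shift_per_sat_nm red shift of the band centre at full saturation, nm.
#' @param ligand_eps optional [spectrum()] of kind `"molar_absorptivity"`
#'   (L mol^-1 cm^-1) for the quencher, used for inner-filter attenuation.
#' @param noise_sd_rel relative s.d. of multiplicative Gaussian noise.
#' @param seed integer RNG seed for the noise.
#' @return An object of class `"ground_truth"` (a validated list).
#' @export
ground_truth <- function(K_bind = 3.93e5, n_sites = 1.3985,
                         dH_kJ = NULL, dS_kJ = NULL,
                         Ksv_dynamic = 0,
                         band_center_nm = 341, band_width_nm = 18,
                         shift_per_sat_nm = 0,
                         ligand_eps = NULL,
                         noise_sd_rel = 0, seed = 1L) {
  if (!is.null(ligand_eps)) {
    stopifnot(inherits(ligand_eps, "spectrum"))
    if (ligand_eps$value_kind != "molar_absorptivity")
      stop("ligand_eps must have value_kind 'molar_absorptivity'",
           call. = FALSE)
  }
  if (K_bind <= 0 || n_sites <= 0 || band_width_nm <= 0 || noise_sd_rel < 0)
    stop("require K_bind > 0, n_sites > 0, band_width_nm > 0, noise_sd_rel >= 0",
         call. = FALSE)
  if (xor(is.null(dH_kJ), is.null(dS_kJ)))
    stop("supply both dH_kJ and dS_kJ or neither", call. = FALSE)
  structure(list(K_bind = K_bind, n_sites = n_sites,
                 dH_kJ = dH_kJ, dS_kJ = dS_kJ,
                 Ksv_dynamic = Ksv_dynamic,
                 band_center_nm = band_center_nm,
                 band_width_nm = band_width_nm,
                 shift_per_sat_nm = shift_per_sat_nm,
                 ligand_eps = ligand_eps,
                 noise_sd_rel = noise_sd_rel,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Gas constant, J mol^-1 K^-1
.R_GAS <- 8.314

#' Binding constant implied by a ground truth at a temperature
#'
#' `exp(-dH/(R T) + dS/R)` when the thermodynamic parameters are set,
#' otherwise `K_bind` unchanged.
#'
#' @param gt a [ground_truth()].
#' @param temperature_K temperature in kelvin.
#' @return binding constant, L/mol.
#' @export
K_at_temperature <- function(gt, temperature_K) {
  if (is.null(gt$dH_kJ)) return(gt$K_bind)
  exp(-gt$dH_kJ * 1000 / (.R_GAS * temperature_K) +
      gt$dS_kJ * 1000 / .R_GAS)
}

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Quenched-fraction model shared by the titration and synchronous generators.
# Returns, per concentration: remaining emitting fraction f_emit and bound
# fraction f_bound (drives the band shift).
.quench_state <- function(gt, concs, temperature_K) {
  K <- K_at_temperature(gt, temperature_K)
  KQ <- K * concs^gt$n_sites
  f_emit <- 1 / ((1 + KQ) * (1 + gt$Ksv_dynamic * concs))
  list(f_emit = f_emit, f_bound = KQ / (1 + KQ), K = K)
}

.band_values <- function(grid, center, width) {
  exp(-((grid - center)^2) / (2 * width^2))
}

#' Generate a synthetic quenching titration
#'
#' Forward model: at each quencher concentration the Gaussian emission band
#' (peak intensity `F0_peak` at zero quencher) is scaled by the emitting
#' fraction `1/(1 + K(T) [Q]^n)`, its centre shifted by
#' `shift_per_sat_nm * bound fraction`, then attenuated by the inner-filter
#' factor `10^-((A_ex + A_em)/2)` (absorbances from `ligand_eps * conc * 1 cm`),
#' and finally multiplied by `1 + noise` with Gaussian relative noise.
#' The recorded `A_ex`/`A_em` of each point are the true absorbances, so the
#' downstream inner-filter correction can undo the attenuation exactly
#' (up to noise).
#'
#' @param gt a [ground_truth()].
#' @param concs quencher concentrations (mol/L), starting at 0, strictly
#'   increasing, length >= 3.
#' @param temperature_K temperature in kelvin.
#' @param grid emission wavelength grid (nm); must span the band centre
#'   +/- 3 band widths.
#' @param protein_conc_M protein concentration recorded in the series
#'   metadata (does not enter the intensity model).
#' @param excitation_nm excitation wavelength recorded in the metadata and
#'   used to look up `A_ex` in `ligand_eps`.
#' @param F0_peak peak intensity of the unquenched band, arbitrary units.
#' @return A [titration_series()].
#' @export
generate_titration <- function(gt, concs, temperature_K, grid,
                               protein_conc_M = 1e-5, excitation_nm = 282,
                               F0_peak = 1000) {
  stopifnot(inherits(gt, "ground_truth"))
  concs <- as.numeric(concs)
  lo <- gt$band_center_nm - 3 * gt$band_width_nm
  hi <- gt$band_center_nm + abs(gt$shift_per_sat_nm) + 3 * gt$band_width_nm
  if (min(grid) > lo || max(grid) < hi)
    stop(sprintf("grid must span the emission band +/- 3 widths [%g, %g] nm",
                 lo, hi), call. = FALSE)
  st <- .quench_state(gt, concs, temperature_K)
  with_seed(gt$seed, {
    pts <- vector("list", length(concs))
    for (i in seq_along(concs)) {
      center <- gt$band_center_nm + gt$shift_per_sat_nm * st$f_bound[i]
      f <- F0_peak * st$f_emit[i] * .band_values(grid, center,
                                                 gt$band_width_nm)
      if (!is.null(gt$ligand_eps)) {
        A_ex <- spectrum_value_at(gt$ligand_eps, excitation_nm) * concs[i]
        A_em <- spectrum_value_at(gt$ligand_eps, center) * concs[i]
      } else {
        A_ex <- 0; A_em <- 0
      }
      f <- f * 10^(-(A_ex + A_em) / 2)
      if (gt$noise_sd_rel > 0)
        f <- f * (1 + stats::rnorm(length(f), 0, gt$noise_sd_rel))
      f <- pmax(f, 0)
      pts[[i]] <- titration_point(concs[i],
                                  spectrum(grid, f, "emission"),
                                  A_ex = A_ex, A_em = A_em)
    }
    titration_series(protein_conc_M, temperature_K, excitation_nm, pts)
  })
}

#' Generate synthetic synchronous-fluorescence scans
#'
#' A synchronous scan records intensity while sweeping excitation and
#' emission together at fixed offset `delta_lambda_nm = lambda_em - lambda_ex`.
#' Here the scan is the emission-band model evaluated at
#' `lambda_em = lambda_ex + delta_lambda`, with the same quench/shift model
#' as [generate_titration()]; the returned spectra are indexed by the
#' excitation wavelength.
#'
#' @param gt a [ground_truth()].
#' @param concs quencher concentrations, mol/L.
#' @param delta_lambda_nm positive wavelength offset, nm (15 reports the
#'   tyrosine microenvironment, 60 the tryptophan one).
#' @param grid excitation wavelength grid, nm.
#' @param temperature_K temperature in kelvin.
#' @param F0_peak unquenched peak intensity.
#' @return List of [spectrum()]s, one per concentration, in order.
#' @export
generate_synchronous <- function(gt, concs, delta_lambda_nm, grid,
                                 temperature_K = 298, F0_peak = 1000) {
  stopifnot(inherits(gt, "ground_truth"))
  if (delta_lambda_nm <= 0)
    stop("delta_lambda_nm must be positive", call. = FALSE)
  concs <- as.numeric(concs)
  st <- .quench_state(gt, concs, temperature_K)
  with_seed(gt$seed, {
    lapply(seq_along(concs), function(i) {
      center <- gt$band_center_nm + gt$shift_per_sat_nm * st$f_bound[i]
      lam_em <- grid + delta_lambda_nm
      f <- F0_peak * st$f_emit[i] *
        .band_values(lam_em, center, gt$band_width_nm)
      if (gt$noise_sd_rel > 0)
        f <- f * (1 + stats::rnorm(length(f), 0, gt$noise_sd_rel))
      spectrum(grid, pmax(f, 0), "emission")
    })
  })
}

#' Generate a two-state spectral mixture series
#'
#' Each output spectrum is the affine mixture
#' `f * spec_native + (1 - f) * spec_final` plus multiplicative noise. At
#' zero noise the intensities at any two wavelengths are exactly collinear
#' across the series — the signature a fluorescence phase diagram tests for.
#'
#' @param f_native fractions of the native state, each in \[0, 1\].
#' @param spec_native,spec_final endpoint [spectrum()]s on a common grid.
#' @param noise_sd_rel relative s.d. of multiplicative Gaussian noise.
#' @param seed RNG seed.
#' @return List of [spectrum()]s, one per fraction.
#' @export
generate_two_state_series <- function(f_native, spec_native, spec_final,
                                      noise_sd_rel = 0, seed = 1L) {
  stopifnot(inherits(spec_native, "spectrum"),
            inherits(spec_final, "spectrum"))
  if (!isTRUE(all.equal(spec_native$wavelengths_nm,
                        spec_final$wavelengths_nm)))
    stop("endpoint spectra must share the same wavelength grid",
         call. = FALSE)
  if (any(f_native < 0 | f_native > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    lapply(f_native, function(f) {
      v <- f * spec_native$values + (1 - f) * spec_final$values
      if (noise_sd_rel > 0)
        v <- v * (1 + stats::rnorm(length(v), 0, noise_sd_rel))
      spectrum(spec_native$wavelengths_nm, pmax(v, 0),
               spec_native$value_kind)
    })
  })
}

#' Default quencher absorptivity used in examples and simulations
#'
#' A smooth two-band molar absorptivity curve emulating a small phenolic
#' quencher that absorbs at both the protein excitation (282 nm) and emission
#' (341 nm) wavelengths — the situation that makes inner-filter correction
#' necessary.
#'
#' @param grid wavelength grid, nm.
#' @param eps_ex,eps_em molar absorptivity (L mol^-1 cm^-1) at 282 and
#'   341 nm respectively.
#' @return A [spectrum()] of kind `"molar_absorptivity"`.
#' @export
example_ligand_eps <- function(grid = seq(240, 500, by = 1),
                               eps_ex = 9000, eps_em = 2500) {
  v <- eps_ex * exp(-((grid - 270)^2) / (2 * 18^2)) +
    eps_em * 1.1 * exp(-((grid - 345)^2) / (2 * 30^2))
  # rescale so the curve hits the requested values exactly at 282/341 nm
  s <- spectrum(grid, v, "molar_absorptivity")
  a282 <- spectrum_value_at(s, 282); a341 <- spectrum_value_at(s, 341)
  # solve for the two band amplitudes giving the target values
  b1 <- exp(-((c(282, 341) - 270)^2) / (2 * 18^2))
  b2 <- exp(-((c(282, 341) - 345)^2) / (2 * 30^2))
  amp <- solve(cbind(b1, b2), c(eps_ex, eps_em))
  v <- amp[1] * exp(-((grid - 270)^2) / (2 * 18^2)) +
    amp[2] * exp(-((grid - 345)^2) / (2 * 30^2))
  spectrum(grid, pmax(v, 0), "molar_absorptivity")
}
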