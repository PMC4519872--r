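#' Analysis configuration for the full pipeline
#'
#' Collects every tunable constant of the analysis chain in one validated
#' object so a run is fully described by (inputs, config).
#'
#' @param tau0_s unquenched fluorophore lifetime, s.
#' @param kappa2,N_refr,Phi FRET constants, see [forster_radius()].
#' @param diffusion_limit collisional quenching ceiling, L mol^-1 s^-1.
#' @param r2_threshold phase-diagram linearity threshold.
#' @param phase_pair the two phase-diagram wavelengths, nm.
#' @param seed seed for any resampling (bootstrap intervals).
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(tau0_s = 1e-8, kappa2 = 2 / 3, N_refr = 1.336,
                            Phi = 0.118, diffusion_limit = 2.0e10,
                            r2_threshold = 0.98, phase_pair = c(320, 365),
                            seed = 1L) {
  if (any(c(tau0_s, kappa2, N_refr, Phi, diffusion_limit,
            r2_threshold) <= 0))
    stop("all physical constants must be positive", call. = FALSE)
  if (length(phase_pair) != 2L)
    stop("phase_pair must name exactly two wavelengths", call. = FALSE)
  structure(list(tau0_s = tau0_s, kappa2 = kappa2, N_refr = N_refr,
                 Phi = Phi, diffusion_limit = diffusion_limit,
                 r2_threshold = r2_threshold, phase_pair = phase_pair,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full quenching/binding/FRET/conformation pipeline
#'
#' Orchestrates the analysis chain on one titration series per temperature:
#' inner-filter correction and Stern-Volmer analysis with mechanism
#' classification, double-logarithmic binding fits, Van't Hoff
#' thermodynamics with force classification (skipped with a warning if only
#' one temperature is supplied), FRET parameters (when an acceptor
#' absorptivity spectrum is given) and the phase-diagram two-state test on
#' each series' emission spectra. Stages communicate through the typed fit
#' objects; TSV output is a serialization layer on top (see
#' [write_report_tsv()]).
#'
#' @param series_list list of [titration_series()] (or paths to YAML
#'   manifests, read via [read_titration()]), one per temperature.
#' @param config an [analysis_config()].
#' @param acceptor_eps optional acceptor molar absorptivity [spectrum()]
#'   enabling the FRET stage; the donor spectrum is the zero-quencher
#'   emission of the first series, and F/F0 is taken at the titration point
#'   whose quencher concentration is closest to the protein concentration
#'   (equimolar donor/acceptor, the standard convention for reporting E).
#' @return An object of class `"binding_report"` with elements `quenching`
#'   (list of [stern_volmer_fit()] + mechanism), `binding` (list of
#'   [double_log_fit()]), `thermo` ([vant_hoff_fit()] or NULL), `fret`
#'   ([fret_analysis()] or NULL), `conformation` (list of
#'   [phase_diagram_fit()]), and `config`.
#' @export
run_pipeline <- function(series_list, config = analysis_config(),
                         acceptor_eps = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  series_list <- lapply(series_list, function(s) {
    if (is.character(s)) read_titration(s) else s
  })
  if (!all(vapply(series_list, inherits, logical(1), "titration_series")))
    stop("series_list must contain titration series or manifest paths",
         call. = FALSE)

  quench <- lapply(series_list, function(s) {
    fit <- stern_volmer_fit(s, tau0_s = config$tau0_s)
    list(fit = fit,
         mechanism = classify_mechanism(fit, config$diffusion_limit))
  })
  binding <- lapply(series_list, double_log_fit)

  thermo <- NULL
  temps <- vapply(series_list, `[[`, numeric(1), "temperature_K")
  if (length(unique(temps)) >= 2L) {
    thermo <- vant_hoff_fit(binding)
  } else {
    warning("only one temperature supplied: Van't Hoff stage skipped",
            call. = FALSE)
  }

  fret <- NULL
  if (!is.null(acceptor_eps)) {
    s1 <- series_list[[1]]
    Fvals <- corrected_peak_intensities(s1)
    concs <- titration_concs(s1)
    i_eq <- which.min(abs(concs - s1$protein_conc_M))
    if (i_eq == 1L) i_eq <- 2L
    fret <- fret_analysis(s1$points[[1]]$emission, acceptor_eps,
                          F = Fvals[i_eq], F0 = Fvals[1],
                          kappa2 = config$kappa2, N_refr = config$N_refr,
                          Phi = config$Phi)
  }

  conformation <- lapply(series_list, function(s) {
    phase_diagram_fit(lapply(s$points, `[[`, "emission"),
                      lambda1_nm = config$phase_pair[1],
                      lambda2_nm = config$phase_pair[2],
                      r2_threshold = config$r2_threshold)
  })

  structure(list(quenching = quench, binding = binding, thermo = thermo,
                 fret = fret, conformation = conformation,
                 temperatures_K = temps, config = config),
            class = "binding_report")
}

#' @export
print.binding_report <- function(x, digits = 4, ...) {
  cat("== Protein-ligand binding analysis report ==\n\n")
  cat("-- Stern-Volmer quenching --\n")
  for (q in x$quenching) {
    print(q$fit, digits = digits)
    cat(sprintf("  mechanism: %s\n", q$mechanism))
  }
  cat("\n-- Binding isotherm (double-log) --\n")
  for (b in x$binding) print(b, digits = digits)
  if (!is.null(x$thermo)) {
    cat("\n-- Van't Hoff thermodynamics --\n")
    print(x$thermo, digits = digits)
  }
  if (!is.null(x$fret)) {
    cat("\n-- FRET --\n")
    print(x$fret, digits = digits)
  }
  cat("\n-- Phase diagram --\n")
  for (p in x$conformation) print(p, digits = digits)
  invisible(x)
}

#' Serialize a pipeline report to TSV tables
#'
#' Writes `quenching.tsv` (one row per temperature: T, Ksv, Kq, intercept,
#' R, SD, p, mechanism), `binding.tsv` (T, K, n, R2, and — when the Van't
#' Hoff stage ran — dG, dS, dH and the force label), optionally `fret.tsv`
#' and `phase_diagram.tsv`, plus `run_log.txt` recording every constant and
#' threshold used. All column headers carry explicit units. Output is
#' deterministic: repeated runs on the same inputs produce byte-identical
#' files.
#'
#' @param report a `"binding_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_tsv <- function(report, dir) {
  stopifnot(inherits(report, "binding_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) formatC(x, digits = 6, format = "g")

  q <- report$quenching
  qt <- data.frame(
    T_K = report$temperatures_K,
    Ksv_L_per_mol = fmt(vapply(q, function(z) z$fit$Ksv, numeric(1))),
    Kq_L_per_mol_s = fmt(vapply(q, function(z) z$fit$Kq, numeric(1))),
    intercept = fmt(vapply(q, function(z) z$fit$intercept, numeric(1))),
    R = fmt(vapply(q, function(z) z$fit$R, numeric(1))),
    SD = fmt(vapply(q, function(z) z$fit$SD, numeric(1))),
    p_value = fmt(vapply(q, function(z) z$fit$p_value, numeric(1))),
    mechanism = vapply(q, `[[`, character(1), "mechanism"))
  utils::write.table(qt, file.path(dir, "quenching.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  b <- report$binding
  bt <- data.frame(
    T_K = report$temperatures_K,
    K_L_per_mol = fmt(vapply(b, `[[`, numeric(1), "K")),
    n = fmt(vapply(b, `[[`, numeric(1), "n")),
    R2 = fmt(vapply(b, `[[`, numeric(1), "R2")))
  if (!is.null(report$thermo)) {
    th <- report$thermo
    bt$dG_kJ_per_mol <- fmt(th$dG_kJ[as.character(report$temperatures_K)])
    bt$dS_kJ_per_mol_K <- fmt(rep(th$dS_kJ, nrow(bt)))
    bt$dH_kJ_per_mol <- fmt(rep(th$dH_kJ, nrow(bt)))
    bt$forces <- rep(th$force_label, nrow(bt))
  }
  utils::write.table(bt, file.path(dir, "binding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (!is.null(report$fret)) {
    f <- report$fret
    ft <- data.frame(E = fmt(f$E), J_cm3_L_per_mol = fmt(f$J),
                     R0_nm = fmt(f$R0_nm), r_nm = fmt(f$r_nm))
    utils::write.table(ft, file.path(dir, "fret.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  p <- report$conformation
  pt <- data.frame(
    T_K = report$temperatures_K,
    lambda1_nm = vapply(p, `[[`, numeric(1), "lambda1_nm"),
    lambda2_nm = vapply(p, `[[`, numeric(1), "lambda2_nm"),
    a_intensity = fmt(vapply(p, `[[`, numeric(1), "a")),
    b_slope = fmt(vapply(p, `[[`, numeric(1), "b")),
    R2 = fmt(vapply(p, `[[`, numeric(1), "R2")),
    verdict = vapply(p, `[[`, character(1), "verdict"))
  utils::write.table(pt, file.path(dir, "phase_diagram.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg <- report$config
  writeLines(c(
    "run configuration",
    sprintf("tau0_s\t%g", cfg$tau0_s),
    sprintf("kappa2\t%g", cfg$kappa2),
    sprintf("N_refr\t%g", cfg$N_refr),
    sprintf("Phi\t%g", cfg$Phi),
    sprintf("diffusion_limit_L_per_mol_s\t%g", cfg$diffusion_limit),
    sprintf("r2_threshold\t%g", cfg$r2_threshold),
    sprintf("phase_pair_nm\t%g,%g", cfg$phase_pair[1], cfg$phase_pair[2]),
    sprintf("seed\t%d", cfg$seed)),
    file.path(dir, "run_log.txt"))
  invisible(dir)
}
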