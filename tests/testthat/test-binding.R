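test_that("double-log fit recovers the generator's K and n exactly", {
  gt <- ground_truth()  # K = 3.93e5, n = 1.3985
  fit <- double_log_fit(make_series(gt))
  expect_equal(fit$K, 3.93e5, tolerance = 1e-6)
  expect_equal(fit$n, 1.3985, tolerance = 1e-6)
  expect_equal(fit$R2, 1, tolerance = 1e-9)
})

test_that("unit stoichiometry gives slope one and the constructed K", {
  gt <- ground_truth(K_bind = 2.5e4, n_sites = 1)
  fit <- double_log_fit(make_series(gt))
  expect_equal(fit$n, 1, tolerance = 1e-9)
  expect_equal(fit$K, 2.5e4, tolerance = 1e-9)
})

test_that("fitted n is invariant to rescaling the concentration axis", {
  gt <- ground_truth(K_bind = 2.5e4, n_sites = 1)
  f1 <- double_log_fit(make_series(gt))
  f2 <- double_log_fit(make_series(gt, concs = 2 * study_concs))
  expect_equal(f2$n, f1$n, tolerance = 1e-9)
  expect_equal(f2$K, f1$K, tolerance = 1e-9)
})

test_that("recovery works only after inner-filter correction", {
  gt <- ground_truth(ligand_eps = example_ligand_eps())
  ser <- make_series(gt)
  raw_peaks <- vapply(ser$points, function(p) max(p$emission$values),
                      numeric(1))
  biased <- double_log_fit(ser, intensities = raw_peaks)
  corrected <- double_log_fit(ser)  # corrected peaks by default
  expect_equal(corrected$K, 3.93e5, tolerance = 1e-6)
  expect_equal(corrected$n, 1.3985, tolerance = 1e-6)
  # uncorrected intensities conflate absorption with quenching
  expect_gt(abs(biased$K / 3.93e5 - 1), 0.05)
})

test_that("double-log fit rejects series without a quenching signal", {
  ser <- make_series()
  expect_error(double_log_fit(ser, intensities = rep(700, 8)), "F >= F0")
  expect_error(double_log_fit(ser, intensities = c(700, 710, rep(600, 6))),
               "F >= F0")
})

test_that("two-point Van't Hoff round-trips the generating dH and dS", {
  dH <- -50.5; dS <- -0.07
  K <- exp(-dH * 1000 / (8.314 * c(298, 310)) + dS * 1000 / 8.314)
  vh <- vant_hoff_fit(list(list(K = K[1], temperature_K = 298),
                           list(K = K[2], temperature_K = 310)))
  expect_equal(vh$dH_kJ, dH, tolerance = 1e-10)
  expect_equal(vh$dS_kJ, dS, tolerance = 1e-10)
})

test_that("full generator-to-thermodynamics round trip is exact", {
  gt <- ground_truth(dH_kJ = -120, dS_kJ = -0.3)
  fits <- lapply(c(288, 298, 310), function(Tk)
    double_log_fit(generate_titration(gt, study_concs, Tk, emission_grid)))
  vh <- vant_hoff_fit(fits)
  expect_equal(vh$dH_kJ, -120, tolerance = 1e-6)
  expect_equal(vh$dS_kJ, -0.3, tolerance = 1e-6)
})

test_that("dG(T) = -RT ln K(T) holds for every fit", {
  vh <- vant_hoff_fit(list(list(K = 3.93e5, temperature_K = 298),
                           list(K = 9.04e2, temperature_K = 310)))
  for (i in seq_along(vh$dG_kJ)) {
    Tk <- vh$temperatures_K[i]
    expect_equal(vh$dG_kJ[[i]], -8.314 * Tk * log(vh$K[[i]]) / 1000,
                 tolerance = 1e-12)
  }
})

test_that("identical K at both temperatures gives dH = 0, dS = R ln K", {
  vh <- suppressWarnings(
    vant_hoff_fit(list(list(K = 1e4, temperature_K = 298),
                       list(K = 1e4, temperature_K = 310))))
  expect_equal(vh$dH_kJ, 0, tolerance = 1e-9)
  expect_equal(vh$dS_kJ, 8.314 * log(1e4) / 1000, tolerance = 1e-10)
})

test_that("Van't Hoff input validation", {
  expect_error(vant_hoff_fit(list(list(K = 1e4, temperature_K = 298))),
               ">= 2")
  expect_error(vant_hoff_fit(list(list(K = 1e4, temperature_K = 298),
                                  list(K = 2e4, temperature_K = 298))),
               "distinct")
})

test_that("force classification follows the thermodynamic sign rules", {
  lab <- function(dH, dS) classify_forces(list(dH_kJ = dH, dS_kJ = dS))
  expect_identical(lab(-388.81, -1.20), "vdw_hbond")
  expect_identical(lab(10, 0.1), "hydrophobic")
  expect_identical(lab(-10, 0.1), "electrostatic_or_hydrophobic")
  expect_warning(out <- lab(0, 0.1), "indeterminate")
  expect_identical(out, "indeterminate")
  expect_error(lab(NaN, 1), "finite")
})

test_that("bootstrap intervals cover the truth under 1% noise", {
  # well-conditioned design: quenched fraction spans ~12-78% so the
  # log-ratio response is defined at every point under the noise level
  K_true <- 5e6; n_true <- 1.3985
  n_rep <- 200L
  hits_K <- 0L; hits_n <- 0L
  for (r in seq_len(n_rep)) {
    gt <- ground_truth(K_bind = K_true, n_sites = n_true,
                       noise_sd_rel = 0.01, seed = 1000L + r)
    fit <- double_log_fit(make_series(gt))
    ci <- confint(fit, level = 0.95, n_boot = 299L, seed = r)
    if (ci["K", 1] <= K_true && K_true <= ci["K", 2]) hits_K <- hits_K + 1L
    if (ci["n", 1] <= n_true && n_true <= ci["n", 2]) hits_n <- hits_n + 1L
  }
  expect_gte(hits_K / n_rep, 0.90)
  expect_gte(hits_n / n_rep, 0.90)
})
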