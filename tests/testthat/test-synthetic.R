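test_that("half-quench analytic case: K [Q]^n = 1 at the top concentration", {
  # choose K so that K * (4e-5)^1 = 1
  gt <- ground_truth(K_bind = 1 / 4e-5, n_sites = 1)
  ser <- make_series(gt)
  top <- ser$points[[8]]$emission$values
  f0 <- ser$points[[1]]$emission$values
  expect_equal(top, f0 / 2, tolerance = 1e-12)
})

test_that("inner-filter attenuation follows 10^(-(A_ex+A_em)/2)", {
  # flat absorptivity spectrum: A_ex = A_em = 0.1 at conc 1e-5 with eps 1e4
  eps <- spectrum(c(200, 500), c(1e4, 1e4), "molar_absorptivity")
  gt_on <- ground_truth(K_bind = 1e4, n_sites = 1, ligand_eps = eps)
  gt_off <- ground_truth(K_bind = 1e4, n_sites = 1)
  concs <- c(0, 0.5, 1, 2) * 1e-5
  on <- generate_titration(gt_on, concs, 298, emission_grid)
  off <- generate_titration(gt_off, concs, 298, emission_grid)
  i <- 3  # conc 1e-5 -> A_ex = A_em = 0.1
  expect_equal(on$points[[i]]$A_ex, 0.1, tolerance = 1e-12)
  expect_equal(on$points[[i]]$A_em, 0.1, tolerance = 1e-12)
  expect_equal(max(on$points[[i]]$emission$values),
               max(off$points[[i]]$emission$values) * 10^(-0.1),
               tolerance = 1e-12)
})

test_that("generator noise is deterministic under the seed", {
  a <- make_series(ground_truth(noise_sd_rel = 0.02, seed = 11))
  b <- make_series(ground_truth(noise_sd_rel = 0.02, seed = 11))
  c <- make_series(ground_truth(noise_sd_rel = 0.02, seed = 12))
  expect_identical(a$points[[4]]$emission$values,
                   b$points[[4]]$emission$values)
  expect_false(identical(a$points[[4]]$emission$values,
                         c$points[[4]]$emission$values))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(make_series(ground_truth(noise_sd_rel = 0.02, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("grid must span the emission band", {
  expect_error(generate_titration(ground_truth(), study_concs, 298,
                                  seq(330, 360)), "span")
})

test_that("synchronous scans: no shift when shift_per_sat is zero", {
  gt <- ground_truth(shift_per_sat_nm = 0)
  scans <- generate_synchronous(gt, study_concs, 60, seq(220, 400))
  pos <- vapply(scans, peak_position, numeric(1))
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-9)
})

test_that("synchronous scans reproduce the configured red shift at saturation", {
  # strong binding so the top concentration is essentially saturating
  gt <- ground_truth(K_bind = 1e7, n_sites = 1, shift_per_sat_nm = 1.6)
  scans <- generate_synchronous(gt, study_concs, 60, seq(220, 400))
  shift <- peak_position(scans[[8]]) - peak_position(scans[[1]])
  expect_equal(shift, 1.6, tolerance = 0.05)
})

test_that("synchronous intensities decrease monotonically with concentration", {
  gt <- ground_truth()
  scans <- generate_synchronous(gt, study_concs, 15, seq(220, 400))
  peaks <- vapply(scans, function(s) max(s$values), numeric(1))
  expect_true(all(diff(peaks) < 0))
  expect_error(generate_synchronous(gt, study_concs, -5, seq(220, 400)),
               "positive")
})

test_that("two-state mixtures are exactly affine at zero noise", {
  sN <- gaussian_spectrum(335, 16)
  sF <- gaussian_spectrum(350, 22, peak = 60)
  out <- generate_two_state_series(c(1, 0.6, 0.3, 0), sN, sF)
  expect_equal(out[[1]]$values, sN$values)   # f = 1 endpoint
  expect_equal(out[[4]]$values, sF$values)
  I1 <- vapply(out, spectrum_value_at, numeric(1), 320)
  I2 <- vapply(out, spectrum_value_at, numeric(1), 365)
  # all points collinear: rank of centred matrix is 1
  M <- cbind(I1 - mean(I1), I2 - mean(I2))
  expect_lt(abs(det(crossprod(M))), 1e-12 * max(I1)^4)
  expect_error(generate_two_state_series(0.5, sN, gaussian_spectrum(
    350, 22, grid = seq(250, 430))), "grid")
  expect_error(generate_two_state_series(1.2, sN, sF), "\\[0, 1\\]")
})

test_that("a three-state path breaks collinearity", {
  sN <- gaussian_spectrum(335, 16)
  sF <- gaussian_spectrum(350, 22, peak = 60)
  sI <- gaussian_spectrum(310, 10, peak = 90)  # off the N-F segment
  first <- generate_two_state_series(c(1, 0.5), sN, sI)
  second <- generate_two_state_series(c(0.5, 0), sI, sF)
  series <- c(first, second)
  I1 <- vapply(series, spectrum_value_at, numeric(1), 320)
  I2 <- vapply(series, spectrum_value_at, numeric(1), 365)
  expect_lt(stats::cor(I1, I2)^2, 0.98)
})

test_that("Van't Hoff parameters drive the generator's temperature dependence", {
  gt <- ground_truth(dH_kJ = -388.81, dS_kJ = -1.20)
  K298 <- K_at_temperature(gt, 298)
  K310 <- K_at_temperature(gt, 310)
  expect_gt(K298, K310)  # binding weakens with temperature
  # closed-form check of the Van't Hoff forward model
  expect_equal(log(K298) - log(K310),
               -(-388.81 * 1000) / 8.314 * (1 / 298 - 1 / 310),
               tolerance = 1e-12)
})
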