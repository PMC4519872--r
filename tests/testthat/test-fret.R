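test_that("transfer efficiency is 1 - F/F0 with guarded domain", {
  expect_equal(transfer_efficiency(0.797, 1), 0.203)
  expect_equal(transfer_efficiency(100, 100), 0)
  expect_equal(transfer_efficiency(50, 100), 0.5)
  expect_error(transfer_efficiency(101, 100), "exceed")
  expect_error(transfer_efficiency(1, 0), "positive")
})

test_that("overlap integral matches the closed-form constant-spectra oracle", {
  # F and eps constant on [400, 500] nm: J = eps0 * int(lambda^4) / (b - a)
  grid <- seq(400, 500, by = 0.5)
  donor <- spectrum(grid, rep(7, length(grid)), "emission")
  eps0 <- 3200
  acc <- spectrum(grid, rep(eps0, length(grid)), "molar_absorptivity")
  a <- 400e-7; b <- 500e-7  # cm
  J_oracle <- eps0 * (b^5 - a^5) / 5 / (b - a)
  # trapezoid is not exact for lambda^4, so compare at the grid's accuracy
  expect_equal(overlap_integral(donor, acc), J_oracle, tolerance = 1e-7)
})

test_that("overlap integral is invariant to donor scaling and zero for dark acceptors", {
  donor <- gaussian_spectrum(341, 18)
  acc <- gaussian_spectrum(345, 30, peak = 2500, kind = "molar_absorptivity")
  J1 <- overlap_integral(donor, acc)
  donor_big <- spectrum(donor$wavelengths_nm, donor$values * 1000,
                        "emission")
  expect_equal(overlap_integral(donor_big, acc), J1, tolerance = 1e-12)
  dark <- spectrum(donor$wavelengths_nm, rep(0, length(donor$values)),
                   "molar_absorptivity")
  expect_equal(overlap_integral(donor, dark), 0)
  # disjoint supports
  far <- gaussian_spectrum(600, 10, grid = seq(580, 620),
                           kind = "molar_absorptivity")
  expect_error(overlap_integral(donor, far), "overlap")
})

test_that("overlap integral agrees with a fine-grid Riemann oracle", {
  donor <- gaussian_spectrum(341, 18, grid = seq(280, 430, by = 1))
  acc <- gaussian_spectrum(350, 28, peak = 4100,
                           grid = seq(280, 430, by = 1),
                           kind = "molar_absorptivity")
  # midpoint Riemann sum on a 1000x finer grid, independent of the package
  lam <- seq(280.0005, 429.9995, by = 0.001)
  Fm <- 100 * exp(-((lam - 341)^2) / (2 * 18^2))
  em <- 4100 * exp(-((lam - 350)^2) / (2 * 28^2))
  lam_cm <- lam * 1e-7
  J_oracle <- sum(Fm * em * lam_cm^4 * 0.001e-7) / sum(Fm * 0.001e-7)
  expect_equal(overlap_integral(donor, acc), J_oracle, tolerance = 1e-4)
})

test_that("Forster radius follows the pinned unit convention", {
  # direct arithmetic oracle, in cm, then nm
  J <- 1.15e-15
  R0_oracle <- (8.8e-25 * (2 / 3) * 1.336^-4 * 0.118 * J)^(1 / 6) * 1e7
  expect_equal(forster_radius(J), R0_oracle, tolerance = 1e-12)
  expect_equal(R0_oracle, 1.71, tolerance = 0.002)  # frozen from the oracle
  # sixth-power scaling: multiplying J by 2^6 doubles R0
  expect_equal(forster_radius(J * 2^6), 2 * forster_radius(J),
               tolerance = 1e-12)
  # Phi -> 0 drives R0 -> 0 (sixth root, so the approach is slow)
  expect_lt(forster_radius(J, Phi = 1e-12), 0.1)
  expect_error(forster_radius(-1), "positive")
})

test_that("donor-acceptor distance inverts the efficiency relation", {
  d <- donor_acceptor_distance(0.203, 1.69)
  expect_equal(d$r_nm, 2.12, tolerance = 0.005 / 2.12)
  expect_true(d$within_6nm)
  expect_equal(donor_acceptor_distance(0.5, 3.7)$r_nm, 3.7)  # E = 1/2 -> r = R0
  expect_lt(donor_acceptor_distance(1 - 1e-9, 2)$r_nm, 0.1)  # E -> 1
  expect_error(donor_acceptor_distance(0, 2), "strictly inside")
  expect_error(donor_acceptor_distance(1, 2), "strictly inside")
})

test_that("efficiency-distance round trip and stored-field identity", {
  for (r in c(0.8, 1.7, 2.12, 4.9)) {
    R0 <- 1.69
    E <- R0^6 / (R0^6 + r^6)
    expect_equal(donor_acceptor_distance(E, R0)$r_nm, r,
                 tolerance = 1e-9)
  }
  # full analysis object satisfies E = R0^6 / (R0^6 + r^6)
  donor <- gaussian_spectrum(341, 18)
  acc <- gaussian_spectrum(345, 30, peak = 2500,
                           kind = "molar_absorptivity")
  res <- fret_analysis(donor, acc, F = 79.7, F0 = 100)
  expect_equal(res$E, res$R0_nm^6 / (res$R0_nm^6 + res$r_nm^6),
               tolerance = 1e-9)
})
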