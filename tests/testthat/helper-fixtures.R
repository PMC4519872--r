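# Shared fixture builders: everything is generated in code at test time.

# Gaussian band sampled on a grid
gaussian_spectrum <- function(center, width, grid = seq(260, 440, by = 1),
                              peak = 100, kind = "emission") {
  spectrum(grid, peak * exp(-((grid - center)^2) / (2 * width^2)), kind)
}

# the study's titration design: eight points, 0 to 4e-5 mol/L
study_concs <- c(0, 0.4, 0.8, 1, 1.6, 2.4, 3.2, 4) * 1e-5

# default emission grid wide enough for the 341 nm band +/- 3 widths
emission_grid <- seq(260, 440, by = 1)

# a minimal clean series from the generator with given truth
make_series <- function(gt = ground_truth(), concs = study_concs,
                        temperature_K = 298, grid = emission_grid) {
  generate_titration(gt, concs, temperature_K, grid)
}

# closed-form two-parameter OLS, the independent oracle for slope fits
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}
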