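#' Inner-filter correction of fluorescence intensities
#'
#' Measured fluorescence is attenuated when the sample absorbs at the
#' excitation or emission wavelength. The standard multiplicative correction
#' restores the intensity that would have been observed without absorption:
#' `F_corr = F_obs * 10^(A_ex/2) * 10^(A_em/2)`, with `A_ex`, `A_em` the
#' absorbances (AU, 1 cm path) at the excitation and emission wavelengths.
#' Vectorized over all three arguments.
#'
#' @param F_obs observed intensity (scalar or vector), >= 0.
#' @param A_ex,A_em absorbance at the excitation / emission wavelength, >= 0.
#' @return Corrected intensity, same shape as `F_obs`.
#' @examples
#' inner_filter_correct(100, 0.1, 0.1)  # 100 * 10^0.1
#' @export
inner_filter_correct <- function(F_obs, A_ex, A_em) {
  if (any(A_ex < 0) || any(A_em < 0))
    stop("absorbances must be >= 0", call. = FALSE)
  if (any(F_obs < 0))
    stop("intensities must be >= 0", call. = FALSE)
  F_obs * 10^((A_ex + A_em) / 2)
}

#' Inner-filter-corrected peak intensities of a titration series
#'
#' Extracts the emission-band maximum of every point and applies
#' [inner_filter_correct()] with the point's recorded absorbances.
#'
#' @param series a [titration_series()].
#' @return Numeric vector of corrected peak intensities, one per point.
#' @export
corrected_peak_intensities <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  vapply(series$points, function(p) {
    inner_filter_correct(max(p$emission$values), p$A_ex, p$A_em)
  }, numeric(1))
}

#' Stern-Volmer quenching analysis
#'
#' Fits the Stern-Volmer relation `F0/F = 1 + Ksv [Q]` by ordinary least
#' squares of `F0/F` on the quencher concentration, with a free intercept
#' (its deviation from 1 is a diagnostic, not forced away). The bimolecular
#' quenching rate constant is `Kq = Ksv / tau0` with `tau0` the unquenched
#' fluorophore lifetime, about 1e-8 s for a protein.
#'
#' @param series a [titration_series()].
#' @param tau0_s unquenched fluorescence lifetime, seconds.
#' @param intensities optional precomputed scalar intensities (one per
#'   point); by default the inner-filter-corrected band maxima.
#' @return An object of class `"sv_fit"` with components `Ksv` (L/mol),
#'   `Kq` (L mol^-1 s^-1), `tau0_s`, `intercept`, `R` (Pearson correlation),
#'   `SD` (residual standard deviation), `p_value` (two-sided t-test on the
#'   slope), `n_points`, `temperature_K`, and the regressed data.
#' @examples
#' gt <- ground_truth(K_bind = 1e5, n_sites = 1)
#' ser <- generate_titration(gt, c(0, 1, 2, 4) * 1e-5, 298, seq(260, 440))
#' stern_volmer_fit(ser)
#' @export
stern_volmer_fit <- function(series, tau0_s = 1e-8, intensities = NULL) {
  stopifnot(inherits(series, "titration_series"))
  if (tau0_s <= 0) stop("tau0_s must be positive", call. = FALSE)
  Fvals <- if (is.null(intensities)) corrected_peak_intensities(series)
           else as.numeric(intensities)
  concs <- titration_concs(series)
  if (length(Fvals) != length(concs))
    stop("one intensity per titration point required", call. = FALSE)
  if (any(Fvals <= 0))
    stop("all intensities must be positive for the F0/F ratio",
         call. = FALSE)
  if (length(concs) < 3L)
    stop("Stern-Volmer fit needs at least 3 points", call. = FALSE)
  ratio <- Fvals[1] / Fvals
  fit <- stats::lm(ratio ~ concs)
  slope <- unname(stats::coef(fit)[2])
  # fit statistics computed directly; summary.lm warns on noiseless data
  m <- length(concs)
  res <- stats::residuals(fit)
  sigma <- sqrt(sum(res^2) / (m - 2))
  se_slope <- sigma / sqrt(sum((concs - mean(concs))^2))
  p <- if (se_slope == 0) 0
       else 2 * stats::pt(abs(slope) / se_slope, df = m - 2,
                          lower.tail = FALSE)
  structure(list(
    Ksv = slope,
    Kq = slope / tau0_s,
    tau0_s = tau0_s,
    intercept = unname(stats::coef(fit)[1]),
    R = unname(stats::cor(concs, ratio)),
    SD = sigma,
    p_value = p,
    n_points = length(concs),
    temperature_K = series$temperature_K,
    data = data.frame(conc_M = concs, F0_over_F = ratio),
    lm = fit),
    class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, digits = 4, ...) {
  cat("Stern-Volmer quenching fit\n")
  cat(sprintf("  T = %g K, n = %d points\n", x$temperature_K, x$n_points))
  cat(sprintf("  Ksv = %s L/mol   Kq = %s L/(mol s)  (tau0 = %g s)\n",
              format(x$Ksv, digits = digits),
              format(x$Kq, digits = digits), x$tau0_s))
  cat(sprintf("  intercept = %s  R = %s  SD = %s  p(slope) = %s\n",
              format(x$intercept, digits = digits),
              format(x$R, digits = digits),
              format(x$SD, digits = digits),
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(intercept = object$intercept, Ksv = object$Ksv)
}

#' @export
summary.sv_fit <- function(object, ...) {
  out <- data.frame(temperature_K = object$temperature_K,
                    Ksv = object$Ksv, Kq = object$Kq,
                    intercept = object$intercept, R = object$R,
                    SD = object$SD, p_value = object$p_value,
                    n_points = object$n_points)
  class(out) <- c("summary.sv_fit", "data.frame")
  out
}

#' @export
plot.sv_fit <- function(x, ...) {
  graphics::plot(x$data$conc_M, x$data$F0_over_F,
                 xlab = "[Q] (mol/L)", ylab = expression(F[0] / F),
                 main = "Stern-Volmer plot", ...)
  graphics::abline(x$intercept, x$Ksv, lty = 2)
  invisible(x)
}

#' Classify the quenching mechanism
#'
#' Compares the apparent bimolecular quenching rate constant with the
#' diffusion-controlled (maximum scatter collision) limit, about
#' 2e10 L mol^-1 s^-1 for quenching of biopolymers. A rate constant far above
#' that limit cannot arise from collisional encounters, so quenching must go
#' through ground-state complex formation (static quenching).
#'
#' @param fit an [stern_volmer_fit()] result.
#' @param diffusion_limit maximum collisional quenching rate constant,
#'   L mol^-1 s^-1.
#' @param alpha significance level for the slope before any mechanism is
#'   claimed.
#' @return `"static"`, `"dynamic"`, or `"none"` (slope not significant).
#' @export
classify_mechanism <- function(fit, diffusion_limit = 2.0e10, alpha = 0.05) {
  stopifnot(inherits(fit, "sv_fit"))
  if (!is.finite(fit$p_value) || fit$p_value >= alpha || fit$Ksv <= 0)
    return("none")
  if (fit$Kq > diffusion_limit) "static" else "dynamic"
}
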