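#' Binding constant and stoichiometry from the double-logarithmic plot
#'
#' For static quenching with independent, equivalent sites, the quenched
#' intensity obeys `log10[(F0 - F)/F] = log10 K + n log10 [Q]`, so an OLS fit
#' of `log10((F0 - F)/F)` on `log10 [Q]` over the nonzero-concentration
#' points yields the binding stoichiometry `n` as the slope and the binding
#' constant `K = 10^intercept` (L/mol). Base-10 logarithms throughout, the
#' convention of this literature — misreading the base changes K by orders
#' of magnitude.
#'
#' @param series a [titration_series()].
#' @param intensities optional precomputed scalar intensities (one per
#'   point); by default the inner-filter-corrected band maxima via
#'   [corrected_peak_intensities()].
#' @return An object of class `"binding_fit"` with components `K` (L/mol),
#'   `n` (dimensionless), `R2`, `temperature_K`, `n_points`, the regressed
#'   data and the underlying `lm` fit.
#' @examples
#' gt <- ground_truth()  # K = 3.93e5, n = 1.3985
#' ser <- generate_titration(gt, c(0, 0.4, 0.8, 1, 1.6, 2.4, 3.2, 4) * 1e-5,
#'                           298, seq(260, 440))
#' coef(double_log_fit(ser))
#' @export
double_log_fit <- function(series, intensities = NULL) {
  stopifnot(inherits(series, "titration_series"))
  Fvals <- if (is.null(intensities)) corrected_peak_intensities(series)
           else as.numeric(intensities)
  concs <- titration_concs(series)
  F0 <- Fvals[1]
  nz <- which(concs > 0)
  if (any(Fvals[nz] <= 0))
    stop("intensities must be positive", call. = FALSE)
  if (any(Fvals[nz] >= F0))
    stop("F >= F0 at a nonzero concentration: no quenching signal to fit",
         call. = FALSE)
  if (length(nz) < 3L)
    stop("double-log fit needs at least 3 nonzero-concentration points",
         call. = FALSE)
  x <- log10(concs[nz])
  y <- log10((F0 - Fvals[nz]) / Fvals[nz])
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  structure(list(
    K = 10^unname(cf[1]),
    n = unname(cf[2]),
    R2 = stats::cor(x, y)^2,
    temperature_K = series$temperature_K,
    n_points = length(nz),
    F0 = F0,
    F = Fvals[nz],
    conc_M = concs[nz],
    data = data.frame(log10_conc = x, log10_ratio = y),
    lm = fit),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, digits = 4, ...) {
  cat("Double-logarithmic binding fit\n")
  cat(sprintf("  T = %g K, %d points\n", x$temperature_K, x$n_points))
  cat(sprintf("  K = %s L/mol   n = %s   R2 = %s\n",
              format(x$K, digits = digits), format(x$n, digits = digits),
              format(x$R2, digits = digits)))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(K = object$K, n = object$n)
}

#' @export
plot.binding_fit <- function(x, ...) {
  graphics::plot(x$data$log10_conc, x$data$log10_ratio,
                 xlab = "log10 [Q]",
                 ylab = expression(log[10] * ((F[0] - F) / F)),
                 main = "Double-logarithmic binding plot", ...)
  graphics::abline(x$lm, lty = 2)
  invisible(x)
}

#' Bootstrap confidence intervals for a binding fit
#'
#' Parametric bootstrap at the intensity level. Measurement noise in a
#' titration is multiplicative on every recorded intensity, including the
#' zero-quencher reference F0 that enters every log-ratio — so an error in
#' F0 tilts all points of the double-log plot coherently, and resampling
#' regression residuals would badly understate the sampling variability.
#' Instead, the relative noise level is estimated from the scatter of the
#' observed intensities around the fitted isotherm
#' `F = F0 / (1 + K [Q]^n)`, new intensity vectors (F0 included) are
#' simulated with that noise, each replicate is refit, and percentile
#' intervals of the resampled `K` and `n` are returned. Replicates in which
#' noise erases the quenching signal at all but fewer than 3 points are
#' dropped (they correspond to titrations one would not fit).
#'
#' @param object a [double_log_fit()] result.
#' @param parm ignored (both parameters are always returned).
#' @param level confidence level.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param ... unused.
#' @return Matrix with rows `K`, `n` and columns giving the interval bounds.
#' @export
confint.binding_fit <- function(object, parm, level = 0.95, n_boot = 499L,
                                seed = 1L, ...) {
  F0 <- object$F0
  concs <- object$conc_M
  m <- length(concs)
  pred <- F0 / (1 + object$K * concs^object$n)
  sigma <- stats::sd(object$F / pred - 1)
  X <- cbind(1, log10(concs))
  draws <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      F0b <- F0 * (1 + stats::rnorm(1, 0, sigma))
      Fb <- pred * (1 + stats::rnorm(m, 0, sigma))
      ok <- Fb > 0 & Fb < F0b
      if (sum(ok) < 3L) return(c(NA_real_, NA_real_))
      cf <- stats::.lm.fit(X[ok, , drop = FALSE],
                           log10((F0b - Fb[ok]) / Fb[ok]))$coefficients
      c(10^cf[1], cf[2])
    }, numeric(2)))
  })
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- rbind(K = stats::quantile(draws[, 1], probs, names = FALSE,
                                   na.rm = TRUE),
               n = stats::quantile(draws[, 2], probs, names = FALSE,
                                   na.rm = TRUE))
  colnames(out) <- sprintf("%.1f %%", probs * 100)
  out
}

#' Van't Hoff analysis of binding constants at several temperatures
#'
#' Regresses `ln K` on `1/T` (exact solve for two temperatures): the slope is
#' `-dH/R` and the intercept `dS/R`, assuming the enthalpy and entropy are
#' constant over the temperature range. The free energy at each fitted
#' temperature is computed as `dG(T) = -R T ln K(T)` from the unrounded
#' fitted K — algebraically identical to `dH - T dS` for a two-point fit,
#' and the form that is robust to rounding of the reported dH/dS.
#'
#' @param fits list of [double_log_fit()] results (or any objects with
#'   fields `K` and `temperature_K`) at two or more distinct temperatures.
#' @return An object of class `"vant_hoff"` with `dH_kJ` (kJ/mol), `dS_kJ`
#'   (kJ/(mol K)), `dG_kJ` (named vector, kJ/mol, one per input
#'   temperature), `K` (the input constants), `force_label` (see
#'   [classify_forces()]).
#' @examples
#' f1 <- list(K = 3.93e5, temperature_K = 298)
#' f2 <- list(K = 9.04e2, temperature_K = 310)
#' vant_hoff_fit(list(f1, f2))
#' @export
vant_hoff_fit <- function(fits) {
  K <- vapply(fits, `[[`, numeric(1), "K")
  Tk <- vapply(fits, `[[`, numeric(1), "temperature_K")
  if (length(K) < 2L)
    stop("Van't Hoff analysis needs >= 2 temperatures", call. = FALSE)
  if (anyDuplicated(Tk))
    stop("temperatures must be distinct", call. = FALSE)
  if (any(K <= 0)) stop("all binding constants must be positive",
                        call. = FALSE)
  ord <- order(Tk)
  K <- K[ord]; Tk <- Tk[ord]
  x <- 1 / Tk; y <- log(K)
  if (length(K) == 2L) {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    intercept <- y[1] - slope * x[1]
  } else {
    cf <- stats::coef(stats::lm(y ~ x))
    intercept <- unname(cf[1]); slope <- unname(cf[2])
  }
  dH <- -slope * .R_GAS / 1000      # kJ/mol
  dS <- intercept * .R_GAS / 1000   # kJ/(mol K)
  dG <- -.R_GAS * Tk * log(K) / 1000
  names(dG) <- as.character(Tk)
  structure(list(dH_kJ = dH, dS_kJ = dS, dG_kJ = dG,
                 K = stats::setNames(K, as.character(Tk)),
                 temperatures_K = Tk,
                 force_label = .force_label(dH, dS)),
            class = "vant_hoff")
}

.force_label <- function(dH, dS) {
  if (dH == 0 || dS == 0) {
    warning("dH or dS exactly zero: force classification indeterminate",
            call. = FALSE)
    return("indeterminate")
  }
  if (dH > 0 && dS > 0) return("hydrophobic")
  if (dH < 0 && dS < 0) return("vdw_hbond")
  if (dS > 0) return("electrostatic_or_hydrophobic")
  # dH > 0, dS < 0: outside the standard sign rules
  "indeterminate"
}

#' Classify the dominant intermolecular force from Van't Hoff signs
#'
#' Standard sign rules for protein-ligand binding: positive dH and dS mean
#' hydrophobic interactions; negative dH and dS mean van der Waals forces
#' plus hydrogen bonding; positive dS with non-positive dH means
#' electrostatic or hydrophobic interactions. Exact zeros (and the
#' dH > 0 / dS < 0 quadrant, which the rules do not cover) return
#' `"indeterminate"` with a warning rather than silently picking a rule.
#'
#' @param t a `"vant_hoff"` object, or a list with `dH_kJ` and `dS_kJ`.
#' @return One of `"hydrophobic"`, `"vdw_hbond"`,
#'   `"electrostatic_or_hydrophobic"`, `"indeterminate"`.
#' @export
classify_forces <- function(t) {
  if (!is.finite(t$dH_kJ) || !is.finite(t$dS_kJ))
    stop("dH and dS must be finite", call. = FALSE)
  .force_label(t$dH_kJ, t$dS_kJ)
}

#' @export
print.vant_hoff <- function(x, digits = 4, ...) {
  cat("Van't Hoff thermodynamic analysis\n")
  cat(sprintf("  dH = %s kJ/mol   dS = %s kJ/(mol K)\n",
              format(x$dH_kJ, digits = digits),
              format(x$dS_kJ, digits = digits)))
  for (i in seq_along(x$dG_kJ))
    cat(sprintf("  dG(%s K) = %s kJ/mol   (K = %s L/mol)\n",
                names(x$dG_kJ)[i], format(x$dG_kJ[i], digits = digits),
                format(x$K[i], digits = digits)))
  cat(sprintf("  dominant forces: %s\n", x$force_label))
  invisible(x)
}

#' @export
coef.vant_hoff <- function(object, ...) {
  c(dH_kJ = object$dH_kJ, dS_kJ = object$dS_kJ)
}

#' Predict the binding constant at new temperatures from a Van't Hoff fit
#' @param object a `"vant_hoff"` object.
#' @param temperature_K temperatures in kelvin.
#' @param ... unused.
#' @return Predicted binding constants, L/mol.
#' @export
predict.vant_hoff <- function(object, temperature_K, ...) {
  exp(-object$dH_kJ * 1000 / (.R_GAS * temperature_K) +
      object$dS_kJ * 1000 / .R_GAS)
}
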