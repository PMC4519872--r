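#' Energy-transfer efficiency from donor quenching
#'
#' Fraction of donor excitation transferred to the acceptor, measured from
#' the donor intensity with (`F`) and without (`F0`) acceptor:
#' `E = 1 - F/F0`.
#'
#' @param F donor intensity in the presence of the acceptor, `0 < F <= F0`.
#' @param F0 donor intensity without acceptor, > 0.
#' @return Efficiency in \[0, 1).
#' @export
transfer_efficiency <- function(F, F0) {
  if (any(F0 <= 0)) stop("F0 must be positive", call. = FALSE)
  if (any(F <= 0)) stop("F must be positive", call. = FALSE)
  if (any(F > F0)) stop("F must not exceed F0", call. = FALSE)
  1 - F / F0
}

#' Spectral overlap integral J between donor emission and acceptor absorption
#'
#' `J = integral F(lambda) eps(lambda) lambda^4 dlambda / integral F(lambda)
#' dlambda`, trapezoidal quadrature over the common wavelength support, with
#' the acceptor absorptivity aligned onto the donor grid by linear
#' interpolation. Wavelengths enter the integrand in cm so that with `eps`
#' in L mol^-1 cm^-1 the result carries cm^3 L mol^-1, the unit convention
#' required by [forster_radius()]. The normalization by the total donor
#' emission makes J invariant to scaling of F.
#'
#' @param donor_emission a [spectrum()] of kind `"emission"`.
#' @param acceptor_eps a [spectrum()] of kind `"molar_absorptivity"`
#'   (L mol^-1 cm^-1).
#' @return J in cm^3 L mol^-1.
#' @export
overlap_integral <- function(donor_emission, acceptor_eps) {
  stopifnot(inherits(donor_emission, "spectrum"),
            inherits(acceptor_eps, "spectrum"))
  lo <- max(min(donor_emission$wavelengths_nm),
            min(acceptor_eps$wavelengths_nm))
  hi <- min(max(donor_emission$wavelengths_nm),
            max(acceptor_eps$wavelengths_nm))
  if (lo >= hi)
    stop("donor emission and acceptor absorption spectra do not overlap",
         call. = FALSE)
  keep <- donor_emission$wavelengths_nm >= lo &
    donor_emission$wavelengths_nm <= hi
  lam_nm <- donor_emission$wavelengths_nm[keep]
  if (length(lam_nm) < 2L)
    stop("overlap region contains fewer than 2 donor grid points",
         call. = FALSE)
  Fv <- donor_emission$values[keep]
  eps <- interpolate_to_grid(acceptor_eps, lam_nm)
  eps <- if (inherits(eps, "spectrum")) eps$values else eps
  lam_cm <- lam_nm * 1e-7
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                           utils::tail(y, -1)) / 2)
  denom <- trapz(lam_cm, Fv)
  if (denom <= 0) stop("donor emission integrates to zero on the overlap",
                       call. = FALSE)
  trapz(lam_cm, Fv * eps * lam_cm^4) / denom
}

#' Förster critical distance R0
#'
#' The donor-acceptor separation at which transfer efficiency is 50%:
#' `R0^6 = 8.8e-25 kappa2 N^-4 Phi J` with `R0` in cm and `J` in
#' cm^3 L mol^-1; the result is returned in nm. The numeric constant is tied
#' to exactly this unit convention, which is pinned by a unit test because
#' it is the most error-prone step of a FRET calculation. Defaults: random
#' dipole orientation (`kappa2 = 2/3`), aqueous buffer refractive index
#' 1.336, tryptophan donor quantum yield 0.118.
#'
#' @param J overlap integral, cm^3 L mol^-1.
#' @param kappa2 dipole orientation factor.
#' @param N_refr refractive index of the medium.
#' @param Phi donor fluorescence quantum yield.
#' @return R0 in nm.
#' @export
forster_radius <- function(J, kappa2 = 2 / 3, N_refr = 1.336, Phi = 0.118) {
  if (any(c(J, kappa2, N_refr, Phi) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  R0_cm <- (8.8e-25 * kappa2 * N_refr^-4 * Phi * J)^(1 / 6)
  R0_cm * 1e7
}

#' Donor-acceptor distance from efficiency and critical distance
#'
#' Inverts `E = R0^6 / (R0^6 + r^6)`: `r = R0 ((1 - E)/E)^(1/6)`. Two
#' admissibility diagnostics accompany the distance: whether `r < 6 nm`
#' (the practical range of the dipole-dipole mechanism) and whether
#' `0.5 R0 < r < 1.5 R0` (the window where efficiency is sensitive to
#' distance).
#'
#' @param E transfer efficiency, strictly inside (0, 1).
#' @param R0_nm critical distance, nm, > 0.
#' @return A list with `r_nm`, `within_6nm`, `within_half_to_1.5_R0`.
#' @examples
#' donor_acceptor_distance(0.203, 1.69)$r_nm  # 2.12 nm
#' @export
donor_acceptor_distance <- function(E, R0_nm) {
  if (any(E <= 0 | E >= 1))
    stop("E must lie strictly inside (0, 1)", call. = FALSE)
  if (any(R0_nm <= 0)) stop("R0 must be positive", call. = FALSE)
  r <- R0_nm * ((1 - E) / E)^(1 / 6)
  list(r_nm = r,
       within_6nm = r < 6,
       within_half_to_1.5_R0 = r > 0.5 * R0_nm & r < 1.5 * R0_nm)
}

#' Full FRET analysis of a donor-acceptor pair
#'
#' Convenience wrapper chaining [transfer_efficiency()],
#' [overlap_integral()], [forster_radius()] and
#' [donor_acceptor_distance()] into one result object.
#'
#' @param donor_emission donor [spectrum()] (no acceptor present).
#' @param acceptor_eps acceptor molar absorptivity [spectrum()].
#' @param F,F0 donor intensities with / without acceptor (scalars, e.g.
#'   band maxima at equimolar acceptor).
#' @param kappa2,N_refr,Phi see [forster_radius()].
#' @return An object of class `"fret_result"` with `E`, `J`, `R0_nm`,
#'   `r_nm`, the constants used, and the admissibility diagnostics.
#' @export
fret_analysis <- function(donor_emission, acceptor_eps, F, F0,
                          kappa2 = 2 / 3, N_refr = 1.336, Phi = 0.118) {
  E <- transfer_efficiency(F, F0)
  if (E <= 0)
    stop("no measurable quenching (F = F0): FRET parameters undefined",
         call. = FALSE)
  J <- overlap_integral(donor_emission, acceptor_eps)
  R0 <- forster_radius(J, kappa2, N_refr, Phi)
  d <- donor_acceptor_distance(E, R0)
  structure(list(E = E, J = J, R0_nm = R0, r_nm = d$r_nm,
                 kappa2 = kappa2, N_refr = N_refr, Phi = Phi,
                 within_6nm = d$within_6nm,
                 within_half_to_1.5_R0 = d$within_half_to_1.5_R0),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, digits = 4, ...) {
  cat("Forster resonance energy transfer analysis\n")
  cat(sprintf("  E = %s   J = %s cm^3 L/mol\n",
              format(x$E, digits = digits), format(x$J, digits = digits)))
  cat(sprintf("  R0 = %s nm   r = %s nm\n",
              format(x$R0_nm, digits = digits),
              format(x$r_nm, digits = digits)))
  cat(sprintf("  (kappa2 = %.4g, N = %.4g, Phi = %.4g)\n",
              x$kappa2, x$N_refr, x$Phi))
  cat(sprintf("  r < 6 nm: %s;  0.5 R0 < r < 1.5 R0: %s\n",
              x$within_6nm, x$within_half_to_1.5_R0))
  invisible(x)
}
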