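#' Construct a spectrum
#'
#' A spectrum is a sampled curve: a strictly increasing wavelength grid (nm)
#' and one value per grid point. The same container holds fluorescence
#' emission (arbitrary units), absorbance (AU) and molar absorptivity
#' (L mol^-1 cm^-1); `value_kind` records which.
#'
#' @param wavelengths_nm numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param values numeric vector of the same length; must be non-negative.
#' @param value_kind one of `"emission"`, `"absorbance"`,
#'   `"molar_absorptivity"`.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelengths_nm`, `values`, `value_kind`.
#' @examples
#' s <- spectrum(c(300, 341, 400), c(0, 100, 0), "emission")
#' peak_position(s)
#' @export
spectrum <- function(wavelengths_nm, values,
                     value_kind = c("emission", "absorbance",
                                    "molar_absorptivity")) {
  value_kind <- match.arg(value_kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have equal length", call. = FALSE)
  if (anyNA(wavelengths_nm) || anyNA(values) ||
      any(!is.finite(wavelengths_nm)) || any(!is.finite(values)))
    stop("wavelengths and values must be finite", call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing (no duplicates)",
         call. = FALSE)
  if (any(values < 0))
    stop(sprintf("%s values must be >= 0", value_kind), call. = FALSE)
  structure(list(wavelengths_nm = wavelengths_nm, values = values,
                 value_kind = value_kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.1f-%.1f nm>\n",
              x$value_kind, length(x$values),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Read a spectrum from a two-column text file
#'
#' The file dialect is deliberately minimal for hand-editability: two columns
#' (wavelength in nm, value), comma- or tab/whitespace-delimited, with `#`
#' comment lines. Rows may appear in any order; the returned spectrum is
#' sorted by wavelength.
#'
#' @param path file path.
#' @param value_kind value kind of the stored curve (see [spectrum()]).
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, value_kind = c("emission", "absorbance",
                                               "molar_absorptivity")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no data rows in ", path, call. = FALSE)
  wl <- numeric(length(idx)); val <- numeric(length(idx))
  for (i in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[i]]), "[,\t ]+")[[1]]
    nums <- suppressWarnings(as.numeric(fields))
    if (length(nums) < 2L || anyNA(nums[1:2]))
      stop(sprintf("parse error in %s at line %d: %s",
                   path, idx[i], lines[idx[i]]), call. = FALSE)
    wl[i] <- nums[1]; val[i] <- nums[2]
  }
  ord <- order(wl)
  if (anyDuplicated(wl))
    stop("duplicate wavelengths in ", path, call. = FALSE)
  spectrum(wl[ord], val[ord], value_kind)
}

#' Write a spectrum to a two-column text file
#'
#' Inverse of [read_spectrum()]; values are written with enough digits
#' (15 significant) for a lossless round trip at double precision.
#'
#' @param s a [spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  header <- sprintf("# wavelength_nm\tvalue (%s)", s$value_kind)
  rows <- sprintf("%.15g\t%.15g", s$wavelengths_nm, s$values)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Linearly interpolate a spectrum onto a new wavelength grid
#'
#' Emission and absorption bands are smooth on the nm sampling used here, so
#' linear interpolation is adequate for aligning spectra (e.g. the acceptor
#' absorptivity onto the donor emission grid for the overlap integral).
#'
#' @param s a [spectrum()].
#' @param grid target wavelengths in nm; must lie within the span of `s`.
#' @return A [spectrum()] on `grid` with the same `value_kind`.
#' @export
interpolate_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- sort(as.numeric(grid))
  if (min(grid) < min(s$wavelengths_nm) || max(grid) > max(s$wavelengths_nm))
    stop(sprintf("grid [%g, %g] outside spectrum span [%g, %g] nm",
                 min(grid), max(grid),
                 min(s$wavelengths_nm), max(s$wavelengths_nm)),
         call. = FALSE)
  v <- stats::approx(s$wavelengths_nm, s$values, xout = grid,
                     method = "linear", ties = "ordered")$y
  if (length(grid) == 1L) {
    # spectrum() requires >= 2 points; single-wavelength queries return the value
    return(v)
  }
  spectrum(grid, v, s$value_kind)
}

#' Value of a spectrum at one wavelength (linear interpolation)
#' @param s a [spectrum()].
#' @param wavelength_nm scalar wavelength in nm within the span of `s`.
#' @return numeric scalar.
#' @export
spectrum_value_at <- function(s, wavelength_nm) {
  stopifnot(length(wavelength_nm) == 1L)
  interpolate_to_grid(s, wavelength_nm)
}

#' Construct a titration point
#'
#' One point of a quenching titration: the quencher concentration, the
#' measured emission spectrum, and the solution absorbance at the excitation
#' and emission wavelengths (used for the inner-filter correction; default 0
#' means no correction needed).
#'
#' @param quencher_conc_M quencher concentration, mol/L, finite and >= 0.
#' @param emission a [spectrum()] with `value_kind = "emission"`.
#' @param A_ex,A_em absorbance (AU) at the excitation / emission wavelength.
#' @return An object of class `"titration_point"`.
#' @export
titration_point <- function(quencher_conc_M, emission, A_ex = 0, A_em = 0) {
  if (!is.finite(quencher_conc_M) || quencher_conc_M < 0)
    stop("quencher_conc_M must be finite and >= 0", call. = FALSE)
  stopifnot(inherits(emission, "spectrum"))
  if (emission$value_kind != "emission")
    stop("titration point spectrum must be of kind 'emission'", call. = FALSE)
  if (A_ex < 0 || A_em < 0)
    stop("absorbances must be >= 0", call. = FALSE)
  structure(list(quencher_conc_M = quencher_conc_M, emission = emission,
                 A_ex = A_ex, A_em = A_em),
            class = "titration_point")
}

#' Construct a titration series
#'
#' An ordered fluorescence titration at fixed protein concentration,
#' temperature and excitation wavelength. The first point must have zero
#' quencher (it defines F0) and concentrations must strictly increase.
#'
#' @param protein_conc_M protein concentration, mol/L.
#' @param temperature_K temperature in kelvin.
#' @param excitation_nm excitation wavelength in nm.
#' @param points list of [titration_point()]s, >= 3, first at zero quencher,
#'   strictly increasing concentrations.
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(protein_conc_M, temperature_K, excitation_nm,
                             points) {
  stopifnot(is.list(points))
  if (!all(vapply(points, inherits, logical(1), "titration_point")))
    stop("points must all be titration_point objects", call. = FALSE)
  if (length(points) < 3L)
    stop("a titration series needs at least 3 points", call. = FALSE)
  concs <- vapply(points, `[[`, numeric(1), "quencher_conc_M")
  if (concs[1] != 0)
    stop("first titration point must have quencher_conc_M = 0 (defines F0)",
         call. = FALSE)
  if (any(diff(concs) <= 0))
    stop("quencher concentrations must be strictly increasing", call. = FALSE)
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be positive", call. = FALSE)
  structure(list(protein_conc_M = protein_conc_M,
                 temperature_K = temperature_K,
                 excitation_nm = excitation_nm,
                 points = points),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  concs <- titration_concs(x)
  cat(sprintf(
    "<titration series: %d points, [Q] 0-%.3g mol/L, %g K, lambda_ex %g nm>\n",
    length(x$points), max(concs), x$temperature_K, x$excitation_nm))
  invisible(x)
}

#' Quencher concentrations of a series
#' @param series a [titration_series()].
#' @return numeric vector of mol/L, in titration order.
#' @export
titration_concs <- function(series) {
  vapply(series$points, `[[`, numeric(1), "quencher_conc_M")
}

#' Read a titration series from a YAML manifest
#'
#' The manifest lists the series metadata and one entry per titration point:
#' ```yaml
#' protein_conc_M: 1.0e-5
#' temperature_K: 298
#' excitation_nm: 282
#' points:
#'   - {conc_M: 0.0, emission_file: p00.tsv, A_ex: 0.0, A_em: 0.0}
#'   - {conc_M: 4.0e-6, emission_file: p01.tsv, A_ex: 0.01, A_em: 0.004}
#' ```
#' Spectrum file paths are resolved relative to the manifest's directory.
#' `A_ex`/`A_em` default to 0 when omitted.
#'
#' @param manifest path to the YAML manifest.
#' @return A [titration_series()].
#' @export
read_titration <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest,
                                   call. = FALSE)
  m <- yaml::read_yaml(manifest)
  req <- c("protein_conc_M", "temperature_K", "excitation_nm", "points")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("manifest missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dir <- dirname(manifest)
  pts <- lapply(m$points, function(p) {
    if (is.null(p$conc_M) || is.null(p$emission_file))
      stop("each manifest point needs conc_M and emission_file",
           call. = FALSE)
    f <- p$emission_file
    if (!file.exists(f)) f <- file.path(dir, p$emission_file)
    titration_point(as.numeric(p$conc_M),
                    read_spectrum(f, "emission"),
                    A_ex = if (is.null(p$A_ex)) 0 else as.numeric(p$A_ex),
                    A_em = if (is.null(p$A_em)) 0 else as.numeric(p$A_em))
  })
  titration_series(as.numeric(m$protein_conc_M), as.numeric(m$temperature_K),
                   as.numeric(m$excitation_nm), pts)
}

#' Write a titration series as a manifest plus spectrum files
#'
#' Serializes `series` into the layout accepted by [read_titration()]:
#' one two-column spectrum file per point and a YAML manifest naming them.
#'
#' @param series a [titration_series()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem for the spectrum files.
#' @return Path to the written manifest, invisibly.
#' @export
write_titration <- function(series, dir, stem = "point") {
  stopifnot(inherits(series, "titration_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(series$points))
  for (i in seq_along(series$points)) {
    files[i] <- sprintf("%s%02d.tsv", stem, i - 1L)
    write_spectrum(series$points[[i]]$emission, file.path(dir, files[i]))
  }
  m <- list(
    protein_conc_M = series$protein_conc_M,
    temperature_K = series$temperature_K,
    excitation_nm = series$excitation_nm,
    points = lapply(seq_along(series$points), function(i) {
      p <- series$points[[i]]
      list(conc_M = p$quencher_conc_M, emission_file = files[i],
           A_ex = p$A_ex, A_em = p$A_em)
    }))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(m, manifest, precision = 15L)
  invisible(manifest)
}
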