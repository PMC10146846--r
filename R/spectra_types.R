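#' Signal kinds understood by the package
#'
#' `absorbance` (AU), `fluorescence` (instrument counts), `cd_mdeg`
#' (circular-dichroism ellipticity in millidegrees) are the measured kinds;
#' `mre` (deg cm^2 dmol^-1) is the derived mean-residue-ellipticity kind
#' produced by [mre_spectrum()].
#'
#' @keywords internal
SIGNAL_KINDS <- c("absorbance", "fluorescence", "cd_mdeg", "mre")

#' Construct a single spectrum
#'
#' A spectrum is a strictly increasing wavelength grid (nm) paired with one
#' finite signal value per wavelength.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param intensity Numeric vector of the same length; absorbance (AU),
#'   fluorescence (counts), or CD ellipticity (mdeg) depending on
#'   `signal_kind`.
#' @param signal_kind One of `"absorbance"`, `"fluorescence"`, `"cd_mdeg"`,
#'   `"mre"`.
#' @return An object of class `sb_spectrum`.
#' @examples
#' spectrum(c(278, 280, 282), c(0.19, 0.20, 0.19), "absorbance")
#' @export
spectrum <- function(wavelength_nm, intensity, signal_kind) {
  signal_kind <- match.arg(signal_kind, SIGNAL_KINDS)
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  x <- structure(list(wavelength_nm = wavelength_nm,
                      intensity = intensity,
                      signal_kind = signal_kind),
                 class = "sb_spectrum")
  validate_spectrum(x)
}

#' @keywords internal
validate_spectrum <- function(x) {
  if (length(x$wavelength_nm) != length(x$intensity))
    sb_stop("wavelength_nm and intensity must have equal length",
            "sb_validation_error")
  if (length(x$wavelength_nm) == 0L)
    sb_stop("spectrum must contain at least one point", "sb_validation_error")
  if (anyNA(x$wavelength_nm) || any(!is.finite(x$wavelength_nm)))
    sb_stop("wavelength_nm contains non-finite values", "sb_validation_error")
  if (any(diff(x$wavelength_nm) <= 0))
    sb_stop("wavelength_nm must be strictly increasing", "sb_validation_error")
  if (any(!is.finite(x$intensity)))
    sb_stop("intensity contains non-finite values", "sb_validation_error")
  if (!x$signal_kind %in% SIGNAL_KINDS)
    sb_stop(sprintf("unknown signal_kind '%s'", x$signal_kind),
            "sb_validation_error")
  x
}

#' @export
print.sb_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm>\n",
              x$signal_kind, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Construct a spectral titration set
#'
#' A titration set holds one spectrum per ligand concentration, measured on a
#' shared wavelength grid at fixed protein concentration and temperature.
#' The first concentration must be 0 (the ligand-free reference).
#'
#' @param ligand_conc_M Numeric vector of ligand concentrations in mol/L,
#'   non-negative, strictly increasing, first element 0.
#' @param spectra List of [spectrum()] objects, one per concentration, all on
#'   the same wavelength grid with the same signal kind.
#' @param protein_conc_M Protein concentration in mol/L.
#' @param temperature_K Temperature in kelvin.
#' @return An object of class `sb_titration`.
#' @export
titration_set <- function(ligand_conc_M, spectra, protein_conc_M,
                          temperature_K = 298) {
  x <- structure(list(ligand_conc_M = as.numeric(ligand_conc_M),
                      spectra = spectra,
                      protein_conc_M = as.numeric(protein_conc_M),
                      temperature_K = as.numeric(temperature_K)),
                 class = "sb_titration")
  validate_titration_set(x)
}

#' @keywords internal
validate_titration_set <- function(x) {
  conc <- x$ligand_conc_M
  if (length(conc) == 0L)
    sb_stop("ligand_conc_M is empty", "sb_validation_error")
  if (anyNA(conc) || any(!is.finite(conc)))
    sb_stop("ligand_conc_M contains non-finite values", "sb_validation_error")
  if (any(conc < 0))
    sb_stop("ligand_conc_M must be non-negative", "sb_validation_error")
  if (conc[1L] != 0)
    sb_stop("first ligand concentration must be 0 (ligand-free reference)",
            "sb_validation_error")
  if (length(conc) > 1L && any(diff(conc) <= 0))
    sb_stop("ligand_conc_M must be strictly increasing",
            "sb_validation_error")
  if (length(x$spectra) != length(conc))
    sb_stop("need exactly one spectrum per ligand concentration",
            "sb_validation_error")
  for (s in x$spectra) validate_spectrum(s)
  grid <- x$spectra[[1L]]$wavelength_nm
  kind <- x$spectra[[1L]]$signal_kind
  for (s in x$spectra) {
    if (!identical(s$wavelength_nm, grid))
      sb_stop("all spectra must share the same wavelength grid",
              "sb_validation_error")
    if (!identical(s$signal_kind, kind))
      sb_stop("all spectra must share the same signal_kind",
              "sb_validation_error")
  }
  if (!is.finite(x$protein_conc_M) || x$protein_conc_M <= 0)
    sb_stop("protein_conc_M must be positive", "sb_validation_error")
  if (!is.finite(x$temperature_K) || x$temperature_K <= 0)
    sb_stop("temperature_K must be positive", "sb_validation_error")
  x
}

#' Signal kind of a titration set
#' @param t An `sb_titration`.
#' @return The shared signal kind of its spectra.
#' @export
titration_signal_kind <- function(t) t$spectra[[1L]]$signal_kind

#' @export
print.sb_titration <- function(x, ...) {
  cat(sprintf(
    "<titration: %s, %d concentrations 0-%g uM, protein %g uM, %g K>\n",
    titration_signal_kind(x), length(x$ligand_conc_M),
    max(x$ligand_conc_M) * 1e6, x$protein_conc_M * 1e6, x$temperature_K))
  invisible(x)
}

#' Construct an excitation-emission matrix (EEM)
#'
#' @param excitation_nm Strictly increasing excitation wavelength grid (nm).
#' @param emission_nm Strictly increasing emission wavelength grid (nm).
#' @param intensity Numeric matrix indexed `[excitation, emission]`, finite
#'   and non-negative.
#' @param ligand_conc_M Optional ligand concentration (mol/L) attached as
#'   metadata for titrated EEM series.
#' @return An object of class `sb_eem`.
#' @export
eem <- function(excitation_nm, emission_nm, intensity, ligand_conc_M = NULL) {
  x <- structure(list(excitation_nm = as.numeric(excitation_nm),
                      emission_nm = as.numeric(emission_nm),
                      intensity = as.matrix(intensity),
                      ligand_conc_M = if (!is.null(ligand_conc_M))
                        as.numeric(ligand_conc_M)),
                 class = "sb_eem")
  validate_eem(x)
}

#' @keywords internal
validate_eem <- function(x) {
  for (g in c("excitation_nm", "emission_nm")) {
    v <- x[[g]]
    if (length(v) == 0L || anyNA(v) || any(!is.finite(v)))
      sb_stop(sprintf("%s must be a non-empty finite grid", g),
              "sb_validation_error")
    if (length(v) > 1L && any(diff(v) <= 0))
      sb_stop(sprintf("%s must be strictly increasing", g),
              "sb_validation_error")
  }
  if (!is.numeric(x$intensity) || !is.matrix(x$intensity))
    sb_stop("intensity must be a numeric matrix", "sb_shape_error")
  if (nrow(x$intensity) != length(x$excitation_nm) ||
      ncol(x$intensity) != length(x$emission_nm))
    sb_stop(sprintf(
      "intensity matrix is %d x %d but grids are %d x %d",
      nrow(x$intensity), ncol(x$intensity),
      length(x$excitation_nm), length(x$emission_nm)), "sb_shape_error")
  if (any(!is.finite(x$intensity)))
    sb_stop("EEM intensities must be finite", "sb_validation_error")
  if (any(x$intensity < 0))
    sb_stop("EEM intensities must be non-negative", "sb_validation_error")
  x
}

#' @export
print.sb_eem <- function(x, ...) {
  cat(sprintf("<EEM: %d x %d, ex %g-%g nm, em %g-%g nm>\n",
              length(x$excitation_nm), length(x$emission_nm),
              min(x$excitation_nm), max(x$excitation_nm),
              min(x$emission_nm), max(x$emission_nm)))
  invisible(x)
}

#' Construct a circular-dichroism spectrum with protein metadata
#'
#' Holds the observed ellipticity in millidegrees together with the protein
#' concentration, residue count and cuvette path length needed to convert to
#' mean residue ellipticity.
#'
#' @param spectrum An [spectrum()] with `signal_kind = "cd_mdeg"`.
#' @param protein_conc_M Protein concentration in mol/L (> 0).
#' @param n_residues Number of amino-acid residues (>= 1); 130 for human
#'   lysozyme.
#' @param path_length_cm Cuvette path length in cm (> 0).
#' @return An object of class `sb_cd`.
#' @export
cd_spectrum <- function(spectrum, protein_conc_M, n_residues = 130,
                        path_length_cm = 0.1) {
  x <- structure(list(spectrum = spectrum,
                      protein_conc_M = as.numeric(protein_conc_M),
                      n_residues = as.numeric(n_residues),
                      path_length_cm = as.numeric(path_length_cm)),
                 class = "sb_cd")
  validate_cd_spectrum(x)
}

#' @keywords internal
validate_cd_spectrum <- function(x) {
  validate_spectrum(x$spectrum)
  if (!identical(x$spectrum$signal_kind, "cd_mdeg"))
    sb_stop("CD spectrum must have signal_kind 'cd_mdeg'",
            "sb_validation_error")
  if (!is.finite(x$protein_conc_M) || x$protein_conc_M <= 0)
    sb_stop("protein_conc_M must be positive", "sb_domain_error")
  if (!is.finite(x$n_residues) || x$n_residues < 1)
    sb_stop("n_residues must be >= 1", "sb_domain_error")
  if (!is.finite(x$path_length_cm) || x$path_length_cm <= 0)
    sb_stop("path_length_cm must be positive", "sb_domain_error")
  x
}

#' @export
print.sb_cd <- function(x, ...) {
  cat(sprintf("<CD spectrum: %d points, protein %g uM, n = %d, l = %g cm>\n",
              length(x$spectrum$wavelength_nm), x$protein_conc_M * 1e6,
              as.integer(x$n_residues), x$path_length_cm))
  invisible(x)
}

#' Construct a titration series
#'
#' A titration series pairs ligand concentrations with one scalar signal per
#' concentration (an absorbance change or a fluorescence peak intensity) read
#' at a fixed analysis wavelength. It is the common input of all the
#' linearised binding fits.
#'
#' @param conc_M Ligand concentrations in mol/L.
#' @param signal Scalar signal per concentration.
#' @param wavelength_nm Analysis wavelength the signal was read at (may be
#'   `NA` when the signal is a spectral maximum).
#' @param kind Signal kind, see [spectrum()].
#' @return A data frame of class `sb_series` with columns `conc_M`, `signal`.
#' @export
titration_series <- function(conc_M, signal, wavelength_nm = NA_real_,
                             kind = "absorbance") {
  conc_M <- as.numeric(conc_M)
  signal <- as.numeric(signal)
  if (length(conc_M) != length(signal))
    sb_stop("conc_M and signal must have equal length", "sb_validation_error")
  if (anyNA(conc_M) || any(!is.finite(conc_M)) || any(conc_M < 0))
    sb_stop("conc_M must be finite and non-negative", "sb_validation_error")
  if (any(!is.finite(signal)))
    sb_stop("signal must be finite", "sb_validation_error")
  structure(data.frame(conc_M = conc_M, signal = signal),
            wavelength_nm = wavelength_nm, kind = kind,
            class = c("sb_series", "data.frame"))
}

#' Linear interpolation of a spectrum at one wavelength
#'
#' @param s An [spectrum()].
#' @param wavelength_nm Wavelength to evaluate at; must lie within the grid
#'   range (values between grid points are linearly interpolated).
#' @return The interpolated intensity.
#' @export
intensity_at <- function(s, wavelength_nm) {
  w <- s$wavelength_nm
  if (wavelength_nm < w[1L] || wavelength_nm > w[length(w)])
    sb_stop(sprintf("wavelength %g nm outside measured range %g-%g nm",
                    wavelength_nm, w[1L], w[length(w)]), "sb_range_error")
  stats::approx(w, s$intensity, xout = wavelength_nm, method = "linear",
                ties = "ordered")$y
}
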