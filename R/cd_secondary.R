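# Circular-dichroism secondary-structure estimation.
#
# Observed ellipticity in millidegrees is normalised to mean residue
# ellipticity,
#     MRE(lambda) = theta_obs(lambda) / (C_p * n * l * 10)
# with C_p the protein molar concentration, n the residue count and l the
# path length in cm, and the alpha-helix fraction follows the empirical
# two-point formula at 208 nm,
#     %helix = (-MRE208 - 4000) / (33000 - 4000) * 100
# where 4000 is the 208 nm MRE of random coil / beta form and 33000 that of
# pure helix.

MRE_COIL_208 <- 4000
MRE_HELIX_208 <- 33000

#' Mean residue ellipticity spectrum
#'
#' Pointwise conversion of observed ellipticity (mdeg) to mean residue
#' ellipticity (deg cm^2 dmol^-1).
#'
#' @param c An [cd_spectrum()].
#' @return An [spectrum()] with `signal_kind = "mre"` on the same wavelength
#'   grid.
#' @export
mre_spectrum <- function(c) {
  validate_cd_spectrum(c)
  denom <- c$protein_conc_M * c$n_residues * c$path_length_cm * 10
  spectrum(c$spectrum$wavelength_nm, c$spectrum$intensity / denom, "mre")
}

#' MRE at a target wavelength
#'
#' Reads the mean residue ellipticity at the requested wavelength, linearly
#' interpolated when it falls between grid points.
#'
#' @param mre An `"mre"` [spectrum()] from [mre_spectrum()].
#' @param wavelength_nm Target wavelength; default 208 nm.
#' @return The MRE value.
#' @export
mre_at <- function(mre, wavelength_nm = 208) {
  if (!identical(mre$signal_kind, "mre"))
    sb_stop("mre_at expects a spectrum of kind 'mre'", "sb_validation_error")
  intensity_at(mre, wavelength_nm)
}

#' Alpha-helix fraction from the MRE at 208 nm
#'
#' Applies the empirical two-point formula
#' `%helix = (-MRE208 - 4000) / 29000 * 100`. Values outside 0-100 are
#' reported with `out_of_model = TRUE` rather than clamped, so breakdown of
#' the two-point model stays visible.
#'
#' @param mre_208 Mean residue ellipticity at 208 nm (deg cm^2 dmol^-1).
#' @return An object of class `sb_helix` with `mre_208`, `helix_percent`,
#'   `out_of_model`, and the endpoint constants `mre_coil_208`,
#'   `mre_helix_208`.
#' @examples
#' helix_percent(-13273.95)$helix_percent  # 31.98
#' @export
helix_percent <- function(mre_208) {
  if (!is.finite(mre_208))
    sb_stop("mre_208 must be finite", "sb_domain_error")
  pct <- (-mre_208 - MRE_COIL_208) / (MRE_HELIX_208 - MRE_COIL_208) * 100
  structure(list(mre_208 = mre_208,
                 helix_percent = pct,
                 out_of_model = pct < 0 || pct > 100,
                 mre_coil_208 = MRE_COIL_208,
                 mre_helix_208 = MRE_HELIX_208),
            class = "sb_helix")
}

#' Full CD secondary-structure analysis
#'
#' Converts a CD spectrum to MRE, reads the 208 nm value and returns the
#' helix estimate.
#'
#' @param c An [cd_spectrum()].
#' @param wavelength_nm Analysis wavelength (default 208 nm).
#' @return An `sb_helix` object (see [helix_percent()]).
#' @export
cd_helix <- function(c, wavelength_nm = 208) {
  helix_percent(mre_at(mre_spectrum(c), wavelength_nm))
}

#' @export
print.sb_helix <- function(x, ...) {
  cat(sprintf("MRE at 208 nm : %.2f deg cm^2 dmol^-1\n", x$mre_208))
  cat(sprintf("alpha-helix   : %.2f %%%s\n", x$helix_percent,
              if (x$out_of_model) "  [outside 0-100: two-point model breakdown]"
              else ""))
  invisible(x)
}
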