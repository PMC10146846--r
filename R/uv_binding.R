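# UV-vis absorbance titration analysis.
#
# The binding model is the linearised 1:1 isotherm: with dA = A([S]) - A(0)
# read at the aromatic band, the double-reciprocal form
#     1/dA = (K_d / dA_inf) * (1/[S]) + 1/dA_inf
# gives K_d and dA_inf from an ordinary least-squares line, and the Hill plot
#     log10(dA / (dA_inf - dA)) = h * log10([S]) + log10(K_a)
# gives the cooperativity h and an independent estimate of K_a. The free
# energy of association is dG0 = -R T ln(K_a).

#' Gas constant in kcal mol^-1 K^-1
#' @keywords internal
R_KCAL <- 1.987204e-3

#' Absorbance-difference series at the analysis wavelength
#'
#' For every nonzero ligand concentration, computes
#' `dA = A([S]) - A(0)` at the analysis wavelength (linearly interpolated if
#' the wavelength falls between grid points). The ligand-free reference point
#' is consumed as the baseline and excluded from the returned series.
#'
#' @param t An absorbance [titration_set()].
#' @param wavelength_nm Analysis wavelength; defaults to 280 nm, the aromatic
#'   (Trp/Tyr/Phe) band.
#' @return A [titration_series()] of `dA` values, one per nonzero
#'   concentration.
#' @export
delta_A_series <- function(t, wavelength_nm = 280) {
  validate_titration_set(t)
  if (titration_signal_kind(t) != "absorbance")
    sb_stop("delta_A_series needs an absorbance titration",
            "sb_validation_error")
  a <- vapply(t$spectra, intensity_at, 0, wavelength_nm = wavelength_nm)
  keep <- t$ligand_conc_M > 0
  titration_series(t$ligand_conc_M[keep], a[keep] - a[1L],
                   wavelength_nm = wavelength_nm, kind = "absorbance")
}

#' Double-reciprocal fit for the dissociation constant
#'
#' Ordinary least-squares line of `1/dA` on `1/[S]`;
#' `K_d = slope / intercept`, `dA_inf = 1 / intercept`. Points with
#' `dA <= 0` cannot enter the reciprocal and are excluded with a warning.
#'
#' @param s A [titration_series()] of absorbance differences (from
#'   [delta_A_series()]).
#' @return A list with `K_d_M`, `delta_A_inf`, `r2`, `n_points_used`,
#'   `slope`, `intercept`.
#' @export
fit_double_reciprocal <- function(s) {
  usable <- s$conc_M > 0 & s$signal > 0
  if (any(!usable))
    sb_warn(sprintf(
      "excluding %d point(s) with dA <= 0 from the double-reciprocal fit",
      sum(!usable)), "sb_points_excluded")
  x <- 1 / s$conc_M[usable]
  y <- 1 / s$signal[usable]
  if (sum(usable) < 3L)
    sb_stop(sprintf(
      "double-reciprocal fit needs >= 3 points with dA > 0, got %d",
      sum(usable)), "sb_insufficient_data_error")
  fit <- stats::lm(y ~ x)
  intercept <- unname(stats::coef(fit)[1L])
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(intercept) || intercept <= 0)
    sb_stop(sprintf(
      "double-reciprocal intercept %.4g is not positive: saturation absorbance undefined (saturated or nonphysical data)",
      intercept), "sb_nonphysical_fit_error")
  K_d <- slope / intercept
  # a saturated series gives slope ~ 0 up to rounding; K_d below numerical
  # resolution on the concentration scale is as nonphysical as a negative one
  floor_K_d <- .Machine$double.eps^0.5 * min(s$conc_M[usable])
  if (!is.finite(K_d) || K_d <= floor_K_d)
    sb_stop(sprintf(
      "fitted K_d = %.4g M is nonphysical (zero, negative or below numerical resolution)",
      K_d), "sb_nonphysical_fit_error")
  list(K_d_M = K_d, delta_A_inf = 1 / intercept,
       r2 = r_squared(fit), n_points_used = sum(usable),
       slope = slope, intercept = intercept)
}

#' Association constant from the dissociation constant
#'
#' @param K_d_M Dissociation constant in mol/L (> 0).
#' @return `K_a = 1 / K_d` in M^-1.
#' @export
association_constant <- function(K_d_M) {
  if (!is.finite(K_d_M) || K_d_M <= 0)
    sb_stop("K_d must be a positive finite number", "sb_domain_error")
  1 / K_d_M
}

#' Hill plot fit for cooperativity
#'
#' Least-squares line of `log10(dA / (dA_inf - dA))` on `log10([S])`.
#' The slope is the Hill coefficient `h` (1 for independent binding) and
#' `10^intercept` is the association constant. Points with `dA <= 0` or
#' `dA >= dA_inf` have no finite Hill transform and are excluded with a
#' warning.
#'
#' @param s A [titration_series()] of absorbance differences.
#' @param delta_A_inf Saturation absorbance difference, normally taken from
#'   [fit_double_reciprocal()].
#' @return A list with `hill_h`, `K_a_per_M`, `r2`, `n_points_used`.
#' @export
fit_hill <- function(s, delta_A_inf) {
  if (!is.finite(delta_A_inf) || delta_A_inf == 0)
    sb_stop("delta_A_inf must be finite and nonzero", "sb_domain_error")
  usable <- s$conc_M > 0 & s$signal > 0 & s$signal < delta_A_inf
  if (any(!usable))
    sb_warn(sprintf(
      "excluding %d point(s) outside 0 < dA < dA_inf from the Hill fit",
      sum(!usable)), "sb_points_excluded")
  if (sum(usable) < 3L)
    sb_stop(sprintf("Hill fit needs >= 3 usable points, got %d",
                    sum(usable)), "sb_insufficient_data_error")
  x <- log10(s$conc_M[usable])
  y <- log10(s$signal[usable] / (delta_A_inf - s$signal[usable]))
  fit <- stats::lm(y ~ x)
  list(hill_h = unname(stats::coef(fit)[2L]),
       K_a_per_M = 10^unname(stats::coef(fit)[1L]),
       r2 = r_squared(fit),
       n_points_used = sum(usable))
}

#' Gibbs free energy of association
#'
#' `dG0 = -R T ln(K_a)` with `R = 1.987204e-3` kcal mol^-1 K^-1.
#'
#' @param K_a_per_M Association constant in M^-1 (> 0).
#' @param temperature_K Temperature in kelvin (> 0).
#' @return Free-energy change in kcal mol^-1 (negative for spontaneous
#'   association with `K_a > 1`).
#' @examples
#' gibbs_free_energy(1.929e5, 298)  # about -7.21 kcal/mol
#' @export
gibbs_free_energy <- function(K_a_per_M, temperature_K = 298) {
  if (!is.finite(K_a_per_M) || K_a_per_M <= 0)
    sb_stop("K_a must be a positive finite number", "sb_domain_error")
  if (!is.finite(temperature_K) || temperature_K <= 0)
    sb_stop("temperature_K must be positive", "sb_domain_error")
  -R_KCAL * temperature_K * log(K_a_per_M)
}

#' Full UV-vis binding analysis of an absorbance titration
#'
#' Runs [delta_A_series()], [fit_double_reciprocal()], [fit_hill()] and
#' [gibbs_free_energy()] and assembles the binding parameters. `K_a_per_M`
#' is `1/K_d` from the double-reciprocal fit; `K_a_hill_per_M` is the
#' independent Hill-intercept estimate — the two are reported side by side
#' and not forced to agree. `delta_G0_kcal_per_mol` uses `K_a_per_M`.
#'
#' @param t An absorbance [titration_set()].
#' @param wavelength_nm Analysis wavelength (default 280 nm).
#' @param temperature_K Temperature for the free energy; defaults to the
#'   titration's own.
#' @return An object of class `sb_uv_fit`.
#' @export
uv_binding_fit <- function(t, wavelength_nm = 280,
                           temperature_K = t$temperature_K) {
  s <- delta_A_series(t, wavelength_nm)
  dr <- fit_double_reciprocal(s)
  hill <- fit_hill(s, dr$delta_A_inf)
  K_a <- association_constant(dr$K_d_M)
  structure(list(
    analysis_wavelength_nm = wavelength_nm,
    temperature_K = temperature_K,
    delta_A_inf = dr$delta_A_inf,
    K_d_M = dr$K_d_M,
    K_a_per_M = K_a,
    K_a_hill_per_M = hill$K_a_per_M,
    hill_h = hill$hill_h,
    delta_G0_kcal_per_mol = gibbs_free_energy(K_a, temperature_K),
    r2_reciprocal = dr$r2,
    r2_hill = hill$r2,
    n_points_used = c(reciprocal = dr$n_points_used,
                      hill = hill$n_points_used)),
    class = "sb_uv_fit")
}

#' @export
print.sb_uv_fit <- function(x, ...) {
  cat("UV-vis binding fit\n")
  cat(sprintf("  analysis wavelength : %g nm\n", x$analysis_wavelength_nm))
  cat(sprintf("  K_d                 : %.3g M        (r2 = %.4f, n = %d)\n",
              x$K_d_M, x$r2_reciprocal, x$n_points_used[["reciprocal"]]))
  cat(sprintf("  K_a = 1/K_d         : %.3g M^-1\n", x$K_a_per_M))
  cat(sprintf("  K_a (Hill intercept): %.3g M^-1\n", x$K_a_hill_per_M))
  cat(sprintf("  dA_inf              : %.4g AU\n", x$delta_A_inf))
  cat(sprintf("  Hill h              : %.3f          (r2 = %.4f, n = %d)\n",
              x$hill_h, x$r2_hill, x$n_points_used[["hill"]]))
  cat(sprintf("  dG0 (%g K)          : %.2f kcal/mol\n",
              x$temperature_K, x$delta_G0_kcal_per_mol))
  invisible(x)
}
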