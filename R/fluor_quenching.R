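# Fluorescence-quenching analysis.
#
# Stern-Volmer: F0/F = 1 + K_sv [Q]. The regression fits an intercept rather
# than forcing the model value of 1, and reports its deviation from 1 as a
# model-adequacy diagnostic (curvature from inner-filter effects or mixed
# quenching shows up there). The bimolecular rate k_q = K_sv / tau0 is
# compared with the diffusion-limited reference 2e10 M^-1 s^-1 to call the
# mechanism: k_q far above the collisional limit implies a ground-state
# complex (static quenching). The modified Stern-Volmer (double-log) plot
# log10((F0-F)/F) = log10(K_b) + n log10([Q]) yields the binding constant
# and the number of binding sites.

#' Peak fluorescence-intensity series
#'
#' For each ligand concentration, the maximum emission intensity over the
#' scanned range (ties resolve to the lowest wavelength). The zero
#' concentration gives `F0`.
#'
#' @param t A fluorescence [titration_set()].
#' @return A [titration_series()] including the zero-concentration point;
#'   attribute `lambda_max_nm` holds the wavelength of each maximum.
#' @export
peak_intensity_series <- function(t) {
  validate_titration_set(t)
  if (titration_signal_kind(t) != "fluorescence")
    sb_stop("peak_intensity_series needs a fluorescence titration",
            "sb_validation_error")
  peak <- vapply(t$spectra, function(s) max(s$intensity), 0)
  lmax <- vapply(t$spectra, function(s)
    s$wavelength_nm[which.max(s$intensity)], 0)
  s <- titration_series(t$ligand_conc_M, peak, kind = "fluorescence")
  attr(s, "lambda_max_nm") <- lmax
  s
}

#' @keywords internal
extract_F0 <- function(s, F0) {
  if (!is.null(F0)) return(F0)
  i <- which(s$conc_M == 0)
  if (length(i) != 1L)
    sb_stop("series has no zero-concentration point; supply F0",
            "sb_validation_error")
  s$signal[i]
}

#' Stern-Volmer fit
#'
#' Least-squares line of `F0/F` on `[Q]` over the nonzero concentrations.
#' `K_sv` is the slope; the fitted intercept (ideally 1) is returned as a
#' diagnostic. Ratios `F0/F < 1` (anti-quenching points) are retained but
#' logged, so violations of monotone quenching stay visible.
#'
#' @param s A [titration_series()] of peak intensities (from
#'   [peak_intensity_series()]).
#' @param F0 Unquenched intensity; taken from the zero-concentration point
#'   when `NULL`.
#' @return A list with `K_sv_per_M`, `intercept`, `r2`, `n_points_used`.
#' @export
stern_volmer_fit <- function(s, F0 = NULL) {
  F0 <- extract_F0(s, F0)
  keep <- s$conc_M > 0
  q <- s$conc_M[keep]
  f <- s$signal[keep]
  if (any(f <= 0))
    sb_stop("fluorescence intensities must be positive", "sb_validation_error")
  if (length(q) < 3L)
    sb_stop(sprintf("Stern-Volmer fit needs >= 3 nonzero points, got %d",
                    length(q)), "sb_insufficient_data_error")
  ratio <- F0 / f
  if (any(ratio < 1))
    sb_warn(sprintf("%d point(s) have F0/F < 1 (anti-quenching); retained",
                    sum(ratio < 1)), "sb_antiquenching")
  fit <- stats::lm(ratio ~ q)
  K_sv <- unname(stats::coef(fit)[2L])
  if (K_sv < 0)
    sb_warn(sprintf("negative Stern-Volmer slope (%.4g M^-1)", K_sv),
            "sb_negative_slope")
  list(K_sv_per_M = K_sv, intercept = unname(stats::coef(fit)[1L]),
       r2 = r_squared(fit), n_points_used = length(q))
}

#' Bimolecular quenching rate constant
#'
#' @param K_sv_per_M Stern-Volmer constant in M^-1.
#' @param tau0_s Unquenched fluorophore lifetime in seconds (> 0); the
#'   default 5.78e-9 s is the literature lifetime of lysozyme's intrinsic
#'   fluorescence.
#' @return `k_q = K_sv / tau0` in M^-1 s^-1.
#' @examples
#' bimolecular_quenching_constant(3.32e3, 5.78e-9)  # 5.74e11
#' @export
bimolecular_quenching_constant <- function(K_sv_per_M, tau0_s = 5.78e-9) {
  if (!is.finite(tau0_s) || tau0_s <= 0)
    sb_stop("tau0 must be a positive lifetime in seconds", "sb_domain_error")
  K_sv_per_M / tau0_s
}

#' Classify the quenching mechanism
#'
#' Compares `k_q` against the diffusion-limited collisional reference
#' (2e10 M^-1 s^-1): `static` when `k_q` exceeds it, `dynamic` when below.
#' A relative tolerance band around the reference avoids a knife-edge call
#' on what is an order-of-magnitude criterion; values inside the band are
#' `indeterminate`.
#'
#' @param k_q_per_M_s Bimolecular quenching rate constant (>= 0).
#' @param k_ref_per_M_s Diffusion-limited reference (default 2e10).
#' @param tol Relative width of the indeterminate band (default 0.05).
#' @return `"static"`, `"dynamic"` or `"indeterminate"`.
#' @export
classify_quenching <- function(k_q_per_M_s, k_ref_per_M_s = 2e10,
                               tol = 0.05) {
  if (!is.finite(k_q_per_M_s) || k_q_per_M_s < 0)
    sb_stop("k_q must be finite and non-negative", "sb_domain_error")
  if (k_q_per_M_s > k_ref_per_M_s * (1 + tol)) "static"
  else if (k_q_per_M_s < k_ref_per_M_s * (1 - tol)) "dynamic"
  else "indeterminate"
}

#' Modified Stern-Volmer (double-log) fit
#'
#' Least-squares line of `log10((F0 - F)/F)` on `log10([Q])`; the slope is
#' the number of binding sites `n` and `10^intercept` is the binding
#' constant `K_b`. Points with `F >= F0` (no quenching) have no finite
#' transform and are excluded with a warning.
#'
#' @inheritParams stern_volmer_fit
#' @return A list with `K_b_per_M`, `n_sites`, `r2`, `n_points_used`.
#' @export
double_log_fit <- function(s, F0 = NULL) {
  F0 <- extract_F0(s, F0)
  usable <- s$conc_M > 0 & s$signal > 0 & s$signal < F0
  excluded <- s$conc_M > 0 & !usable
  if (any(excluded))
    sb_warn(sprintf(
      "excluding %d point(s) with F >= F0 from the double-log fit",
      sum(excluded)), "sb_points_excluded")
  if (sum(usable) < 3L)
    sb_stop(sprintf("double-log fit needs >= 3 usable points, got %d",
                    sum(usable)), "sb_insufficient_data_error")
  x <- log10(s$conc_M[usable])
  y <- log10((F0 - s$signal[usable]) / s$signal[usable])
  fit <- stats::lm(y ~ x)
  list(K_b_per_M = 10^unname(stats::coef(fit)[1L]),
       n_sites = unname(stats::coef(fit)[2L]),
       r2 = r_squared(fit),
       n_points_used = sum(usable))
}

#' Full quenching analysis of a fluorescence titration
#'
#' Runs [peak_intensity_series()], [stern_volmer_fit()],
#' [bimolecular_quenching_constant()], [classify_quenching()] and
#' [double_log_fit()].
#'
#' @param t A fluorescence [titration_set()].
#' @param tau0_s Unquenched fluorophore lifetime in seconds.
#' @param k_ref_per_M_s Diffusion-limited reference rate for the mechanism
#'   call.
#' @return An object of class `sb_quench_fit`.
#' @export
quench_fit <- function(t, tau0_s = 5.78e-9, k_ref_per_M_s = 2e10) {
  s <- peak_intensity_series(t)
  F0 <- extract_F0(s, NULL)
  sv <- stern_volmer_fit(s, F0)
  k_q <- bimolecular_quenching_constant(sv$K_sv_per_M, tau0_s)
  dl <- double_log_fit(s, F0)
  structure(list(
    F0 = F0,
    K_sv_per_M = sv$K_sv_per_M,
    sv_intercept = sv$intercept,
    tau0_s = tau0_s,
    k_q_per_M_s = k_q,
    k_ref_per_M_s = k_ref_per_M_s,
    mode = classify_quenching(max(k_q, 0), k_ref_per_M_s),
    K_b_per_M = dl$K_b_per_M,
    n_sites = dl$n_sites,
    r2_sv = sv$r2,
    r2_loglog = dl$r2,
    lambda_max_nm = attr(s, "lambda_max_nm")),
    class = "sb_quench_fit")
}

#' @export
print.sb_quench_fit <- function(x, ...) {
  cat("Fluorescence quenching fit\n")
  cat(sprintf("  F0                : %.4g (peak at %g nm)\n",
              x$F0, x$lambda_max_nm[1L]))
  cat(sprintf("  K_sv              : %.3g M^-1    (intercept %.4f, r2 = %.4f)\n",
              x$K_sv_per_M, x$sv_intercept, x$r2_sv))
  cat(sprintf("  k_q = K_sv/tau0   : %.3g M^-1 s^-1 (tau0 = %.3g s)\n",
              x$k_q_per_M_s, x$tau0_s))
  cat(sprintf("  mechanism         : %s (reference %.3g M^-1 s^-1)\n",
              x$mode, x$k_ref_per_M_s))
  cat(sprintf("  K_b (double-log)  : %.3g M^-1\n", x$K_b_per_M))
  cat(sprintf("  n sites           : %.3f         (r2 = %.4f)\n",
              x$n_sites, x$r2_loglog))
  invisible(x)
}
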