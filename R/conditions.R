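#' @keywords internal
sb_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message,
                      class = c(class, "specbind_error"),
                      call = call))
}

#' @keywords internal
sb_warn <- function(message, class = "specbind_warning") {
  warning(warningCondition(message, class = c(class, "specbind_warning")))
}

# Error taxonomy used throughout:
#   sb_format_error        malformed file / header
#   sb_shape_error         dimension mismatch in matrix input
#   sb_validation_error    invariant violation on a domain object
#   sb_range_error         requested wavelength outside the measured grid
#   sb_domain_error        argument outside the mathematical domain
#   sb_insufficient_data_error  fewer usable points than a regression needs
#   sb_nonphysical_fit_error    fit converged to a physically meaningless value

# coefficient of determination without summary.lm's perfect-fit warning
#' @keywords internal
r_squared <- function(fit) {
  r <- stats::residuals(fit)
  y <- stats::fitted(fit) + r
  ss <- sum((y - mean(y))^2)
  if (ss == 0) return(NaN)
  max(0, min(1, 1 - sum(r^2) / ss))
}
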