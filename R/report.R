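# End-to-end analysis report over a directory of inputs, plus the YAML
# configuration that makes every tolerance and physical default explicit and
# overridable.

#' Analysis configuration
#'
#' All analysis tolerances, thresholds and physical defaults in one place.
#' A YAML file with the same nesting overrides the defaults field by field.
#'
#' @param path Optional path to a YAML override file.
#' @return A nested list of class `sb_config`.
#' @export
sb_config <- function(path = NULL) {
  cfg <- list(
    uv = list(wavelength_nm = 280),
    quench = list(tau0_s = 5.78e-9, k_ref_per_M_s = 2e10, tol = 0.05),
    synchro = list(delta_lambda_nm = c(15, 60), shift_threshold_nm = 1.0),
    eem = list(min_prominence = 0.05, scatter_tol_nm = 10,
               second_order_tol_nm = 30),
    cd = list(wavelength_nm = 208))
  if (!is.null(path)) {
    if (!file.exists(path))
      sb_stop(sprintf("config file not found: %s", path), "sb_format_error")
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path), keep.null = TRUE)
  }
  structure(cfg, class = "sb_config")
}

#' Run the full analysis over a directory of inputs
#'
#' Recognised inputs (package CSV/JSON dialect): `uv.csv` (absorbance
#' titration), `quench.csv` (fluorescence titration), `eem_*.csv` (one or
#' more EEMs; when at least two carry a `ligand_conc` header, synchronous
#' shift analyses at each configured delta-lambda are added), `cd.csv`
#' (CD spectrum). `.json` twins of any of these are accepted. Missing inputs
#' leave their report section absent — only an empty directory warns.
#'
#' @param input_dir Directory containing the inputs.
#' @param config An [sb_config()].
#' @return An object of class `sb_report`: a list with `schema`, and
#'   sections `uv`, `quench`, `eem_peaks`, `synchronous`, `cd` (absent
#'   sections are `NULL`).
#' @export
run_all <- function(input_dir, config = sb_config()) {
  if (!dir.exists(input_dir))
    sb_stop(sprintf("input directory not found: %s", input_dir),
            "sb_format_error")
  find_input <- function(stem) {
    for (ext in c("csv", "json")) {
      p <- file.path(input_dir, paste0(stem, ".", ext))
      if (file.exists(p)) return(p)
    }
    NULL
  }
  report <- list(schema = "specbind-report/1", input_dir = input_dir,
                 uv = NULL, quench = NULL, eem_peaks = NULL,
                 synchronous = NULL, cd = NULL)

  p <- find_input("uv")
  if (!is.null(p)) {
    fit <- uv_binding_fit(read_titration(p),
                          wavelength_nm = config$uv$wavelength_nm)
    report$uv <- unclass(fit)
  }

  p <- find_input("quench")
  if (!is.null(p)) {
    fit <- quench_fit(read_titration(p), tau0_s = config$quench$tau0_s,
                      k_ref_per_M_s = config$quench$k_ref_per_M_s)
    report$quench <- unclass(fit)
  }

  eem_paths <- sort(list.files(input_dir,
                               pattern = "^eem_[0-9]+\\.(csv|json)$",
                               full.names = TRUE))
  if (length(eem_paths)) {
    eems <- lapply(eem_paths, read_eem)
    report$eem_peaks <- lapply(seq_along(eems), function(i) list(
      file = basename(eem_paths[i]),
      ligand_conc_M = eems[[i]]$ligand_conc_M,
      peaks = find_eem_peaks(eems[[i]],
                             min_prominence = config$eem$min_prominence,
                             scatter_tol_nm = config$eem$scatter_tol_nm,
                             second_order_tol_nm =
                               config$eem$second_order_tol_nm)))
    conc <- vapply(eems, function(e)
      if (is.null(e$ligand_conc_M)) NA_real_ else e$ligand_conc_M, 0)
    if (length(eems) >= 2L && !anyNA(conc) && any(conc == 0)) {
      report$synchronous <- lapply(config$synchro$delta_lambda_nm,
                                   function(dl) {
        sh <- shift_analysis(lapply(eems, synchronous_from_eem, dl),
                             threshold_nm =
                               config$synchro$shift_threshold_nm)
        unclass(sh)
      })
    }
  }

  p <- find_input("cd")
  if (!is.null(p)) {
    cd <- read_cd(p)
    hr <- cd_helix(cd, wavelength_nm = config$cd$wavelength_nm)
    report$cd <- c(list(protein_conc_M = cd$protein_conc_M,
                        n_residues = cd$n_residues,
                        path_length_cm = cd$path_length_cm),
                   unclass(hr))
  }

  if (is.null(report$uv) && is.null(report$quench) &&
      is.null(report$eem_peaks) && is.null(report$cd))
    sb_warn(sprintf("no recognized inputs in %s; all sections absent",
                    input_dir), "sb_empty_report")
  structure(report, class = "sb_report")
}

#' Write a report as JSON
#'
#' @param report An `sb_report` from [run_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", dataframe = "rows")
  invisible(path)
}

#' @export
print.sb_report <- function(x, ...) {
  cat("specbind report (", x$schema, ")\n", sep = "")
  if (!is.null(x$uv)) {
    cat("\nUV-vis binding (", x$uv$analysis_wavelength_nm, " nm)\n",
        sep = "")
    cat(sprintf("  %-6s %-12s %-12s %-8s %s\n",
                "T (K)", "K_d (M)", "K_a (M^-1)", "h", "dG0 (kcal/mol)"))
    cat(sprintf("  %-6g %-12.3g %-12.3g %-8.3f %.2f\n",
                x$uv$temperature_K, x$uv$K_d_M, x$uv$K_a_per_M,
                x$uv$hill_h, x$uv$delta_G0_kcal_per_mol))
  } else cat("\nUV-vis binding: absent\n")
  if (!is.null(x$quench)) {
    cat(sprintf(
      "\nQuenching: K_sv = %.3g M^-1, k_q = %.3g M^-1 s^-1 (%s), K_b = %.3g M^-1, n = %.3f\n",
      x$quench$K_sv_per_M, x$quench$k_q_per_M_s, x$quench$mode,
      x$quench$K_b_per_M, x$quench$n_sites))
  } else cat("\nQuenching: absent\n")
  if (!is.null(x$eem_peaks)) {
    cat("\nEEM peaks:\n")
    for (ep in x$eem_peaks)
      cat(sprintf("  %s: %d peak(s) [%s]\n", ep$file, nrow(ep$peaks),
                  paste(ep$peaks$peak_class, collapse = ", ")))
  } else cat("\nEEM peaks: absent\n")
  if (!is.null(x$synchronous)) {
    for (sh in x$synchronous)
      cat(sprintf(
        "Synchronous delta_lambda = %g nm: net shift %+.2f nm (%s)\n",
        sh$delta_lambda_nm, sh$net_shift_nm, sh$call))
  }
  if (!is.null(x$cd)) {
    cat(sprintf("\nCD: MRE208 = %.2f deg cm^2 dmol^-1, helix = %.2f %%\n",
                x$cd$mre_208, x$cd$helix_percent))
  } else cat("\nCD: absent\n")
  invisible(x)
}
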