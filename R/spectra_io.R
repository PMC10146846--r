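# On-disk dialect
# ---------------
# CSV files are UTF-8, comma-separated, with `#`-prefixed `key: value` header
# lines before the column header. Concentrations may be declared in M, mM,
# uM or nM via a `units` header key (default M) and are converted to mol/L on
# ingest; internally everything is mol/L and nm. Numbers are written with 17
# significant digits so a write/read roundtrip is exact.
#
#   titration CSV: `# protein_conc: 1e-05 M`, `# temperature: 298 K`,
#     `# signal: absorbance`, optional `# units: uM`; columns
#     `wavelength_nm` then one column per ligand concentration.
#   EEM CSV: optional `# ligand_conc:` header; first row = emission grid
#     (leading empty cell), first column = excitation grid, body = intensity.
#   CD CSV: `# protein_conc:`, `# n_residues:`, `# path_length: 0.1 cm`,
#     `# signal: cd_mdeg`; columns `wavelength_nm,ellipticity_mdeg`.
#
# JSON files mirror the in-memory field names exactly.

CONC_UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6,
                       nM = 1e-9)

#' @keywords internal
fmt_num <- function(x) sprintf("%.17g", x)

#' @keywords internal
conc_to_molar <- function(value, unit) {
  if (!unit %in% names(CONC_UNIT_FACTORS))
    sb_stop(sprintf("unknown concentration unit '%s'", unit),
            "sb_format_error")
  value * CONC_UNIT_FACTORS[[unit]]
}

#' @keywords internal
infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext
  else sb_stop(sprintf("cannot infer format from extension '.%s'", ext),
               "sb_format_error")
}

#' @keywords internal
read_lines_checked <- function(path) {
  if (!file.exists(path))
    sb_stop(sprintf("file not found: %s", path), "sb_format_error")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

# split `# key: value` header lines from the body
#' @keywords internal
split_header <- function(lines) {
  is_hdr <- grepl("^\\s*#", lines)
  body_start <- which(!is_hdr & nzchar(trimws(lines)))
  header <- list()
  for (ln in lines[is_hdr]) {
    ln <- sub("^\\s*#\\s*", "", ln)
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) header[[trimws(m[2L])]] <- trimws(m[3L])
  }
  list(header = header,
       body = if (length(body_start)) lines[min(body_start):length(lines)]
              else character(0))
}

# parse "1e-05 M" / "298 K" / "0.1 cm" -> list(value, unit)
#' @keywords internal
parse_quantity <- function(txt, field) {
  parts <- strsplit(trimws(txt), "\\s+")[[1L]]
  value <- suppressWarnings(as.numeric(parts[1L]))
  if (is.na(value))
    sb_stop(sprintf("header field '%s' is not numeric: '%s'", field, txt),
            "sb_format_error")
  list(value = value, unit = if (length(parts) > 1L) parts[2L] else NA)
}

#' @keywords internal
require_header <- function(header, key, path) {
  if (is.null(header[[key]]))
    sb_stop(sprintf("missing required header '# %s:' in %s", key, path),
            "sb_format_error")
  header[[key]]
}

#' @keywords internal
parse_csv_body <- function(body, path) {
  rows <- strsplit(body, ",", fixed = TRUE)
  n <- lengths(rows)
  if (length(unique(n)) != 1L)
    sb_stop(sprintf("ragged CSV body in %s: rows have %s fields", path,
                    paste(unique(n), collapse = "/")), "sb_shape_error")
  do.call(rbind, rows)
}

#' @keywords internal
as_num_matrix <- function(chr, path, what) {
  x <- suppressWarnings(matrix(as.numeric(chr), nrow = nrow(chr)))
  if (anyNA(x))
    sb_stop(sprintf("non-numeric %s in %s", what, path), "sb_format_error")
  x
}

# ---- titration ------------------------------------------------------------

#' Read a spectral titration set
#'
#' @param path Path to a `.csv` or `.json` file in the package dialect (see
#'   the methods vignette).
#' @param format `"csv"` or `"json"`; inferred from the extension when `NULL`.
#' @return An [titration_set()] object.
#' @export
read_titration <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("ligand_conc_M", "wavelength_nm", "intensity",
                "protein_conc_M", "temperature_K", "signal"))
      if (is.null(j[[f]]))
        sb_stop(sprintf("missing field '%s' in %s", f, path),
                "sb_format_error")
    inten <- j$intensity
    if (is.list(inten)) inten <- do.call(rbind, inten)
    inten <- as.matrix(inten)  # one row per concentration
    specs <- lapply(seq_len(nrow(inten)), function(i)
      spectrum(j$wavelength_nm, inten[i, ], j$signal))
    return(titration_set(j$ligand_conc_M, specs, j$protein_conc_M,
                         j$temperature_K))
  }
  lines <- read_lines_checked(path)
  parts <- split_header(lines)
  hdr <- parts$header
  pc <- parse_quantity(require_header(hdr, "protein_conc", path),
                       "protein_conc")
  protein_conc_M <- conc_to_molar(pc$value,
                                  if (is.na(pc$unit)) "M" else pc$unit)
  temperature_K <- parse_quantity(require_header(hdr, "temperature", path),
                                  "temperature")$value
  signal <- require_header(hdr, "signal", path)
  if (!signal %in% SIGNAL_KINDS)
    sb_stop(sprintf("unknown signal kind '%s' in %s", signal, path),
            "sb_format_error")
  units <- if (is.null(hdr$units)) "M" else hdr$units
  if (length(parts$body) < 2L)
    sb_stop(sprintf("no data rows in %s", path), "sb_format_error")
  cells <- parse_csv_body(parts$body, path)
  colnames_row <- cells[1L, ]
  if (trimws(colnames_row[1L]) != "wavelength_nm")
    sb_stop(sprintf("first column of %s must be 'wavelength_nm'", path),
            "sb_format_error")
  conc_raw <- suppressWarnings(as.numeric(colnames_row[-1L]))
  if (anyNA(conc_raw))
    sb_stop(sprintf(
      "titration column names in %s must be ligand concentrations", path),
      "sb_format_error")
  conc_M <- conc_to_molar(conc_raw, units)
  num <- as_num_matrix(cells[-1L, , drop = FALSE], path, "data value")
  specs <- lapply(seq_along(conc_M), function(i)
    spectrum(num[, 1L], num[, i + 1L], signal))
  titration_set(conc_M, specs, protein_conc_M, temperature_K)
}

#' Write a spectral titration set
#'
#' @param t An [titration_set()].
#' @inheritParams read_titration
#' @return `path`, invisibly.
#' @export
write_titration <- function(t, path, format = NULL) {
  format <- infer_format(path, format)
  validate_titration_set(t)
  if (format == "json") {
    inten <- t(vapply(t$spectra, function(s) s$intensity,
                      numeric(length(t$spectra[[1L]]$wavelength_nm))))
    obj <- list(protein_conc_M = t$protein_conc_M,
                temperature_K = t$temperature_K,
                signal = titration_signal_kind(t),
                ligand_conc_M = t$ligand_conc_M,
                wavelength_nm = t$spectra[[1L]]$wavelength_nm,
                intensity = inten)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
    return(invisible(path))
  }
  hdr <- c(sprintf("# protein_conc: %s M", fmt_num(t$protein_conc_M)),
           sprintf("# temperature: %s K", fmt_num(t$temperature_K)),
           sprintf("# signal: %s", titration_signal_kind(t)),
           "# units: M")
  cols <- c("wavelength_nm", fmt_num(t$ligand_conc_M))
  grid <- t$spectra[[1L]]$wavelength_nm
  body <- vapply(seq_along(grid), function(i)
    paste(c(fmt_num(grid[i]),
            vapply(t$spectra, function(s) fmt_num(s$intensity[i]), "")),
          collapse = ","), "")
  writeLines(c(hdr, paste(cols, collapse = ","), body), path,
             useBytes = TRUE)
  invisible(path)
}

# ---- EEM ------------------------------------------------------------------

#' Read an excitation-emission matrix
#'
#' @inheritParams read_titration
#' @return An [eem()] object.
#' @export
read_eem <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("excitation_nm", "emission_nm", "intensity"))
      if (is.null(j[[f]]))
        sb_stop(sprintf("missing field '%s' in %s", f, path),
                "sb_format_error")
    inten <- j$intensity
    if (is.list(inten)) inten <- do.call(rbind, inten)
    return(eem(j$excitation_nm, j$emission_nm, as.matrix(inten),
               ligand_conc_M = j$ligand_conc_M))
  }
  lines <- read_lines_checked(path)
  parts <- split_header(lines)
  conc <- NULL
  if (!is.null(parts$header$ligand_conc)) {
    q <- parse_quantity(parts$header$ligand_conc, "ligand_conc")
    conc <- conc_to_molar(q$value, if (is.na(q$unit)) "M" else q$unit)
  }
  if (length(parts$body) < 2L)
    sb_stop(sprintf("no data rows in %s", path), "sb_format_error")
  cells <- parse_csv_body(parts$body, path)
  emission <- as_num_matrix(cells[1L, -1L, drop = FALSE], path,
                            "emission grid")
  excitation <- as_num_matrix(cells[-1L, 1L, drop = FALSE], path,
                              "excitation grid")
  inten <- as_num_matrix(cells[-1L, -1L, drop = FALSE], path, "intensity")
  eem(as.numeric(excitation), as.numeric(emission), inten,
      ligand_conc_M = conc)
}

#' Write an excitation-emission matrix
#'
#' @param e An [eem()].
#' @inheritParams read_titration
#' @return `path`, invisibly.
#' @export
write_eem <- function(e, path, format = NULL) {
  format <- infer_format(path, format)
  validate_eem(e)
  if (format == "json") {
    obj <- list(excitation_nm = e$excitation_nm, emission_nm = e$emission_nm,
                intensity = e$intensity)
    if (!is.null(e$ligand_conc_M)) obj$ligand_conc_M <- e$ligand_conc_M
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
    return(invisible(path))
  }
  hdr <- if (!is.null(e$ligand_conc_M))
    sprintf("# ligand_conc: %s M", fmt_num(e$ligand_conc_M)) else character(0)
  first <- paste(c("", fmt_num(e$emission_nm)), collapse = ",")
  body <- vapply(seq_along(e$excitation_nm), function(i)
    paste(c(fmt_num(e$excitation_nm[i]), fmt_num(e$intensity[i, ])),
          collapse = ","), "")
  writeLines(c(hdr, first, body), path, useBytes = TRUE)
  invisible(path)
}

# ---- CD -------------------------------------------------------------------

#' Read a circular-dichroism spectrum
#'
#' @inheritParams read_titration
#' @return An [cd_spectrum()] object.
#' @export
read_cd <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("wavelength_nm", "ellipticity_mdeg", "protein_conc_M",
                "n_residues", "path_length_cm"))
      if (is.null(j[[f]]))
        sb_stop(sprintf("missing field '%s' in %s", f, path),
                "sb_format_error")
    return(cd_spectrum(spectrum(j$wavelength_nm, j$ellipticity_mdeg,
                                "cd_mdeg"),
                       j$protein_conc_M, j$n_residues, j$path_length_cm))
  }
  lines <- read_lines_checked(path)
  parts <- split_header(lines)
  hdr <- parts$header
  pc <- parse_quantity(require_header(hdr, "protein_conc", path),
                       "protein_conc")
  protein_conc_M <- conc_to_molar(pc$value,
                                  if (is.na(pc$unit)) "M" else pc$unit)
  n_residues <- parse_quantity(require_header(hdr, "n_residues", path),
                               "n_residues")$value
  path_length_cm <- parse_quantity(require_header(hdr, "path_length", path),
                                   "path_length")$value
  if (length(parts$body) < 2L)
    sb_stop(sprintf("no data rows in %s", path), "sb_format_error")
  cells <- parse_csv_body(parts$body, path)
  if (!identical(trimws(cells[1L, ]), c("wavelength_nm",
                                        "ellipticity_mdeg")))
    sb_stop(sprintf(
      "CD CSV %s must have columns wavelength_nm,ellipticity_mdeg", path),
      "sb_format_error")
  num <- as_num_matrix(cells[-1L, , drop = FALSE], path, "data value")
  cd_spectrum(spectrum(num[, 1L], num[, 2L], "cd_mdeg"),
              protein_conc_M, n_residues, path_length_cm)
}

#' Write a circular-dichroism spectrum
#'
#' @param c An [cd_spectrum()].
#' @inheritParams read_titration
#' @return `path`, invisibly.
#' @export
write_cd <- function(c, path, format = NULL) {
  format <- infer_format(path, format)
  validate_cd_spectrum(c)
  if (format == "json") {
    obj <- list(protein_conc_M = c$protein_conc_M,
                n_residues = c$n_residues,
                path_length_cm = c$path_length_cm,
                wavelength_nm = c$spectrum$wavelength_nm,
                ellipticity_mdeg = c$spectrum$intensity)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
    return(invisible(path))
  }
  hdr <- c(sprintf("# protein_conc: %s M", fmt_num(c$protein_conc_M)),
           sprintf("# n_residues: %s", fmt_num(c$n_residues)),
           sprintf("# path_length: %s cm", fmt_num(c$path_length_cm)),
           "# signal: cd_mdeg")
  body <- paste(fmt_num(c$spectrum$wavelength_nm),
                fmt_num(c$spectrum$intensity), sep = ",")
  writeLines(c(hdr, "wavelength_nm,ellipticity_mdeg", body), path,
             useBytes = TRUE)
  invisible(path)
}

# ---- single spectrum ------------------------------------------------------

#' Read a single spectrum
#'
#' @inheritParams read_titration
#' @return An [spectrum()] object.
#' @export
read_spectrum <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("wavelength_nm", "intensity", "signal"))
      if (is.null(j[[f]]))
        sb_stop(sprintf("missing field '%s' in %s", f, path),
                "sb_format_error")
    return(spectrum(j$wavelength_nm, j$intensity, j$signal))
  }
  lines <- read_lines_checked(path)
  parts <- split_header(lines)
  signal <- require_header(parts$header, "signal", path)
  cells <- parse_csv_body(parts$body, path)
  num <- as_num_matrix(cells[-1L, , drop = FALSE], path, "data value")
  spectrum(num[, 1L], num[, 2L], signal)
}

#' Write a single spectrum
#'
#' @param s An [spectrum()].
#' @inheritParams read_titration
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = NULL) {
  format <- infer_format(path, format)
  validate_spectrum(s)
  if (format == "json") {
    jsonlite::write_json(list(signal = s$signal_kind,
                              wavelength_nm = s$wavelength_nm,
                              intensity = s$intensity),
                         path, auto_unbox = TRUE, digits = I(17))
    return(invisible(path))
  }
  writeLines(c(sprintf("# signal: %s", s$signal_kind),
               "wavelength_nm,intensity",
               paste(fmt_num(s$wavelength_nm), fmt_num(s$intensity),
                     sep = ",")), path, useBytes = TRUE)
  invisible(path)
}
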