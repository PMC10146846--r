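# Seeded synthetic instrument data with ground-truth manifests.
#
# The generators emulate the study conditions of the analysis pipeline:
# 10 uM protein titrated with ligand over 0-30 uM (UV absorbance, aromatic
# band at 280 nm, hyperchromic 1:1/Hill isotherm), 0-60 uM (fluorescence
# quenching of a 341 nm tryptophan emission band), EEMs on 200-400 /
# 200-550 nm grids with two fluorophore bands plus Rayleigh (em = ex) and
# second-order (em ~ 2 ex) scatter ridges, and far-UV CD spectra (190-260
# nm, double negative band at 208/222 nm) parameterised by helix fraction.
# Noise is additive Gaussian per signal channel; every dataset carries a
# truth manifest (attribute "truth", see [sim_truth()]) so estimators are
# tested by parameter recovery.

#' @keywords internal
gaussf <- function(x, mu, sd) exp(-((x - mu) / sd)^2 / 2)

# evaluate code under a fixed seed without disturbing the global RNG stream
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Builds the configuration consumed by the `simulate_*` generators. Nested
#' lists passed as arguments override the matching defaults field by field
#' (unnamed fields keep their defaults), so
#' `sim_config(binding = list(hill_h = 2))` changes only the Hill exponent.
#'
#' Default parameter values are the study conditions the analysis targets:
#' `K_d = 5.18e-6` M, `dA_inf = 0.30` AU, `h = 1`, `K_sv = 3.32e3` M^-1,
#' `F0 = 1000` counts with a 341 nm emission band, Table-2-like EEM bands at
#' (280, 340) and (230, 340) with Rayleigh/second-order ridges, and 31.97 %
#' helix CD at 7 uM protein. Per-channel noise defaults are 1 % of the
#' saturation signal (0.003 AU, 10 counts), 200 counts for the EEM and
#' 0.05 mdeg for CD.
#'
#' @param seed Integer RNG seed; fixes every stochastic output bit-for-bit.
#' @param ... Named overrides: `protein_conc_M`, `temperature_K`, and/or the
#'   nested lists `binding`, `quenching`, `eem`, `cd`.
#' @return An object of class `sb_sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = 1L,
    protein_conc_M = 1e-5,
    temperature_K = 298,
    binding = list(
      K_d_M = 5.18e-6, delta_A_inf = 0.30, hill_h = 1,
      baseline_A280 = 0.20, sigma = 0.003,
      conc_M = seq(0, 30e-6, by = 2e-6),
      wavelength_nm = seq(200, 325, by = 1),
      analysis_wavelength_nm = 280, band_width_nm = 14),
    quenching = list(
      F0 = 1000, K_sv_per_M = 3.32e3, K_b_per_M = NULL, n_sites = NULL,
      sigma = 10,
      conc_M = seq(0, 60e-6, by = 5e-6),
      emission_nm = seq(290, 450, by = 1),
      emission_peak_nm = 341, band_width_nm = 25),
    eem = list(
      excitation_nm = seq(200, 400, by = 5),
      emission_nm = seq(200, 550, by = 5),
      bands = list(
        list(centre_ex = 280, centre_em = 340, width_ex = 15,
             width_em = 20, amplitude = 9.7e4),
        list(centre_ex = 230, centre_em = 340, width_ex = 12,
             width_em = 20, amplitude = 3.6e4)),
      rayleigh_amplitude = 2.45e5, rayleigh_width_nm = 4,
      second_order_amplitude = 2.0e4, second_order_width_nm = 25,
      source_centre_nm = 280, source_width_nm = 25,
      sigma = 200,
      conc_M = c(0, 1e-5, 2e-5), centre_shift_nm = 0),
    cd = list(
      helix_percent = 31.97, C_p = 7e-6, n_residues = 130,
      path_length_cm = 0.1,
      wavelength_nm = seq(190, 260, by = 1), sigma = 0.05))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    sb_stop(sprintf("unknown sim_config field(s): %s",
                    paste(bad, collapse = ", ")), "sb_validation_error")
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  # modifyList merges by name, which silently skips unnamed lists: the EEM
  # band list must replace the default wholesale
  if (!is.null(over$eem) && "bands" %in% names(over$eem))
    cfg$eem$bands <- over$eem$bands
  cfg$seed <- as.integer(seed)
  for (f in c("K_d_M", "delta_A_inf"))
    if (!is.finite(cfg$binding[[f]]) || cfg$binding[[f]] <= 0)
      sb_stop(sprintf("binding$%s must be positive", f),
              "sb_validation_error")
  if (cfg$quenching$F0 <= 0)
    sb_stop("quenching$F0 must be positive", "sb_validation_error")
  if (cfg$cd$helix_percent < 0 || cfg$cd$helix_percent > 100)
    sb_stop("cd$helix_percent must lie in [0, 100]", "sb_validation_error")
  for (blk in c("binding", "quenching", "eem", "cd"))
    if (cfg[[blk]]$sigma < 0)
      sb_stop(sprintf("%s$sigma must be >= 0", blk), "sb_validation_error")
  structure(cfg, class = "sb_sim_config")
}

#' Ground-truth manifest of a simulated dataset
#'
#' @param x Any object returned by a `simulate_*` generator.
#' @return The truth manifest (a named list) recorded at generation time.
#' @export
sim_truth <- function(x) attr(x, "truth")

#' Simulate a UV-vis absorbance titration
#'
#' Absorbance spectra whose 280 nm difference series follows the Hill
#' isotherm `dA = dA_inf * K_a [S]^h / (1 + K_a [S]^h)` (the 1:1 hyperbola
#' when `h = 1`) on top of a fixed aromatic-band baseline, plus N(0, sigma)
#' noise per point.
#'
#' @param cfg An [sim_config()].
#' @return An absorbance [titration_set()] with a truth manifest.
#' @export
simulate_uv_titration <- function(cfg) {
  b <- cfg$binding
  wl <- b$wavelength_nm
  conc <- b$conc_M
  K_a <- 1 / b$K_d_M
  x <- K_a * conc^b$hill_h
  dA <- b$delta_A_inf * x / (1 + x)
  dA[conc == 0] <- 0
  band <- gaussf(wl, b$analysis_wavelength_nm, b$band_width_nm)
  baseline <- b$baseline_A280 * band + 1.2 * gaussf(wl, 220, 10)
  specs <- with_seed(cfg$seed, lapply(seq_along(conc), function(i)
    spectrum(wl, baseline + dA[i] * band +
                 stats::rnorm(length(wl), 0, b$sigma), "absorbance")))
  out <- titration_set(conc, specs, cfg$protein_conc_M, cfg$temperature_K)
  attr(out, "truth") <- list(
    model = "hill_isotherm", K_d_M = b$K_d_M, K_a_per_M = K_a,
    delta_A_inf = b$delta_A_inf, hill_h = b$hill_h,
    analysis_wavelength_nm = b$analysis_wavelength_nm,
    sigma = b$sigma, delta_A = dA, ligand_conc_M = conc)
  out
}

#' Simulate a fluorescence-quenching titration
#'
#' A Gaussian emission band (centre 341 nm) whose peak intensity follows
#' `F = F0 / (1 + K_sv [Q])` (Stern-Volmer), or the power model
#' `(F0 - F)/F = K_b [Q]^n` when `quenching$K_b_per_M` and
#' `quenching$n_sites` are set, plus N(0, sigma) noise per point.
#'
#' @param cfg An [sim_config()].
#' @return A fluorescence [titration_set()] with a truth manifest.
#' @export
simulate_quenching <- function(cfg) {
  q <- cfg$quenching
  wl <- q$emission_nm
  conc <- q$conc_M
  power <- !is.null(q$K_b_per_M) && !is.null(q$n_sites)
  f <- if (power) q$F0 / (1 + q$K_b_per_M * conc^q$n_sites)
       else q$F0 / (1 + q$K_sv_per_M * conc)
  f[conc == 0] <- q$F0
  band <- gaussf(wl, q$emission_peak_nm, q$band_width_nm)
  specs <- with_seed(cfg$seed, lapply(seq_along(conc), function(i)
    spectrum(wl, f[i] * band + stats::rnorm(length(wl), 0, q$sigma),
             "fluorescence")))
  out <- titration_set(conc, specs, cfg$protein_conc_M, cfg$temperature_K)
  attr(out, "truth") <- list(
    model = if (power) "power" else "stern_volmer",
    F0 = q$F0, K_sv_per_M = if (power) NULL else q$K_sv_per_M,
    K_b_per_M = q$K_b_per_M, n_sites = q$n_sites,
    emission_peak_nm = q$emission_peak_nm, sigma = q$sigma,
    F = f, ligand_conc_M = conc)
  out
}

#' @keywords internal
eem_field <- function(ec, centre_shift_nm = 0) {
  ex <- ec$excitation_nm
  em <- ec$emission_nm
  z <- matrix(0, length(ex), length(em))
  # the shift translates each band along both axes, emulating a
  # microenvironment polarity change that moves the whole band
  for (b in ec$bands)
    z <- z + b$amplitude *
      outer(gaussf(ex, b$centre_ex + centre_shift_nm, b$width_ex),
            gaussf(em, b$centre_em + centre_shift_nm, b$width_em))
  src <- gaussf(ex, ec$source_centre_nm, ec$source_width_nm)
  z <- z + ec$rayleigh_amplitude *
    src * t(vapply(ex, function(x)
      gaussf(em - x, 0, ec$rayleigh_width_nm), numeric(length(em))))
  z + ec$second_order_amplitude *
    src * t(vapply(ex, function(x)
      gaussf(em - 2 * x, 0, ec$second_order_width_nm),
      numeric(length(em))))
}

#' Simulate an excitation-emission matrix
#'
#' Sum of Gaussian fluorophore bands, a Rayleigh ridge along `em = ex`
#' and a second-order ridge along `em = 2 ex` (both amplitude-modulated by a
#' Gaussian source profile over excitation), plus N(0, sigma) noise clamped
#' at zero.
#'
#' @param cfg An [sim_config()].
#' @param ligand_conc_M Ligand concentration recorded in the EEM metadata;
#'   together with `eem$centre_shift_nm` it translates the fluorophore bands
#'   (both centres) linearly in concentration, for titrated EEM series.
#' @return An [eem()] with a truth manifest.
#' @export
simulate_eem <- function(cfg, ligand_conc_M = 0) {
  ec <- cfg$eem
  max_conc <- max(ec$conc_M)
  shift <- if (max_conc > 0) ec$centre_shift_nm * ligand_conc_M / max_conc
           else 0
  z <- eem_field(ec, centre_shift_nm = shift)
  z <- with_seed(cfg$seed + round(ligand_conc_M * 1e6), pmax(
    z + matrix(stats::rnorm(length(z), 0, ec$sigma), nrow(z)), 0))
  out <- eem(ec$excitation_nm, ec$emission_nm, z,
             ligand_conc_M = ligand_conc_M)
  attr(out, "truth") <- list(
    bands = lapply(ec$bands, function(b) {
      b$centre_ex <- b$centre_ex + shift
      b$centre_em <- b$centre_em + shift
      b
    }),
    rayleigh_amplitude = ec$rayleigh_amplitude,
    second_order_amplitude = ec$second_order_amplitude,
    source_centre_nm = ec$source_centre_nm,
    centre_shift_nm = shift, sigma = ec$sigma,
    expected_classes = c("rayleigh", "second_order",
                         rep("fluorophore", length(ec$bands))))
  out
}

#' Simulate a titrated EEM series
#'
#' One EEM per concentration in `eem$conc_M`, with the fluorophore bands
#' translated linearly up to `eem$centre_shift_nm` at the highest
#' concentration (a red shift when positive).
#'
#' @param cfg An [sim_config()].
#' @return A list of [eem()] objects.
#' @export
simulate_eem_series <- function(cfg) {
  lapply(cfg$eem$conc_M, function(conc) simulate_eem(cfg, conc))
}

#' Simulate a far-UV CD spectrum
#'
#' Builds the double-negative-band (208/222 nm) helix spectrum whose mean
#' residue ellipticity at 208 nm equals the inverse two-point formula value
#' `MRE208 = -(helix/100 * 29000 + 4000)`, converts it to observed
#' millidegrees via the MRE definition, and adds N(0, sigma) mdeg noise.
#'
#' @param cfg An [sim_config()].
#' @return An [cd_spectrum()] with a truth manifest.
#' @export
simulate_cd <- function(cfg) {
  cc <- cfg$cd
  wl <- cc$wavelength_nm
  mre_208 <- -(cc$helix_percent / 100 * (MRE_HELIX_208 - MRE_COIL_208) +
                 MRE_COIL_208)
  shape <- gaussf(wl, 208, 7) + 0.9 * gaussf(wl, 222, 8)
  shape_208 <- gaussf(208, 208, 7) + 0.9 * gaussf(208, 222, 8)
  mre <- mre_208 * shape / shape_208
  theta <- mre * (cc$C_p * cc$n_residues * cc$path_length_cm * 10)
  theta <- with_seed(cfg$seed,
                     theta + stats::rnorm(length(wl), 0, cc$sigma))
  out <- cd_spectrum(spectrum(wl, theta, "cd_mdeg"),
                     cc$C_p, cc$n_residues, cc$path_length_cm)
  attr(out, "truth") <- list(
    helix_percent = cc$helix_percent, mre_208 = mre_208,
    C_p = cc$C_p, n_residues = cc$n_residues,
    path_length_cm = cc$path_length_cm, sigma = cc$sigma)
  out
}

#' Write a full synthetic dataset to disk
#'
#' Generates the UV titration, quenching titration, EEM series and CD
#' spectrum from one configuration and writes them in the package CSV
#' dialect, each with its truth manifest as a JSON file alongside
#' (`<name>_truth.json`).
#'
#' @param cfg An [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the data files written, invisibly.
#' @export
write_simulation <- function(cfg, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    writer(obj, path)
    jsonlite::write_json(sim_truth(obj),
                         file.path(out_dir, paste0(name, "_truth.json")),
                         auto_unbox = TRUE, digits = I(17), null = "null")
    written <<- c(written, path)
  }
  emit(simulate_uv_titration(cfg), "uv", write_titration)
  emit(simulate_quenching(cfg), "quench", write_titration)
  eems <- simulate_eem_series(cfg)
  for (i in seq_along(eems))
    emit(eems[[i]], sprintf("eem_%02d", i), write_eem)
  emit(simulate_cd(cfg), "cd", write_cd)
  invisible(written)
}
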