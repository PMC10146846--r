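# In-code fixtures shared across test files. Expected values are computed
# with the generating equations written out here, independently of the
# package's fitting code.

# absorbance titration whose 280 nm difference follows the 1:1 hyperbola
# dA = dA_inf * S / (K_d + S) on a flat baseline
make_uv_titration <- function(conc_M = seq(0, 30e-6, by = 2e-6),
                              K_d = 5.18e-6, dA_inf = 0.30, A0 = 0.20,
                              wl = seq(270, 290, by = 1)) {
  specs <- lapply(conc_M, function(s) {
    dA <- if (s == 0) 0 else dA_inf * s / (K_d + s)
    spectrum(wl, rep(A0 + dA, length(wl)), "absorbance")
  })
  titration_set(conc_M, specs, protein_conc_M = 1e-5, temperature_K = 298)
}

# fluorescence titration with F = F0 / (1 + K_sv Q) peaked at 341 nm
make_quench_titration <- function(conc_M = seq(0, 60e-6, by = 5e-6),
                                  F0 = 1000, K_sv = 3320,
                                  wl = seq(290, 450, by = 1)) {
  band <- exp(-((wl - 341) / 25)^2 / 2)
  specs <- lapply(conc_M, function(q)
    spectrum(wl, (F0 / (1 + K_sv * q)) * band, "fluorescence"))
  titration_set(conc_M, specs, protein_conc_M = 1e-5, temperature_K = 298)
}

# EEM holding a single separable Gaussian band
make_band_eem <- function(centre_ex = 280, centre_em = 340, width_ex = 15,
                          width_em = 20, amplitude = 1000,
                          ex = seq(200, 400, by = 5),
                          em = seq(200, 550, by = 5), conc = NULL) {
  z <- amplitude * outer(exp(-((ex - centre_ex) / width_ex)^2 / 2),
                         exp(-((em - centre_em) / width_em)^2 / 2))
  eem(ex, em, z, ligand_conc_M = conc)
}

expect_sb_error <- function(expr, class) {
  expect_error(expr, class = class)
}
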