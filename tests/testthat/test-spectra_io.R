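test_that("spectrum constructor enforces its invariants", {
  s <- spectrum(c(278, 280, 282), c(0.19, 0.20, 0.19), "absorbance")
  expect_s3_class(s, "sb_spectrum")
  expect_sb_error(spectrum(c(280, 278), c(1, 2), "absorbance"),
                  "sb_validation_error")        # not increasing
  expect_sb_error(spectrum(c(278, 280), c(1, NA), "absorbance"),
                  "sb_validation_error")        # non-finite intensity
  expect_sb_error(spectrum(c(278, 280), c(1, Inf), "absorbance"),
                  "sb_validation_error")
  expect_sb_error(spectrum(c(278, 280), 1, "absorbance"),
                  "sb_validation_error")        # length mismatch
  expect_error(spectrum(c(278, 280), c(1, 2), "volts"))
})

test_that("titration set enforces ordering and the zero reference", {
  mk <- function(conc) {
    specs <- lapply(conc, function(i)
      spectrum(c(278, 280, 282), c(0.1, 0.2, 0.1), "absorbance"))
    titration_set(conc, specs, 1e-5)
  }
  expect_s3_class(mk(c(0, 1e-5)), "sb_titration")
  expect_sb_error(mk(c(1e-5, 0)), "sb_validation_error")   # wrong order
  expect_sb_error(mk(c(1e-5, 2e-5)), "sb_validation_error") # no zero ref
  expect_sb_error(mk(c(0, 1e-5, 1e-5)), "sb_validation_error") # duplicate
  expect_sb_error(mk(c(0, -1e-5)), "sb_validation_error")
})

test_that("titration CSV reading parses header, units and body", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# protein_conc: 10 uM",
               "# temperature: 298 K",
               "# signal: absorbance",
               "# units: uM",
               "wavelength_nm,0,10",
               "278,0.19,0.22",
               "280,0.20,0.25",
               "282,0.19,0.23"), path)
  t <- read_titration(path)
  expect_length(t$spectra, 2L)
  expect_equal(t$ligand_conc_M, c(0, 1e-5))
  expect_equal(t$protein_conc_M, 1e-5)
  expect_equal(t$temperature_K, 298)
  expect_equal(titration_signal_kind(t), "absorbance")
  expect_equal(t$spectra[[2]]$intensity, c(0.22, 0.25, 0.23))
})

test_that("titration CSV with out-of-order concentrations is rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# protein_conc: 1e-5 M",
               "# temperature: 298 K",
               "# signal: absorbance",
               "# units: uM",
               "wavelength_nm,10,0",
               "278,0.22,0.19",
               "280,0.25,0.20"), path)
  expect_sb_error(read_titration(path), "sb_validation_error")
})

test_that("missing required header is a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# temperature: 298 K",
               "# signal: absorbance",
               "wavelength_nm,0,1e-5",
               "280,0.2,0.25"), path)
  expect_sb_error(read_titration(path), "sb_format_error")
})

test_that("titration roundtrips bit-for-bit through CSV and JSON", {
  set.seed(42)
  wl <- seq(200, 325, by = 1)
  conc <- c(0, sort(runif(5, 1e-6, 3e-5)))
  specs <- lapply(conc, function(i)
    spectrum(wl, runif(length(wl), 0, 2), "absorbance"))
  t <- titration_set(conc, specs, protein_conc_M = 1.37e-5,
                     temperature_K = 298.15)
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_titration(t, path)
    t2 <- read_titration(path)
    expect_identical(t2$ligand_conc_M, t$ligand_conc_M)
    expect_identical(t2$protein_conc_M, t$protein_conc_M)
    expect_identical(t2$temperature_K, t$temperature_K)
    for (i in seq_along(conc)) {
      expect_identical(t2$spectra[[i]]$wavelength_nm,
                       t$spectra[[i]]$wavelength_nm)
      expect_identical(t2$spectra[[i]]$intensity, t$spectra[[i]]$intensity)
    }
  }
})

test_that("EEM reading, shape validation and roundtrip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",300,310", "250,1,2", "260,3,4"), path)
  e <- read_eem(path)
  expect_equal(e$excitation_nm, c(250, 260))
  expect_equal(e$emission_nm, c(300, 310))
  expect_equal(e$intensity, matrix(c(1, 3, 2, 4), 2))

  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",300,310", "250,1,2", "260,3"), ragged)
  expect_sb_error(read_eem(ragged), "sb_shape_error")

  expect_sb_error(eem(c(250, 260), c(300, 310), matrix(1, 3, 2)),
                  "sb_shape_error")
  expect_sb_error(eem(c(250, 260), c(300, 310), matrix(-1, 2, 2)),
                  "sb_validation_error")

  set.seed(7)
  big <- eem(seq(200, 400, 10), seq(200, 550, 10),
             matrix(runif(21 * 36, 0, 1e5), 21), ligand_conc_M = 2e-5)
  for (ext in c(".csv", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_eem(big, p)
    b2 <- read_eem(p)
    expect_identical(b2$excitation_nm, big$excitation_nm)
    expect_identical(b2$emission_nm, big$emission_nm)
    expect_identical(b2$intensity, big$intensity)
    expect_identical(b2$ligand_conc_M, big$ligand_conc_M)
  }
})

test_that("CD spectra roundtrip with metadata and validate", {
  set.seed(11)
  wl <- seq(190, 260, by = 1)
  cd <- cd_spectrum(spectrum(wl, rnorm(length(wl), -8, 3), "cd_mdeg"),
                    protein_conc_M = 7e-6, n_residues = 130,
                    path_length_cm = 0.1)
  for (ext in c(".csv", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_cd(cd, p)
    c2 <- read_cd(p)
    expect_identical(c2$spectrum$intensity, cd$spectrum$intensity)
    expect_identical(c2$protein_conc_M, cd$protein_conc_M)
    expect_identical(c2$n_residues, cd$n_residues)
    expect_identical(c2$path_length_cm, cd$path_length_cm)
  }
  expect_sb_error(cd_spectrum(spectrum(wl, rep(1, length(wl)), "cd_mdeg"),
                              protein_conc_M = 0), "sb_domain_error")
  expect_sb_error(cd_spectrum(spectrum(wl, rep(1, length(wl)), "cd_mdeg"),
                              7e-6, n_residues = 0), "sb_domain_error")
  expect_sb_error(cd_spectrum(spectrum(wl, rep(1, length(wl)), "absorbance"),
                              7e-6), "sb_validation_error")
})

test_that("single spectra roundtrip through both formats", {
  s <- spectrum(c(278, 280, 282), c(0.191234567891234, 0.2, 1 / 3),
                "fluorescence")
  for (ext in c(".csv", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_spectrum(s, p)
    s2 <- read_spectrum(p)
    expect_identical(s2$wavelength_nm, s$wavelength_nm)
    expect_identical(s2$intensity, s$intensity)
    expect_identical(s2$signal_kind, s$signal_kind)
  }
})

test_that("intensity_at interpolates linearly and rejects out-of-range", {
  s <- spectrum(c(278, 280, 282), c(0.1, 0.2, 0.4), "absorbance")
  expect_equal(intensity_at(s, 280), 0.2)
  expect_equal(intensity_at(s, 279), 0.15)   # midpoint of 0.1 and 0.2
  expect_sb_error(intensity_at(s, 277), "sb_range_error")
  expect_sb_error(intensity_at(s, 283), "sb_range_error")
})
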