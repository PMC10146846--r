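test_that("synchronous spectrum from a single Gaussian band peaks at the band", {
  # separable band centred (280, 340): along em = ex + 60 the product of the
  # two Gaussians is maximised at the precision-weighted mean of 280 and
  # (340 - 60) = 280, i.e. exactly at ex = 280
  e <- make_band_eem(280, 340, ex = seq(200, 400, 1), em = seq(200, 550, 1))
  sync <- synchronous_from_eem(e, 60)
  expect_equal(sync$lambda_max_nm, 280)
  expect_equal(sync$delta_lambda_nm, 60)
  # sampled values equal the analytic band along the offset diagonal
  analytic <- 1000 * exp(-((sync$excitation_nm - 280) / 15)^2 / 2) *
    exp(-((sync$excitation_nm + 60 - 340) / 20)^2 / 2)
  expect_equal(sync$intensity, analytic, tolerance = 1e-12)
})

test_that("delta_lambda = 0 samples the Rayleigh diagonal", {
  ex <- seq(300, 320, 5)
  z <- matrix(seq_len(25), 5, 5)
  e <- eem(ex, ex, z)
  sync <- synchronous_from_eem(e, 0)
  expect_equal(sync$intensity, diag(z))
})

test_that("uniform and off-grid synchronous cases behave per the tie rules", {
  e <- eem(seq(200, 300, 10), seq(200, 400, 10), matrix(5, 11, 21))
  sync <- synchronous_from_eem(e, 15)
  expect_true(all(sync$intensity == 5))
  expect_equal(sync$lambda_max_nm, sync$excitation_nm[1])  # lowest wavelength

  # offset pushing every point off the emission grid
  expect_sb_error(synchronous_from_eem(e, 500), "sb_range_error")
  expect_sb_error(synchronous_from_eem(e, -5), "sb_domain_error")
})

test_that("synchronous extraction commutes with intensity scaling", {
  e <- make_band_eem(260, 330)
  scaled <- eem(e$excitation_nm, e$emission_nm, 3.7 * e$intensity)
  s1 <- synchronous_from_eem(e, 15)
  s2 <- synchronous_from_eem(scaled, 15)
  expect_equal(s2$intensity, 3.7 * s1$intensity, tolerance = 1e-12)
  expect_equal(s2$lambda_max_nm, s1$lambda_max_nm)
})

test_that("shift analysis calls red, blue and negligible correctly", {
  mk <- function(centre, conc) {
    e <- make_band_eem(centre, centre + 60, ex = seq(200, 400, 1),
                       em = seq(200, 550, 1), conc = conc)
    synchronous_from_eem(e, 60)
  }
  # identical spectra at all concentrations: net 0, negligible
  same <- shift_analysis(list(mk(280, 0), mk(280, 3e-5), mk(280, 6e-5)))
  expect_equal(same$net_shift_nm, 0)
  expect_identical(same$call, "negligible")

  # band translated +2 nm over the titration: net +2, red
  red <- shift_analysis(list(mk(280, 0), mk(281, 3e-5), mk(282, 6e-5)))
  expect_equal(red$net_shift_nm, 2)
  expect_identical(red$call, "red")

  blue <- shift_analysis(list(mk(280, 0), mk(277, 6e-5)))
  expect_equal(blue$net_shift_nm, -3)
  expect_identical(blue$call, "blue")

  # shifts within the 1 nm threshold stay negligible
  tiny <- shift_analysis(list(mk(280, 0), mk(281, 6e-5)))
  expect_identical(tiny$call, "negligible")

  # mismatched delta_lambda is a validation error
  e0 <- make_band_eem(280, 340, conc = 0)
  e1 <- make_band_eem(280, 340, conc = 6e-5)
  expect_sb_error(
    shift_analysis(list(synchronous_from_eem(e0, 15),
                        synchronous_from_eem(e1, 60))),
    "sb_validation_error")
  # fewer than two concentrations / missing zero
  expect_sb_error(shift_analysis(list(mk(280, 1e-5), mk(281, 2e-5))),
                  "sb_validation_error")
})

test_that("generator-truth shift is recovered through the full pipeline", {
  # 1 nm grids so lambda_max does not snap to 5 nm steps
  cfg <- sim_config(seed = 3, eem = list(
    centre_shift_nm = 2, sigma = 0,
    excitation_nm = seq(200, 400, 1), emission_nm = seq(200, 550, 1)))
  specs <- lapply(simulate_eem_series(cfg), synchronous_from_eem, 15)
  rep <- shift_analysis(specs)
  expect_equal(rep$net_shift_nm, 2, tolerance = 1e-9)
  expect_identical(rep$call, "red")
})

test_that("EEM peaks are found and classified on analytic fields", {
  # all-zero EEM: no peaks
  none <- find_eem_peaks(eem(seq(200, 300, 10), seq(200, 400, 10),
                             matrix(0, 11, 21)))
  expect_equal(nrow(none), 0L)

  # single spike at (280, 280) is one Rayleigh peak
  ex <- seq(200, 400, 5)
  em <- seq(200, 550, 5)
  z <- matrix(0, length(ex), length(em))
  z[ex == 280, em == 280] <- 100
  spike <- find_eem_peaks(eem(ex, em, z))
  expect_equal(nrow(spike), 1L)
  expect_identical(spike$peak_class, "rayleigh")
  expect_equal(spike$excitation_nm, 280)

  # default synthetic EEM, noiseless: the four-feature taxonomy
  e <- simulate_eem(sim_config(seed = 1, eem = list(sigma = 0)))
  peaks <- find_eem_peaks(e)
  expect_equal(nrow(peaks), 4L)
  expect_setequal(peaks$peak_class,
                  c("rayleigh", "second_order", "fluorophore", "fluorophore"))
  fl <- peaks[peaks$peak_class == "fluorophore", ]
  expect_setequal(fl$excitation_nm, c(280, 230))
  expect_true(all(fl$emission_nm == 340))
  expect_true(all(diff(peaks$intensity) <= 0))   # sorted descending
})

test_that("peak classification is invariant to scaling and grid refinement", {
  cfg5 <- sim_config(seed = 1, eem = list(sigma = 0))
  cfg1 <- sim_config(seed = 1, eem = list(
    sigma = 0, excitation_nm = seq(200, 400, 1),
    emission_nm = seq(200, 550, 1)))
  e5 <- simulate_eem(cfg5)
  e1 <- simulate_eem(cfg1)
  p5 <- find_eem_peaks(e5)
  p1 <- find_eem_peaks(e1)
  expect_identical(sort(p5$peak_class), sort(p1$peak_class))

  scaled <- eem(e5$excitation_nm, e5$emission_nm, 0.001 * e5$intensity)
  ps <- find_eem_peaks(scaled)
  expect_identical(ps$peak_class, p5$peak_class)
  expect_equal(ps$excitation_nm, p5$excitation_nm)
})

test_that("every reported peak is a strict 8-neighbour local maximum", {
  for (seed in c(1, 5, 9)) {
    e <- simulate_eem(sim_config(seed = seed))
    peaks <- find_eem_peaks(e)
    z <- e$intensity
    for (k in seq_len(nrow(peaks))) {
      i <- match(peaks$excitation_nm[k], e$excitation_nm)
      j <- match(peaks$emission_nm[k], e$emission_nm)
      nb <- z[max(1, i - 1):min(nrow(z), i + 1),
              max(1, j - 1):min(ncol(z), j + 1)]
      expect_equal(sum(nb >= z[i, j]), 1L)
    }
  }
})

test_that("default taxonomy is stable across seeds", {
  for (seed in 1:25) {
    p <- find_eem_peaks(simulate_eem(sim_config(seed = seed)))
    expect_identical(sort(p$peak_class),
                     c("fluorophore", "fluorophore", "rayleigh",
                       "second_order"),
                     label = sprintf("seed %d classes", seed))
  }
})

test_that("instrument-count amplitudes classify like the published peak table", {
  # amplitudes as printed for the free protein: Rayleigh 244663.4,
  # bands 96680.4 / 35574.9, second order 5036.2 (2% of the global max,
  # hence the lower prominence floor here)
  cfg <- sim_config(seed = 1, eem = list(
    sigma = 0,
    bands = list(
      list(centre_ex = 280, centre_em = 340, width_ex = 15, width_em = 20,
           amplitude = 96680.4),
      list(centre_ex = 230, centre_em = 340, width_ex = 12, width_em = 20,
           amplitude = 35574.9)),
    rayleigh_amplitude = 244663.4, second_order_amplitude = 5036.2))
  peaks <- find_eem_peaks(simulate_eem(cfg), min_prominence = 0.01)
  expect_equal(nrow(peaks), 4L)
  expect_setequal(peaks$peak_class,
                  c("rayleigh", "second_order", "fluorophore", "fluorophore"))
})
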