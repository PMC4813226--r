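# (ratio)A method, overlap integral, Forster radius, distance and angle.

test_that("ratio_a recovers identity, scaling and Gaussian amplitude ratios", {
  band <- c(570, 700)
  spA <- gaussian_spectrum(600, 15, 100, "acceptor_emission")

  expect_equal(ratio_a(spA, spA, band), 1.0)

  half <- gaussian_spectrum(600, 15, 50, "acceptor_emission")
  expect_equal(ratio_a(half, spA, band), 0.5)

  # scaled Gaussians integrated over center +/- 2 sigma: ratio is the
  # amplitude ratio (quadrature errors cancel between numerator and
  # denominator); expected value from the closed form 120/100
  sp120 <- gaussian_spectrum(600, 15, 120, "acceptor_emission")
  expect_equal(ratio_a(sp120, spA, c(600 - 30, 600 + 30)), 1.2,
               tolerance = 1e-12)
})

test_that("ratio_a signals absent acceptor and incompatible grids", {
  spA <- gaussian_spectrum(600, 15, 100, "acceptor_emission")
  zero <- spectrum_hj(seq(470, 720, 2), rep(0, 126), "acceptor_emission")
  expect_error(ratio_a(spA, zero), class = "hjbind_acceptor_absent")
  narrow <- gaussian_spectrum(600, 15, 100, "acceptor_emission",
                              grid = seq(590, 610, 2))
  expect_error(ratio_a(spA, narrow, c(570, 700)),
               class = "hjbind_incompatible_spectra")
})

test_that("fret_efficiency implements the extinction-corrected affine map", {
  dyes <- fam_tamra_dyes()
  # ratio equal to the crosstalk term: pure direct excitation, E = 0
  r0 <- dyes$eps_acceptor_at_donor_ex / dyes$eps_acceptor_at_acceptor_ex
  expect_equal(fret_efficiency(r0, dyes), 0)

  # hand evaluation with no crosstalk: 0.1 * 89100 / 78000
  dyes0 <- fam_tamra_dyes(crosstalk = 0)
  expect_equal(fret_efficiency(0.1, dyes0), 0.11423, tolerance = 1e-4)

  # affine in r with slope epsA(acceptor ex) / (fD epsD(donor ex))
  rs <- c(0.05, 0.2, 0.41)
  Es <- fret_efficiency(rs, dyes)
  slope <- diff(Es) / diff(rs)
  expect_equal(slope, rep(89100 / 78000, 2), tolerance = 1e-12)

  # round trip through the inverse at the initial-state efficiency
  r <- ratio_a_from_efficiency(0.05, dyes)
  expect_equal(fret_efficiency(r, dyes), 0.05, tolerance = 1e-12)

  expect_error(dye_photophysics(eps_acceptor_at_donor_ex = 8910,
                                fraction_donor_labeled = 0),
               class = "hjbind_invalid_labeling")
})

test_that("donor normalization divides out donor quenching and bleaching", {
  conc <- c(0, 1, 2, 5, 10) * 1e-6
  clean <- titration_series(conc, c(0.05, 0.1, 0.2, 0.3, 0.35))

  flat_ref <- titration_series(conc, rep(1000, 5))
  expect_equal(donor_normalize(clean, flat_ref)$signal, clean$signal)

  dim_ref <- titration_series(conc, c(1000, rep(900, 4)))
  normed <- donor_normalize(clean, dim_ref)
  expect_equal(normed$signal, clean$signal / c(1, rep(0.9, 4)))

  # 5% linear bleach applied and divided out reproduces the clean curve
  bleach <- seq(1, 0.95, length.out = 5)
  bleached <- titration_series(conc, clean$signal * bleach)
  ref <- titration_series(conc, 1000 * bleach)
  expect_equal(donor_normalize(bleached, ref)$signal, clean$signal,
               tolerance = 1e-12)

  other_grid <- titration_series(conc * 2, rep(1000, 5))
  expect_error(donor_normalize(clean, other_grid),
               class = "hjbind_grid_mismatch")
})

test_that("overlap integral matches a dense-grid oracle and converges", {
  donor <- gaussian_spectrum(520, 15, 7, "donor_emission")
  acceptor <- gaussian_spectrum(555, 15, 89100, "acceptor_absorption")
  J <- overlap_integral(donor, acceptor)

  # independent oracle: adaptive quadrature on the analytic band shapes
  fd <- function(wl) exp(-(wl - 520)^2 / (2 * 15^2))
  ea <- function(wl) 89100 * exp(-(wl - 555)^2 / (2 * 15^2))
  num <- stats::integrate(function(wl) fd(wl) * ea(wl) * wl^4, 470, 720,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(fd, 470, 720, rel.tol = 1e-10)$value
  expect_equal(J, num / den, tolerance = 1e-3)

  # grid refinement: halving the step changes J by < 0.1%
  donor_f <- gaussian_spectrum(520, 15, 7, "donor_emission",
                               grid = seq(470, 720, 1))
  acceptor_f <- gaussian_spectrum(555, 15, 89100, "acceptor_absorption",
                                  grid = seq(470, 720, 1))
  J_fine <- overlap_integral(donor_f, acceptor_f)
  expect_lt(abs(J - J_fine) / J_fine, 1e-3)

  # zero acceptor extinction
  zero <- spectrum_hj(seq(470, 720, 2), rep(0, 126), "acceptor_absorption")
  expect_equal(overlap_integral(donor, zero), 0)

  # delta-like donor band: J -> eps(l0) l0^4
  l0 <- 555
  delta_grid <- seq(l0 - 1, l0 + 1, by = 0.01)
  delta <- spectrum_hj(delta_grid,
                       exp(-(delta_grid - l0)^2 / (2 * 0.05^2)),
                       "donor_emission")
  # tolerance limited by linear interpolation of the 2-nm acceptor grid at
  # the band peak
  expect_equal(overlap_integral(delta, acceptor), 89100 * l0^4,
               tolerance = 5e-3)

  # disjoint spectra warn and return 0
  uv <- gaussian_spectrum(300, 5, 1, "donor_emission", grid = seq(280, 320, 2))
  expect_warning(J0 <- overlap_integral(uv, acceptor), "overlap")
  expect_equal(J0, 0)
})

test_that("forster_radius obeys the one-sixth-power scaling and prefactor", {
  fp <- forster_params(overlap_integral_J = 3e15)
  R0 <- forster_radius(fp)
  fp2 <- forster_params(donor_quantum_yield = 0.45,
                        overlap_integral_J = 3e15)
  fp1 <- forster_params(donor_quantum_yield = 0.9,
                        overlap_integral_J = 3e15)
  expect_equal(forster_radius(fp1) / forster_radius(fp2), 2^(1 / 6),
               tolerance = 1e-12)

  # algebraic identity: R0^6 = 8.79e-5 kappa^2 n^-4 QD J in Angstrom^6
  expect_equal(R0^6,
               8.79e-5 * fp$kappa_squared * fp$refractive_index^-4 *
                 fp$donor_quantum_yield * fp$overlap_integral_J,
               tolerance = 1e-9)

  # R0 depends on the factors only through their product
  a <- forster_params(kappa_squared = 1.2, refractive_index = 1,
                      donor_quantum_yield = 0.5, overlap_integral_J = 1e15)
  b <- forster_params(kappa_squared = 0.5, refractive_index = 1,
                      donor_quantum_yield = 1.0, overlap_integral_J = 1.2e15)
  expect_equal(forster_radius(a), forster_radius(b), tolerance = 1e-12)

  expect_error(forster_radius(forster_params(overlap_integral_J = 0)),
               class = "hjbind_invalid_photophysics")
})

test_that("a 50 A Forster radius round-trips through the prefactor", {
  # choose J so that R0 = 50 A at the default photophysics, then recompute
  fp0 <- forster_params(overlap_integral_J = 1)
  J50 <- (50 / forster_radius(fp0))^6
  expect_equal(forster_radius(forster_params(overlap_integral_J = J50)), 50,
               tolerance = 1e-9)
})

test_that("efficiency-to-distance conversion and its inverse agree", {
  expect_equal(fret_distance(0.5, 50, iso2_fraction = 1), 50)
  expect_equal(fret_distance(0.35, 50, iso2_fraction = 0.77), 51.5,
               tolerance = 1e-3)

  # experimental-scale window: ensemble dE of 0.25-0.35 lies within 50-60 A
  d <- fret_distance(c(0.25, 0.35), 50)
  expect_true(all(d >= 50 & d <= 60))

  # mutual inverses across the invertible range
  f <- 0.77
  E_obs <- seq(0.01 * f, 0.99 * f, length.out = 41)
  R <- fret_distance(E_obs, 50, f)
  expect_equal(efficiency_from_distance(R, 50, f), E_obs, tolerance = 1e-9)

  expect_error(fret_distance(0.8, 50, iso2_fraction = 0.77),
               class = "hjbind_efficiency_range")
  expect_error(fret_distance(0, 50), class = "hjbind_efficiency_range")
})

test_that("interduplex angle follows the law of cosines and is monotone", {
  geom <- junction_geometry(arm_length_bp = 17, rise_per_bp = 3.4)
  a <- geom$arm_length_A
  expect_equal(interduplex_angle(a, geom), 60)
  expect_equal(interduplex_angle(a * sqrt(2), geom), 90)
  expect_equal(interduplex_angle(50, geom), 51.3, tolerance = 1e-3)

  cs <- seq(20, 110, by = 5)
  expect_true(all(diff(interduplex_angle(cs, geom)) > 0))

  expect_error(interduplex_angle(2 * a, geom),
               class = "hjbind_inconsistent_geometry")
})

test_that("acceptor crosstalk ratio is recovered from acceptor-only spectra", {
  # acceptor-only emission scales with the extinction at the excitation
  # wavelength, so the band ratio equals epsA(donor)/epsA(acceptor)
  truth <- 8910 / 89100
  direct <- gaussian_spectrum(600, 15, 100, "acceptor_emission")
  donor_ex <- gaussian_spectrum(600, 15, 100 * truth, "acceptor_emission")
  expect_equal(acceptor_crosstalk_ratio(donor_ex, direct), truth,
               tolerance = 1e-12)
})
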