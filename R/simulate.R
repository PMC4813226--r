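## Seeded synthetic-data generators emulating every input of the pipeline:
## Hill titration curves, two-class ITC thermograms, Gaussian emission bands,
## mono-exponential decays and van't Hoff temperature series.

#' Simulation configuration
#'
#' Controls the random-number stream and noise model of all `gen_*`
#' generators. Each generator reseeds base R's RNG from `seed`, so a fixed
#' seed gives bit-identical output on repeated calls.
#'
#' @param seed integer seed.
#' @param noise_model `"gaussian_additive"` or `"poisson"`.
#' @param noise_scale noise standard deviation in signal units (ignored by
#'   the Poisson model), >= 0.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       noise_model = c("gaussian_additive", "poisson"),
                       noise_scale = 0) {
  noise_model <- match.arg(noise_model)
  if (noise_scale < 0) .hj_stop("noise_scale must be >= 0", "hjbind_invalid_input")
  structure(list(seed = as.integer(seed), noise_model = noise_model,
                 noise_scale = noise_scale),
            class = "sim_config")
}

.with_seed <- function(cfg, expr) {
  set.seed(cfg$seed)
  expr
}

.add_noise <- function(mu, cfg) {
  switch(cfg$noise_model,
    gaussian_additive = mu + stats::rnorm(length(mu), 0, cfg$noise_scale),
    poisson = stats::rpois(length(mu), pmax(mu, 0))
  )
}

#' Simulate a two-state ion-titration curve
#'
#' Signal from the two-state Hill model plus noise, on a log-spaced
#' concentration grid spanning `[Kd/50, 50 Kd]` by default. The default
#' parameters are the Mg2+ condition: Kd = 22 uM, Hill n = 1.05, efficiency
#' rising from 0.05 to 0.35, Gaussian noise sd 0.01.
#'
#' @param Kd_M true apparent dissociation constant, M.
#' @param hill_n true Hill coefficient.
#' @param E0,Ei true initial and final signals.
#' @param n_points number of titration points (default 20).
#' @param conc_range_M optional length-2 concentration range, M.
#' @param cfg a [sim_config()]; default Gaussian noise sd 0.01.
#' @param ion ion label carried in the series metadata.
#' @param temperature_K temperature metadata, K.
#' @return A [titration_series()].
#' @export
gen_fret_titration <- function(Kd_M = 22e-6, hill_n = 1.05, E0 = 0.05,
                               Ei = 0.35, n_points = 20,
                               conc_range_M = NULL,
                               cfg = sim_config(noise_scale = 0.01),
                               ion = "Mg2+", temperature_K = 283.15) {
  if (Kd_M <= 0 || hill_n <= 0) {
    .hj_stop("Kd and hill_n must be positive", "hjbind_invalid_input")
  }
  if (is.null(conc_range_M)) conc_range_M <- c(Kd_M / 50, Kd_M * 50)
  conc <- 10^seq(log10(conc_range_M[1]), log10(conc_range_M[2]),
                 length.out = n_points)
  Ka <- Kd_M^(-hill_n)
  mu <- two_state_model(conc, E0, Ei, Ka, hill_n)
  sig <- .with_seed(cfg, .add_noise(mu, cfg))
  titration_series(conc, sig, ion = ion, temperature_K = temperature_K)
}

#' Simulate an ITC experiment's per-injection heats
#'
#' Forward-models the injection series for a two-class (or general) site
#' model and adds Gaussian heat noise. The default schedule and truth are
#' the Mg2+-junction condition: 50 x 10 uL of 0.85 mM titrant into 16 uM
#' junction in a 1.4 mL cell, with the strong exothermic class
#' (n 2.1, Ka 40180 /M, dH -14.9 kcal/mol) and weak endothermic class
#' (n 15.9, Ka 25000 /M, dH +1.9 kcal/mol), heat noise sd 0.1 ucal.
#'
#' @param classes list of true [binding_class()] objects.
#' @param exp_ an [itc_experiment()] giving schedule and concentrations.
#' @param cfg a [sim_config()]; `noise_scale` is in ucal.
#' @return The [itc_experiment()] with simulated `heats_ucal` attached.
#' @export
gen_itc <- function(classes = itc_truth_classes(),
                    exp_ = itc_experiment(
                      cell_macromolecule_M = 16e-6,
                      syringe_ligand_M = 0.85e-3,
                      injection_volumes_L = rep(10e-6, 50)),
                    cfg = sim_config(noise_scale = 0.1)) {
  stopifnot(inherits(exp_, "itc_experiment"))
  heats <- simulate_injection_series(exp_, classes)$heat_ucal
  exp_$heats_ucal <- .with_seed(cfg, .add_noise(heats, cfg))
  exp_
}

#' Two-class truth parameters for the Mg2+-junction ITC condition
#'
#' Strong specific class (stoichiometry 2.1, Ka 40180 /M, dH -14.9
#' kcal/mol) and weak nonspecific class (15.9 sites, Ka 25000 /M,
#' dH +1.9 kcal/mol).
#'
#' @return List of two [binding_class()] objects.
#' @export
itc_truth_classes <- function() {
  list(binding_class(2.1, 40180, -14.9),
       binding_class(15.9, 25000, 1.9))
}

#' Simulate a mono-exponential luminescence decay
#'
#' I(t) = amp exp(-t/tau) + baseline + noise on a 0-1000 us grid at 1 us
#' spacing by default. With `noise_model = "poisson"` the counts are Poisson
#' draws of the model mean (SNR ~ sqrt(amp) at the peak); the Gaussian model
#' adds noise of sd `noise_scale` counts.
#'
#' @param tau_us true lifetime, us.
#' @param amp amplitude, counts.
#' @param baseline baseline, counts.
#' @param t_max_us,dt_us time grid extent and spacing, us.
#' @param excitation_nm excitation wavelength metadata.
#' @param cfg a [sim_config()].
#' @return A [luminescence_decay()].
#' @export
gen_decay <- function(tau_us = 124.8, amp = 1e4, baseline = 100,
                      t_max_us = 1000, dt_us = 1, excitation_nm = 464.1,
                      cfg = sim_config(noise_scale = 0)) {
  if (tau_us <= 0) .hj_stop("tau must be positive", "hjbind_invalid_input")
  t <- seq(0, t_max_us, by = dt_us)
  mu <- amp * exp(-t / tau_us) + baseline
  y <- .with_seed(cfg, .add_noise(mu, cfg))
  luminescence_decay(t, pmax(y, 0), excitation_nm = excitation_nm,
                     label = sprintf("synthetic tau=%.1f us", tau_us))
}

#' Simulate donor/acceptor emission spectra for the (ratio)A method
#'
#' Builds Gaussian emission bands emulating the FAM/TAMRA channels on the
#' instrument's scan grids (2 nm/point): the acceptor band under direct
#' acceptor excitation, and the same band under donor excitation whose
#' amplitude encodes a preset transfer efficiency plus the acceptor's
#' direct-excitation crosstalk. Inverting the efficiency relation
#' analytically for the amplitude makes noiseless spectra recover
#' `efficiency` exactly through [ratio_a()] and [fret_efficiency()].
#'
#' @param efficiency preset transfer efficiency encoded in the spectra.
#' @param dyes a [dye_photophysics()]; its crosstalk term
#'   `eps_acceptor_at_donor_ex` is included in the donor-excited band.
#' @param acceptor_center_nm,acceptor_sigma_nm acceptor band shape.
#' @param acceptor_amplitude peak intensity of the directly excited band.
#' @param donor_center_nm,donor_sigma_nm,donor_amplitude donor emission band
#'   (returned for overlap-integral use).
#' @param cfg a [sim_config()]; Gaussian noise is added to intensities.
#' @return List of [spectrum_hj()]: `spec_AD` (donor-excited acceptor
#'   emission, 508-652 nm grid), `spec_A` (directly excited acceptor
#'   emission, 570-700 nm grid extended to cover the band), `donor_em`
#'   (donor emission).
#' @export
gen_spectra_pair <- function(efficiency = 0.35,
                             dyes = dye_photophysics(
                               eps_acceptor_at_donor_ex = 8910),
                             acceptor_center_nm = 580,
                             acceptor_sigma_nm = 15,
                             acceptor_amplitude = 100,
                             donor_center_nm = 520, donor_sigma_nm = 15,
                             donor_amplitude = 100,
                             cfg = sim_config(noise_scale = 0)) {
  r <- ratio_a_from_efficiency(efficiency, dyes)
  grid_A <- seq(508, 700, by = 2)   # common grid covering both scan windows
  gauss <- function(wl, c0, s, a) a * exp(-(wl - c0)^2 / (2 * s^2))
  make <- function(amp, role) {
    y <- gauss(grid_A, acceptor_center_nm, acceptor_sigma_nm, amp)
    y <- .add_noise(y, cfg)
    spectrum_hj(grid_A, pmax(y, 0), role)
  }
  set.seed(cfg$seed)
  spec_A <- make(acceptor_amplitude, "acceptor_emission")
  spec_AD <- make(acceptor_amplitude * r, "acceptor_emission")
  grid_D <- seq(470, 652, by = 2)
  donor <- spectrum_hj(
    grid_D,
    pmax(.add_noise(gauss(grid_D, donor_center_nm, donor_sigma_nm,
                          donor_amplitude), cfg), 0),
    "donor_emission")
  list(spec_AD = spec_AD, spec_A = spec_A, donor_em = donor)
}

#' Simulate association constants across a temperature series
#'
#' Ka(T) = exp(-dH/(R T) + dS/R) at the given temperatures, with optional
#' lognormal noise (sd `noise_scale` on the log scale). Defaults are the
#' strong-class van't Hoff parameters at the five experimental temperatures
#' (4, 10, 20, 25, 30 C).
#'
#' @param dH enthalpy, kcal/mol.
#' @param dS entropy, cal/(mol K).
#' @param temps_K temperatures, K.
#' @param cfg a [sim_config()].
#' @return List with `temps_K` and `Ka` (M^-1).
#' @export
gen_temperature_series <- function(dH = -14.9, dS = -31.5,
                                   temps_K = 273.15 + c(4, 10, 20, 25, 30),
                                   cfg = sim_config(noise_scale = 0)) {
  if (any(temps_K <= 0)) .hj_stop("temperatures must be positive",
                                  "hjbind_invalid_input")
  Ka <- exp(-dH * 1000 / (.R_CAL * temps_K) + dS / .R_CAL)
  if (cfg$noise_scale > 0) {
    Ka <- .with_seed(cfg, Ka * exp(stats::rnorm(length(Ka), 0, cfg$noise_scale)))
  }
  list(temps_K = temps_K, Ka = Ka)
}

#' Simulate a Tb3+ sensitized-luminescence titration
#'
#' Integrated-intensity curve combining a saturable site-specific component
#' and a weaker, lower-affinity nonspecific component:
#' S(c) = amp_specific c/(Kd_s + c) + amp_nonspecific c/(Kd_ns + c) + noise.
#' The defaults (specific Kd 0.2 uM as seen by FRET; equal-amplitude
#' nonspecific component with Kd 8 uM) place the single-site apparent Kd of
#' the composite near the 1.2 uM seen by luminescence.
#'
#' @param kd_specific_M site-specific dissociation constant, M.
#' @param kd_nonspecific_M nonspecific dissociation constant, M (must
#'   exceed `kd_specific_M`).
#' @param amp_specific,amp_nonspecific component amplitudes (signal units).
#' @param n_points titration points (log-spaced over
#'   `[kd_specific/20, 50 kd_nonspecific]`).
#' @param cfg a [sim_config()]; default noise sd is 1% of the dynamic range.
#' @return A [titration_series()] with ion `"Tb3+"`.
#' @export
gen_tb_binding <- function(kd_specific_M = 0.2e-6, kd_nonspecific_M = 8e-6,
                           amp_specific = 0.5, amp_nonspecific = 0.5,
                           n_points = 20,
                           cfg = sim_config(noise_scale = 0.01)) {
  if (kd_specific_M >= kd_nonspecific_M) {
    .hj_stop("specific Kd must be below nonspecific Kd", "hjbind_invalid_input")
  }
  conc <- 10^seq(log10(kd_specific_M / 20), log10(kd_nonspecific_M * 50),
                 length.out = n_points)
  mu <- amp_specific * conc / (kd_specific_M + conc) +
    amp_nonspecific * conc / (kd_nonspecific_M + conc)
  sig <- .with_seed(cfg, .add_noise(mu, cfg))
  titration_series(conc, sig, ion = "Tb3+", temperature_K = 283.15)
}
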