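#' Fluorescence spectrum
#'
#' A wavelength/intensity series with a role tag saying which measurement it
#' represents: acceptor emission under donor excitation (`"donor_emission"`
#' channel of the doubly labelled sample is *not* a role here — roles name the
#' physical spectrum), directly excited acceptor emission, or an acceptor
#' excitation/absorption spectrum on an extinction scale.
#'
#' @param wavelength_nm numeric, strictly increasing wavelength grid (nm).
#' @param intensity numeric, non-negative intensities (arbitrary units, or
#'   M^-1 cm^-1 for absorption-scale spectra).
#' @param role one of `"donor_emission"`, `"acceptor_emission"`,
#'   `"acceptor_excitation"`, `"acceptor_absorption"`.
#' @return A `spectrum_hj` object (data frame with columns `wavelength_nm`,
#'   `intensity` and a `role` attribute).
#' @examples
#' wl <- seq(500, 700, by = 2)
#' sp <- spectrum_hj(wl, exp(-(wl - 580)^2 / (2 * 15^2)), "acceptor_emission")
#' @export
spectrum_hj <- function(wavelength_nm, intensity,
                        role = c("donor_emission", "acceptor_emission",
                                 "acceptor_excitation", "acceptor_absorption")) {
  role <- match.arg(role)
  .assert_finite_numeric(wavelength_nm, "wavelength_nm")
  .assert_finite_numeric(intensity, "intensity")
  if (length(wavelength_nm) == 0L) {
    .hj_stop("spectrum must be non-empty", "hjbind_invalid_input")
  }
  if (length(wavelength_nm) != length(intensity)) {
    .hj_stop("wavelength and intensity lengths differ", "hjbind_invalid_input")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    .hj_stop("wavelengths must be strictly increasing", "hjbind_invalid_input")
  }
  if (any(intensity < 0)) {
    .hj_stop("intensities must be >= 0", "hjbind_invalid_input")
  }
  structure(
    data.frame(wavelength_nm = as.numeric(wavelength_nm),
               intensity = as.numeric(intensity)),
    role = role,
    class = c("spectrum_hj", "data.frame")
  )
}

#' @export
print.spectrum_hj <- function(x, ...) {
  cat(sprintf("<spectrum_hj> role=%s, %d points, %.1f-%.1f nm\n",
              attr(x, "role"), nrow(x),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Ion-titration series
#'
#' Ordered (ion concentration, signal) pairs from a titration experiment,
#' e.g. FRET efficiency or integrated sensitized luminescence versus added
#' ion. Concentrations are in molar, matching the convention that free ion is
#' approximated by total added ion (ligand in large excess over the ~50 nM
#' junction).
#'
#' @param conc_M numeric, ion concentrations in M, non-negative and weakly
#'   increasing.
#' @param signal numeric signal values (dimensionless).
#' @param signal_sd optional per-point standard deviations (same length).
#' @param ion label for the titrant (e.g. `"Mg2+"`).
#' @param temperature_K sample temperature in kelvin.
#' @return A `titration_series` object.
#' @export
titration_series <- function(conc_M, signal, signal_sd = NULL,
                             ion = "ion", temperature_K = 283.15) {
  .assert_finite_numeric(conc_M, "conc_M")
  .assert_finite_numeric(signal, "signal")
  if (length(conc_M) != length(signal)) {
    .hj_stop("conc_M and signal lengths differ", "hjbind_invalid_input")
  }
  if (any(conc_M < 0)) .hj_stop("concentrations must be >= 0", "hjbind_invalid_input")
  if (is.unsorted(conc_M)) {
    .hj_stop("concentrations must be weakly increasing", "hjbind_invalid_input")
  }
  if (anyDuplicated(conc_M[-1])) {
    .hj_stop("concentrations must be distinct beyond the first point",
             "hjbind_invalid_input")
  }
  if (!is.null(signal_sd)) {
    .assert_finite_numeric(signal_sd, "signal_sd")
    if (length(signal_sd) != length(signal)) {
      .hj_stop("signal_sd length differs from signal", "hjbind_invalid_input")
    }
    if (any(signal_sd <= 0)) {
      .hj_stop("signal_sd must be positive", "hjbind_invalid_input")
    }
  }
  df <- data.frame(conc_M = as.numeric(conc_M), signal = as.numeric(signal))
  if (!is.null(signal_sd)) df$signal_sd <- as.numeric(signal_sd)
  structure(df, ion = ion, temperature_K = temperature_K,
            class = c("titration_series", "data.frame"))
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> ion=%s, T=%.2f K, %d points, conc %.3g-%.3g M\n",
              attr(x, "ion"), attr(x, "temperature_K"), nrow(x),
              min(x$conc_M), max(x$conc_M)))
  invisible(x)
}

#' Dye photophysics for the (ratio)A efficiency calculation
#'
#' Extinction coefficients of the FAM/TAMRA pair at the two excitation
#' wavelengths, the donor quantum yield and the donor labelling fraction.
#' The acceptor extinction at the donor excitation wavelength is not a
#' published constant for this system; supply it directly or derive it from
#' an acceptor-only spectrum pair with [acceptor_crosstalk_ratio()].
#'
#' @param eps_acceptor_at_acceptor_ex acceptor extinction at its own
#'   excitation wavelength (M^-1 cm^-1); TAMRA at 555 nm is 89100.
#' @param eps_acceptor_at_donor_ex acceptor extinction at the donor
#'   excitation wavelength (M^-1 cm^-1).
#' @param eps_donor_at_donor_ex donor extinction at its excitation
#'   wavelength (M^-1 cm^-1); FAM at 494 nm is 78000.
#' @param donor_quantum_yield donor quantum yield in (0, 1].
#' @param fraction_donor_labeled fraction of molecules carrying the donor,
#'   in (0, 1].
#' @return A `dye_photophysics` list.
#' @export
dye_photophysics <- function(eps_acceptor_at_acceptor_ex = 89100,
                             eps_acceptor_at_donor_ex,
                             eps_donor_at_donor_ex = 78000,
                             donor_quantum_yield = 0.9,
                             fraction_donor_labeled = 1) {
  eps <- c(eps_acceptor_at_acceptor_ex, eps_acceptor_at_donor_ex,
           eps_donor_at_donor_ex)
  .assert_finite_numeric(eps, "extinction coefficients")
  if (eps_acceptor_at_acceptor_ex <= 0 || eps_donor_at_donor_ex <= 0 ||
      eps_acceptor_at_donor_ex < 0) {
    .hj_stop("extinction coefficients must be positive", "hjbind_invalid_input")
  }
  if (donor_quantum_yield <= 0 || donor_quantum_yield > 1) {
    .hj_stop("donor quantum yield must be in (0, 1]", "hjbind_invalid_input")
  }
  if (fraction_donor_labeled <= 0 || fraction_donor_labeled > 1) {
    .hj_stop("invalid labeling fraction", "hjbind_invalid_labeling")
  }
  structure(list(
    eps_acceptor_at_acceptor_ex = eps_acceptor_at_acceptor_ex,
    eps_acceptor_at_donor_ex = eps_acceptor_at_donor_ex,
    eps_donor_at_donor_ex = eps_donor_at_donor_ex,
    donor_quantum_yield = donor_quantum_yield,
    fraction_donor_labeled = fraction_donor_labeled
  ), class = "dye_photophysics")
}

#' Forster-theory parameters
#'
#' Bundle of the photophysical quantities entering the Forster radius:
#' orientation factor kappa^2 (2/3 for isotropic dye motion), solvent
#' refractive index, donor quantum yield and the spectral overlap integral J
#' in M^-1 cm^-1 nm^4.
#'
#' @param kappa_squared orientation factor (default 2/3).
#' @param refractive_index medium refractive index (default 1.4, aqueous
#'   buffer with biomolecules).
#' @param donor_quantum_yield donor quantum yield in (0, 1].
#' @param overlap_integral_J overlap integral (M^-1 cm^-1 nm^4), >= 0.
#' @return A `forster_params` list.
#' @export
forster_params <- function(kappa_squared = 2 / 3, refractive_index = 1.4,
                           donor_quantum_yield = 0.9, overlap_integral_J) {
  vals <- c(kappa_squared, refractive_index, donor_quantum_yield,
            overlap_integral_J)
  .assert_finite_numeric(vals, "forster parameters")
  if (kappa_squared <= 0 || refractive_index <= 0 ||
      donor_quantum_yield <= 0 || donor_quantum_yield > 1 ||
      overlap_integral_J < 0) {
    .hj_stop("invalid photophysics", "hjbind_invalid_photophysics")
  }
  structure(list(
    kappa_squared = kappa_squared,
    refractive_index = refractive_index,
    donor_quantum_yield = donor_quantum_yield,
    overlap_integral_J = overlap_integral_J
  ), class = "forster_params")
}

#' Junction arm geometry
#'
#' Geometry of the two labelled junction arms used to convert the
#' FRET-measured dye-dye distance into an interduplex angle by the law of
#' cosines. Arms are assumed straight with B-DNA rise; the ~8 A dye-linker
#' offset is not modelled and enters as a systematic error on distances.
#'
#' @param arm_length_bp arm length in base pairs (default 17).
#' @param rise_per_bp helix rise per base pair in Angstrom (default 3.4).
#' @param iso2_fraction population of the high-FRET (isoII) stacked
#'   conformer, in (0, 1]; default 0.77. The isoI conformer places the dyes
#'   beyond 2 R0 and contributes no transfer.
#' @return A `junction_geometry` list with derived arm length in Angstrom.
#' @export
junction_geometry <- function(arm_length_bp = 17, rise_per_bp = 3.4,
                              iso2_fraction = 0.77) {
  if (arm_length_bp <= 0 || rise_per_bp <= 0) {
    .hj_stop("arm geometry must be positive", "hjbind_invalid_input")
  }
  if (iso2_fraction <= 0 || iso2_fraction > 1) {
    .hj_stop("iso2_fraction must be in (0, 1]", "hjbind_invalid_input")
  }
  structure(list(
    arm_length_bp = arm_length_bp,
    rise_per_bp = rise_per_bp,
    arm_length_A = arm_length_bp * rise_per_bp,
    iso2_fraction = iso2_fraction
  ), class = "junction_geometry")
}

#' Thermodynamic parameter bundle for one binding class
#'
#' Internally consistent (dH, dS, dG, Ka, T) set: dG = dH - T dS and
#' dG = -R T ln Ka with R = 1.9872 cal/(mol K). Provide `dH` plus either
#' `dS` or `Ka`; the remaining members are derived.
#'
#' @param dH binding enthalpy, kcal/mol.
#' @param dS binding entropy, cal/(mol K) (optional if `Ka` given).
#' @param Ka association constant, M^-1 (optional if `dS` given).
#' @param T_K temperature, K (default 283.15, the 10 C experimental
#'   temperature).
#' @return A `thermo_params` list with `dH`, `dS`, `dG` (kcal/mol), `Ka`,
#'   `T_K`.
#' @examples
#' thermo_params(dH = -14.9, dS = -31.5)   # strong, exothermic class
#' @export
thermo_params <- function(dH, dS = NULL, Ka = NULL, T_K = 283.15) {
  if (T_K <= 0) .hj_stop("temperature must be positive", "hjbind_invalid_input")
  if (is.null(dS) && is.null(Ka)) {
    .hj_stop("provide dS or Ka", "hjbind_invalid_input")
  }
  if (is.null(dS)) {
    if (Ka <= 0) .hj_stop("Ka must be positive", "hjbind_invalid_input")
    dG <- -.R_CAL * T_K * log(Ka) / 1000
    dS <- (dH - dG) * 1000 / T_K
  } else {
    dG <- dH - T_K * dS / 1000
    Ka <- exp(-dG * 1000 / (.R_CAL * T_K))
  }
  structure(list(dH = dH, dS = dS, dG = dG, Ka = Ka, T_K = T_K),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "<thermo_params> T=%.2f K: dH=%.2f kcal/mol, dS=%.2f cal/(mol K), dG=%.2f kcal/mol, Ka=%.4g /M\n",
    x$T_K, x$dH, x$dS, x$dG, x$Ka))
  invisible(x)
}
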