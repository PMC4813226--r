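## FRET efficiency chain: (ratio)A -> E -> distance -> interduplex angle.

#' Trapezoidal integral of a spectrum over a wavelength band
#' @noRd
.band_integral <- function(spec, band) {
  wl <- spec$wavelength_nm
  if (band[1] < min(wl) || band[2] > max(wl)) {
    .hj_stop("incompatible spectra: band not covered by spectrum grid",
             "hjbind_incompatible_spectra")
  }
  inside <- wl >= band[1] & wl <= band[2]
  ## include the exact band edges by interpolation so the integral is over
  ## [band1, band2] rather than the nearest grid points
  x <- c(band[1], wl[inside], band[2])
  y <- stats::approx(wl, spec$intensity, xout = x, rule = 1)$y
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Acceptor-band intensity ratio (ratio)A
#'
#' Ratio of integrated acceptor-band emission of the doubly labelled sample
#' under donor excitation to that under direct acceptor excitation. This is
#' the raw quantity from which the FRET efficiency is computed with
#' [fret_efficiency()].
#'
#' @param spec_AD acceptor emission [spectrum_hj()] recorded with donor
#'   excitation.
#' @param spec_A acceptor emission spectrum recorded with direct acceptor
#'   excitation.
#' @param band_nm numeric length-2 wavelength interval over which to
#'   integrate; default `c(570, 700)`, the acceptor emission scan range.
#' @return Dimensionless ratio >= 0.
#' @export
ratio_a <- function(spec_AD, spec_A, band_nm = c(570, 700)) {
  stopifnot(inherits(spec_AD, "spectrum_hj"), inherits(spec_A, "spectrum_hj"))
  if (length(band_nm) != 2L || band_nm[1] >= band_nm[2]) {
    .hj_stop("band_nm must be an increasing length-2 interval",
             "hjbind_invalid_input")
  }
  num <- .band_integral(spec_AD, band_nm)
  den <- .band_integral(spec_A, band_nm)
  if (den <= 0) {
    .hj_stop("acceptor signal absent: zero integrated intensity under direct excitation",
             "hjbind_acceptor_absent")
  }
  num / den
}

#' FRET efficiency from (ratio)A
#'
#' Converts the acceptor-band ratio to an energy-transfer efficiency,
#' subtracting the direct-excitation contribution of the acceptor at the
#' donor wavelength and rescaling by the extinction-coefficient ratio and the
#' donor labelling fraction:
#' E = (r - epsA(donor ex)/epsA(acceptor ex)) * (1/fD) *
#'     (epsA(acceptor ex)/epsD(donor ex)).
#'
#' Noisy ratios can produce slightly negative efficiencies; these are
#' returned as-is unless `clamp = TRUE`.
#'
#' @param r (ratio)A value, >= 0.
#' @param dyes a [dye_photophysics()] object.
#' @param clamp if `TRUE`, negative efficiencies are clamped to 0.
#' @return Energy-transfer efficiency (dimensionless).
#' @export
fret_efficiency <- function(r, dyes, clamp = FALSE) {
  stopifnot(inherits(dyes, "dye_photophysics"))
  .assert_finite_numeric(r, "r")
  if (any(r < 0)) .hj_stop("(ratio)A must be >= 0", "hjbind_invalid_input")
  epsA_a <- dyes$eps_acceptor_at_acceptor_ex
  epsA_d <- dyes$eps_acceptor_at_donor_ex
  epsD_d <- dyes$eps_donor_at_donor_ex
  E <- (r - epsA_d / epsA_a) * (1 / dyes$fraction_donor_labeled) *
    (epsA_a / epsD_d)
  if (clamp) E <- pmax(E, 0)
  E
}

#' Invert the efficiency relation back to (ratio)A
#'
#' Exact inverse of [fret_efficiency()]; useful for constructing spectra or
#' checking round trips.
#'
#' @inheritParams fret_efficiency
#' @param E efficiency value(s).
#' @return (ratio)A value(s).
#' @export
ratio_a_from_efficiency <- function(E, dyes) {
  stopifnot(inherits(dyes, "dye_photophysics"))
  epsA_a <- dyes$eps_acceptor_at_acceptor_ex
  E * dyes$fraction_donor_labeled * dyes$eps_donor_at_donor_ex / epsA_a +
    dyes$eps_acceptor_at_donor_ex / epsA_a
}

#' Acceptor direct-excitation crosstalk from an acceptor-only spectrum pair
#'
#' The acceptor extinction coefficient at the donor excitation wavelength is
#' not tabulated for this dye pair; it is measured as the ratio of
#' acceptor-only emission under donor excitation to that under direct
#' acceptor excitation, which equals epsA(donor ex)/epsA(acceptor ex).
#'
#' @param spec_A_donor_ex acceptor-only emission spectrum, donor excitation.
#' @param spec_A_acceptor_ex acceptor-only emission spectrum, direct
#'   excitation.
#' @param band_nm integration band, as in [ratio_a()].
#' @return Dimensionless extinction ratio epsA(donor)/epsA(acceptor).
#' @export
acceptor_crosstalk_ratio <- function(spec_A_donor_ex, spec_A_acceptor_ex,
                                     band_nm = c(570, 700)) {
  ratio_a(spec_A_donor_ex, spec_A_acceptor_ex, band_nm)
}

#' Normalize a (ratio)A titration to a donor-only reference
#'
#' Divides each (ratio)A value by the donor-only fluorescence at the same
#' titration point relative to its initial value, correcting for ion-induced
#' donor quenching and photobleaching over the titration.
#'
#' @param series [titration_series()] of (ratio)A values.
#' @param donor_only_series [titration_series()] of donor-only intensities on
#'   the same concentration grid.
#' @return A [titration_series()] with corrected signals.
#' @export
donor_normalize <- function(series, donor_only_series) {
  stopifnot(inherits(series, "titration_series"),
            inherits(donor_only_series, "titration_series"))
  if (nrow(series) != nrow(donor_only_series) ||
      !isTRUE(all.equal(series$conc_M, donor_only_series$conc_M))) {
    .hj_stop("grid mismatch between titration and donor-only series",
             "hjbind_grid_mismatch")
  }
  ref <- donor_only_series$signal / donor_only_series$signal[1]
  if (any(ref <= 0)) {
    .hj_stop("donor-only reference signal must stay positive",
             "hjbind_invalid_input")
  }
  titration_series(series$conc_M, series$signal / ref,
                   signal_sd = series$signal_sd,
                   ion = attr(series, "ion"),
                   temperature_K = attr(series, "temperature_K"))
}

#' Donor-acceptor spectral overlap integral
#'
#' J = int FD(lambda) epsA(lambda) lambda^4 dlambda / int FD(lambda) dlambda,
#' evaluated by trapezoidal quadrature after linear interpolation of both
#' spectra onto the finer of the two grids over their common wavelength
#' range. The donor emission is area-normalized internally, so its intensity
#' scale is irrelevant.
#'
#' @param donor_em donor emission [spectrum_hj()] (arbitrary units).
#' @param acceptor_abs acceptor absorption/excitation spectrum on an
#'   extinction scale (M^-1 cm^-1).
#' @return Overlap integral in M^-1 cm^-1 nm^4. Returns 0 with a warning if
#'   the spectra do not overlap.
#' @export
overlap_integral <- function(donor_em, acceptor_abs) {
  stopifnot(inherits(donor_em, "spectrum_hj"),
            inherits(acceptor_abs, "spectrum_hj"))
  lo <- max(min(donor_em$wavelength_nm), min(acceptor_abs$wavelength_nm))
  hi <- min(max(donor_em$wavelength_nm), max(acceptor_abs$wavelength_nm))
  if (lo >= hi) {
    warning("no spectral overlap between donor emission and acceptor absorption")
    return(0)
  }
  ## finer of the two grids, restricted to the common range
  step <- min(min(diff(donor_em$wavelength_nm)),
              min(diff(acceptor_abs$wavelength_nm)))
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  fd <- stats::approx(donor_em$wavelength_nm, donor_em$intensity, grid)$y
  ea <- stats::approx(acceptor_abs$wavelength_nm, acceptor_abs$intensity, grid)$y
  trap <- function(y) {
    sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  fd_area <- trap(fd)
  if (fd_area <= 0) {
    warning("donor emission has zero area over the common range")
    return(0)
  }
  trap(fd * ea * grid^4) / fd_area
}

## R0^6 (A^6) = 8.79e-5 kappa^2 n^-4 QD J, J in M^-1 cm^-1 nm^4
.FORSTER_PREFACTOR_A6 <- 8.79e-5

#' Forster radius from photophysical parameters
#'
#' R0 = (8.79e-5 kappa^2 n^-4 QD J)^(1/6) Angstrom with J in
#' M^-1 cm^-1 nm^4 (equivalently 0.02108 (kappa^2 n^-4 QD J)^(1/6) nm).
#'
#' @param fp a [forster_params()] object.
#' @return Forster radius in Angstrom.
#' @export
forster_radius <- function(fp) {
  stopifnot(inherits(fp, "forster_params"))
  if (fp$overlap_integral_J <= 0) {
    .hj_stop("invalid photophysics: overlap integral must be > 0",
             "hjbind_invalid_photophysics")
  }
  (.FORSTER_PREFACTOR_A6 * fp$kappa_squared * fp$refractive_index^-4 *
     fp$donor_quantum_yield * fp$overlap_integral_J)^(1 / 6)
}

#' Inter-dye distance from an observed efficiency
#'
#' The observed efficiency is first corrected for the stacked-conformer
#' population: only the high-FRET isoII conformer (fraction `iso2_fraction`)
#' transfers, the isoI dye separation exceeding 2 R0, so
#' E_corr = E_obs / iso2_fraction. The distance is then
#' R = R0 (1/E_corr - 1)^(1/6).
#'
#' @param E_obs observed ensemble efficiency.
#' @param R0 Forster radius in Angstrom.
#' @param iso2_fraction high-FRET conformer population (default 0.77).
#' @return Distance in Angstrom.
#' @export
fret_distance <- function(E_obs, R0, iso2_fraction = 0.77) {
  if (R0 <= 0) .hj_stop("R0 must be positive", "hjbind_invalid_input")
  if (iso2_fraction <= 0 || iso2_fraction > 1) {
    .hj_stop("iso2_fraction must be in (0, 1]", "hjbind_invalid_input")
  }
  E_corr <- E_obs / iso2_fraction
  if (any(E_corr <= 0) || any(E_corr >= 1)) {
    .hj_stop("efficiency out of invertible range (corrected E must lie in (0,1))",
             "hjbind_efficiency_range")
  }
  R0 * (1 / E_corr - 1)^(1 / 6)
}

#' Forward map: ensemble efficiency expected at a given distance
#'
#' E_obs(R) = iso2_fraction * R0^6 / (R0^6 + R^6); the inverse of
#' [fret_distance()].
#'
#' @param R inter-dye distance in Angstrom.
#' @inheritParams fret_distance
#' @return Observed (population-weighted) efficiency.
#' @export
efficiency_from_distance <- function(R, R0, iso2_fraction = 0.77) {
  if (any(R <= 0) || R0 <= 0) {
    .hj_stop("distances must be positive", "hjbind_invalid_input")
  }
  iso2_fraction * R0^6 / (R0^6 + R^6)
}

#' Interduplex angle from the dye-dye distance
#'
#' Law of cosines with both labelled arms of equal length a:
#' theta = arccos((a^2 + b^2 - c^2) / (2ab)), where c is the FRET-measured
#' distance between the dyes at the arm ends.
#'
#' @param c_A dye-dye distance in Angstrom (the side opposite the junction
#'   angle).
#' @param geom a [junction_geometry()] object; arm length a = b =
#'   `arm_length_bp * rise_per_bp`.
#' @return Angle in degrees, in (0, 180).
#' @export
interduplex_angle <- function(c_A, geom = junction_geometry()) {
  stopifnot(inherits(geom, "junction_geometry"))
  a <- geom$arm_length_A
  b <- a
  if (any(c_A <= abs(a - b)) || any(c_A >= a + b)) {
    .hj_stop("inconsistent geometry: triangle inequality violated",
             "hjbind_inconsistent_geometry")
  }
  acos((a^2 + b^2 - c_A^2) / (2 * a * b)) * 180 / pi
}
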