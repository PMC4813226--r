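## CSV dialects and run configuration. Every file starts with a
## schema-version comment line; column names carry explicit units.

.SCHEMA_VERSION <- 1L

.write_hj_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hjbind_schema: %d", .SCHEMA_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_hj_csv <- function(path, required_cols, optional_cols = character()) {
  if (!file.exists(path)) {
    .hj_stop(sprintf("file not found: %s", path), "hjbind_parse_error")
  }
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#\\s*hjbind_schema:", first)) {
    ver <- suppressWarnings(as.integer(sub("^#\\s*hjbind_schema:\\s*", "", first)))
    if (is.na(ver)) {
      .hj_stop(sprintf("%s:1: unparseable schema header", path),
               "hjbind_parse_error")
    }
    if (ver > .SCHEMA_VERSION) {
      .hj_stop(sprintf("%s:1: schema version %d newer than supported %d",
                       path, ver, .SCHEMA_VERSION), "hjbind_parse_error")
    }
    skip <- 1L
  }
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    .hj_stop(sprintf(
      "%s:%d: missing/mismatched columns: %s (expected %s; units are part of the column name)",
      path, skip + 1L, paste(missing, collapse = ", "),
      paste(required_cols, collapse = ",")), "hjbind_parse_error")
  }
  for (col in intersect(c(required_cols, optional_cols), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad)) {
      .hj_stop(sprintf("%s:%d: non-numeric value in column `%s`",
                       path, skip + 1L + bad[1], col), "hjbind_parse_error")
    }
    df[[col]] <- v
  }
  df
}

#' Read / write an ion-titration CSV
#'
#' Dialect: columns `conc_M,signal` with optional `signal_sd`, preceded by a
#' `# hjbind_schema: 1` header line. Units are part of the column names and
#' never inferred; a `conc_uM` column is rejected.
#'
#' @param path file path.
#' @param ion,temperature_K series metadata (not stored in the CSV).
#' @return [read_titration()]: a [titration_series()].
#' @export
read_titration <- function(path, ion = "ion", temperature_K = 283.15) {
  df <- .read_hj_csv(path, c("conc_M", "signal"), "signal_sd")
  titration_series(df$conc_M, df$signal, signal_sd = df$signal_sd,
                   ion = ion, temperature_K = temperature_K)
}

#' @rdname read_titration
#' @param series a [titration_series()] to write.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  .write_hj_csv(as.data.frame(series), path)
}

#' Read / write a spectrum CSV
#'
#' Dialect: columns `wavelength_nm,intensity`; the spectral role is supplied
#' by the caller, not stored in the file.
#'
#' @param path file path.
#' @param role spectral role, see [spectrum_hj()].
#' @return [read_spectrum()]: a [spectrum_hj()].
#' @export
read_spectrum <- function(path, role = "acceptor_emission") {
  df <- .read_hj_csv(path, c("wavelength_nm", "intensity"))
  if (any(diff(df$wavelength_nm) <= 0)) {
    .hj_stop(sprintf("%s: wavelength grid not strictly increasing", path),
             "hjbind_parse_error")
  }
  spectrum_hj(df$wavelength_nm, df$intensity, role)
}

#' @rdname read_spectrum
#' @param spec a [spectrum_hj()] to write.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_hj"))
  .write_hj_csv(as.data.frame(spec), path)
}

#' Read / write an ITC injection CSV
#'
#' Dialect: columns `injection_index,volume_uL,heat_ucal`. Cell/syringe
#' concentrations, cell volume and temperature are experiment metadata
#' supplied as arguments (or from a run config), not stored per-row.
#'
#' @param path file path.
#' @param cell_volume_L,cell_macromolecule_M,syringe_ligand_M,temperature_K
#'   experiment metadata; see [itc_experiment()].
#' @return [read_itc()]: an [itc_experiment()] with heats.
#' @export
read_itc <- function(path, cell_volume_L = 1.4e-3, cell_macromolecule_M,
                     syringe_ligand_M, temperature_K = 283.15) {
  df <- .read_hj_csv(path, c("injection_index", "volume_uL", "heat_ucal"))
  itc_experiment(cell_volume_L = cell_volume_L,
                 cell_macromolecule_M = cell_macromolecule_M,
                 syringe_ligand_M = syringe_ligand_M,
                 injection_volumes_L = df$volume_uL * 1e-6,
                 heats_ucal = df$heat_ucal,
                 temperature_K = temperature_K)
}

#' @rdname read_itc
#' @param exp_ an [itc_experiment()] with heats to write.
#' @export
write_itc <- function(exp_, path) {
  stopifnot(inherits(exp_, "itc_experiment"))
  if (is.null(exp_$heats_ucal)) {
    .hj_stop("experiment carries no heats", "hjbind_invalid_input")
  }
  .write_hj_csv(data.frame(
    injection_index = seq_along(exp_$injection_volumes_L),
    volume_uL = exp_$injection_volumes_L * 1e6,
    heat_ucal = exp_$heats_ucal
  ), path)
}

#' Read / write a luminescence-decay CSV
#'
#' Dialect: columns `time_us,intensity`; the excitation wavelength is
#' metadata supplied by the caller.
#'
#' @param path file path.
#' @param excitation_nm excitation wavelength tag.
#' @return [read_decay()]: a [luminescence_decay()].
#' @export
read_decay <- function(path, excitation_nm = NA_real_) {
  df <- .read_hj_csv(path, c("time_us", "intensity"))
  if (any(diff(df$time_us) <= 0)) {
    .hj_stop(sprintf("%s: time grid not strictly increasing", path),
             "hjbind_parse_error")
  }
  luminescence_decay(df$time_us, df$intensity, excitation_nm = excitation_nm)
}

#' @rdname read_decay
#' @param decay a [luminescence_decay()] to write.
#' @export
write_decay <- function(decay, path) {
  stopifnot(inherits(decay, "luminescence_decay"))
  .write_hj_csv(as.data.frame(decay), path)
}

#' Run configuration for the end-to-end analysis
#'
#' Defaults mirror the module-level design choices; every key a user did not
#' set explicitly is recorded in the returned object so the report can log
#' which defaults were in effect. Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults (see Details).
#' @param yaml_path optional YAML file of overrides, applied before `...`.
#' @details Recognised keys: `seed`; `fret_noise_sd`, `fret_points`;
#'   `itc_noise_ucal`, `itc_injections`, `itc_injection_uL`,
#'   `itc_cell_mL`, `itc_cell_uM`, `itc_syringe_mM`; `iso2_fraction`,
#'   `band_nm`, `kappa_squared`, `refractive_index`;
#'   `lifetimes_aq_us`, `lifetimes_4wj_us`, `excitations_nm`,
#'   `tau_da_us`, `lret_r0_A`, `lret_e_1to1`; `vanthoff_dH`, `vanthoff_dS`,
#'   `temps_C`; `kd_truths_uM` (named vector of per-ion Kd truths);
#'   `tb_kd_specific_uM`, `tb_kd_nonspecific_uM`.
#' @return A `run_config` list with attribute `defaulted` naming unset keys.
#' @export
run_config <- function(..., yaml_path = NULL) {
  defaults <- list(
    seed = 1L,
    fret_noise_sd = 0.01, fret_points = 20L,
    itc_noise_ucal = 0.1, itc_injections = 50L, itc_injection_uL = 10,
    itc_cell_mL = 1.4, itc_cell_uM = 16, itc_syringe_mM = 0.85,
    iso2_fraction = 0.77, band_nm = c(570, 700),
    kappa_squared = 2 / 3, refractive_index = 1.4,
    lifetimes_aq_us = c(105.9, 117.8, 140.0),
    lifetimes_4wj_us = c(121.4, 124.4, 128.7),
    excitations_nm = c(464.1, 464.5, 465.0),
    tau_da_us = 74.7, lret_r0_A = 6.0, lret_e_1to1 = 0.325,
    vanthoff_dH = -14.9, vanthoff_dS = -31.5,
    temps_C = c(4, 10, 20, 25, 30),
    kd_truths_uM = c("Mg2+" = 22, "Ca2+" = 55, "CoHex3+" = 4,
                     "Tb3+" = 0.1, "Eu3+" = 3, "Nd3+" = 0.7),
    tb_kd_specific_uM = 0.2, tb_kd_nonspecific_uM = 8
  )
  user <- list(...)
  if (!is.null(yaml_path)) {
    yml <- yaml::read_yaml(yaml_path)
    user <- utils::modifyList(as.list(yml), user)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    .hj_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
             "hjbind_invalid_config")
  }
  cfg <- utils::modifyList(defaults, user)
  structure(cfg, defaulted = setdiff(names(defaults), names(user)),
            class = "run_config")
}
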