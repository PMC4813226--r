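## Two-class independent-sites ITC: forward model, injection simulation,
## constrained fitting, and the van't Hoff bridge from FRET-determined Ka(T).

#' One class of independent binding sites
#'
#' @param n_sites sites per junction, > 0.
#' @param Ka site association constant, M^-1, > 0.
#' @param dH binding enthalpy, kcal per mol of ion.
#' @return A `binding_class` list.
#' @examples
#' binding_class(n_sites = 2.1, Ka = 40180, dH = -14.9)  # strong/specific
#' binding_class(n_sites = 15.9, Ka = 25000, dH = 1.9)   # weak/nonspecific
#' @export
binding_class <- function(n_sites, Ka, dH) {
  .assert_finite_numeric(c(n_sites, Ka, dH), "binding class parameters")
  if (n_sites <= 0 || Ka <= 0) {
    .hj_stop("n_sites and Ka must be positive", "hjbind_invalid_input")
  }
  structure(list(n_sites = n_sites, Ka = Ka, dH = dH),
            class = "binding_class")
}

.as_class_list <- function(classes) {
  if (inherits(classes, "binding_class")) classes <- list(classes)
  if (!length(classes) || !all(vapply(classes, inherits, TRUE, "binding_class"))) {
    .hj_stop("`classes` must be a list of binding_class objects",
             "hjbind_invalid_input")
  }
  classes
}

#' ITC experiment description
#'
#' Cell and syringe composition plus the injection schedule of an isothermal
#' titration calorimetry run. Heats may be absent until simulated with
#' [simulate_injection_series()] or loaded with [read_itc()].
#'
#' @param cell_volume_L active cell volume in litres (default 1.4e-3, typical
#'   for this instrument class; the active volume is a config value, not a
#'   published constant).
#' @param cell_macromolecule_M junction concentration in the cell, M.
#' @param syringe_ligand_M titrant concentration in the syringe, M.
#' @param injection_volumes_L vector of injection volumes, L.
#' @param heats_ucal optional measured/simulated per-injection heats, ucal.
#' @param temperature_K experiment temperature (default 283.15 K).
#' @return An `itc_experiment` list.
#' @examples
#' itc_experiment(cell_macromolecule_M = 16e-6, syringe_ligand_M = 0.85e-3,
#'                injection_volumes_L = rep(10e-6, 50))
#' @export
itc_experiment <- function(cell_volume_L = 1.4e-3, cell_macromolecule_M,
                           syringe_ligand_M, injection_volumes_L,
                           heats_ucal = NULL, temperature_K = 283.15) {
  .assert_finite_numeric(injection_volumes_L, "injection_volumes_L")
  if (cell_volume_L <= 0 || any(injection_volumes_L <= 0)) {
    .hj_stop("volumes must be positive", "hjbind_invalid_input")
  }
  if (cell_macromolecule_M < 0 || syringe_ligand_M < 0) {
    .hj_stop("concentrations must be >= 0", "hjbind_invalid_input")
  }
  if (length(injection_volumes_L) < 1L) {
    .hj_stop("need at least one injection", "hjbind_invalid_input")
  }
  if (!is.null(heats_ucal) && length(heats_ucal) != length(injection_volumes_L)) {
    .hj_stop("heats length must match injections", "hjbind_invalid_input")
  }
  structure(list(
    cell_volume_L = cell_volume_L,
    cell_macromolecule_M = cell_macromolecule_M,
    syringe_ligand_M = syringe_ligand_M,
    injection_volumes_L = as.numeric(injection_volumes_L),
    heats_ucal = heats_ucal,
    temperature_K = temperature_K
  ), class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf(
    "<itc_experiment> %d injections (%.3g mL total) of %.3g M into %.3g M, cell %.3g mL, T=%.2f K%s\n",
    length(x$injection_volumes_L), sum(x$injection_volumes_L) * 1e3,
    x$syringe_ligand_M, x$cell_macromolecule_M, x$cell_volume_L * 1e3,
    x$temperature_K,
    if (is.null(x$heats_ucal)) " [no heats]" else ""))
  invisible(x)
}

#' Free-ligand concentration from mass balance
#'
#' Solves L_tot = L + M_tot sum_i n_i K_i L / (1 + K_i L) for the free
#' ligand concentration L. The left-hand side minus the right is strictly
#' monotone in L, so the root on [0, L_tot] exists and is unique; it is
#' bracketed with [stats::uniroot()] and polished by Newton steps to
#' relative tolerance 1e-12.
#'
#' @param L_tot total ligand concentration, M, >= 0 (vectorized).
#' @param M_tot total macromolecule concentration, M, >= 0 (recycled
#'   against `L_tot`).
#' @param classes a [binding_class()] or list of them.
#' @return Free ligand concentration(s) in `[0, L_tot]`.
#' @export
solve_free_ligand <- function(L_tot, M_tot, classes) {
  classes <- .as_class_list(classes)
  .assert_finite_numeric(c(L_tot, M_tot), "concentrations")
  if (any(L_tot < 0) || any(M_tot < 0)) {
    .hj_stop("concentrations must be >= 0", "hjbind_invalid_input")
  }
  n <- vapply(classes, `[[`, 0, "n_sites")
  K <- vapply(classes, `[[`, 0, "Ka")
  solve1 <- function(Lt, Mt) {
    if (Lt == 0 || Mt == 0 || all(K == 0)) return(Lt)
    bound <- function(L) Mt * sum(n * K * L / (1 + K * L))
    f <- function(L) L + bound(L) - Lt
    L <- stats::uniroot(f, c(0, Lt), tol = 1e-13 * max(Lt, 1e-12))$root
    for (i in 1:4) { # Newton polish to machine precision
      dbound <- Mt * sum(n * K / (1 + K * L)^2)
      L <- min(max(L - f(L) / (1 + dbound), 0), Lt)
    }
    L
  }
  mapply(solve1, L_tot, rep_len(M_tot, length(L_tot)))
}

#' Cumulative heat of binding at a given composition
#'
#' Q = V [M] sum_i n_i dH_i K_i [L] / (1 + K_i [L]) with [L] from
#' [solve_free_ligand()]; the heat of a multi-class system is the sum of the
#' heats of binding to each class. Enthalpies in kcal/mol are converted so
#' the return value is in calories.
#'
#' @inheritParams solve_free_ligand
#' @param V_L reaction volume, L.
#' @param M_tot macromolecule concentration, M (recycled against `L_tot`).
#' @return Cumulative heat in cal (vectorized over `L_tot`).
#' @export
cumulative_heat <- function(L_tot, M_tot, classes, V_L) {
  classes <- .as_class_list(classes)
  if (V_L <= 0) .hj_stop("volume must be positive", "hjbind_invalid_input")
  L <- solve_free_ligand(L_tot, M_tot, classes)
  M_tot <- rep_len(M_tot, length(L))
  n <- vapply(classes, `[[`, 0, "n_sites")
  K <- vapply(classes, `[[`, 0, "Ka")
  dH <- vapply(classes, `[[`, 0, "dH")
  vapply(seq_along(L), function(i) {
    V_L * M_tot[i] * sum(n * dH * 1000 * K * L[i] / (1 + K * L[i]))
  }, 0)
}

#' Cell composition along an injection schedule
#'
#' Exponential perfusion dilution for an overfilled cell: injection i of
#' volume v changes cell concentrations as M_i = M_(i-1)(1 - v/V) and
#' L_i = L_(i-1)(1 - v/V) + L_syr (v/V).
#'
#' @param exp_ an [itc_experiment()].
#' @return Data frame with per-injection `M_tot` and `L_tot` (after each
#'   injection), plus the initial composition as attribute `initial`.
#' @export
injection_composition <- function(exp_) {
  stopifnot(inherits(exp_, "itc_experiment"))
  V <- exp_$cell_volume_L
  M <- exp_$cell_macromolecule_M
  L <- 0
  k <- length(exp_$injection_volumes_L)
  out <- data.frame(injection = seq_len(k), M_tot = NA_real_, L_tot = NA_real_)
  for (i in seq_len(k)) {
    d <- exp_$injection_volumes_L[i] / V
    M <- M * (1 - d)
    L <- L * (1 - d) + exp_$syringe_ligand_M * d
    out$M_tot[i] <- M
    out$L_tot[i] <- L
  }
  attr(out, "initial") <- c(M_tot = exp_$cell_macromolecule_M, L_tot = 0)
  out
}

#' Simulate the per-injection heats of an ITC experiment
#'
#' Evaluates the cumulative heat at the composition after each injection and
#' differences it, with the midpoint displaced-volume correction
#' dQ_i = Q_i - Q_(i-1) + (v_i/V)(Q_i + Q_(i-1))/2 accounting for reacted
#' material expelled from the active volume. Cell composition follows the
#' exponential perfusion model of [injection_composition()].
#'
#' @param exp_ an [itc_experiment()].
#' @param classes list of [binding_class()] objects (the truth).
#' @param displaced_volume_correction apply the midpoint correction
#'   (default `TRUE`).
#' @return Data frame: `injection`, `heat_ucal` and `ndh_kcal_per_mol`
#'   (heat normalized per mole of injected titrant).
#' @export
simulate_injection_series <- function(exp_, classes,
                                      displaced_volume_correction = TRUE) {
  stopifnot(inherits(exp_, "itc_experiment"))
  classes <- .as_class_list(classes)
  V <- exp_$cell_volume_L
  comp <- injection_composition(exp_)
  Q <- cumulative_heat(comp$L_tot, comp$M_tot, classes, V)
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev
  if (displaced_volume_correction) {
    dQ <- dQ + (exp_$injection_volumes_L / V) * (Q + Qprev) / 2
  }
  moles_inj <- exp_$injection_volumes_L * exp_$syringe_ligand_M
  data.frame(
    injection = comp$injection,
    heat_ucal = dQ * 1e6,
    ndh_kcal_per_mol = dQ / moles_inj / 1000
  )
}

#' Concatenate successive ITC rounds on the same cell
#'
#' Appends the injection schedules of experiments run back-to-back on the
#' same cell contents (syringe refilled with the same titrant), carrying the
#' cumulative dilution across rounds. Heats are concatenated when all rounds
#' have them.
#'
#' @param exps list of [itc_experiment()] objects sharing cell volume,
#'   initial cell contents, titrant and temperature.
#' @return A single [itc_experiment()] with the combined schedule.
#' @export
concatenate_itc <- function(exps) {
  exps <- exps[vapply(exps, function(e) length(e$injection_volumes_L) > 0 ||
                        !is.null(e), TRUE)]
  stopifnot(length(exps) >= 1, all(vapply(exps, inherits, TRUE, "itc_experiment")))
  first <- exps[[1]]
  for (e in exps[-1]) {
    same <- isTRUE(all.equal(e$cell_volume_L, first$cell_volume_L)) &&
      isTRUE(all.equal(e$cell_macromolecule_M, first$cell_macromolecule_M)) &&
      isTRUE(all.equal(e$syringe_ligand_M, first$syringe_ligand_M)) &&
      isTRUE(all.equal(e$temperature_K, first$temperature_K))
    if (!same) {
      .hj_stop("mismatched cell metadata between rounds", "hjbind_invalid_input")
    }
  }
  vols <- unlist(lapply(exps, `[[`, "injection_volumes_L"))
  heats <- lapply(exps, `[[`, "heats_ucal")
  heats <- if (all(!vapply(heats, is.null, TRUE))) unlist(heats) else NULL
  itc_experiment(
    cell_volume_L = first$cell_volume_L,
    cell_macromolecule_M = first$cell_macromolecule_M,
    syringe_ligand_M = first$syringe_ligand_M,
    injection_volumes_L = vols,
    heats_ucal = heats,
    temperature_K = first$temperature_K
  )
}

.itc_resid <- function(exp_, classes, blank_ucal) {
  pred <- simulate_injection_series(exp_, classes)$heat_ucal + blank_ucal
  exp_$heats_ucal - pred
}

#' Fit ITC heats with two classes of sites, class 1 constrained
#'
#' Least squares over (n1, n2, dH2, K2) with class-1 enthalpy and
#' association constant fixed to independently determined (van't Hoff)
#' values. Stoichiometries and K2 are kept positive by fitting on a log
#' scale. The per-class entropy is derived with [entropy_from()] at the
#' experiment temperature. chi2 is the sum of squared residuals in ucal^2
#' (absolute comparability with vendor-software chi-squared values is not
#' claimed).
#'
#' @param exp_ an [itc_experiment()] carrying heats.
#' @param fixed_class1 a [binding_class()] whose `dH` and `Ka` are held
#'   fixed; its `n_sites` is the n1 starting value.
#' @param start optional named list of starting values (`n1`, `n2`, `dH2`,
#'   `K2`).
#' @param blank_ucal constant per-injection blank heat subtracted from the
#'   data (default 0).
#' @return A `two_class_fit` list: fitted `class1` and `class2`
#'   [binding_class()] objects, `dS1`, `dS2` (cal/(mol K)), `chi2`,
#'   standard errors `se`, `residuals`, `converged`, and `identifiable`
#'   (`FALSE`, with a warning, when the Jacobian is singular — typically
#'   because the data carry no resolvable second class).
#' @export
fit_two_class <- function(exp_, fixed_class1, start = NULL, blank_ucal = 0) {
  stopifnot(inherits(exp_, "itc_experiment"),
            inherits(fixed_class1, "binding_class"))
  if (is.null(exp_$heats_ucal)) {
    .hj_stop("experiment carries no heats", "hjbind_invalid_input")
  }
  y <- exp_$heats_ucal - blank_ucal
  exp_fit <- exp_
  exp_fit$heats_ucal <- y

  s <- list(n1 = fixed_class1$n_sites, n2 = 10,
            dH2 = 1, K2 = fixed_class1$Ka / 2)
  if (!is.null(start)) s[names(start)] <- start
  ## guess dH2 sign from the late-injection heats
  tail_mean <- mean(utils::tail(y, 5))
  if (abs(s$dH2) == 1 && tail_mean < 0) s$dH2 <- -1

  par0 <- c(log(s$n1), log(s$n2), s$dH2, log(s$K2))
  resid_fn <- function(p) {
    cls <- list(
      binding_class(exp(p[1]), fixed_class1$Ka, fixed_class1$dH),
      binding_class(exp(p[2]), exp(p[4]), p[3])
    )
    .itc_resid(exp_fit, cls, 0)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (!(fit$info %in% 1:4)) {
    warning("two-class ITC fit did not fully converge; best-so-far returned")
  }
  p <- fit$par
  identifiable <- TRUE
  covmat <- tryCatch({
    dof <- max(length(y) - 4L, 1L)
    (fit$deviance / dof) * solve(fit$hessian)
  }, error = function(e) {
    identifiable <<- FALSE
    matrix(NA_real_, 4, 4)
  })
  if (!identifiable) {
    warning("singular Jacobian: some parameters are unidentifiable ",
            "(typical when the data carry no second binding class); ",
            "standard errors unavailable")
  }
  se_log <- sqrt(pmax(diag(covmat), 0))
  ## delta-method errors on the natural scale for log-fitted parameters
  se <- c(n1 = exp(p[1]) * se_log[1], n2 = exp(p[2]) * se_log[2],
          dH2 = se_log[3], K2 = exp(p[4]) * se_log[4])

  class1 <- binding_class(exp(p[1]), fixed_class1$Ka, fixed_class1$dH)
  class2 <- binding_class(exp(p[2]), exp(p[4]), p[3])
  out <- list(
    class1 = class1, class2 = class2,
    dS1 = entropy_from(class1$dH, class1$Ka, exp_$temperature_K),
    dS2 = entropy_from(class2$dH, class2$Ka, exp_$temperature_K),
    chi2 = fit$deviance, se = se, covariance = covmat,
    residuals = resid_fn(p), converged = fit$info %in% 1:4,
    identifiable = identifiable,
    temperature_K = exp_$temperature_K
  )
  class(out) <- "two_class_fit"
  out
}

#' @export
print.two_class_fit <- function(x, ...) {
  cat("<two_class_fit>\n")
  cat(sprintf("  class 1 (fixed dH, Ka): n=%.3f, Ka=%.4g /M, dH=%.2f kcal/mol, dS=%.2f cal/(mol K)\n",
              x$class1$n_sites, x$class1$Ka, x$class1$dH, x$dS1))
  cat(sprintf("  class 2: n=%.3f, Ka=%.4g /M, dH=%.2f kcal/mol, dS=%.2f cal/(mol K)\n",
              x$class2$n_sites, x$class2$Ka, x$class2$dH, x$dS2))
  cat(sprintf("  chi2 (ucal^2) = %.4g%s\n", x$chi2,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Fit ITC heats with a single unconstrained class of sites
#'
#' Reference fit used to judge whether a second binding class is required:
#' least squares over (n, dH, K), all free.
#'
#' @inheritParams fit_two_class
#' @return A list with the fitted [binding_class()], `chi2`, `residuals`,
#'   `converged`.
#' @export
fit_one_class <- function(exp_, start = NULL, blank_ucal = 0) {
  stopifnot(inherits(exp_, "itc_experiment"))
  if (is.null(exp_$heats_ucal)) {
    .hj_stop("experiment carries no heats", "hjbind_invalid_input")
  }
  y <- exp_$heats_ucal - blank_ucal
  exp_fit <- exp_
  exp_fit$heats_ucal <- y
  s <- list(n = 2, dH = if (y[1] < 0) -10 else 10, K = 1e4)
  if (!is.null(start)) s[names(start)] <- start
  resid_fn <- function(p) {
    .itc_resid(exp_fit, list(binding_class(exp(p[1]), exp(p[3]), p[2])), 0)
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(s$n), s$dH, log(s$K)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  p <- fit$par
  list(class1 = binding_class(exp(p[1]), exp(p[3]), p[2]),
       chi2 = fit$deviance, residuals = resid_fn(p),
       converged = fit$info %in% 1:4)
}

#' van't Hoff regression of association constants on temperature
#'
#' Ordinary least squares of ln Ka on 1/T: ln Ka = -(dH/R)(1/T) + dS/R, so
#' dH = -slope R and dS = intercept R, with R = 1.9872 cal/(mol K).
#'
#' @param temps_K temperatures, K (>= 3 values).
#' @param Kas association constants, M^-1, > 0.
#' @return A `vant_hoff_fit` list: `dH` (kcal/mol), `dS` (cal/(mol K)),
#'   `r_squared`, plus the input series and the underlying [stats::lm()] fit.
#' @export
vant_hoff_fit <- function(temps_K, Kas) {
  .assert_finite_numeric(c(temps_K, Kas), "van't Hoff inputs")
  if (length(temps_K) != length(Kas)) {
    .hj_stop("temperature and Ka lengths differ", "hjbind_invalid_input")
  }
  if (length(temps_K) < 3L) {
    .hj_stop("need at least 3 temperatures", "hjbind_invalid_input")
  }
  if (any(temps_K <= 0) || any(Kas <= 0)) {
    .hj_stop("temperatures and Kas must be positive", "hjbind_invalid_input")
  }
  fit <- stats::lm(log(Kas) ~ I(1 / temps_K))
  slope <- stats::coef(fit)[[2]]
  intercept <- stats::coef(fit)[[1]]
  tss <- sum((log(Kas) - mean(log(Kas)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  structure(list(
    dH = -slope * .R_CAL / 1000,
    dS = intercept * .R_CAL,
    r_squared = r2,
    temperatures_K = temps_K, Ka_values = Kas, lm_fit = fit
  ), class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf(
    "<vant_hoff_fit> %d temperatures: dH = %.3f kcal/mol, dS = %.3f cal/(mol K), R^2 = %.4f\n",
    length(x$temperatures_K), x$dH, x$dS, x$r_squared))
  invisible(x)
}

#' Binding entropy from enthalpy and association constant
#'
#' dG = -R T ln Ka (kcal/mol) and dS = (dH - dG)/T, returned in
#' cal/(mol K); R = 1.9872 cal/(mol K).
#'
#' @param dH binding enthalpy, kcal/mol.
#' @param Ka association constant, M^-1, > 0.
#' @param T_K temperature, K, > 0.
#' @return Entropy in cal/(mol K).
#' @examples
#' entropy_from(1.9, 25000, 283.15)   # weak endothermic class: ~26.8
#' @export
entropy_from <- function(dH, Ka, T_K) {
  if (any(Ka <= 0) || any(T_K <= 0)) {
    .hj_stop("Ka and T must be positive", "hjbind_invalid_input")
  }
  dG <- -.R_CAL * T_K * log(Ka) / 1000
  (dH - dG) * 1000 / T_K
}
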