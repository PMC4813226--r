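# Two-class ITC forward model, constrained fit, van't Hoff and entropies.

test_that("free-ligand solver satisfies mass balance and its limit cases", {
  classes <- table1_classes()
  expect_equal(solve_free_ligand(5e-5, 0, classes), 5e-5)

  # grid-scan oracle at the mid-titration composition
  L_tot <- 100e-6
  M_tot <- 16e-6
  L <- solve_free_ligand(L_tot, M_tot, classes)
  grid <- seq(0, L_tot, length.out = 1e7 + 1)
  n <- c(2.1, 15.9); K <- c(40180, 25000)
  bal <- abs(grid + M_tot * (n[1] * K[1] * grid / (1 + K[1] * grid) +
                               n[2] * K[2] * grid / (1 + K[2] * grid)) - L_tot)
  expect_lt(abs(L - grid[which.min(bal)]), 1e-10)

  # exact mass balance at the returned root
  bound <- M_tot * sum(n * K * L / (1 + K * L))
  expect_lt(abs(L + bound - L_tot), 1e-12 * max(L_tot, 1e-12))

  # monotone in total ligand
  Ls <- solve_free_ligand(seq(1e-6, 3e-4, length.out = 25), M_tot, classes)
  expect_true(all(diff(Ls) > 0))
})

test_that("cumulative heat has the right zero, plateau and additivity", {
  V <- 1.4e-3
  one <- binding_class(2.1, 40180, -14.9)
  expect_equal(cumulative_heat(0, 16e-6, one, V), 0)

  # saturation plateau: V M0 n dH (kcal -> cal)
  plateau <- cumulative_heat(1, 16e-6, one, V)
  expect_equal(plateau, V * 16e-6 * 2.1 * -14.9 * 1000, tolerance = 1e-3)

  # Eq-6 additivity at fixed free ligand: evaluate each class at the free
  # ligand concentration of the combined system
  classes <- table1_classes()
  L_tot <- 120e-6
  Lf <- solve_free_ligand(L_tot, 16e-6, classes)
  q_both <- cumulative_heat(L_tot, 16e-6, classes, V)
  per_class <- vapply(classes, function(cl) {
    n <- cl$n_sites; K <- cl$Ka
    V * 16e-6 * n * cl$dH * 1000 * K * Lf / (1 + K * Lf)
  }, 0)
  expect_equal(q_both, sum(per_class), tolerance = 1e-12)
})

test_that("perfusion dilution keeps macromolecule non-increasing and ligand increasing", {
  comp <- injection_composition(fig2_schedule())
  expect_true(all(diff(c(16e-6, comp$M_tot)) < 0))
  expect_true(all(diff(c(0, comp$L_tot)) > 0))
})

test_that("injection series telescopes, zeroes out and changes sign once", {
  ex <- fig2_schedule()
  zero_heat <- list(binding_class(2.1, 40180, 0), binding_class(15.9, 25000, 0))
  expect_equal(simulate_injection_series(ex, zero_heat)$heat_ucal,
               rep(0, 50))

  # telescoping without the displacement correction: sum of increments
  # equals the cumulative heat at the final composition
  classes <- table1_classes()
  ser <- simulate_injection_series(ex, classes,
                                   displaced_volume_correction = FALSE)
  comp <- injection_composition(ex)
  Q_final <- cumulative_heat(comp$L_tot[50], comp$M_tot[50], classes, 1.4e-3)
  expect_equal(sum(ser$heat_ucal) * 1e-6, Q_final, tolerance = 1e-12)

  # exothermic start, endothermic finish, single sign change
  heats <- simulate_injection_series(ex, classes)$heat_ucal
  expect_lt(heats[1], 0)
  expect_gt(heats[50], 0)
  expect_equal(sum(diff(sign(heats)) != 0), 1)
})

test_that("concatenating rounds reproduces a single long run", {
  classes <- table1_classes()
  r25 <- itc_experiment(cell_macromolecule_M = 16e-6,
                        syringe_ligand_M = 0.85e-3,
                        injection_volumes_L = rep(10e-6, 25))
  joined <- concatenate_itc(list(r25, r25))
  expect_length(joined$injection_volumes_L, 50)
  single <- fig2_schedule(50)
  expect_equal(injection_composition(joined)$L_tot,
               injection_composition(single)$L_tot, tolerance = 1e-12)
  expect_equal(simulate_injection_series(joined, classes)$heat_ucal,
               simulate_injection_series(single, classes)$heat_ucal,
               tolerance = 1e-12)

  expect_equal(concatenate_itc(list(r25))$injection_volumes_L,
               r25$injection_volumes_L)

  other <- itc_experiment(cell_macromolecule_M = 8e-6,
                          syringe_ligand_M = 0.85e-3,
                          injection_volumes_L = rep(10e-6, 25))
  expect_error(concatenate_itc(list(r25, other)),
               class = "hjbind_invalid_input")
})

test_that("noiseless two-class data are recovered exactly with class 1 fixed", {
  ex <- gen_itc(table1_classes(), fig2_schedule(),
                cfg = sim_config(seed = 1, noise_scale = 0))
  fit <- fit_two_class(ex, binding_class(2, 40180, -14.9))
  expect_lt(abs(fit$class1$n_sites - 2.1) / 2.1, 1e-6)
  expect_lt(abs(fit$class2$n_sites - 15.9) / 15.9, 1e-6)
  expect_lt(abs(fit$class2$dH - 1.9) / 1.9, 1e-6)
  expect_lt(abs(fit$class2$Ka - 25000) / 25000, 1e-6)
})

test_that("seeded noisy thermograms recover the strong-class stoichiometry", {
  ex <- gen_itc(table1_classes(), fig2_schedule(),
                cfg = sim_config(seed = 9, noise_scale = 0.1))
  fit <- fit_two_class(ex, binding_class(2, 40180, -14.9))
  expect_lt(abs(fit$class1$n_sites - 2.1), 0.4)
  # two classes describe two-class data far better than one
  one <- fit_one_class(ex)
  expect_lt(fit$chi2, one$chi2 / 5)
})

test_that("one-class synthetic data make the second class collapse", {
  one_class <- list(binding_class(2.1, 40180, -14.9))
  ex <- gen_itc(one_class, fig2_schedule(),
                cfg = sim_config(seed = 4, noise_scale = 0.05))
  fit <- suppressWarnings(
    fit_two_class(ex, binding_class(2, 40180, -14.9)))
  # flagged as unidentifiable, or the phantom class collapses to (near)
  # zero heat capacity n2 dH2
  expect_true(!fit$identifiable ||
                abs(fit$class2$n_sites * fit$class2$dH) < 0.5)
})

test_that("van't Hoff regression recovers generating parameters exactly", {
  ts <- gen_temperature_series(dH = -14.9, dS = -31.5,
                               cfg = sim_config(seed = 1, noise_scale = 0))
  fit <- suppressWarnings(vant_hoff_fit(ts$temps_K, ts$Ka))
  expect_equal(fit$dH, -14.9, tolerance = 1e-9)
  expect_equal(fit$dS, -31.5, tolerance = 1e-9)

  # constant Ka -> zero enthalpy
  flat <- suppressWarnings(vant_hoff_fit(273.15 + c(4, 10, 20, 25),
                                         rep(4e4, 4)))
  expect_equal(flat$dH, 0, tolerance = 1e-12)

  expect_error(vant_hoff_fit(c(280, 290), c(1e4, 2e4)),
               class = "hjbind_invalid_input")
})

test_that("two-point van't Hoff slope equals the closed-form difference", {
  T1 <- 277.15; T2 <- 303.15; K1 <- 5e4; K2 <- 1e4
  # regression through two points is the two-point slope formula
  fit3 <- suppressWarnings(
    vant_hoff_fit(c(T1, T2, T2), c(K1, K2, K2)))
  slope <- (log(K2) - log(K1)) / (1 / T2 - 1 / T1)
  expect_equal(fit3$dH, -slope * 1.9872 / 1000, tolerance = 1e-9)
})

test_that("entropy derivation matches the thermodynamic identities", {
  expect_equal(round(entropy_from(1.9, 25000, 283.15), 1), 26.8)
  expect_equal(round(entropy_from(-14.9, 40180, 283.15), 2), -31.56)
  # dH equal to dG gives zero entropy
  dG <- -1.9872 * 283.15 * log(25000) / 1000
  expect_equal(entropy_from(dG, 25000, 283.15), 0, tolerance = 1e-12)
  expect_error(entropy_from(1, -5, 283.15), class = "hjbind_invalid_input")
})

test_that("thermo_params keeps dG, dH, dS and Ka mutually consistent", {
  tp <- thermo_params(dH = -14.9, dS = -31.5)
  expect_equal(tp$dG, tp$dH - tp$T_K * tp$dS / 1000, tolerance = 1e-9)
  expect_equal(tp$dG, -1.9872 * tp$T_K * log(tp$Ka) / 1000, tolerance = 1e-9)
  tp2 <- thermo_params(dH = 1.9, Ka = 25000)
  expect_equal(round(tp2$dS, 1), 26.8)
})
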