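# Shared fixtures built in code.

gaussian_spectrum <- function(center, sigma, amplitude, role,
                              grid = seq(470, 720, by = 2)) {
  spectrum_hj(grid, amplitude * exp(-(grid - center)^2 / (2 * sigma^2)), role)
}

fam_tamra_dyes <- function(crosstalk = 8910) {
  dye_photophysics(eps_acceptor_at_acceptor_ex = 89100,
                   eps_acceptor_at_donor_ex = crosstalk,
                   eps_donor_at_donor_ex = 78000)
}

table1_classes <- function() {
  list(binding_class(2.1, 40180, -14.9),
       binding_class(15.9, 25000, 1.9))
}

fig2_schedule <- function(n_inj = 50) {
  itc_experiment(cell_volume_L = 1.4e-3,
                 cell_macromolecule_M = 16e-6,
                 syringe_ligand_M = 0.85e-3,
                 injection_volumes_L = rep(10e-6, n_inj))
}
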