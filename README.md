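# hjbind

Quantitative analysis of metal-ion binding to DNA four-way (Holliday)
junctions.

Holliday junctions switch between an extended open form and a compact
stacked-X form when cations screen the charge at the branch point. Three
experiments probe this transition, and hjbind implements the full analysis
chain for each, for spectroscopists and nucleic-acid biophysicists working
with junction (or similar folding) systems:

* **FRET ion titrations** — efficiencies from acceptor spectra by the
  (ratio)A method, E = [(ratio)A − ε_A(494)/ε_A(555)] (1/f_D)
  (ε_A(555)/ε_D(494)); Förster radii from overlap integrals,
  R₀⁶ = 8.79×10⁻⁵ κ² n⁻⁴ Q_D J (Å⁶); distances R = R₀(1/E − 1)^{1/6}
  with a stacked-conformer population correction; interduplex angles by the
  law of cosines. Folding curves are fit to the two-state Hill isotherm
  E([M]) = E₀ + K_a[M]ⁿ(E_i − E₀)/(1 + K_a[M]ⁿ), with
  K_d = K_a^{−1/n}.
* **Isothermal titration calorimetry** — forward model and constrained fit
  of Q = V[M] Σᵢ nᵢΔHᵢKᵢ[L]/(1 + Kᵢ[L]) with two classes of independent
  sites, free ligand from mass balance, perfusion-cell dilution and
  displaced-volume corrections, plus the van't Hoff bridge
  ΔH = −R d ln K_a / d(1/T) that fixes the class-1 parameters from
  temperature-dependent FRET.
* **Lanthanide luminescence** — mono-exponential decay fits; hydration
  numbers from the Kimura relation q = A′(1/τ − α′) (A′ = 1.11 ms,
  α′ = 0.44 ms⁻¹); inter-ion distances by luminescence resonance energy
  transfer between bound Eu³⁺ and Nd³⁺, E = 1 − τ_DA/τ_D and
  R = R₀(1/E − 1)^{1/6} with R₀ = 6.0 Å.

A seeded synthetic-data module (`gen_*` functions) generates every input
the pipeline consumes — Hill titration curves, two-class thermograms,
Gaussian emission bands, exponential decays, van't Hoff series — so all
stages run and are tested without instrument data.

## Worked example

```r
library(hjbind)

# simulate a Mg2+ folding titration (truth: Kd = 22 uM) and fit it
tr  <- gen_fret_titration(Kd_M = 22e-6,
                          cfg = sim_config(seed = 42, noise_scale = 0.01))
fit <- fit_two_state(tr)
fit
#> <two_state_fit> ion=Mg2+
#>   E0=0.0535 Ei=0.3385 Ka=1.356e+05 /M^n hill_n=1.084
#>   apparent Kd = 1.847e-05 M (18.5 uM)

# hydration state of the bound vs aqueous ion from lifetimes
hydration_number(c(124.8, 111.9))
#> <hydration_result> tau = 124.8, 111.9 us -> q = 8.4, 9.4 water(s)

# inter-ion distance from the LRET-quenched donor lifetime
E <- lret_efficiency(74.7, 124.8)
lret_distance(E)         # 6.42 A

# dye-dye distance and arm geometry from an ensemble efficiency
d <- fret_distance(0.35, R0 = 50, iso2_fraction = 0.77)
interduplex_angle(d)     # 53.0 deg for a 51.5 A separation
```

The fitted Kd of 18.5 µM sits within noise of the 22 µM truth and the Hill
coefficient near 1 indicates non-cooperative binding; the hydration numbers
say the junction-bound ion keeps ~8 of its ~9 inner-sphere waters (one
direct coordination to the DNA); and the LRET distance places the two bound
ions ~6.4 Å apart.

`run_full_analysis(run_config(seed = 1))` chains every stage on the bundled
synthetic presets and returns (optionally writes as JSON) the per-ion Kd
table, van't Hoff thermodynamics, the constrained two-class ITC fit, the
lifetime/hydration table and the LRET distances.

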