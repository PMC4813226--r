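---
title: "Models and methods: ion binding and folding of DNA four-way junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ion binding and folding of DNA four-way junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hjbind)
```

DNA four-way (Holliday) junctions fold from an extended open form into a
compact stacked-X form when cations neutralise the charge concentrated at
the branch point. hjbind implements the quantitative chain that turns three
kinds of spectroscopic measurements into binding and structural parameters:
FRET ion titrations (affinity and geometry of folding), isothermal titration
calorimetry (thermodynamics and stoichiometry of binding), and lanthanide
luminescence (hydration state of the bound ion and the distance between two
bound ions). A seeded synthetic-data module generates each input, so the
whole pipeline runs and is tested without instrument data.

## FRET efficiencies by the (ratio)A method

The efficiency is obtained from acceptor emission only, comparing the
acceptor band of the doubly labelled junction under donor excitation
(`F_AD`) with the same band under direct acceptor excitation (`F_A`):

$$(\mathrm{ratio})_A = \frac{F_{AD}(\lambda^{em}_A)}{F_A(\lambda^{em}_A)},
\qquad
E = \left[(\mathrm{ratio})_A - \frac{\varepsilon_A(494)}{\varepsilon_A(555)}\right]
    \frac{1}{f_D}\,\frac{\varepsilon_A(555)}{\varepsilon_D(494)}$$

`ratio_a()` integrates both spectra over a wavelength band (default
570–700 nm, the acceptor scan range; configurable) with trapezoidal
quadrature, and `fret_efficiency()` applies the extinction correction. Two
parameter choices matter:

* `eps_acceptor_at_donor_ex` — the acceptor (TAMRA) extinction at the donor
  excitation wavelength is not a tabulated constant for this system. It is
  a required input; `acceptor_crosstalk_ratio()` derives the ratio
  $\varepsilon_A(494)/\varepsilon_A(555)$ from an acceptor-only spectrum
  pair, which is how it would be measured. No literature value is baked in.
* `fraction_donor_labeled` — incomplete donor labelling scales the
  sensitized emission and is divided out.

`donor_normalize()` divides each titration point by the donor-only
fluorescence relative to its initial value, removing ion-induced donor
quenching and photobleaching. The exact normalisation rule used historically
for this assay is not fully specified in the literature we follow; the
per-point division is the natural form and is what the package implements.

Efficiencies are never clamped silently: values outside the invertible
range raise a classed error, and `fret_efficiency(clamp = TRUE)` is an
explicit opt-in for noisy data.

## Distances and the interduplex angle

The junction populates two stacked conformers; only the high-FRET isoII
conformer (default population 0.77, configurable) transfers measurably, the
isoI dye separation being beyond twice the Förster radius. `fret_distance()`
therefore corrects the ensemble efficiency by simple division,
$E_{corr} = E_{obs}/f_{iso2}$, before inverting

$$R = R_0\left(\frac{1}{E_{corr}} - 1\right)^{1/6}.$$

`forster_radius()` uses the standard prefactor, stated once and unit-tested
as an algebraic identity:
$R_0^6\,[\text{Å}^6] = 8.79\times10^{-5}\,\kappa^2 n^{-4} Q_D J$ with $J$ in
M⁻¹cm⁻¹nm⁴ from `overlap_integral()` (trapezoid on the finer of the two
grids after linear interpolation; refining the grid changes $J$ by <0.1%
for smooth bands). Defaults: $\kappa^2 = 2/3$ (isotropic dye motion,
supported by low dye anisotropies in this system) and $n = 1.4$.

`interduplex_angle()` converts the dye–dye distance to the angle between
the two labelled arms by the law of cosines with equal arm lengths
$a = b = 17\,\text{bp} \times 3.4\,\text{Å/bp} = 57.8$ Å. Two caveats are
deliberate: the dyes sit on ~8 Å linkers that are not modelled (a known
systematic on the distance, smaller than the ±11 Å dye-mobility error), and
with $a = 57.8$ Å the 50–60 Å distance window maps to ≈51°–62.5°, slightly
wider than the 54°–60° customarily quoted for this junction — the effective
arm length including linkers is not published, so the package exposes arm
length as a parameter rather than forcing agreement.

## Two-state folding isotherm

Folding versus ion concentration is described by a two-state Hill model,

$$E([M]) = E_0 + \frac{K_a [M]^n (E_i - E_0)}{1 + K_a [M]^n},$$

with the apparent dissociation constant defined by the equal-population
point, $K_d = K_a^{-1/n}$. `fit_two_state()` fits $(E_0, E_i, \log K_a, n)$
by Levenberg–Marquardt: fitting $\log K_a$ enforces positivity, $n$ is
bounded to [0.3, 4] (well outside the non-cooperative 1–1.1 range expected
here), starts come from the first/last points and the mid-signal crossing,
and a log-spaced $K_d$ grid (8 points per decade) guards against local
minima. Weights are $1/\sigma_i^2$ when per-point uncertainties exist,
otherwise the fit is unweighted (the historical fits do not state weights).
Free ion concentration is approximated by total added ion — the junction is
at ~50 nM, far below every $K_d$ of interest. The same fit serves
sensitized-luminescence titrations through `binding_from_luminescence()`.

## ITC with two classes of independent sites

The cumulative heat after equilibration at total ligand $L_{tot}$ is

$$Q = V[M]\sum_i \frac{n_i \Delta H_i K_i [L]}{1 + K_i [L]},$$

with the free ligand $[L]$ the unique root of the mass balance
$L_{tot} = L + [M]\sum_i n_i K_i L/(1+K_i L)$ (`solve_free_ligand()`;
bracketed `uniroot` polished by Newton steps, checked against a 10⁷-point
grid scan to <10⁻¹⁰ M). Per-injection heats difference $Q$ along the
injection schedule with two instrument-model choices that the source
protocol leaves open:

* **Cell dilution.** An overfilled perfusion cell: injection of volume $v$
  into cell volume $V$ dilutes both species by $(1 - v/V)$ and delivers
  $L_{syr}\,v/V$. This is the standard treatment for this instrument class.
* **Displaced volume.** The expelled reaction volume carries half-reacted
  material; the midpoint correction
  $\Delta Q_i = Q_i - Q_{i-1} + (v_i/V)(Q_i + Q_{i-1})/2$ matches the
  common vendor treatment.

The active cell volume (default 1.4 mL) is a configuration value typical of
the instrument class, not a published number — results depend on it only
weakly through the dilution factor, but it is exposed prominently.

`fit_two_class()` follows the constrained protocol: class-1 $\Delta H$ and
$K$ are fixed to values determined independently by van't Hoff analysis of
temperature-dependent FRET ($\ln K_a$ regressed on $1/T$ over 4–30 °C;
`vant_hoff_fit()`), while $(n_1, n_2, \Delta H_2, K_2)$ float (positives on
a log scale). Entropies then follow from
$\Delta G = -RT\ln K_a$ and $\Delta S = (\Delta H - \Delta G)/T$ with
$R = 1.9872$ cal mol⁻¹ K⁻¹ (`entropy_from()`). χ² is reported as the plain
sum of squared residuals in µcal²; comparability with vendor-software χ²
values is not claimed — only the one-class versus two-class ordering is
meaningful. A singular Jacobian (one-class data offered to the two-class
model) is flagged `identifiable = FALSE` with a warning, never silently
reported. Note that fixing class-1 parameters to van't Hoff estimates that
differ slightly from the calorimetric truth (here $K_a$ ≈ 41,300 vs 40,180
M⁻¹ when regenerated from rounded ΔH/ΔS) propagates a small bias into the
recovered $n_1$; this is inherent to the constrained protocol, not a fit
artefact.

Blank/dilution heats are handled as a constant per-injection offset
(`blank_ucal`), the default model for background correction. Raw
power-trace integration and baseline drift are out of scope — the package
starts from integrated per-injection heats.

## Lanthanide luminescence

`fit_decay()` fits $I(t) = A e^{-t/\tau} + b$ (mono-exponential only; the
junction-bound species resolves as a single component), skipping a
configurable 2 µs after the excitation pulse. The hydration number follows
the Kimura relation

$$q = A'\left(\frac{1}{\tau_{H_2O}} - \alpha'\right),
\quad A' = 1.11\ \text{ms},\ \alpha' = 0.44\ \text{ms}^{-1},$$

with lifetimes supplied in µs and converted internally; `hydration_number()`
returns both full precision and the one-decimal rounded convention used in
lifetime tables. Two conventions are encoded deliberately: the aqueous Eu³⁺
average uses only the 464.1 and 464.5 nm excitations (the 465.0 nm lifetime
is anomalously long, attributed to impurities, and is retained in output but
excluded from averages); and published one-decimal q values were evidently
computed from unrounded lifetimes, so recomputing from rounded lifetimes
can land one decimal step away (e.g. τ = 105.9 µs gives q = 9.99 → 10.0).

LRET between a bound Eu³⁺ donor and Nd³⁺ acceptor uses lifetimes only:
$E = 1 - \tau_{DA}/\tau_D$ and $R = R_0(1/E - 1)^{1/6}$ with $R_0 = 6.0$ Å
for this lanthanide pair. $\tau_D$ defaults to the junction-bound donor
lifetime (124.8 µs) rather than aqueous Eu³⁺; because free Eu³⁺ also
contributes to the observed decay, derived distances are upper limits, and
the report records that caveat. The efficiency at the 1:1 Nd:Eu point
(0.325) is taken as an input — the underlying lifetime is not published —
while the first-point efficiency is recomputed from lifetimes.

## What the generators emulate — and what they do not

Each `gen_*` function is the exact forward model of its fitter plus a
simple noise process, seeded through `sim_config()` (base R RNG; fixed seed
⇒ bit-identical output):

* `gen_fret_titration()` — Hill curve on a 20-point log grid spanning
  [Kd/50, 50 Kd]; Gaussian noise sd 0.01 efficiency units, consistent with
  the small error bars of the folding curves relative to the 0.25–0.35
  efficiency change.
* `gen_itc()` — 50 × 10 µL of 0.85 mM titrant into 16 µM junction, 1.4 mL
  cell, the two-class truth (2.1 sites at 40,180 M⁻¹, −14.9 kcal/mol;
  15.9 sites at 25,000 M⁻¹, +1.9 kcal/mol), Gaussian heat noise sd
  0.1 µcal. The thermogram crosses from exothermic to endothermic once.
* `gen_decay()` — mono-exponential on a 0–1000 µs, 1 µs grid; Gaussian
  (SNR 100 convention: sd = amplitude/100) or Poisson counts.
* `gen_temperature_series()` — exact van't Hoff $K_a(T)$, optional
  lognormal noise.
* `gen_tb_binding()` — composite specific + nonspecific saturable
  components. The preset (specific Kd 0.2 µM as seen by FRET; nonspecific
  Kd 8 µM at equal amplitude) was calibrated once, by fitting the noiseless
  composite, so that the single-site apparent Kd lands near the 1.2 µM seen
  by luminescence, then frozen.
* `gen_spectra_pair()` — Gaussian bands on 2 nm grids; the donor-excited
  amplitude is set by analytically inverting the efficiency relation, so
  noiseless spectra recover the preset efficiency exactly.

The generators do **not** emulate baseline drift, inner-filter effects,
shutter transients, dye-linker conformational averaging, multi-exponential
decays, or ionic-background (Na⁺ competition) effects. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimators under the stated statistical model, not robustness to every
instrument artefact in real data.

## Numerical choices and problem sizes

Tolerances: free-ligand mass balance to 10⁻¹² relative; LM fits run with
ftol/ptol 10⁻¹⁴–10⁻¹⁵; noiseless generate→fit round trips recover truth to
10⁻⁶ relative or better for all five generator/fitter pairs. The test and
acceptance workloads are sized for interactive use: 100 titration
replicates for the Kd-recovery statistic, one 50-injection thermogram for
the ITC recovery, 10⁷-point grid scans for the solver oracle, 20 decay
replicates for the lifetime-precision property.

## Known limitations

* Distances carry the unmodelled dye-linker offset; angles inherit it.
* The two-state Hill description is phenomenological; multi-site or
  counterion-condensation models are out of scope.
* ITC χ² values are not comparable across software.
* Only one lifetime component is fitted; mixed Eu³⁺ species bias LRET
  distances upward (reported as such).
* The conformer fraction (0.77) is a fixed input, not fitted.
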