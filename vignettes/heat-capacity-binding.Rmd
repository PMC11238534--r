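---
title: "Binding heat capacity from energy derivatives and conformational equilibria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding heat capacity from energy derivatives and conformational equilibria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindcp)
```

## The problem

Isothermal titration calorimetry on many protein–ligand systems shows a
binding enthalpy that changes markedly with temperature — a nonzero binding
heat capacity change, ΔCp, typically a few tenths of a kcal/mol/K and
negative. `bindcp` implements two complementary computational treatments of
this quantity for systems such as the benzamidine-class thrombin inhibitors
that motivated the package: a direct estimator of ΔCp from simulation
energies, and a conformational-equilibrium model that explains where a
negative ΔCp can come from without any intrinsic heat-capacity difference
between the bound and free states.

## The four-system derivative estimator

Since ΔCp = ∂ΔH/∂T, and for a condensed-phase system the enthalpy is well
approximated by the mean total potential energy ⟨U⟩, the binding ΔCp can be
assembled from the temperature derivatives of ⟨U⟩ of four separately
simulated systems:

ΔCp = (∂U/∂T)_holo − (∂U/∂T)_apo − [ (∂U/∂T)_lig − (∂U/∂T)_wat ]

The pairing matters: the holo/apo pair and the ligand-in-water/pure-water
pair are each built with identical numbers of water molecules, so every
degree of freedom appears once on each side of the difference and the
(large) kinetic and solvent contributions cancel. If the water counts are
not matched, `binding_heat_capacity()` applies a correction of
−n_imbalance × 0.018 kcal/mol/K, the experimental heat capacity of a bulk
water molecule; `per_molecule_cp()` exposes the corresponding check — a
potential-energy derivative per molecule plus the 3R equipartition term —
which for bulk water evaluates to ≈0.0179 kcal/mol/K.

Each derivative comes from `fit_dudt()`, an unweighted ordinary
least-squares fit of per-temperature mean energies (block-averaged by
`trace_mean()`/`aggregate_scan()`) against temperature, with the asymptotic
slope standard error as its uncertainty. Unweighted OLS is deliberate: for
converged simulations the per-temperature means are extremely precise and
essentially perfectly linear in T (R² = 1 to several decimals), so the
residual scatter, not the per-point SEM, is the honest noise scale. The
ΔCp uncertainty is the quadrature sum of the four slope errors; replicas
are pooled into the per-temperature means by frame-weighted averaging
rather than fitted separately, matching the one-mean-per-temperature
structure of the data.

```{r cycle}
res <- binding_heat_capacity(holo = 66.962, apo = 67.307,
                             lig = 23.083, wat = 22.871)
res$delta_cp
```

## The mandatory-coupling equilibrium model

An alternative (and in this system, the explanatory) source of negative
ΔCp is a conformational pre-equilibrium. In the mandatory-coupling scheme
(E+L)′ ⇌ E+L → EL only the binding-competent state E+L can form the
complex; K_eq is the inactive/active population ratio with
ΔG_eq = ΔH_eq − TΔS_eq. The observed quantities are then

* ΔH_app(T) = ΔH_b − ΔH_eq·K_eq/(1+K_eq)   (`apparent_enthalpy()`)
* ΔCp_app(T) = −(ΔH_eq²/RT²)·[1/(1+K_eq)]·[K_eq/(1+K_eq)]   (`apparent_cp()`)
* ΔG_app(T) = ΔH_b − TΔS_b + RT·ln(1+K_eq)   (`apparent_free_energy()`)

ΔCp_app is the exact temperature derivative of ΔH_app (the test suite
verifies this numerically over random parameter sets) and is always ≤ 0,
with its strongest dip −ΔH_eq²/(4RT²) where the two conformers are equally
populated. With equilibrium parameters of roughly ΔH_eq ≈ 17.6 kcal/mol and
ΔS_eq ≈ 0.058 kcal/mol/K — the regime fitted for the thrombin inhibitors —
the dip is ≈ −0.42 kcal/mol/K near 298 K and varies slowly over the
calorimetric window, mimicking a constant ΔCp.

```{r model}
avg <- equilibrium_params(dh_eq = 17.57, ds_eq = 0.0582, dh_b = 0)
apparent_cp(avg, 298.15)
```

### Fitting and the two-solution structure

`fit_equilibrium()` fits ΔH_app(T) to an ITC-style series by
Levenberg–Marquardt nonlinear least squares. Three facts shape the design:

* the objective always has two exactly equivalent minima, related by the
  transform (ΔH_eq, ΔS_eq, ΔH_b, ΔS_b) → (−ΔH_eq, −ΔS_eq, ΔH_b − ΔH_eq,
  ΔS_b − ΔS_eq) (`alternate_solution()`), because the model cannot tell
  which conformer is "active" from enthalpies alone;
* when the transition temperature lies outside the data range the
  objective develops flat directions;
* ΔS_b does not enter ΔH_app at all.

The fitter therefore multistarts from ΔH_eq ∈ {5, 10, 20, 40} kcal/mol
(with ΔS_eq = ΔH_eq/300 so the transition starts near the data) and
ΔH_b = mean(ΔH_app), keeps the lowest-residual optimum, and reports the
ΔH_eq > 0 branch by convention — for these ligands the structural evidence
(extended conformers uphill in enthalpy) favours that branch. ΔS_b is
solved separately from one reference ΔG_app value when supplied, and left
`NA` (never silently 0) otherwise. Points are weighted by 1/sd² only when
the series carries uncertainties. Parameter errors are asymptotic, from
the Jacobian at the optimum.

All "298 K" quantities use 298.15 K. Parameters quoted to 2–4 decimals
limit round-trip agreement of derived quantities to a few hundredths of a
kcal/mol, which is the tolerance the acceptance checks use.

## Conformational analyses

The free-ligand conformational story is quantified through the end-to-end
distance: `end_to_end_series()` (explicit atom selectors — which atoms
define "end to end" is a modelling choice the user makes),
`distance_distribution()` (0.5 Å bins over 3–20 Å by default),
`state_fractions()` with compact/extended cuts at 8 and 11 Å (between a
compact mode near 5.5 Å and extended conformers beyond 11 Å), and
`binned_energy_profile()` for intramolecular and ligand–solvent energies
versus distance, with empty bins reported as `NA` rather than zero.
`distribution_modes()` reports histogram modes after suppressing local
maxima closer than 2 Å, the noise scale of finite-count histograms on a
broad peak.

Ensemble analyses follow the standard structural-biology toolchain:
`superpose_ensemble()` iteratively aligns all frames to the running mean
(unweighted Kabsch superposition over a selection, convergence when the
mean shifts < 1e-6 Å, at most 100 sweeps — each sweep cannot increase the
total squared deviation, so this converges quickly), `ca_rmsd()` compares
structures after optimal superposition, `rmsf_per_residue()` computes
fluctuations about the ensemble mean (warning if the selection centroid
drifts > 1 Å, a sign of unaligned input), and `rmsf_from_bfactors()`
applies the isotropic relation B = (8π²/3)·RMSF². Multi-model PDB files
are read and written through bio3d, with residue numbering preserved
as-is.

## What the synthetic generators emulate — and what they do not

Because the package targets analyses downstream of molecular dynamics, its
generators reproduce the *statistical* structure of MD output, not its
physics:

* `gen_energy_scan()`: per system and temperature,
  U_t = u₀ + (∂U/∂T)·T + AR(1) noise. Defaults are the study conditions:
  temperatures {283, 288, 293, 298, 303} K, slopes the published
  derivative quadruple of the first inhibitor system (66.962, 67.307,
  23.083, 22.871 kcal/mol/K, implying ΔCp = −0.557), noise sd 1 kcal/mol,
  AR(1) coefficient 0.9 so that block averaging is materially different
  from naive √n error estimates, 1000 frames per trace.
* `gen_itc_series()`: ΔH_app(T) from the model plus Gaussian noise
  (default sd 0.1 kcal/mol over 283–313 K, the experimental window).
* `gen_two_state_trajectory()`: per frame a latent compact/extended state
  drawn with the model's inactive probability (or a fixed fraction),
  Gaussian distances per state (compact 5.5 ± 0.7 Å, extended
  12.5 ± 1.8 Å — widths chosen to visually match published bimodal
  histograms), and opposing linear energy trends (intramolecular −2,
  solvent +3 kcal/mol/Å) mirroring the charge-separation physics.
* `gen_ensemble()`: base structure + isotropic per-residue Gaussian
  displacements, optional random rigid-body motion per frame. All
  displacement draws precede the rigid-motion draws so the same seed
  yields the identical displacement field with rigid motion on or off —
  that is what makes the superposition-invariance test exact.

Every generator is a pure function of (spec, seed). What they do *not*
model: force-field energetics, water structure, correlated collective
motions, anisotropic fluctuations, or equilibration transients. Passing
recovery tests on this synthetic data therefore validates the estimator
and model algebra — the regression, error propagation, fitting, and
geometry — not the MD sampling itself. One consequence worth noting: with
the default state widths, the fraction of frames beyond the 11 Å cut is
systematically below the latent extended-state probability (the compact
tail contributes nothing, but the extended Gaussian puts ~20% of its mass
below 11 Å), so tests compare observed fractions against the analytic
truncated-Gaussian expectation, not against the latent probability.

## Numerical choices and problem sizes

R = 0.0019872 kcal/mol/K throughout. Histogram overflow values are tallied
explicitly, never silently dropped. Degenerate inputs (fewer than 3
temperatures, < 3 superposition atoms, inverted state cuts, negative
B-factors, non-positive temperatures) raise errors rather than propagate
nonsense. The default test-suite problem sizes — 400–2000 frames per
trace, 100-seed coverage runs, 300-frame ensembles, 10⁴-frame
two-state trajectories — were chosen so the whole suite runs in seconds
while keeping Monte-Carlo error well inside the asserted tolerances; the
analysis drivers under `analysis/` use 2000-frame traces.

## Known limitations

* The estimator assumes ΔCp is constant over the scanned temperature
  window (linear ⟨U⟩(T)); strongly curved scans would need a different
  model, and `fit_dudt()` would mask the curvature in an honest but large
  residual error.
* Cp estimation from energy-fluctuation variance (⟨δU²⟩/kT²) is
  deliberately out of scope; only the derivative route is implemented.
* The equilibrium model is strictly mandatory-coupling: binding from both
  conformers, protonation-linked or aggregation equilibria are not
  modelled.
* `fit_vant_hoff()` is provided mainly to demonstrate *why* free-energy
  van't Hoff curvature is an unreliable ΔCp route at realistic noise
  levels (its Monte-Carlo test shows dcp spreads several times larger than
  the true value over a 20 K window).
* Anisotropic B-factors and per-atom occupancies are ignored by the RMSF
  conversion.
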