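---
title: "Methods: models, parameters and design choices in allofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in allofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allofit)
```

allofit quantifies ensemble allostery in enzyme complexes that exchange
between an inactive ground conformation and a sparsely populated active
conformation, with the HisFH glutaminase/cyclase complex as the
motivating system. This vignette explains each model, its assumptions
and tunable parameters, the synthetic-data generators the test suite is
built on, and the design decisions that were genuinely open.

## Binding equilibria

**Two-state model.** A reporter in fast exchange between free and
ligand-bound protein resonates at the population-weighted shift. The
bound fraction comes from the exact mass balance
(`free_ligand()` solves the quadratic for the free ligand
concentration), not the ligand-excess approximation. At the
concentrations this package targets (protein 0.05–0.15 mM, KD in the
mM range) the approximation would be almost harmless, but the exact
solution costs nothing and keeps the functions correct for arbitrary
reuse, e.g. tight binders.

**Three-state model.** When an activating ligand occupies the second
active site, ligand binding (fast exchange, shift observable) is
followed by a slow conformational transition to the active state
(slow exchange, intensity observable). The scheme is

1. apo inactive state,
2. ligand-bound inactive state,
3. ligand-bound active state,

with both bound states parameterised by *apparent* dissociation
constants from state 1 (`kd_inactive_mM`, `kd_active_mM`). Whether the
physical path runs 1→2→3 or admits direct 1→3 binding is not
distinguishable at equilibrium — both give identical population curves
under this parameterisation — so the package fits apparent constants
and provides the populations (`three_state_populations()`). In the
saturating limit the active fraction tends to
`kd_inactive / (kd_inactive + kd_active)`
(`saturation_active_fraction()`), which for apparent constants of
1.4 and 0.2 mM gives 87.5 %.

**Fitting.** Both fits (`fit_two_state()`, `fit_three_state()`) use
Levenberg–Marquardt least squares (minpack.lm) on log-transformed
positive parameters with ten multi-starts log-spaced a decade either
side of a data-driven KD guess (the concentration at half-maximal shift
change). This removes the need for user-supplied starting values and in
our experience never lands in a local minimum on realistic titrations.
Uncertainties are Jacobian-based 1-SD values by default; a jackknife
(leave-one-titration-point-out) option mirrors the error protocol
common in lineshape-fitting software. Two identifiability guards turn
silent failures into errors: a shift range below three times the noise
level (two-state) and an identically zero intensity observable
(three-state).

## Two-site exchange lineshapes

`two_site_spectrum()` evaluates the standard frequency-domain solution
of the two-site McConnell equations: the absorption spectrum is the
real part of `1' (iω·I − L)⁻¹ p` with the 2×2 complex evolution
operator inverted in closed form per frequency. The forward model is
validated against an independent time-domain oracle (eigenpropagation
of the evolution matrix followed by explicit Fourier integration) to
better than 1e-6 relative.

The global titration fit (`fit_lineshape_titration()`) shares one set
of spectroscopic parameters (two offsets, two R2s) and the pair
(KD, koff) across all spectra; populations and exchange rates at each
titration point derive from the binding model, so kinetics and
thermodynamics are fitted jointly. Per-spectrum amplitudes are linear
nuisance parameters (receiver gain) and are profiled analytically,
which keeps the nonlinear parameter count at six regardless of series
length. Two-dimensional multiplet physics is deliberately out of
scope: a 2D experiment is treated as (at most) two independent 1D
fits, a documented approximation.

When exchange is too fast, the exchange broadening
(≈ p_f p_b Δω²/kex) falls below the noise floor and koff becomes a
lower bound rather than an estimate. The guard is the Jacobian-based
relative SD of koff: above `bound_threshold` (default 1, i.e. a
standard error the size of the estimate) the result is flagged
`koff_is_bound`. On dense, low-noise grids the fit can legitimately pin
surprisingly large koff values, so the flag is driven by the actual
curvature of the fit rather than a fixed kex cutoff.

## ZZ-exchange

`zz_intensities()` solves
`d/dt [M_I, M_A] = K [M_I, M_A]`,
`K = [[−R1_I−k_IA, k_AI], [k_IA, −R1_A−k_AI]]`, in closed form via the
2×2 eigen-solution (with the degenerate equal-eigenvalue limit handled
analytically), giving two auto and two cross curves versus mixing time.
The closed form is tested against a numerical matrix exponential on a
random parameter grid. `fit_zz()` fits all four curves jointly; the
default shares one R1 between states because separate R1s are rarely
resolvable from four curves and the package's motivating datasets did
not report them — a distinct-R1 mode exists. Initial amplitudes are
free parameters (they are detection-efficiency–scaled state
populations). The default initial condition of the generator is the
physical one: amplitudes proportional to the equilibrium populations
`k_AI/(k_IA+k_AI)` and `k_IA/(k_IA+k_AI)`. The equilibrium active
fraction `k_IA/(k_IA+k_AI)` (`equilibrium_population()`) is the
detailed-balance check against populations measured independently from
peak volumes; with forward/backward rates of 5 and 9 s⁻¹ it is 36 % to
the nearest percent.

## Turnover kinetics

Progress curves arrive as substrate/product signal-integral pairs;
normalising by the combined integral (`glu_fraction()`) removes the
instrument scale, and `kcat = slope × S0 / E` converts the initial-rate
slope to a turnover number in min⁻¹. The initial-rate window is a
product fraction below 0.3: at the assay concentrations (≈10 mM
substrate, enzyme ≤ 20 µM) the substrate stays far above any plausible
Michaelis constant throughout that window, so the true curve is linear
in it and the estimate is insensitive to the exact ceiling (tightening
0.5 → 0.2 moves noiseless estimates by < 1e-9). Fewer than five usable
points is an error, not a fit.

## Populations, free energies and the activity linkage

Per-reporter active fractions `V_a/(V_a+V_i)` are averaged across
reporters; the reported SD is the between-reporter scatter
(`population_from_volumes()`). The thermodynamic chain
`K_a = p/(1−p)` → `dG = −RT ln K_a` → `ddG = dG_mut − dG_ref` →
`kcat_mut = kcat_ref exp(−ddG/RT)` is implemented in
`ka_from_population()`, `delta_g()`, `ddg_mut()`, `predict_kcat()` and
assembled by `thermo_table()`. Energies are in kJ/mol with
R = 8.3145 J mol⁻¹ K⁻¹ and a default temperature of 303.15 K (30 °C,
the measurement temperature of the packaged conditions), so
RT ≈ 2.52 kJ/mol. Population SDs propagate to ddG by the first-order
delta method, `sd(dG) = RT·sd(p)/(p(1−p))`.

`fit_lnkcat_vs_ddg()` fits `ln(kcat)` against ddG either with the slope
pinned at −1/RT (the linkage's prediction; only the intercept is
estimated) or with a free slope as a consistency check — on data
generated exactly under the linkage the free slope returns −1/RT to
1e-10.

Two encoding choices deserve emphasis. First, the fully activated
fD98E condition has no measured population, only a lower bound; it is
encoded as 0.99, which fixes its (extreme) rank in the correlation but
makes its ddG a convention. Second, `spearman_exact()` computes the
rank correlation with midranks and, for n ≤ 8, the exact two-sided
p-value by full enumeration of all n! rank permutations — for seven
concordant conditions that is exactly 2/5040 ≈ 3.97×10⁻⁴. Above n = 8
a normal approximation (`z = rs√(n−1)`) takes over; enumeration of 9!+
permutations buys no practical precision at those sizes.

## Structure metrics

`read_structure()` parses PDB files (via bio3d) into a flat atom
table, resolving alternate locations to the highest-occupancy altloc
with ties going to "A". `three_point_angle()` measures the angle at the
middle atom — the standard three-point convention; for inter-subunit
orientation metrics the vertex is the interface-proximal atom.
`kabsch_superpose()` is an SVD-based least-squares rigid superposition
with the reflection branch corrected to a proper rotation; it is
tested against a general-purpose optimiser over rotation angles and
random rigid-transform probes. `local_backbone_rmsd()` superposes each
chain globally on backbone atoms (N, CA, C, O) and then reports
per-residue RMSD, so that localized loop rearrangements stand out
against a rigid background; the alignment uses all shared residues (no
core-subset iteration) and author residue numbering as-is. Per-residue
(not sliding-window) values are reported because state-to-state
comparisons are typically visualised per residue.

## Synthetic-data generators

Every generator (`sim_titration()`, `sim_zz_curves()`,
`sim_lineshape_series()`, `sim_progress_curve()`,
`sim_peak_volumes()`) calls the same forward-model code the fits use
and then adds noise, so model and generator cannot drift apart; with
noise set to zero the fits recover generating parameters to 1e-6
relative or better, which is the backbone of the test suite. Noise is
additive Gaussian on the observable — 0.002 ppm on shifts
(spectral-resolution scale) and 2 % of the maximum on intensities by
default, 3 % multiplicative on peak volumes — chosen as realistic
spectrometer-scale values; the motivating datasets state error bars at
the spectral resolution but no numeric noise levels, so these defaults
are conventions, configurable per call. Seeds are mandatory arguments;
generators evaluate under a local RNG state (withr) and never touch the
caller's random stream, and identical seeds give bit-identical tables.

What the generators emulate: fast-exchange titration shifts with
mM-range KDs, three-state intensity partitioning, two-site exchange
spectra across a titration, four-curve ZZ build-up/decay with R1 decay,
linear progress curves sampled every 34 s, and per-reporter volume
pairs at a given active fraction. What they do not emulate: baseline
and phase artefacts, peak overlap, temperature drift, multiplet
structure, or correlated noise. Passing recovery tests therefore
demonstrate the estimators are correct and well calibrated for clean
data of the assumed structure, not that any particular real dataset is
free of those artefacts.

## Problem sizes and numerical choices

The standard recovery protocols — chosen once as the study conditions
and used by both the tests and `scripts/acceptance.R` — are: 12-point
titrations (0–20 mM, 0.1 mM protein, 20 replicate seeds), 8 mixing
times (0–0.3 s, shared R1 1.5 s⁻¹, 2 % noise, 20 seeds), 6 spectra of
651 points (offsets ±150 Hz, R2 30 s⁻¹, 1 % noise, 10 seeds), 20-min
progress curves at 34-s sampling (1 % noise, 20 seeds) and 8-reporter
volume tables (3 % noise, 20 seeds). Root finds use `uniroot()` at
1e-13 tolerance on the mass balance; optimisations run up to 300 LM
iterations; the ZZ propagator switches to its series limit when the
eigenvalue splitting underflows; spectra carry a `grid_warning`
attribute when the frequency grid captures less than 99 % of the
theoretical integral.

## Known limitations

* Exchange models are strictly two-site (lineshape) / two-state (ZZ);
  no three-site networks, CPMG/CEST, or cross-relaxation.
* The lineshape module is 1D; 2D multiplet effects are approximated
  away.
* `fit_three_state()` treats the activating ligand as saturating; its
  own binding is not modelled.
* ddG for a fully activated condition is an encoding convention, and
  the linkage intercept conflates the reference turnover with the
  active-state rate constant — the two are not separable from these
  data.
* Michaelis–Menten saturation is not modelled in the turnover fit; the
  initial-rate window is the guard.
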