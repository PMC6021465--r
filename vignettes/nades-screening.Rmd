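---
title: "Dissociation-aware screening of natural deep eutectic solvents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociation-aware screening of natural deep eutectic solvents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadescreen)
```

## The problem

Natural deep eutectic solvents (NADES) are liquids formed by mixing two
plant-derived solids — here a dicarboxylic (or tricarboxylic) acid and an
amino acid in a 1:1 molar ratio — whose mutual hydrogen bonding and ion
pairing depress the melting point below ambient temperature. They are
attractive, food-grade media for solubilizing compounds that dissolve
poorly in water, such as the flavonoid rutin. Because the number of
candidate acid/amino-acid pairs grows combinatorially, experimental
screening is impractical; `nadescreen` implements an in-silico screen
that ranks candidate pairs by predicted solubility.

The pipeline has four stages:

1. **Speciation.** In the liquid, each component partly ionizes by
   proton transfer to its partner. Given the set of proton-transfer
   reactions and their equilibrium constants, the equilibrium mole
   fractions of all neutral and ionic forms are computed.
2. **Mixture sigma profile.** Each molecular form carries a sigma
   profile — the histogram p(σ) of its screening surface area over
   screening charge density σ from a continuum-solvation calculation.
   The solvent's surface composition function is the mole-fraction
   weighted sum of the form profiles.
3. **Activity.** The self-consistent segment chemical-potential
   equations of conductor-like screening (COSMO-RS) theory yield the
   solute's chemical potential in the solvent and hence its
   infinite-dilution activity coefficient γ∞.
4. **Calibration and ranking.** Computed ln γ∞ is regressed on
   experimental solubilities for a training set of solvents; the fitted
   line converts ln γ∞ of every candidate into a predicted solubility,
   which is ranked and reported relative to the best training solvent
   and to water.

The decisive modelling choice — demonstrated by the `no_dissociation`
switch — is stage 1: a naive model that mixes only the two neutral
forms correlates poorly with experiment, while the dissociation-aware
model correlates tightly. The screen is a deterministic ranking; no
hypothesis testing is involved, so no multiplicity machinery is
attached.

## Speciation model and solver

Reactions follow the convention `acid + amino = anion + cation`
(declarations in the reverse direction are inverted on ingestion).
Equilibrium constants enter either directly or through the reaction
free energy via K = exp(−ΔG°/RT), with R = 1.98720425·10⁻³
kcal/(mol·K) and T = 298.15 K by default; these values reproduce the
printed ΔG°/K pairs of the reference glutamic acid–proline system to
their printed precision. Only singly ionized forms are enumerated
automatically — one anion per acidic site, one cation per basic site —
because single proton-transfer events between the two parents are the
modelled chemistry; multiply charged species may still be declared by
hand. Zwitterionic tautomers are folded into the "neutral" form of
each parent rather than treated as distinct species: the reaction table
is written in terms of net charge classes, and a tautomer split would
require micro-constants that are not available.

The mass-action law is written on mole fractions over **all** forms of
both components — the neat binary liquid is its own solvent, and no
water or free proton is modelled. Ideal mixing (activity = mole
fraction) is assumed inside the mass-action law; measurements that
would pin a non-ideal activity model for these media do not exist, and
the choice is isolated in one function so a non-ideal loop could be
added.
The solver works on reaction extents, which enforce mass balance by
construction; charge balance follows because every reaction conserves
charge. Newton iteration on the extents (Jacobian SᵀD⁻¹S with D the
species amounts, steps clamped to keep all amounts positive, tiny
Tikhonov ridge when reaction sets are stoichiometrically dependent) is
seeded by Gauss–Seidel sweeps that solve each reaction's scalar
mass-action equation by bisection; the sweeps alone are the fallback
if Newton stalls. Convergence demands the worst relative mass-action
residual |Q/K − 1| < 10⁻¹⁰; amounts below 10⁻³⁰ mol are floored only
inside logarithms. Non-convergence is an error carrying the final
residuals, never a silent result.

For testing, an independent route to the same equilibrium is provided:
`speciation_oracle()` minimizes the ideal-mixing Gibbs energy
Σ nᵢ(ln xᵢ + μ⁰ᵢ) over the feasible extent box (coarse grid scan, then
per-coordinate bisection on the Gibbs gradient), with the
standard-state potentials μ⁰ recovered from ln K by an SVD
pseudo-inverse of the stoichiometry matrix. Solver and oracle agree to
better than 10⁻⁶ mole fraction across seeded random networks spanning
K from 10⁻⁶ to 10⁶.

```{r speciation}
sys <- nades_example_reactions()
mix <- mixture_spec(c(`7` = 1, A = 1), sys$forms)
res <- solve_speciation(mix, sys$reactions)
res
```

The equilibrium is dominated by the ion pair of the most acidic
carboxylate and the protonated amine, with only about 0.1 % of either
component remaining neutral — which is why the undissociated model
misrepresents these liquids.

## Sigma profiles

Profiles are discretized on the de-facto standard grid of 51 uniform
bins on σ ∈ [−0.025, +0.025] e/Å² (0.001 spacing, configurable). The
file format is plain two-column text (σ, p(σ); `#` comments), the
layout of the common public sigma-profile databases; non-uniform grids
are rejected rather than resampled, so resolution changes are always
explicit. The mixture profile is normalized by the mole-fraction
weighted mean molecular surface area, making p_S a probability-like
composition function (it sums to 1); this is the normalization under
which the conductor-limit fixed point μ ≡ 0 holds exactly when all
interaction energies vanish.

Quantum-chemistry profile generation is out of scope. For testing and
self-contained runs, `synthesize_profile()` builds smooth,
non-negative, bounded-support stand-ins as sums of truncated Gaussians,
and `make_profile_set()` draws plausible ones (areas 150–400 Å²,
support within ±0.02 e/Å²) deterministically per seed. One profile per
form is assumed; conformer weighting, if any, must happen upstream.
Synthetic profiles are labelled as such (`rutin_synthetic`) wherever
they stand in for a real molecule.

## Segment activity model

The per-contact interaction energy between segments of charge density
σ and σ′ combines an electrostatic misfit term (α′/2)(σ+σ′)², a
hydrogen-bond term c_hb·max(0, σ_acc − σ_hb)·max(0, −σ_don − σ_hb)
(σ_don = min(σ,σ′), σ_acc = max(σ,σ′)) that is active only when donor
and acceptor densities both pass the threshold σ_hb, and a σ-independent
van der Waals constant that cancels in activity-coefficient differences
and defaults to zero. With c_hb ≤ 0 the hydrogen-bond term is
attractive; positive c_hb is rejected. Defaults follow the widely used
open segment-activity parameterization: a_eff = 7.5 Å²,
α′ = 16466.72 kcal·Å⁴/(mol·e²), c_hb = −85580 kcal·Å⁴/(mol·e²),
σ_hb = 0.0084 e/Å². All are configurable; no claim is made that they
reproduce any proprietary parameterization, which is why a linear
recalibration against experiment closes the loop. A combinatorial
(size/shape) contribution is deliberately excluded: the recalibration
absorbs systematic offsets, and adding a Staverman–Guggenheim term
would change nothing about the ranking once refitted.

The segment equations are solved as a root problem on the fixed-point
residual μ − step(μ) by Levenberg–Marquardt with the analytic Jacobian
I + W, where W is the softmax matrix of contact weights. Plain damped
substitution is a poor algorithm here: for strongly interacting
profiles W concentrates onto +σ/−σ contact pairs and acquires an
eigenvalue near −1, so substitution needs thousands of iterations and
plain Newton meets a near-singular Jacobian; the adaptive ridge
resolves exactly that degeneracy. A short homotopy in interaction
strength (stages at 25/50/75/100 % of the full energies, each
warm-starting the next, loose 10⁻⁴ tolerance at intermediate stages)
keeps every stage in the fast local regime; typical totals are 10–80
iterations to a 10⁻⁸ kcal/mol residual. The iteration is fully
deterministic (fixed start μ ≡ 0, fixed schedule), and log-sum-exp
evaluation prevents under/overflow. A damped substitution step (mixing
fraction 0.4) is retained as the fallback whenever no ridge level
reduces the least-squares merit.

Infinite dilution is implemented literally: the solute is excluded from
the solvent composition, not present at a small ε. Neutral solutes use
the pure-compound reference state μ_P (pure-liquid profile of the
solute itself — for a solid solute this is a hypothetical liquid
reference, which the calibration step absorbs); ionic solutes have no
meaningful pure liquid and must use the infinite-dilution reference,
under which ln γ = 0 by construction and only chemical potentials are
informative.

Two consistency checks anchor the implementation: a single-occupied-bin
solvent admits the closed form μ(σ) = e(σ,σ₀) − e(σ₀,σ₀)/2, which the
solver reproduces to 10⁻¹⁰, and finite-composition activity
coefficients of a synthetic binary satisfy the Gibbs–Duhem relation
with a residual that is pure central-difference error (it falls by a
factor of four when the step halves). Note that the discretized
equations are grid-dependent at order Δσ²: ln γ shifts by ~0.07 when
the grid is refined from 51 to 101 bins for smooth synthetic profiles.
This is inherent to the quadrature, not a solver artifact; comparisons
between implementations are therefore made on a common grid, and grid
choice is part of the model specification.

## Calibration and screening

`fit_calibration()` regresses experimental solubility (mg/mL) on
computed ln γ∞ by ordinary least squares — the axes of the validation
correlation. Because the underlying relation is only known to be close
to linear, a log-form variant (ln s on ln γ∞) is available behind
`form = "log"`; neither form is asserted to be the published one. The
fitted object is a standard R model with `print`, `summary`, `coef`,
`predict`, `confint`, `residuals` and `plot` methods.

`predict_and_rank()` converts candidate ln γ∞ values into predicted
solubilities and reports, per candidate, the percent increase over a
reference solvent (default 2.26 mg/mL, the best training system:
glutamic acid–proline) and the fold-improvement over water (default
0.120 mg/mL). Reported percentages and folds are rounded to integers
and solubilities to two decimals — the printed precision of such
screens — while full precision is retained in the `s_pred` column, and
the rounding is applied only at the reporting edge so ranks never
depend on it. `pka_solubility_correlation()` quantifies the
structure–performance trend between the lowest substituent micro-pKa
of the acid component and predicted solubility (least-squares slope and
Pearson r); micro-pKa values are inputs, never predicted.

## The synthetic fixture suite

`export_fixtures()` writes a complete input set so the entire pipeline
runs with no external software: six acids and three amino acids from
the packaged 27-compound library, seeded equilibrium constants for all
18 pairs, Gaussian sigma profiles for every ionic form plus a
`rutin_synthetic` solute, a 15-system training table (matching the
size of the experimental training set; the remaining 3 pairs are
screening-only candidates), and a ready-to-run `config.yaml`.
Equilibrium constants are drawn per ionic form (log₁₀ contributions
uniform on [0.5, 3], so pair constants span 10¹–10⁶, the
product-favoured regime of acid/amino-acid proton transfer) — drawing
per form rather than per reaction keeps stoichiometrically dependent
reaction sets, which arise for multi-site parents such as ornithine,
thermodynamically consistent. Training solubilities are laid over the
pipeline's own computed ln γ∞ by a linear law with Gaussian noise
(signal s.d. 0.45 mg/mL around a 1.2 mg/mL centre, noise s.d.
0.08 mg/mL, solubilities kept positive), which puts the refit R² near
0.97 — the regime of a well-calibrated screen; the generating truth is
written to `truth.yaml` for recovery tests. All generators draw from
named pseudo-random streams derived from one master seed, so adding a
generator never perturbs existing fixtures, and regeneration with the
same seed is bit-identical.

What passing on these fixtures shows — and what it does not: the
synthetic profiles are smooth few-Gaussian shapes, so the tests
demonstrate that the solvers, the mixing algebra, the calibration and
the ranking are implemented correctly and consistently, not that the
default interaction parameters reproduce any measured γ∞ or solubility
of real NADES. Real sigma profiles are multimodal, conformer-averaged
objects tied to a specific quantum-chemistry parameterization, and
absolute predictions inherit that dependence; the package's claim on
real data is the calibrated *ranking*, not absolute solubilities.

```{r pipeline}
dest <- file.path(tempdir(), "fixture-suite")
fx <- export_fixtures(dest, seed = 1)
cfg <- read_run_config(file.path(dest, "config.yaml"))
report <- run_pipeline(cfg)
report
```

```{r naive}
cfg$out_dir <- file.path(dest, "out-naive")
cfg$options$no_dissociation <- TRUE
naive <- run_pipeline(cfg)
c(dissociation_R2 = report$calibration$r_squared,
  naive_R2 = naive$calibration$r_squared)
```

The contrast between the two coefficients of determination is the
package's central methodological point: which molecular forms you put
into the solvent model matters more than any downstream fitting.

## Numerical choices, problem sizes, and limitations

* Grid: 51 bins on ±0.025 e/Å²; tolerances: 10⁻¹⁰ on |Q/K − 1|
  (speciation), 10⁻⁸ kcal/mol max-norm (segment potentials); floors:
  10⁻³⁰ mol inside logarithms. Dominant-form cutoff for profile
  mixing: 10⁻⁴ mole fraction (renormalized), so negligible species do
  not require profiles.
* Test problem sizes were chosen to exercise every code path at
  comfortable margins: random speciation networks of 1–3 reactions
  with K spanning twelve decades, an 18-pair end-to-end screen, and a
  200-replicate calibration-coverage study.
* Ternary and higher mixtures are architecturally possible (the solver
  is written for general stoichiometry) but untested and unsupported.
* Temperature-dependent equilibrium constants, ionic-strength
  corrections, electrolyte long-range terms, sigma-profile generation
  from structures, and pKa prediction are out of scope by design.
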