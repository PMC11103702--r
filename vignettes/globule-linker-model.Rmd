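---
title: "Predicting hydrodynamic radii of disordered proteins with the globule-linker model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hydrodynamic radii of disordered proteins with the globule-linker model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glmrh)
```

## The problem

Intrinsically disordered proteins (IDPs) and multidomain proteins with long
unstructured linkers have no single native structure: what experiments such
as FCS, PFG-NMR, SEC, DLS or AUC measure is the translational diffusion
coefficient of the whole conformational ensemble, reported as a hydrodynamic
radius $R_h$ through the Stokes–Einstein relation
$R_h = k_B T / (6 \pi \eta D)$. Predicting $R_h$ from sequence therefore
requires two ingredients: a physically sensible ensemble of conformations,
and a hydrodynamic model that turns an ensemble into a diffusion
coefficient. `glmrh` implements both at a deliberately coarse resolution
chosen so that a full prediction takes seconds to minutes on one CPU.

## The globule-linker model

The chain is reduced to an alternating sequence of two bead types.

**Domain boundaries.** A residue run is called ordered when its disorder
probability (e.g. a DISOPRED3 track) is strictly below 50% for at least
3 consecutive residues; disordered loops of at most 14 residues flanked by
ordered runs are absorbed, so that one folded domain may contain short
internal loops. Both cutoffs are exposed in `glm_params()`
(`disorder_threshold`, `min_ordered_run`, `max_loop`). Loop merging is
iterated to a fixed point with left-to-right sweeps; a single pass is not
enough because a merge can create a new flanked loop, and the fixed point
of this sweep order is well defined (the suite checks idempotence).
Explicit domain intervals (a two-column TSV) bypass these rules entirely.

**Bead sizes.** Each folded domain becomes one sphere whose radius follows
from its mass $m$ at bulk protein density,
$R = (3 m / 4 \pi \rho_\mathrm{globular})^{1/3} + a_\mathrm{hydration}$,
with $\rho_\mathrm{globular} = 0.52\ \mathrm{Da/\AA^3}$ and a one-layer
hydration shell $a_\mathrm{hydration} = 3\ \mathrm{\AA}$. Domain masses are
sums of average (not monoisotopic) residue masses without terminal water:
the density is a bulk average, so average masses are the consistent choice,
and domains are interior fragments of a chain. Ambiguity codes X/B/Z/U get
the mean standard residue mass so that tagged constructs remain usable; a
strict mode refuses them. Each disordered residue becomes one linker bead
of steric diameter equal to the trans-peptide C$_\alpha$–C$_\alpha$ spacing
(3.8 Å — the canonical value; the quantity is exposed as `ca_ca_distance`).

**Linker hydration.** After sampling, linker beads are assigned a larger
hydrodynamic radius $R_\mathrm{disordered} = 4.2$ Å (the median residue
value), so neighbouring linker beads overlap hydrodynamically. $R_h$ of
long thin filaments depends only logarithmically on thickness, so results
are insensitive to this number; the mobility model below is what makes the
overlaps well defined.

## Sampling: self-avoiding random walk of spheres

The ensemble distribution is defined in two steps. The auxiliary
distribution places consecutive bead centres at distance equal to the sum
of their steric radii along independent, uniformly distributed directions
(`sample_auxiliary_walk()`); the SARWS distribution is the auxiliary one
conditioned on no non-adjacent pair of spheres overlapping
(`has_overlap()`). Adjacent pairs touch exactly by construction and are
exempt; a relative tolerance (`overlap_tolerance`, default $10^{-9}$)
guards the junction contacts against floating-point false positives.

Naive rejection (draw a whole walk, accept if self-avoiding) has
exponentially small acceptance in chain length. `sample_sarws()` instead
uses exact recursive dimerization: split the bead list in half, draw a
valid SARWS for each half recursively, join them with a fresh uniform bond
direction, and accept iff no inter-half overlap; on rejection both halves
are redrawn. Because the self-avoidance indicator factorizes into
intra-half and cross-half terms, this rejection scheme reproduces the exact
conditional distribution. Chains of at most 8 beads are drawn by one-shot
rejection (the crossover where recursion stops paying). The test suite
verifies distributional equivalence of the two samplers by two-sample KS
tests, and checks the known acceptance probability $3/4$ for a trimer of
equal touching spheres.

The sampler core is compiled (Rcpp) and driven by R's RNG, so
`sample_ensemble(chain, n, seed)` is bit-reproducible for a given seed. A
per-recursion-level attempt budget (default $10^6$) turns pathologically
constrained geometries into an informative error instead of a hang.

What the sampler deliberately ignores: Ramachandran statistics, residue
charge and any linker–linker interaction beyond excluded volume. These
shape short-range structure, but hydrodynamic interactions decay as $1/r$
and are dominated by long-range pair statistics, which excluded volume
controls.

## Hydrodynamics: Kirkwood–Riseman and minimum dissipation

Let $a_i$ be bead hydrodynamic radii and $r_{ij}$ centre distances. The
full Kirkwood formula estimates
$$R_h^{-1} = N^{-2} \Big( \sum_i a_i^{-1} + \sum_{i \ne j} \langle
r_{ij}^{-1} \rangle \Big),$$
the short-time diffusivity of the geometric centre; the widely used
simplified form drops the $\sum_i a_i^{-1}$ term (negligible at large
$N$). `kirkwood_rh()` computes either; the simplified form is what the
benchmark's "KR" rows use. Both use the bare $\langle 1/r \rangle$ even for
overlapping beads, as conventionally written; a flag (`use_grpy`) swaps in
the regularized pair mobility for sensitivity analysis.

The better estimator is the minimum dissipation approximation (MDA). Define
$A_{ij} = 2 \pi \eta\, \mathrm{Tr} \langle \boldsymbol{\mu}_{ij} \rangle$
from the generalized Rotne–Prager–Yamakawa (GRPY) pair mobility, which is
positive definite for arbitrary, even overlapping, polydisperse spheres.
The trace-contracted form used here is
$$A_{ij} = \begin{cases} 1/r_{ij} & r_{ij} \ge a_i + a_j \\
\dfrac{16 r^3 (a_i + a_j) - \big((a_i - a_j)^2 + 3 r^2\big)^2 +
\big((a_i - a_j)^2 - r^2\big)^2}{32 r^3 a_i a_j} & |a_i - a_j| < r_{ij} < a_i + a_j \\
1/\max(a_i, a_j) & r_{ij} \le |a_i - a_j|, \end{cases}$$
with $A_{ii} = 1/a_i$; viscosity cancels by construction. The branches meet
continuously at both boundaries — the suite checks this to $10^{-10}$,
which guards the transcription of the overlap form. With $B = A^{-1}$,
$$R_h = \sum_{ij} B_{ij}, \qquad x_i = \sum_j B_{ij} \Big/ \sum_{kj} B_{kj},$$
where $x$ are the diffusion-centre weights. Equivalently $R_h^{-1}$
minimizes $x^\top A x$ over weights summing to one, so the MDA radius is
never below the full Kirkwood radius (uniform weights are feasible) — a
property the suite asserts on every sampled ensemble. The ensemble average
sits inside $A$: one inversion total, never per conformer, and inversion
uses a Cholesky factorization that fails loudly (reporting the smallest
eigenvalue) rather than regularizing silently.

Monte Carlo uncertainty of the MDA estimate is reported by batch means
(at least 4 disjoint batches, each with its own $A$ and inversion), since
per-conformer MDA values do not exist.

## Choices made where the design was open

* **Recursion scheme.** Any split point gives the exact distribution; we
  split at the midpoint and redraw both halves on rejection. Redrawing only
  one half would bias the conditional distribution.
* **Kirkwood pair term.** The bare Oseen $\langle 1/r \rangle$ is kept in
  Eq.-style Kirkwood estimates (with the GRPY form reserved for the MDA
  matrix), matching the conventional presentation of those formulas.
* **Quartiles** in the benchmark metrics interpolate linearly between order
  statistics (R type 7), the most common convention; configurable.
* **$R^2$** is the coefficient of determination about the experimental
  mean, not a squared correlation — poor predictors legitimately score
  negative values, and the suite includes an anti-correlated discriminator
  case to keep it that way.
* **Power-law baselines** are fitted in log–log space by ordinary least
  squares (multiplicative errors match the relative-deviation metrics); the
  one-parameter "random coil" baseline fixes the exponent at the
  excluded-volume value 0.588 (configurable) and fits only the prefactor,
  which is then the geometric mean of $R_h / N^{0.588}$. Benchmark scoring
  of fitted baselines is always leave-one-out.

## What the synthetic fixtures are and are not

`generate_fixture()` builds sequences with a prescribed ordered/disordered
layout, disorder probabilities centred at 0.1/0.9 with bounded jitter
(≤ 0.4, so no residue crosses the 0.5 threshold), and ground-truth
annotations and domain masses. Fixtures exercise the full pipeline —
parsing, annotation recovery, bead building, sampling, scoring — without
any external predictor. They do not emulate real disorder tracks near the
threshold, compositional bias of linkers, or experimental noise, so green
tests on fixtures validate the machinery, not agreement with experiment;
agreement with experiment requires a user-assembled benchmark table of
measured radii, sequences and disorder tracks.

## Problem sizes and numerical conventions

The scaling study in the acceptance script and suite uses fully disordered
chains of $N$ = 100–800 residues with 200 conformers per length — sizes at
which the fitted exponent is stable against Monte Carlo noise while a full
run stays in the minutes range on one CPU. The ensemble-size convergence
check contrasts 40 against 1000 conformers on a 100-residue chain, the
regime where batch-mean standard errors are meaningful. Finite chains fit
slightly below the asymptotic excluded-volume exponent 0.588 (corrections
decay slowly with $N$), which is why the scaling check allows a finite-size
tolerance of 0.04 beyond the fit's standard error. All coordinates and
radii are in Å everywhere, residue intervals are 1-based inclusive, and
every stochastic entry point takes an explicit integer seed.

## Known limitations

* Domain boundary quality bounds prediction quality: with no annotation
  (`no_domains = TRUE`) multidomain chains are systematically overestimated.
* No environmental dependence (ionic strength, temperature beyond the
  Stokes–Einstein conversion, crowding), no complex formation.
* MDA is a short-time bound on the long-time diffusivity, not the exact
  long-time coefficient; memory effects are outside scope.
* Linker sequence specificity (charge patterning, PPII propensity) is
  ignored by design.

## A worked example

```{r example}
fx <- generate_fixture(list(c("disordered", 30), c("ordered", 50),
                            c("disordered", 30)), seed = 7)
fit <- glm_rh(fx$track, n_conformers = 100, seed = 1)
fit
coef(fit)
predict(fit, "diffusion")  # m^2/s at 293.15 K in water
```
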