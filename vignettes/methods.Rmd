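---
title: "Flux sampling and strain comparison for enological fermentations: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux sampling and strain comparison for enological fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinoflux)
library(dplyr)
```

## The problem

Commercial wine yeasts ferment the same must into measurably different
aroma profiles. The volatile organic compounds (VOCs) behind those
profiles — fusel alcohols, acetate esters, fatty-acid ethyl esters — are
end products of interconnected carbon and nitrogen pathways (glycolysis,
the Ehrlich route from amino acids through transaminases, decarboxylases
and alcohol dehydrogenases, and acetyl-transfer ester synthesis), so a
handful of extracellular measurements cannot by themselves say *where in
the network* two strains differ. Constraint-based modeling can: the
steady-state assumption restricts intracellular fluxes to the polytope

$$ P = \{\, v \in \mathbb{R}^n : S v = 0,\; lb \le v \le ub \,\}, $$

where $S$ is the stoichiometric matrix of a genome-scale metabolic model
and the bounds encode both reversibility and the measured exchange
rates. Rather than picking a single "optimal" flux state — enological
fermentations have no obvious objective to optimize — the package
samples $P$ uniformly per strain and time point and compares the
resulting flux distributions between strains.

The workflow is: (1) derive specific extracellular fluxes and growth
rates from concentration/biomass time courses; (2) put the model into
its anaerobic (enological) state; (3) fix exchange bounds to the
measured fluxes; (4) sample each constrained polytope with an
artificially-centered hit-and-run (ACHR) chain; (5) compare strains by
median-difference reaction rankings, PCA of the extracellular fluxes
with squared-cosine (cos2) diagnostics, and Pearson-correlation
hierarchical clustering of the median flux vectors.

## Flux estimation from time courses

For a compound concentration series $C(t)$ (mmol/L) and biomass $X(t)$
(gDW/L) measured at times $t_1 < \dots < t_m$, the specific flux at an
interior point is the midpoint (central-difference) rule normalized by
biomass:

$$ q(t_i) = \frac{C(t_{i+1}) - C(t_{i-1})}{t_{i+1} - t_{i-1}}
            \cdot \frac{1}{X(t_i)}, $$

with one-sided differences at the endpoints and **no prior smoothing**.
Consumption is negative, production positive, matching the
exchange-reaction sign convention (uptake < 0). The growth rate is the
same estimator applied to $X$ itself, $\mu = X'/X$. The central
difference is exact on linear and quadratic profiles at equally spaced
interior points, and `estimate_specific_flux()` is linear in the
concentrations; both properties are asserted in the test suite.

Two conventions are configurable because the field uses both:
normalization by $X$ at the evaluation point (`biomass_at = "point"`,
the default) or by the stencil mean (`"interval"`). Unequal spacing is
supported by the general $(C_{i+1}-C_{i-1})/(t_{i+1}-t_{i-1})$ form.

A caution that matters in practice: differencing large, slowly-changing
concentrations (glucose early in fermentation) amplifies measurement
noise by roughly $\mathrm{CV} \cdot C \sqrt{2} / (2\,\Delta t\, X)$.
With a 2 h grid this is the dominant error source in the derived
constraint fluxes; see the noise discussion under the generator below.

## Anaerobic setup and constraint fixing

Yeast genome-scale models are parameterized aerobically.
`apply_anaerobic_modifications()` encodes the standard enological
corrections as a reusable recipe: oxygen exchange closed (LB = UB = 0);
uptake of sterols and oleate opened (their biosynthesis requires
molecular oxygen, so anaerobic growth depends on supplementation — the
conventional yeast-GEM ids r_1757, r_1915, r_2106, r_2134, r_2137,
r_2189 are the defaults); respiratory shuttle reactions blocked
(defaults r_0713, r_0714, r_0487); and heme A, unused anaerobically,
deleted from the biomass equation. "Unrestricted" uptake is encoded as a
lower bound of −1000 mmol gDW⁻¹ h⁻¹, the package-wide reversible
default. The operation is idempotent and never changes the model's
dimensions. Blocked reactions are closed in both directions, and the
growth rate is fixed exactly (LB = UB = μ), mirroring the exchange
treatment; both points were genuinely open design choices.

`fix_exchange_fluxes()` sets LB = UB = flux for every measured exchange
(and the biomass reaction) — optionally LB/UB = flux ∓ band·|flux| with
a relative `tolerance_band`, the knob used for infeasibility handling.

**Infeasibility handling.** Exactly fixed noisy measurements frequently
make $P$ empty: the measured vector must lie exactly on the
mass-balance-consistent subspace, and noise pushes it off. The pipeline
first retries along a band ladder (default 0, then 0.05). If the
polytope is still empty it falls back to *measured-rate reconciliation*:
the weighted least-squares projection

$$ \min_v \sum_j \left( \frac{v_j - f_j}{s_j} \right)^2
   \quad \text{s.t. } S v = 0,\; lb \le v \le ub, $$

with $s_j = \max(|f_j|, \mathrm{median}|f|)$ so adjustments are relative
to each flux's size, solved as a strictly convex QP. Exchanges are then
fixed at the reconciled values, which are feasible by construction. This
is the standard treatment of measured rates in metabolic flux analysis;
the band-only "abort" mode is retained (`infeasible_action = "abort"`).
Every run's manifest records, per strain × time point, which band was
used and whether reconciliation was applied.

## Uniform sampling of the flux polytope

`achr_sample()` implements artificially-centered hit-and-run. Warmup
points are the $2n$ flux-variability (FVA) vertices — the LP minimizer
and maximizer of every reaction — pulled 33% toward their centroid so no
chain starts on the boundary. Each step draws a direction from a random
warmup point to the running center of all visited points, intersects the
line with the bounds to get the feasible segment, jumps to a uniform
point on it, and updates the center. Recorded samples are thinned
(default 100 × the number of free dimensions per recorded sample, capped
so the total step count never exceeds the hard ceiling of $10^{10}$),
and `n_samples` defaults to 10,000 recorded points.

Numerical choices that proved load-bearing:

* **Drift control.** Every `projection_period` (default 50) recorded
  samples, both the state *and the running center* are re-projected onto
  the affine solution set of $Sv = 0$ via an orthonormal null-space
  basis. Projecting only the state is not enough: off-subspace error
  stored in the center re-enters every direction and grows
  geometrically.
* **No clamping after projection.** The projected state can sit
  $O(10^{-12})$ outside a bound; clamping it back would push it off the
  subspace and can wedge the chain in a corner where every segment is
  empty. The excursion is left alone — the next accepted step moves back
  inside — and all samples are validated against a 10⁻⁶ tolerance.
* **Zero-width pinning.** Fixed exchanges often force *internal*
  reactions onto a knife edge: their feasible range has width ~0 while
  their declared bounds stay wide. Such reactions are detected from the
  FVA ranges and pinned to the range midpoint before sampling, so they
  are treated as fixed dimensions rather than producing empty segments.
* Direction vectors with norm < 10⁻¹² are resampled (100 consecutive
  failures ⇒ the polytope is declared degenerate and its unique point is
  returned); segment components below 10⁻¹² are treated as zero; steps
  landing on a bound are inset toward the interior by 10⁻¹².

Correctness is checked against two independent oracles, both in the test
suite and recomputed by `scripts/acceptance.R`: on a one-free-dimension
chain the through-flux must be uniform on its FVA interval
(Kolmogorov–Smirnov at α = 0.01, mean 5 ± 0.15, variance 8.33 ± 0.5 at
n = 10,000), and on a two-free-dimension branch split the per-reaction
means and variances must match `rejection_sample()` — an exactly uniform
rejection sampler over the orthonormal null-space parameterization,
guarded to ≤ 4 free dimensions — within 5 Monte-Carlo standard errors.
Sampling is bit-reproducible given a seed: the compiled core draws from
R's RNG, so `set.seed()` governs.

## Comparison statistics

**Median rankings.** For each reaction the per-strain sample medians are
summarized by their range (max − min over strains), which for scalars
equals the largest pairwise absolute difference; the top k = 20 by this
spread, ties broken lexicographically for determinism, form the
shortlist of fluxes that most distinguish the strains. The percent
variant divides by the magnitude of the grand median, floored at
`min_abs_flux`; reactions whose largest absolute median falls below
10⁻¹² mmol gDW⁻¹ h⁻¹ are excluded outright — such miniscule fluxes are
numerically meaningless and would dominate any relative ranking. The
top-20 set computed at the early time point is reused for the later ones
(`rank_at`), so the same reactions are tracked across the fermentation.

**PCA with cos2.** `pca_with_cos2()` runs centered, by default
unit-variance-scaled PCA (SVD) on an observations × variables flux
table — in the pipeline, strains × measured extracellular fluxes per
time point. The squared cosine of a variable on a component is its
squared correlation with that component; summed over all components it
is exactly 1 for scaled PCA, an identity the tests assert to 10⁻⁹.
Observation cos2 is the squared score over the squared distance to the
origin in centered space. Constant variables are rejected by name when
scaling (the pipeline drops constant columns before calling, since a
flux identical across strains carries no comparative signal).

**Clustergrams.** `cluster_strains()` uses distance
$1 - \rho_{\mathrm{Pearson}}$ between strain median vectors over a
reaction subset (by default the top-20 list), with average linkage;
correlation makes the grouping invariant to positive rescaling of any
strain's vector. A reaction-standardized variant was considered and
rejected: for strains that are biologically identical, standardized
residuals are pure noise, so correlating them *destroys* exactly the
similarity the statistic should detect. The dendrogram exports as Newick
(`cluster_newick()`), the merge structure via `tidy()`, and
`first_merge()` names the most similar pair.

**Histograms.** `histogram_report()` bins each selected reaction on a
range shared across strains and normalizes frequencies to 1 per strain,
the direct numerical analogue of per-reaction sampling-distribution
plots; `plot_flux_histograms()`, `autoplot()` on PCA and clustering
results render the standard figures.

## The synthetic benchmark: what it emulates, and what it does not

Because suitable multi-strain enological time courses are not publicly
deposited, the package ships a first-class generator.
`build_toy_wine_network()` is a ~24-reaction, fully mass-balanced wine
network: glucose → hexokinase → lumped glycolysis → pyruvate; an
ethanol branch (pyruvate decarboxylase + alcohol dehydrogenase, each
with a parallel isoenzyme so the constrained polytope keeps sampling
volume — the biological analogue being PDC1/PDC5/PDC6 and ADH
isoforms); a glycerol branch; an Ehrlich branch per amino acid
(transaminase with a parallel isoform, 2-oxo-acid decarboxylase, fusel
aldehyde dehydrogenase, fusel alcohol exchange); acetyl-transfer ester
synthesis; and an oxygen-requiring heme A synthesis feeding the biomass
pseudo-reaction — so the anaerobic recipe is *needed* to make the model
grow without oxygen, exactly as in the genome-scale case.

`simulate_strain_timeseries()` integrates, per strain on a 2 h grid to
144 h, phase-wise constant specific rates with growth phases
exponential → deceleration → stationary (boundaries 36 h and 58 h,
evaluation times 24/58/144 h). Within a phase the biomass follows the
exact exponential $X(t+\Delta t) = X e^{\mu \Delta t}$ and each
concentration accumulates the exact integral
$C(t+\Delta t) = C + qX(e^{\mu \Delta t}-1)/\mu$ (limit $qX\Delta t$ at
$\mu = 0$). Exact integration, rather than an explicit-Euler update, is
deliberate: it makes the midpoint estimator's relative error
$O((\mu\Delta t)^2)$ — about 0.17% at μ = 0.05 h⁻¹ and Δt = 2 h — where
Euler compounding would bias it by $\mu\Delta t/2 \approx 4.5\%$; and it
gives all noise-free flux and growth estimates a *common* attenuation
factor $\sinh(\mu\Delta t)/(\mu\Delta t)$, so noise-free constraint sets
are exactly mass-balance-consistent and feasible at band 0 (asserted for
all 12 benchmark strain × time combinations).

Exchange rates are derived from pathway-level parameters (glucose
uptake, glycerol fraction, per-branch amino-acid uptakes, ester rate,
growth rate) through the network's steady-state balances, so every
planted rate vector is feasible by construction.

**Noise model.** Every biomass and concentration reading gets
multiplicative Gaussian noise truncated at ±3 CV (keeping readings
positive). The default `noise_cv = 0.001` was calibrated from the
estimator's noise amplification: at must-strength glucose
(~1100 mmol/L), a 2 h grid and exponential-phase biomass ~1 gDW/L, a CV
of 0.1% propagates to roughly 10–15% relative error on the large
central-carbon fluxes (and ~1% on the VOC fluxes, whose concentrations
change proportionally faster). That is the regime in which derived
constraint fluxes remain individually interpretable, which is the
premise of the whole comparison; a CV much above this drowns the
glucose-scale fluxes in differencing noise regardless of how well the
rest of the pipeline works. A CV of 0.1% corresponds to
replicate-averaged chromatographic assays — optimistic for a single
injection, reasonable for averaged triplicates.

**The four-strain benchmark** (`make_benchmark_scenario()`): strains 1
and 2 share every rate (the similar pair); strain 3 runs its Ehrlich
branch at 3× amino-acid flux; strain 4 has half the VOC rates and 1.3×
the glucose flux (low-aroma, high-central-carbon). Ground truth — the
planted reactions, fold changes, and expected first merge — is returned
alongside. End-to-end recovery (planted Ehrlich reactions in the top-20
absolute ranking; first merge = strains 1+2) is asserted over three
seeds at n = 2,000 samples per condition.

What the benchmark does *not* emulate — and therefore what passing tests
do not show about real data: replicate-to-replicate biological
variation; lag phases and diauxic shifts; compartmentalized metabolism
and cofactor balancing (the toy network is carbon-skeleton only);
sampling schedules sparser than 2 h; correlated or heteroscedastic
measurement error; and genome-scale dimensionality (a constrained
Yeast-GEM polytope has hundreds of free dimensions, where mixing is far
slower — the sampler's thinning heuristic scales with free dimensions,
but convergence on genome-scale models should be checked with the
warning-only mean-split diagnostics — `sampling_diagnostics()`, logged
per condition in the run manifest — not assumed. The diagnostic's
z-score uses an iid standard error, so residual autocorrelation
inflates it; read it as a relative mixing indicator, not a calibrated
test).

## Problem sizes and determinism

The shipped test and acceptance runs use n = 10,000 samples on the
analytic polytopes and n = 2,000 per strain × time point on the
benchmark (12 polytopes, 3–8 free dimensions each), sizes at which the
whole suite completes in a few minutes on one core. All randomness —
noise generation, warmup, chain, rejection oracle — flows from
`set.seed()`; pipeline re-runs with the same configuration and seed
produce bitwise-identical sample files, which the manifest's MD5
checksums make easy to verify. Per-condition sampler seeds are derived
from the master seed, so conditions are independent but reproducible.

## Known limitations

* The LP kernel is a dense two-phase bounded-variable simplex intended
  for desk-scale networks (tens to a few hundred reactions); FVA on a
  full genome-scale model would want a sparse solver.
* Reconciliation weights unmeasured fluxes with a negligible ridge
  penalty, which breaks QP degeneracy but mildly prefers small
  unmeasured fluxes among equally-fitting solutions.
* The SBML writer targets the toy scale (full-model SBML writing is out
  of scope); the reader handles Level 3 with fbc bounds/GPRs and
  groups-based subsystems.
* No ellipsoidal rounding (CHRR-style) is applied before hit-and-run;
  for strongly anisotropic genome-scale polytopes that transform would
  improve mixing and is the natural next step.
* Median-difference rankings are descriptive; no significance testing
  is attached to them.
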