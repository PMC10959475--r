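---
title: "Catastrophic mutation accumulation and the evolution of senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catastrophic mutation accumulation and the evolution of senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senaccum)
```

## The model and its assumptions

`senaccum` studies the fate of age-dependent dominant lethal mutations in a
*stationary*, density-regulated population. Stationarity is the load-bearing
assumption: recruitment into the adult population exactly compensates
mortality, so lifetime reproductive success (LRS) equals one at all times.
The analytic layer adds the standard simplifications of this literature —
extrinsic mortality μ independent of age, fecundity F independent of age,
age at first reproduction `x_min` (default 0) — so that age-specific
reproductive success is k(t) = F·e^(−μt) on [x_min, X], where X is the
maximum age at death imposed by the earliest lethal mutation already fixed.
Stationarity pins the fecundity to F = μ/(e^(−μ·x_min) − e^(−μX)): the
earlier the wall of death, the higher the compensating recruitment.

A mutant lethal at age x with fecundity multiplier α has
LRS_mut = α·∫ k(t) dt over [x_min, x], and selection coefficient
s(x) = LRS_mut − 1, increasing from −1 (death before any reproduction) to
α − 1 (death at the current maximum age). A deleterious mutation drifts to
fixation when purging selection is weaker than drift, s(x) > −1/Ne
(`Ne > 1`); `critical_age()` solves s(x̂*) = −1/Ne in closed form. Two
consequences drive everything else:

* **x̂\* < X whenever it exists.** Compensatory recruitment after each
  fixation tilts the age distribution towards the young and weakens
  selection on later-acting mutations, so each fixation enables an earlier
  one. `iterate_accumulation()` iterates X ← x̂*(X); without pleiotropy the
  trajectory converges to `x_min` — the population evolves towards
  semelparity.
* **A mutation can invade at *some* age iff α > (Ne−1)/Ne.** Below that
  fecundity, purging wins at every age; at the boundary we break the tie
  conservatively (strict inequality: a mutation exactly at the drift
  barrier does not invade).

When mutational effects can occur only at ages spaced a grain δ apart
(`grained_accumulation()`), the iteration halts as soon as no grid age lies
in (x̂*(X), X). The halt age lands in the closed-form interval returned by
`equilibrium_interval()`, whose width is exactly δ; *which* age inside the
interval is realized depends on the grid phase, which is why the grid
anchor is exposed as an argument rather than guessed.

## Numerical choices

Closed forms are used wherever they exist; the critical-age expression is
grouped as (e^(−μ·x_min)(α−1−τ) + (1+τ)e^(−μX))/α (τ the invasion
threshold) to avoid cancellation at large Ne. An infinite current maximum
age is represented as `Inf` and takes the e^(−μX) → 0 branch explicitly,
never a large-number sentinel. The general-`x_min` equilibrium interval is
found with `uniroot` at tolerance 1e−12; the independent oracles used in
the tests (quadrature of k, grid search over s, bisection on
X − x̂*(X) = δ) run at absolute tolerance 1e−10. The sequential iteration
stops when X − x_min falls below `stop_tol` (default 1e−6 age units) —
near x_min the per-step decrement shrinks like X/Ne, so the exact stopping
rule matters only for how long the tail of the trajectory is, not where it
goes. `critical_age()` returns `NA_real_` (not an error) when no age can
invade, because that regime is a legitimate model outcome.

## The individual-based simulator

The simulator realizes the same biology with genuine drift: `N` diploid
individuals, dominant mutations at dynamically created loci, each locus
carrying an expression trigger (an age on a grid, or a somatic stage),
an effect (lethal, or an increment `d` added to the per-step death
probability), and a fecundity multiplier. Each step applies, in order:
extrinsic deaths (probability 1 − e^(−μ·dt)), expression deaths, somatic
stage advance, then recruitment — vacancies are refilled by offspring of
two distinct parents sampled with weight equal to the product of their
carried multipliers, with Mendelian transmission, per-allele reversion at
rate `reverse_rate`, and at most one new mutation per offspring
(probability `U`, trigger uniform on the grid). With `F_max` finite,
recruits are capped at `F_max`·(alive)·dt and the census can decline;
extinction is declared below 2 individuals. Without reverse mutation,
fixed loci are folded into population-level state (lethals into the
"wall", the minimum fixed trigger), which keeps the genotype table small
over long runs; with reverse mutation every locus stays tracked because
fixation is revocable. The core loop is C++ (Rcpp) driven by R's RNG, so
runs are bit-reproducible from `seed`.

### What the default conditions emulate

The defaults are chosen once to put the simulator in the regimes the
theory distinguishes, at sizes a single CPU handles comfortably:

* `N = 300`, with Ne taken equal to the census when comparing against the
  analytic layer — an acknowledged approximation (overlapping generations
  make the true Ne somewhat smaller), not a calibration.
* `mu = 0.46` (as in the package's small worked examples): a generation
  then spans only ~2.2 steps, so a neutral fixation sweep (~4Ne
  generations ≈ 2,600 steps) completes several times inside a 6,000-step
  horizon. The horizon was set from that sweep-time argument, not tuned.
* `U = 0.02` keeps tens of loci segregating — enough mutational supply for
  sequential fixations without the bookkeeping dominating runtime.
* `max_expr_age = 40` ≈ 3·ln(N)/μ, so a genuinely neutral "beyond any
  attainable age" region exists and the first fixations build a wall from
  above, as in the theory.
* Fine versus coarse grain is `age_grid_delta = 1` (one step) versus `5`,
  mirroring a day/year contrast: the fine grid declines towards its
  (low) grained equilibrium throughout the horizon, the coarse grid halts
  visibly at the analytic interval.
* The capped-recruitment scenario starts already senescent (`X0 = 6`) with
  `F_max = 0.62` offspring per parent per step. At these rates a
  *nonsenescent* population needs a per-survivor recruitment fraction of
  0.369/(1−0.369) = 0.584 and is sustainable, while a wall at age 6 needs
  0.394/(1−0.394) = 0.649 and is not: the cap binds precisely because of
  the fixed lethal burden, and every replicate collapses. Starting at a
  finite wall stands in for the end state of an accumulation phase that
  would otherwise take ≥10⁵ generations to simulate, since near a wall X
  the invadable window shrinks like X/Ne.
* The reverse-mutation scenario uses `reverse_rate = 1e-5` per allele per
  meiosis. The recorded wall requires strict fixation (every allele
  mutant); with ~100 recruits per step, a reversal rate r injects ~0.2·r·10³
  wildtype lineages per step, each persisting ~2·ln(2N) generations, so
  rates much above 1e−5 keep every locus permanently polymorphic and the
  statistic undefined rather than testing whether *rare* reversions stop
  the decline. At 1e−5 roughly one reversion arises per sweep — present
  but rare, which is the regime of interest.

### What passing simulations do and do not show

The IBM shares the analytic model's idealizations: well-mixed mating, no
linkage (each locus transmits independently), no spatial or stage
structure beyond the optional somatic stages, fecundity constant in age,
and mutational effects that are either fully dominant lethals or simple
mortality increments. Agreement between the simulator and the closed forms
therefore validates the *logic* of the feedback — compensation, weakened
purging, sequential fixation, grain-dependent halting — under those
idealizations. It does not show that real populations collapse to
semelparity: real mutational effect distributions, pleiotropy structures,
and the somatic triggers that discretize expression ages are exactly the
features the grained and somatic modes caricature with a single parameter.
The somatic mode (`stage_advance_prob`) makes expression contingent on a
stochastic internal stage; at rate 1 it reduces exactly to the
age-triggered model, at rate p the mean trigger age scales like 1/p, which
is the one-parameter version of "deleterious effects are triggered by
somatic change, not by time itself".

## Design decisions that were genuinely open

* **Iteration rule.** Each invading mutation is taken to be lethal exactly
  at the current critical age; an `offset` argument provides the
  "slightly above" variant (default 0).
* **Grid anchoring.** Grained expression ages sit at `x_min + j·δ`;
  the anchor is an argument because only the spacing, not the phase, is
  part of the model.
* **Multiplicative pleiotropy across loci** in the IBM (weights multiply);
  the analytic α is defined per single mutation, so any cross-locus rule
  is a modeling choice.
* **Concurrent segregation.** The IBM allows many loci to segregate at
  once; sequential fixation is the analytic idealization, not enforced.
* **Increment semantics.** Whether a nonlethal mutation raises mortality
  from its trigger age onward or only at that age is configurable
  (`increment_mode`), since both readings are defensible; the default is
  "onward".
* **Extinction threshold** at census < 2 (no mating pair).

## Problem sizes used by the test suite

The analytic identities are checked exactly (tolerances 1e−10 to 1e−12)
and against 1,000 random parameter draws for the grid-search oracle.
The simulator batteries use N = 300 with 20 replicates per scenario and
horizons of 3,000–6,000 steps, and the neutral-drift control uses 10⁴
replicates at N = 20, checked against the exact binomial interval around
the 1/(2N) fixation probability. These sizes were chosen so the whole
suite runs in a few minutes while keeping every qualitative contrast
(decline vs. halt vs. collapse) far from its decision boundary.

## Known limitations

* Ne is an input, not an emergent property; the feedback studied here
  operates through the selection gradient at fixed Ne, deliberately
  excluding mutational-meltdown dynamics (shrinking populations amplifying
  drift) except transiently in the capped-recruitment scenario.
* The closed forms assume k(t) = F·e^(−μt); arbitrary reproductive-success
  schedules are supported only through the quadrature oracles in the test
  suite, not as a public API.
* The grained equilibrium interval predicts *where* accumulation halts,
  not the waiting time to reach it; IBM halt ages are compared to the
  interval ± δ because drift can fix a final mutation on either side of
  the analytic boundary age.
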