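---
title: "Connectivity or size change? IICR modelling with nisland"
author: "nisland package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity or size change? IICR modelling with nisland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(nisland)
```

## The problem

PSMC-style methods take the genome of a single diploid individual and return
a trajectory that is routinely read as "effective population size through
time".  What these methods actually estimate is the IICR — the inverse
instantaneous coalescence rate of the sample,

$$\mathrm{IICR}(t) = \frac{P(T_2 > t)}{f_{T_2}(t)},$$

where $T_2$ is the coalescence time of the two sampled gene copies.  Under
random mating the IICR *is* the size trajectory $N_e(t)$.  Under population
structure it is not: a perfectly constant-sized metapopulation whose
connectivity changes produces an IICR indistinguishable in kind from a
history of expansions and bottlenecks.  `nisland` implements both readings
of a curve and the machinery to fit, simulate and cross-check the structured
one.

## The model

The structured model is the symmetric n-island coalescent, made
*piecewise-stationary*: `n` demes of constant diploid size `N`, with scaled
migration rate $M = 4Nm$ (the `ms` convention: expected number of immigrant
gene copies per deme per coalescent time unit, divided by 2 per lineage)
held constant within each of `c` time components and changing at ages
$t_1 < \dots < t_{c-1}$ (coalescent units of $2N$ generations, present = 0).

For two lineages the ancestral process is a three-state Markov chain —
same deme (S), different demes (D), coalesced (C) — with rates (per $2N$
generations): S→C at 1, S→D at $M$, D→S at $M/(n-1)$.  Within a component
the S/D sub-generator is 2×2 with real distinct eigenvalues, so the package
propagates the state distribution in closed form (no numeric matrix
exponential, no step-size tolerance); at each change time the distribution
is handed to the next component's generator exactly.  The IICR in
coalescent units is $(p_S + p_D)/p_S$, and $N$ times that in diploid-Ne
units.  Useful exact checks fall out of the chain:

* panmixia (`n = 1`) gives a constant IICR equal to `N`;
* $t \to 0$ with same-deme sampling gives `N` (only within-deme pairs can
  coalesce immediately);
* $M \to \infty$ gives the constant $nN$;
* for any single-component scenario the within-deme mean of $T_2$ is
  exactly `n`, independent of $M$.

All of these are asserted in the test suite, the last one against an
independent numerical integration of the survival function.

```{r exact}
sc <- island_scenario(n_islands = 20, deme_size = 1000,
                      change_times = 1, migration_rates = c(10, 0.5))
curve <- exact_iicr(sc, make_log_grid(500, 5e5, 64, unit = "years"))
plot(curve)
```

The sampling configuration defaults to `same_deme` — the two alleles of one
diploid individual, which is what a PSMC analysis sees.  The migration
convention and the sampling default are package choices; published analyses
in this area typically do not state either, and both are pinned here by the
Monte-Carlo cross-check below rather than by any external program.

## Monte-Carlo pathway and its estimator

`sample_t2()` simulates the same chain directly: exponential waiting times
with the current component's rates, truncated at each component boundary and
resumed — exact by memorylessness, no time-rescaling needed.  The default
sample size is 100,000 draws, the size used to produce well-estimated
empirical IICR curves.

`empirical_iicr()` turns draws into a curve by a discrete hazard on a log
grid.  With empirical survival $\hat S$, the value attributed to
$[t_k, t_{k+1})$ is

$$\frac{(t_{k+1}-t_k)\,(\hat S_k + \hat S_{k+1})}{2(\hat S_k - \hat S_{k+1})}.$$

The *central* (midpoint-corrected) form is deliberate: the one-sided
estimator $\hat S_k (t_{k+1}-t_k)/(\hat S_k - \hat S_{k+1})$ carries a
first-order discretization bias of half the interval width — about 10% at
the coarse end of a typical 64-point grid — while the central form's bias
is second order.  Kernel smoothing was rejected: a step-function estimator
matches the step nature of PSMC targets and introduces no bandwidth choice.
Empty intervals are merged rightward until they contain events.

When the exact and empirical pathways are compared (`iicr_mc_check()`), the
comparison is restricted to intervals holding at least 1200 events.  That
floor is derived from the agreement band the check is used with: the
binomial standard error of a bin with $e$ events is roughly
$1/(\sqrt{e}\,\ln 10)$ log10 units, so 1200 events place the 0.05-log10
band at four standard errors — outside that region the statistic would
measure shot noise, not disagreement.  The suite requires a maximum
absolute log10 ratio below 0.05 across random scenarios at 100,000 draws;
observed values are typically 0.01–0.03.

## PSMC input and output

`read_psmc()` parses the standard `.psmc` text dialect (RD/TR/RS records,
last block = final iteration), `scale_psmc()` applies the usual rescaling
$N_0 = \theta_0 / (4\mu s)$ (with $s$ the 100-bp binning, configurable,
since published analyses rarely state it), step starts
$2 N_0 t_k g$ years, sizes $N_0 \lambda_k$.  Defaults are the mouse-lemur
constants used throughout: $\mu = 1.2\times10^{-8}$ per site per
generation and $g = 2.5$ years.  `write_psmc()` and `make_psmc_fixture()`
invert the mapping so that any known history — panmictic or structured —
can be encoded as a synthetic `.psmc` document whose truth is fully known;
fixtures built from an `island_scenario` sample its exact IICR at the
geometric midpoint of each atomic interval of a `-p` pattern such as
`"4+25*2+4+6"` (64 intervals).

## Fitting connectivity-change scenarios

`fit_islands()` is the modelling core: given a target curve in (years,
diploid Ne) — a rescaled PSMC curve, a simulated IICR, or an empirical one
— it searches for the scenario $(n, N, t_i, M_i)$ whose exact IICR
minimizes the mean squared difference of log10 values over a comparison
grid.  The log10 distance reflects how these curves are actually read: on
log-log axes spanning several decades in both time and size.

Numerical choices that matter:

* **Quadrature.** Smooth targets are compared on a 64-point log grid
  spanning the target's support.  Step targets are compared once per step,
  at the step's geometric centre: a fixed log grid evaluated
  right-continuously against a 64-step curve quantizes apparent transition
  times by up to one atomic interval (15–20%), which would swamp the 10%
  change-time tolerance used in validation.
* **Search.** A seeded, bound-constrained differential evolution in log10
  space for $N$, $t_i$ (parameterized in years, so the time boxes are
  interpretable) and $M_i$, with the integer deme count relaxed to a
  rounded coordinate.  Population 20 per free dimension, 400 generations
  by default, mutation factor dithered on $[0.5, 1]$ per mutation, and
  stall-triggered full restarts (80 stagnant generations) that set the
  incumbent aside — multi-component landscapes contain genuine local traps
  that a single population can collapse into.  Every restart decision is a
  deterministic function of the trajectory, so a run is exactly
  reproducible from its seed and a longer budget replays a shorter one:
  doubling `iters` can never worsen the result.
* **Degenerate inputs.** Candidates whose chain has numerically vanished
  (survival below $10^{-12}$) anywhere on the grid receive a large
  penalty; ties in sorted change times (measure zero, but reachable by
  rounding) are nudged apart; a fitted `n = 1` collapses cleanly to the
  panmictic constant.

The component count `c` is fixed per run, as in published applications of
this approach; `fit_components_sweep()` reports distance against `c` but
deliberately applies no penalized selection rule, because none is
established for this distance.

One symmetry is worth stating precisely.  The model family is *not* closed
under scaling the curve values alone: `N` pins both the vertical scale
(IICR(0+) = N, strong-migration plateau nN) and the time scale (coalescent
units are 2N generations).  The family's exact symmetry multiplies values
and times jointly by $k$, mapping $(n, N, t_i^{(coal)}, M_i)$ to
$(n, kN, t_i^{(coal)}, M_i)$; the fitter is equivariant under that joint
scaling, and the suite asserts it.

## Validation by re-inference

A fit is only as trustworthy as it is recoverable.
`validate_by_reinference()` regenerates the exact IICR of the fitted
scenario, refits from a fresh seed, and compares parameters: deme count
within ±1, deme size and migration rates by relative error (10% / 20%),
change times on the log scale (10%).  These default tolerances are package
choices — no published values exist — and are configurable.  The expected
failure mode is informative: under strong migration the IICR approaches
$nN$ and the deme count and deme size trade off freely, so near-panmictic
fits fail re-inference and are flagged as weakly identified rather than
trusted.

## The two readings, side by side

`iicr_as_ne_history()` is the panmictic reading: step starts become epoch
starts, values become Ne, nothing else.  `interpretation_report()` runs
both readings against the same target with the same distance and ranks
neither — that refusal is the point.  For any structured scenario with at
least one genuine connectivity change, the panmictic reading of its exact
IICR is non-constant: the suite checks >1% variation in 100/100 random
scenarios drawn with adjacent migration rates differing by at least a
factor 2 and $M \le 5$.  Both restrictions are part of what "genuine
change" means here: in the strong-migration limit every island model's
IICR tends to $nN$, so arbitrarily small contrasts between large rates
cannot be required to leave a 1% signature.

Climate-window annotations (LIG ~132–112 kyr, LGM ~26.5–19 kyr, AHP ~15–5
kyr) can be attached to reports as labels; they are never used in
computation.

## Synthetic data and what passing tests mean

`random_scenario()` draws valid scenarios from configurable ranges
(defaults: n 2–100, N $10^2$–$10^6$, c 1–8, M 0.05–50, change times
0.01–20 coalescent units, all log-uniform), with optional separation
constraints.  `noisy_target()` produces targets with no noise, with
finite-sample noise (the empirical IICR of a T2 sample — correlated across
the grid the way real estimation noise is, and the default), or with iid
log-normal perturbation.  `study_preset()` provides six-component
templates whose change ages (129.1, 42.7, 30.7, 13.7, 5.1 kyr and 338.9,
135.6, 27.1, 20.1, 7.9 kyr) and deme counts (84, 61) follow the published
mouse-lemur fits; their deme size (1000) and alternating migration rates
(0.5/5) were never published and are illustrative only.

The recovery experiments draw from an *identifiable regime* chosen a
priori: adjacent migration rates differing by ≥3×, change times separated
by ≥4×, n between 4 and 30, M between 0.5 and 5.  Outside that regime
recovery is not expected — near-equal adjacent rates make the change time
between them meaningless, and strong migration collapses $(n, N)$ onto
their product — and the re-inference check exists precisely to catch such
cases on real targets.

What the synthetic generator does *not* emulate: recombination-limited
information (finite genomes give PSMC far fewer independent $T_2$ draws
than 100,000 at old time depths), HMM discretization artefacts at the
recent edge (the "humps" reported for real curves), sequencing error and
coverage effects.  A pipeline that passes every test here can therefore
still be wrong about a real genome in ways those factors control; what the
tests do establish is that the chain, the simulator, the estimator, the
format handling and the optimizer are mutually consistent and that the
central structural confound is real, reproducible and quantifiable.

## Problem sizes

The suite and the acceptance script run the experiments at the sizes the
methods are designed around: 100,000-draw T2 samples for oracle
comparisons (5 random scenarios), 10 recovery cases at 2–3 components with
re-inference, 100 scenarios for the spurious-size-change property, and
64-point grids throughout.

## Known limitations

* Asymmetric or stepping-stone structure, per-deme sizes, per-epoch sizes
  and samples larger than two lineages are out of scope.
* Mixed scenarios (simultaneous size and connectivity change) are not
  fitted; the two readings are alternatives, not a joint model.
* The distance is a fitting criterion, not a likelihood; no model
  comparison across component counts is asserted.
* Change times pushed below the target's support, or rate changes between
  two already-large migration rates, are structurally unidentifiable; the
  re-inference verdict is the guard, not the optimizer.
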