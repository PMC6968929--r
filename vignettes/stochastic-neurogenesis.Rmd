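---
title: "Models and methods for pyramidal-cell lineage analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for pyramidal-cell lineage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pclineage)
```

## The data and its conventions

A lineage (clone) is the set of labelled pyramidal cells descended from one
tagged ventricular-zone progenitor, summarised as neuron counts in cortical
layers II/III, IV, V and VI. Layer I holds no pyramidal cells and is never
represented. Internally the canonical layer order is the *generation*
(inside-out) order VI, V, IV, II/III — deep layers are produced first — and
every external table uses explicit column names (`l23`, `l4`, `l5`, `l6`)
so that column order is never semantically loaded. Counts are strict
non-negative integers, and blank cells are errors rather than zeros: a zero
is a meaningful observation (it feeds the censoring rule below), so it must
be stated, not imputed.

Clones with fewer than 3 cells arise from labelling a postmitotic neuron or
an intermediate progenitor, and clones with more than 12 cells predominantly
reflect symmetric proliferative divisions; `neurogenic_filter()` implements
this 3–12 window. One- and two-cell clones are kept in the tables (they are
informative in their own analyses) and the floor is applied only where an
analysis calls for it. For MADM data, `split_madm_lineage()` labels clones
with three or more cells in *each* reporter as symmetric divisions, clones
of one or two cells in total as excluded, and the remainder — the
informative ones — as asymmetric neurogenic.

## The permutation null

`permute_dataset()` pools every neuron as a layer label, shuffles the pool
uniformly, and refills clones of the original sizes in the original order.
Per-layer totals and the clone-size multiset are conserved *by
construction*, and the analysis loop asserts this on every repeat rather
than trusting it. The refill order is immaterial — any exchangeable refill
induces the same distribution — but is fixed (original order, sequential
draws) for reproducibility.

Two numerical points are worth noting. First, the null ensemble's
superficial–deep correlation is not centred exactly at zero: with clone
sizes fixed, a clone that receives more superficial neurons must receive
fewer deep ones, leaving a mild mechanical anti-correlation whose size
depends on the spread of clone sizes. The meaningful comparison is
therefore observed-versus-ensemble, which `run_permutation_analysis()`
reports as mean ± sd per statistic with a flag when the observed value
falls outside mean ± 2 sd (the 2-sd threshold is this package's choice of a
conventional flag, not a hypothesis test). Second, with `n_repeats = 1` the
standard deviation is undefined and reported as `NA` with no flags raised.

## The Dirichlet-process binomial mixture

The generative model: each lineage *i* is assigned a progenitor type
`t[i]` drawn categorically with frequencies `f`; each layer count is then
`S[i,j] ~ Binomial(N_max, p[t[i], j])` with `N_max = 20`, the cap on
neurons per layer per clone. The joint log-likelihood implemented in
`dp_log_likelihood()` is

```
sum_t n_t log f_t +
sum_{i,j} sigma[i,j] * ( S[i,j] log p[t_i,j] + (N_max - S[i,j]) log(1 - p[t_i,j]) )
```

The binomial coefficient is deliberately omitted: it is constant in
`(t, p, f, K)` given the data, so the posterior is unaffected; keeping the
implementation equal to the model definition makes the likelihood directly
checkable term by term.

**Censoring.** A clone's most superficial empty layers, when not followed
(more superficially) by an occupied layer, may be spurious zeros — an
external process (premature terminal division, progenitor death) can stop
a lineage before those layers are generated. `selection_mask()` therefore
scans each row from II/III toward VI and masks empty layers until the
first occupied layer is reached; every layer from there on is kept,
including interior zeros, which *are* informative. A fully empty row is
fully masked, kept in the dataset (it still contributes prior terms to the
clustering), and reported with a warning.

**Priors and sampler.** Occupancy probabilities get a Beta(a, b) prior
(default the flat Beta(1,1)); the number of types is governed by a
Dirichlet process with concentration `alpha` (default 1); both are
configurable in `gibbs_config()`. Sampling uses auxiliary-component
(algorithm-8 style) Gibbs updates with `n_aux = 3` fresh candidates per
assignment, which lets the chain remove existing types and introduce new
ones. One bookkeeping rule matters for correctness: when an update empties
a singleton type, that type's parameter vector is retained as the first
auxiliary candidate rather than discarded — dropping it biases the
stationary distribution, which is detectable against the exact two-lineage
partition posterior (a test does exactly this). Conjugacy makes the `p`
update exact: Beta(a + Σ σS, b + Σ σ(N_max − S)) over each type's members.

Defaults are 4000 retained draws after a burn-in of 1000; the inference on
datasets of a few hundred clones mixes well within a fraction of that.
Type frequencies are represented implicitly by the occupied-type counts
(`f = n_t / N` in the recorded draws). Degenerate probabilities never raise
errors in the likelihood: an extreme `p` contradicted by a count yields
`-Inf`, and a consistent extreme contributes 0.

**Validation strategy.** Three independent oracles pin the sampler down:
(i) with everything censored the K-distribution must match
Chinese-restaurant-process closed forms (mean `Σ alpha/(alpha+i)`);
(ii) with two lineages the partition posterior is computable exactly from
CRP weights and Beta-binomial marginal likelihoods; (iii) on synthetic
data from `generate_occupancy_dataset()` with two well-separated types
(`p` deep-biased versus superficial-biased, N = 200), the modal posterior
K must be 2 and the posterior-mean `p` within ±0.05 of truth across
seeded replications. Censoring introduces a small, quantifiable upward
bias in layers where true `p` is low (zeros get masked when terminal);
at `p = 0.05`, `N_max = 20` the conditional mean shifts `p̂` to ≈ 0.078,
comfortably inside the ±0.05 recovery band.

**Posterior predictive.** `posterior_predictive()` draws new clones by
sampling a posterior draw, a type, and binomial layer counts, then applies
the same 3–12 filter used for experimental comparisons, so predictive and
observed datasets are filtered identically (whether to filter modelled
clones was an open choice; symmetric treatment is the defensible one).

## The sequential simulator

`simulate_lineage()` is the literal sequential process: layers in
generation order; per layer an opportunity count drawn uniformly on
`1..M[j]`; per opportunity, interruption with probability `q` *before* the
generation attempt, terminating the entire remaining lineage, otherwise a
neuron with probability `P[j]`. Interruption-before-generation and
whole-lineage termination are this package's reading of premature terminal
division/death semantics; the order is documented because it is not forced
by the narrative.

`simulate_model()` uses an exactly equivalent vectorised engine: the index
of the first interrupting opportunity is Geometric(q), so the number of
surviving opportunities per layer is a deterministic clamp, and counts are
binomial over surviving opportunities. The two routes are compared
distributionally in the tests (chi-square on clone sizes, layer means
within Monte-Carlo error); closed forms anchor both: with `q = 0` the
expected count in layer j is `P[j] * (M[j] + 1) / 2` and layers are
independent.

When fitting real data, the opportunity caps `M` default to the maximum
count observed for each layer in any single clone across the pooled
experiments (`opportunity_caps()`); for synthetic work they are explicit
spec fields.

**Fitting.** `fit_model()` minimises the sum of squared model–data
z-scores over the four laminar fractions, the clone-size histogram bins
(as per-repeat fractions) and, when provided, the three class fractions.
The search is coordinate descent with a shrinking step over the free
parameters (`P` per type, `q` per type, and the population share for
two-type templates), using a fixed evaluation seed — common random
numbers — so that candidate comparisons are not drowned in simulation
noise. Standard deviations in the objective are floored at 1e-3 to keep
z-scores finite for rarely-populated histogram bins. The fit report's
final z-scores are recomputed at the template's full repeat count with an
independent seed. Self-consistency (fitting a known model's own summaries
back from a neutral start, reaching |z| < 2 on every tracked statistic) is
part of the acceptance tests.

**z-scores.** `zscore()` is `|mean(sim) − observed| / sd(sim)` with the
sample (n−1) standard deviation across simulation repeats; values above 1
mean the model–data distance exceeds repeat-to-repeat variability. The
correlation statistic uses neuron *counts* per compartment by default
(`fractions = TRUE` switches to per-clone fractions); both conventions
appear in the literature, and the choice is exposed rather than hidden.

## The synthetic benchmark

`synthetic_preset()` defines a two-population generator used throughout
the tests: a majority type (62%) producing larger translaminar clones
centred near eight cells, and a minority type (38%) producing small
superficially biased clones centred near four cells, both with a 2%
per-opportunity interruption chance. The parameter values are this
package's own choices, fixed once to give the benchmark the qualitative
structure the analyses target — a bimodal clone-size distribution with
modes near 4 and 8, a majority of translaminar clones with both restricted
classes present, and a clearly negative superficial–deep correlation
(about −0.25 at large n).

What the preset emulates: mixture of progenitor types, sequential
inside-out generation with per-layer opportunity windows, probabilistic
interruption, and the resulting size/configuration structure. What it does
not emulate: cortical-area differences, cell death after neurogenesis,
intermediate-progenitor amplification, spatial structure, and measurement
noise in layer assignment. Tests passing on the preset therefore validate
the *statistical machinery* — classification, conservation, inference,
recovery — not any biological claim about real lineage data.

`generate_occupancy_dataset()` is the matching generator for the Bayesian
model (direct binomial sampling from known `(p, f)`), with one RNG
substream per lineage spawned from the master seed so that enlarging a
dataset never perturbs the lineages already generated.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at sizes chosen to make
their statistical assertions sharp but cheap: 1e5 draws for closed-form
simulator checks (3-standard-error bands), 1000 permutation repeats,
10,000 post-burn-in sweeps for CRP prior recovery (batch-means standard
errors, since sweeps are autocorrelated), 20 seeded replications of the
two-type recovery run at N = 200 with 600 retained draws each, and
coordinate-descent fits with 30 evaluation repeats of 100 progenitors.
Fraction outputs are asserted to normalise to 1 at 1e-12; probabilities
inside the sampler are clamped to [1e-12, 1 − 1e-12] purely as a log-guard.
Occupancy counts above `N_max` are errors, never clamped. Chi-square
versus Fisher switching follows the standard rule (Fisher for 2×2 tables
or any expected cell below 5), which is a documented package convention.

## Known limitations

- The Gibbs sampler is plain auxiliary-component CRP sampling; no
  split–merge moves. On well-separated types this is ample; heavily
  overlapping types at small N will mix slowly.
- The censoring rule is deterministic and row-wise; it does not model the
  interruption process itself (the sequential simulator does that).
- `fit_model()` is a local search: with a deliberately poor template it
  can stop in a local minimum. The common-random-numbers design makes the
  objective deterministic given the seed, so restarts are cheap and
  reproducible.
- Subtype analyses assume categorical Ctip2/Satb2 calls; marker-intensity
  modelling is out of scope, and superficial-layer cells with
  non-canonical marker combinations are conservatively left unclassified
  (clones containing unclassified cells are excluded from the diversity
  summary and counted in its `n_excluded` attribute).
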