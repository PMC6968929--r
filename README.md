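# pclineage

Quantitative clonal analysis of pyramidal-cell (PC) lineages in the
developing neocortex.

Clonal lineage-tracing experiments (retroviral labelling, MADM, genetic
fate-mapping) record, for each tagged ventricular-zone progenitor, how many
pyramidal cells its clone placed in cortical layers II/III, IV, V and VI.
Two questions drive the analysis: how heterogeneous are the laminar
configurations of individual clones, and how many distinct progenitor
behaviours are needed to explain them? `pclineage` provides the complete
analysis chain for such data:

- **Classification and filtering.** Clones are classified as translaminar
  (cells in both the deep V–VI and superficial II/III–IV compartments),
  deep-restricted or superficial-restricted; by their laminar configuration
  (the 15 possible presence/absence patterns over four layers); and, with
  Ctip2/Satb2 marker calls, into projection subtypes (CCPN, SCPN, CThPN,
  HPN). Standard filters: the 3–12-cell neurogenic window, and the MADM
  symmetric/asymmetric division rules.
- **Permutation null.** Neurons are shuffled among clones while each neuron
  keeps its laminar identity and each clone keeps its size, preserving by
  construction the clone-size distribution and the per-layer totals. What
  survives this scrambling (and what does not — e.g. the superficial–deep
  anti-correlation) tells you which features are genuine lineage structure.
- **Bayesian inference of progenitor types.** Layer-occupancy counts
  `S[i,j]` are modelled as a mixture over progenitor types `t`, with
  `S[i,j] ~ Binomial(N_max = 20, p[t,j])` and a censoring mask σ that
  excludes each clone's most superficial empty layers not followed by an
  occupied layer (such zeros may reflect an externally interrupted lineage,
  not a true generation probability). A Dirichlet-process prior with Gibbs
  sampling (auxiliary-component updates) yields a posterior over the number
  of types K, the occupancy probabilities `p` and the type frequencies `f`.
- **Sequential stochastic simulator.** In-silico progenitors generate
  neurons layer by layer in the inside-out order VI → V → IV → II/III. In
  each layer the progenitor receives a uniformly drawn number of
  opportunities (1..M per layer); at each opportunity the lineage is
  interrupted with probability `q`, otherwise a neuron is added with the
  layer-specific probability `P`. One population defines Model 1, a
  majority/minority pair defines Model 2. A fitting loop tunes `P`, `q` and
  the population share to match target laminar fractions, clone-size
  histograms and class fractions, scoring candidates by model–data
  z-scores `|mean(sim) − observed| / sd(sim)` across simulation repeats.

## Worked example

A small synthetic demonstration table ships with the package (50 clones in
the standard schema `lineage_id, method, area, age, l23, l4, l5, l6`):

```r
library(pclineage)

demo <- read_lineage_table(system.file("extdata",
  "demo_synthetic_lineages.csv", package = "pclineage"))
summarize_lineages(demo)
#> Lineage summary (50 lineages)
#>   cells per layer (%): II/III 25.8, IV 15.2, V 29.2, VI 29.8
#>   classes (%): translaminar 74, deep-restricted 6, superficial-restricted 20
#>   superficial-deep Spearman r: -0.102
```

Three quarters of the clones are translaminar and the rest are restricted
to one compartment; clones that place more cells superficially tend to
place fewer deep (negative Spearman r). The permutation null shows the
anti-correlation is a lineage-level feature, not a by-product of layer
densities:

```r
pr <- run_permutation_analysis(demo, n_repeats = 1000, seed = 7)
pr$observed[["spearman_r"]]                       # -0.102
pr$perm_mean[["spearman_r"]]                      #  0.143 +/- 0.107
pr$flagged[["spearman_r"]]                        #  TRUE
```

The observed correlation sits more than two null standard deviations below
the permutation ensemble. Fitting the Dirichlet-process binomial mixture
asks how many progenitor types the occupancy patterns demand:

```r
fit <- run_inference(demo, gibbs_config(n_draws = 2000, burn_in = 500,
                                        seed = 7))
progenitor_count_distribution(fit)
#>     2     3
#> 0.983 0.017
```

98% of posterior draws use two occupied types — consistent with the
two-population process that generated this dataset
(see `synthetic_preset()`).

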