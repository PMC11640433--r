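---
title: "Measuring groupness: models, permutation machinery and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring groupness: models, permutation machinery and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupness)
```

This vignette is the package's own account of its methods: the
statistical model behind each step, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made.

## From point samples to associations

The sampling unit is the *instantaneous focal point sample*: at a fixed
instant, the identity of a focal animal and of every individual within a
proximity threshold (its neighbours) is recorded; a focal with no
neighbour is a solitary sample. The observation design the defaults
emulate follows each individual for 18 ten-minute follows sampled at
1-minute intervals, i.e. 180 point samples per individual (3 h each; 61
individuals across two groups gives 183 h and 10,980 periods).

Each point sample is one *sampling period* and one row of the
group-by-individual (GBI) matrix; follows are not collapsed, because the
instantaneous sample — not the follow — is the association record.
Under the **gambit of the group**, the focal and its neighbours form one
observed group whose members are treated as pairwise associated. This is
the standard resolution for focal-centred proximity data, and it is an
assumption: associations between two neighbours of the same focal are
inferred, not observed. All supplied point samples are pooled, including
any periods in which an individual appears only as a neighbour of
another focal; nothing in the data distinguishes "incidental" from
"scheduled" observations once pooled, and pooling uses all information.

Dyadic association is summarised by the **simple ratio index**

$$\mathrm{SRI}_{ab} = \frac{x}{y_a + y_b + y_{ab} + x},$$

the proportion of periods the pair spent together among periods in which
either was seen. Periods where neither was identified ($y_{Null}$) carry
no information about the dyad and are excluded by assumption — adding
such periods leaves every SRI unchanged (a property the test suite
checks). Under single-focal sampling each period holds one observed
group, so "both identified but not associated" ($y_{ab}$) cannot occur
and is structurally zero; the counting code nevertheless handles periods
containing several observed groups, in which case $y_{ab}$ becomes
informative.

Two deliberate conventions:

* **Never-identified dyads score 0, not `NA`.** A dense matrix keeps all
  downstream metric code total; the dyads are flagged in the matrix's
  `never_identified` attribute and counted in the pipeline's run log, so
  the information is not silently lost. Semantically, "never seen
  together because never seen" and "seen apart whenever seen" both mean
  *no evidence of association*, which is what a zero index encodes.
* **Mean association rates average over unordered dyads, zeros
  included, with sample (n − 1) SD.** A single mean ± SD over all dyads
  of the mixed-species network is the headline association statistic; a
  species-pair filter (`within_species_dyads`, `mixed_species_dyads`)
  restricts the summary to a dyad class when the contrast itself is of
  interest.

## The weighted network and its metrics

An edge joins two individuals when their SRI exceeds a threshold
(default 0: any observed association is a tie), weighted by the SRI.
The default threshold is deliberately permissive — with thousands of
sampling periods even rare co-occurrence creates a tie, and the SRI
weight, not the tie's existence, carries the strength information.
Raising the threshold is the exploratory knob for sociogram structure
(the README example uses 0.05 to expose the species cliques), and every
analysis records which threshold produced it.

Per-node metrics follow the conventions of the mixed-species network
literature this package is aligned with:

* **Degree** is the binarized tie count, not summed edge weight: a mean
  degree of 17.8 among 26 possible partners is interpretable as "ties to
  two-thirds of the group", which is the reading the species-comparison
  tables rely on. Mean degree over all nodes always equals density
  times (n − 1), an identity the tests verify on every network.
* **Eigenvector centrality** is computed on the *weighted* adjacency and
  rescaled so the maximum is 1. On a disconnected network the
  computation runs on the full matrix, so the component with the
  dominant eigenvalue carries essentially all mass and the other
  components score near zero. That is a real property of eigenvector
  centrality, not an artefact — it is exactly how two species-cliques of
  unequal internal association strength show up as a large species
  contrast — but it means per-component comparisons need care, which is
  why the value is documented here rather than patched per component.
* **Betweenness** is the unnormalized count of shortest paths through a
  node, with tied geodesics given equal fractional credit.
* **Clustering** is the local unweighted coefficient on the binarized
  network; nodes with fewer than two neighbours have no defined
  coefficient (`NaN`) and are excluded from species means rather than
  imputed.

**The geodesic convention deserves emphasis.** Path-based metrics
(betweenness, average path length) take the *SRI weight itself* as the
edge length: a geodesic is the path minimising the sum of tie weights,
and path lengths are on the SRI scale. This matches the sociogram
convention the package mirrors, where the geodesic distance is described
as the sum of the weights of ties along the shortest path — but it makes
strongly associated dyads "far apart", the opposite of the more common
1/weight convention. Both are available (`path_weight = "sri"` is the
default, `"inverse"` the alternative); conclusions about *which* species
bridges a network can flip between them, so reports should state the
convention.

## Permutation inference

### Data-stream randomization

Association data violate the independence assumptions of classical
tests twice over: dyads share individuals, and individuals differ in how
often they were observed. The data-stream permutation addresses both by
randomizing the GBI itself with checkerboard swaps — find periods $p, q$
and individuals $A, B$ with $A$ only in $p$ and $B$ only in $q$, and
exchange them. Row sums (group sizes) and column sums (observation
counts) are conserved exactly, so the null retains each individual's
gregariousness and the sampling effort, destroying only *who* associates
with *whom*. The implementation runs a serial chain; the statistic is
recorded every `swaps_per_iteration` swaps after `burn_in` swaps.

The chain's tuning is not something the underlying method prescribes, so
the defaults follow common practice for serial swap chains and are
recorded in every result: `burn_in = 1000` swaps (many multiples of the
number of periods' worth of mixing before the first draw),
`swaps_per_iteration = 10` (successive draws differ by several swaps;
they remain autocorrelated, which is expected — the chain as a whole,
not any single draw, represents the null), `iterations = 1000`.

The headline use is the mean association rate. One subtlety argues for
testing the *mixed-species* mean SRI directionally rather than the
overall mean: the total number of co-occurrences is invariant under
swaps, so randomization mostly *redistributes* association from the
abundant within-species dyads to the rare mixed dyads. For assortative
data the mixed-dyad mean SRI therefore sits far below its null (the
"less mixed-species association than chance" claim, lower-tail p), while
the overall mean responds only through the nonlinearity of the index.
The pipeline reports both tests.

### Node-label permutation t-tests

Species differences in node metrics are tested by shuffling species
labels across individuals: the observed statistic is the difference in
species means (first roster species minus second), and each iteration
recomputes it under a random reassignment. For small groups
`method = "exhaustive"` enumerates all $\binom{n}{n_1}$ assignments and
returns the exact permutation p-value; the test suite holds the sampled
and exhaustive routes against an independent enumeration oracle.

p-values follow the *proportion equal-or-more-extreme* rule (ties count
as extreme, with a $10^{-12}$ tolerance so recomputed floating-point
means do not break exact ties). The raw proportion can be 0 at finite
iterations, read as "below 1/iterations"; the add-one corrected
$(b+1)/(N+1)$ versions, which cannot be 0, are always reported
alongside, and results record which convention a number came from. The
metric-difference tests are two-tailed; directional p-values are
attached for the claims that are directional (association lower than
chance). With four metrics per group the family-wise alpha 0.05 is
Bonferroni-adjusted to 0.0125, and the pipeline flags each test against
the adjusted level.

Calibration is tested, not assumed: under a null with no species effect
the sampled label test rejects at 0.05 within Monte-Carlo error
(500 replicates at 200 iterations each in the acceptance suite), and
with a large injected difference its power exceeds 0.95.

### Reproducibility contract

Every stochastic entry point takes a seed and restores the caller's RNG
state afterwards; identical seed and inputs give bit-identical results,
and `run_analysis()` derives per-test sub-seeds deterministically from
its root seed, which is written to the run log and every serialized
result.

## The synthetic focal-sampling generator

The generator exists so the full pipeline — file dialects, GBI
construction, SRI, metrics, both permutation schemes — can be exercised
and calibrated without observational data. It emulates the *sampling
design* (round-robin focal schedule, 18 follows × 10 samples per
individual by default, West-like 18 + 9 and East-like 17 + 17
compositions) over a latent dyadic model: a same-species dyad is in
proximity in any given sample with probability `p_within = 0.15`, a
mixed dyad with `p_between = 0.01`, optionally modulated by lognormal
per-individual gregariousness multipliers (mean 1), a clique split
within one species, and a shared-space gate that multiplicatively
suppresses mixed dyads only (emulating species that rarely co-use the
shared enclosure).

The default probabilities encode the strong species assortativity the
mixed-species exhibits showed — an order of magnitude between
within-species and mixed association, at per-sample rates that yield
mean SRIs of a few hundredths to ~0.1, the magnitude typical of
proximity-based primate networks. They were chosen once, as the
generator's definition of "realistic assortative data", and the
parameter-recovery checks run against them: with these defaults the
pipeline recovers within > mixed mean SRI in every seed and the
directional mixed-association randomization test is significant in
essentially every run.

What the generator does *not* emulate, and hence what passing tests do
not show about real data:

* **Group coherence.** Neighbours join the focal independently
  (Bernoulli per dyad per period); real groups cohere beyond the focal,
  so real GBIs have more large-group periods than the generator's
  binomial neighbour counts.
* **Spatial and temporal structure.** No enclosure geometry, zone
  occupancy, diurnal rhythm or social dynamics over time; samples are
  exchangeable by construction.
* **Observation error.** No misidentification, no out-of-sight
  censoring (the real protocol abandons focals out of sight for more
  than three minutes).

For the homogeneous model (`gregariousness_sd = 0`), `expected_sri()`
computes the plug-in approximation $E[x]/(E[x]+E[y_a]+E[y_b])$ from the
schedule and the dyad-class probabilities. It is an approximation — the
expectation of a ratio is not the ratio of expectations — and the test
suite uses it with a 0.02 tolerance against a 200-replicate Monte-Carlo
mean, which is ample at 360 periods per dyad.

## Numerical and interface choices

* Association-matrix symmetry is exact by construction (`crossprod`),
  and the brute-force equivalence tests for SRI and all network metrics
  use a $10^{-9}$ absolute tolerance.
* Identifier matching is case-sensitive after whitespace stripping; two
  point-sample CSV dialects are accepted (long per-individual rows,
  canonical; per-period neighbour-list rows) and are parsed to the same
  canonical tibble.
* Groups are always analyzed as separate networks; nothing pools across
  group labels.
* The package's interface is its functions: `run_analysis()` is the
  one-call pipeline, `analyze_deposit()` the wrapper from deposited
  CSVs to headline numbers, and the `tidy()`/`glance()`/`autoplot()`
  methods the reporting layer, so an analysis is a short R script
  rather than a shell invocation. `run_analysis(output_dir = ...)`
  writes the archival bundle (association matrix CSV, GraphML and edge
  list, node metrics, species summary, JSON test results, run log with
  seed and settings).

## Problem sizes used by the test and acceptance suites

Chosen as the package's own trade-off between evidence and turnaround:
oracle equivalence runs 1000 random instances at ≤ 6 nodes (exhaustive
path enumeration is exact there); margin conservation runs 10,000
swaps; type-I calibration runs 500 null replicates at 200 iterations;
parameter recovery runs the full 18 × 10 design for both compositions
over 10 runs with 1000-iteration randomization tests. The acceptance
script runs the complete pipeline once per composition at the full
design size.

## Known limitations

* The gambit of the group over-connects large observed groups; with a
  single observer and focal-centred sampling this is unavoidable and
  standard, but SRIs between two frequent neighbours of the same third
  individual are partly inferred.
* Eigenvector centrality's all-or-nothing behaviour across components
  (above) makes its species contrast discontinuous in the edge
  threshold near the point where a network disconnects.
* The data-stream null conditions on the observed margins; effects that
  live in the margins themselves (one species simply observed in
  smaller groups) are by construction not testable with it.
* p-values from the serial swap chain treat autocorrelated draws as a
  sample of the null; this is the standard practice the method follows,
  but raw proportions at small `iterations` are coarse.
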