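---
title: "Mapping co-activation networks from regional immediate early gene counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping co-activation networks from regional immediate early gene counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

## The problem

Brain-wide immediate early gene (IEG) mapping quantifies the density of
Fos- or Egr-1-positive nuclei in each of many brain regions, one number
per region per animal. Because each animal contributes a single snapshot,
functional connectivity cannot be computed within subjects as in fMRI;
instead it is estimated **across subjects**: two regions are functionally
coupled when their activity co-varies over the animals of a group. From a
region x subject table (here: positive nuclei per 10,000 square
micrometres; typically 84 regions and 8 subjects per experimental group)
the pipeline computes all pairwise inter-regional correlations, keeps the
strongest positive ones, and characterizes the resulting graph.

`fosnet` implements that workflow end to end, together with synthetic
cohort generators whose planted covariance structure provides ground
truth for every stage.

## From correlations to networks

With `n` subjects, the sample correlation `r` relates to Student's t by
`t = r sqrt((n-2)/(1-r^2))`. Inverting at the upper one-tailed quantile
gives the critical value used for thresholding:

```{r}
critical_r(0.005, n = 8)
```

Three tiers are used throughout: low (`alpha = 0.01`, `r >= 0.7887` at
n = 8), primary (`0.005`, `0.8343`) and high (`0.0025`, `0.8697`),
matching the convention of thresholding an 8-subject correlation matrix
at an uncorrected one-tailed significance level. Edges are the defined,
positive correlations at or above `r_crit` (the boundary is inclusive);
negative and undefined correlations never form edges, and all regions
stay in the node set so nodes may be inactive (degree 0). Zero-variance
regions are flagged undefined rather than raising errors, and are
excluded from thresholding and block means.

A note on Spearman networks: rank-based networks use the same numeric
threshold as the Pearson tier rather than a Spearman-specific critical
value. This mirrors standard practice for these data; the trade-off is
that the nominal significance level of a rank correlation at the same
cutoff differs slightly.

## Graph characterization

All averaged measures are computed on **active** nodes (degree >= 1) of
the binary topology; edge weights are kept only for export.

* Segregation: mean clustering coefficient `C` (per-node triangle density,
  0 for degree < 2), transitivity `T` (3 x triangles / connected
  triples), and local efficiency `E_loc` (mean global efficiency of each
  node's neighbour subgraph).
* Integration: characteristic path length `L` (mean shortest path over
  reachable pairs) and global efficiency `E_glob` (mean inverse shortest
  path over all pairs, unreachable pairs contributing zero — which is why
  `E_glob` is preferred when networks fragment).
* Centrality: degree and unnormalized betweenness with fractional
  attribution over tied shortest paths (Brandes accumulation). Whether
  the original toolbox split ties is not documented anywhere we know of;
  tie-splitting only matters ordinally for hub ranking.
* Degree assortativity: the Pearson correlation of endpoint degrees over
  the directed edge list; undefined (NA) on degree-regular graphs.

Every metric is validated in the test suite against brute-force
enumeration oracles (explicit BFS, path enumeration, triangle counting)
on all 208 non-isomorphic graphs with up to six nodes.

## Null models and uncertainty

Two sources of reference variation are kept strictly separate:

* **Topological nulls**: 1000 degree-matched random networks produced by
  repeated double-edge swaps (default `swap_factor = 10` attempted swaps
  per edge, a standard mixing heuristic; the matched ensemble preserves
  every node's degree exactly). Connectedness is not enforced.
* **Sampling uncertainty**: subjects are resampled with replacement
  (default 1000 replicates), the correlation matrix recomputed, the
  network re-thresholded at the *original* `r_crit` (the threshold is not
  adapted to the replicate's effective sample size), and the metric
  recomputed; the 2.5th/97.5th percentiles give the 95% CI.

The small-world decision compares the bootstrapped CI of the observed
metric against the ensemble-averaged null value: a network is reported
as small-world-like when clustering is reliably above the null mean
while global efficiency is statistically indistinguishable from it. The
full null distribution is retained, so comparisons against the ensemble
interval are also available; note, however, that the rewiring ensemble's
interval for a global metric of an 84-node graph is extremely narrow
(width on the order of 0.01), so *any* genuinely clustered network sits
below it in global efficiency — locally redundant edges always cost some
path efficiency. The bootstrap-versus-null-mean comparison is the one
with a meaningful operating characteristic at n = 8.

A related caution: thresholded correlation networks built from
**null data** are not Erdos-Renyi. Sample correlations are transitive
(conditional on `r_ij` and `r_ik` being large, `r_jk` is elevated), so
even noise-only cohorts produce graphs with a real clustering excess
over their degree-preserving rewirings. Claims of small-worldness in
correlation networks should therefore always be read against this
baseline artifact; in the package's own calibration tests the
no-excess property is verified on true Erdos-Renyi graphs, not on
null-cohort correlation networks.

## Clustering and hubs

`mcl_cluster()` implements the Markov Cluster Algorithm on the binary
adjacency of active nodes with self-loops added before column
normalization (standard MCL practice): expansion (matrix squaring)
alternates with inflation (entrywise power, default 2.6, then column
renormalization) until the maximum entry change falls below `1e-6` or
200 iterations. Clusters are read from the attractor structure of the
limit matrix; a node attracted to several attractor systems goes to the
lowest-indexed cluster (an arbitrary but deterministic tie-break), and
inactive nodes form singleton clusters. The algorithm is deterministic,
never merges connected components, and is run on the binary graph because
thresholding has already reduced the topology to near-binary; both the
weighted/binary choice and the self-loop convention are assumptions the
original analyses leave open.

`identify_hubs()` ranks active nodes by degree and betweenness within
each threshold tier; the percentile of a node is the fraction of active
nodes with a strictly lower value (ties share a percentile, so a
degree-regular network has no node above the 0th percentile). Candidate
hubs must exceed the cutoff percentile (default 80) in **both** measures
in **all** tiers.

`attack_simulation()` removes active nodes sequentially — uniformly at
random (averaged over repetitions) or in descending order of original
degree (static order, ties broken by region order) — and re-measures the
largest connected component. "Complete disintegration" defaults to a
largest component of at most two nodes, a configurable operationalization
since no numeric criterion is standard.

## Group comparisons

* `block_mean_contrast()` bootstraps subjects within each group to put a
  95% CI on the difference between block mean correlations (unique
  off-diagonal pairs when the block is square); a difference is flagged
  reliable when the CI excludes zero.
* `compare_matrices_permutation()` shuffles subject-to-group labels,
  recomputes every pairwise correlation difference, and reports one-sided
  exceedance p-values in the observed direction with add-one smoothing
  (`p = (#exceedances + 1)/(n_perm + 1)`, never exactly zero), followed
  by Benjamini-Hochberg control at the 5% level across all R(R-1)/2
  pairs. Significant pairs are reported split by direction.

The one-sided exceedance convention follows the original description of
the procedure (counting permutation statistics that exceed the observed
one); with the discreteness of smoothed permutation p-values, BH at
q = 0.05 over thousands of pairs essentially never rejects on null data,
which the calibration tests confirm.

## Partial least squares

Task PLS uses the **mean-centered** variant: the condition x region
matrix of condition means is column-centered at the grand mean across
conditions and decomposed by SVD. Each latent variable (LV) pairs a
design salience (condition contrast) with a unit-norm region salience
pattern at a non-negative singular value. Mean-centering is the standard
variant for condition-contrast designs of this kind.

Seed PLS stacks, for every condition and seed region, the raw
correlation vector between the seed and all regions (no Fisher z, no
centering) and decomposes the stack. With two conditions the leading LV
typically carries the map common to both conditions (anchored by the
seed's self-correlation of 1) and the second LV the condition-specific
coupling.

Inference follows the permutation/bootstrap scheme: LV significance by
shuffling subject-to-condition assignment (default 500 permutations,
add-one p on each singular value), salience reliability by resampling
subjects within condition (default 500 replicates), aligning each
replicate's LV signs to the original by the sign of the dot product
(adequate in the 1-3 LV regime; a full Procrustes rotation would matter
only under heavy LV reordering), and reporting bootstrap ratios
BSR = salience / bootstrap SE with |BSR| >= 3 as the reliability cutoff.
Sign indeterminacy of the SVD never affects |BSR| or permutation p.

## The synthetic cohorts

`synthetic_spec()` defines a one-factor-per-module Gaussian model:
region i of module m has activity
`x = baseline + group shift + lambda_i f_m + eps`, with subject-level
module factors `f_m` and iid noise (`sd = noise_sd`). Within a module the
expected correlation has the closed form
`lambda_i lambda_j / sqrt((lambda_i^2 + sigma^2)(lambda_j^2 + sigma^2))`,
which the generator tests verify at n = 10,000 to within 0.02. Hubs carry
additional loadings on other modules' factors; one region's loadings can
be sign-flipped to plant a negatively coupled region (the analogue of an
anterodorsal-thalamus-like observation: a region that consistently
anticorrelates with its network and therefore never forms edges in
positive-threshold networks). Optionally all module factors share a
global component (`factor_correlation`), emulating the brain-wide common
activation that couples anatomical modules in real IEG data; without it,
no planted structure can make an 84-region network both clustered and
integrated at the r >= 0.83 threshold, because a region can be strongly
correlated with several mutually orthogonal blocks only up to the
variance budget `sum u^2 <= 1`.

Negative values are truncated at zero (densities are counts). Truncation
biases correlations when a region's mean is within a few SDs of zero, so
the presets lift every baseline to at least five **total** (factor +
noise) SDs — the total SD matters: a strongly loaded hub region has
`sd ~ lambda`, not `sigma`.

Four presets freeze the study conditions used by the tests and the
acceptance script (all with 8 subjects per group, mirroring the
eight-animal groups of brain-wide Fos studies):

* `spec_modular()` — three orthogonal 20-region modules with
  within-module correlation 0.94 plus independent background; the MCL
  recovery benchmark. Strong loadings are needed because at n = 8 two
  module factors correlate by chance at a level that occasionally
  bridges modules; with these settings MCL at inflation 2.6 recovers
  the planted partition (adjusted Rand >= 0.9) in essentially all
  cohorts.
* `spec_fearlike()` — a 12-region core (three hub regions with stronger,
  cleaner loadings), eighteen 3-region satellites, factor correlation
  0.55, a negatively coupled region, background regions, and a
  genotype x delay group design with an additive core activation in the
  remote-delay wild-type-like group. Used for the small-world benchmark.
* `spec_star_core()` — one near-noiseless hub on a 24-member blob plus
  twenty 2-region "dumbbell" modules whose members are active at degree 1
  and betweenness 0, anchoring the percentile ranking; the hub-recovery
  benchmark.
* `spec_assortative_core()` — twenty high-loading core regions forming a
  planted rich club plus sixteen 4-region satellites; the attack
  resilience benchmark.

### What the generator does and does not emulate

The factor model reproduces the features the pipeline is sensitive to —
block correlation structure, hubs, group mean shifts, a global
activation component, zero truncation — but not others present in real
data: counts are Gaussian rather than overdispersed-Poisson, factors are
shared exactly within a module, there is no spatial autocorrelation
between anatomically adjacent regions, and no per-animal staining or
batch covariate. Passing tests therefore demonstrate that the pipeline
recovers known structure under an idealized but fair generative model,
not that any particular biological claim holds.

### A design note on hub recovery at n = 8

Planting a hub that lands above the 80th percentile in *both* degree and
betweenness in *all three* tiers in nearly every cohort turns out to be
impossible in this model class, for two structural reasons worth knowing
about. First, correlation matrices are positive semidefinite: if many
regions correlate strongly with a hub they must correlate with each
other, so the sparse star topology that would pin betweenness on the hub
cannot be expressed at thresholds of r >= 0.79-0.87. Second, with eight
subjects the sampling SE of a correlation is about 0.45 on the z scale,
so a few periphery regions overtake the planted hub in betweenness in a
minority of cohorts no matter how clean its loading is. The
`spec_star_core()` design maximizes recovery (around 70-80% of cohorts);
the acceptance materials report the achieved rate rather than forcing
it. On any single real dataset this instability is invisible — one
realization yields one hub set — which is exactly why the multi-tier
consistency requirement exists in the first place.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and restores the
caller's RNG state. The pipeline derives per-stage seeds by hashing the
master seed with the stage name, so adding a stage never perturbs
another stage's draws, and a fixed master seed reproduces every output
byte for byte.

The packaged benchmarks run at the study's native scale — 84 regions,
8 subjects, 1000-network null ensembles — with 20 cohort replicates per
property, 300 bootstrap replicates for the small-world CIs, 200-500
permutations for calibration checks, and 200 replicate cohorts for the
p-uniformity test; these sizes give Monte-Carlo error comfortably below
the decision margins of each property.

## Worked example

```{r example}
spec <- spec_fearlike(seed = 1)
cohort <- generate_cohort(spec)
corr <- pairwise_correlations(cohort$wt_1d)
net <- build_network(corr, threshold_spec(0.005, 8, "primary"))
net
segregation_metrics(net)$C
integration_metrics(net)$E_glob
nd <- null_distribution(net, "clustering", ensemble_size = 200, seed = 2)
nd
part <- mcl_cluster(net)
part
```

The observed clustering sits far above the degree-matched ensemble while
the partition recovers the planted core and satellites; the full
per-group pipeline (`run_pipeline()`) writes these results, the hub
report, attack curves, matrix comparisons and PLS tables as
tab-delimited files with a JSON manifest.

## Known limitations

* Across-subject correlation networks confound co-activation with any
  shared subject-level covariate; the pipeline quantifies, but cannot
  de-confound, such structure.
* Thresholded binary topology discards correlation magnitude beyond the
  cutoff; weighted-graph metric variants are out of scope.
* Permutation comparisons assume exchangeable subjects under the null;
  groups measured with different baselines or variances violate this
  (the test suite demonstrates how a baseline offset between groups
  makes every relabelled statistic degenerate).
* MCL on graphs of this size needs no sparse-flow optimizations; the
  implementation is dense and deliberately simple.
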