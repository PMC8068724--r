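---
title: "Rich-club analysis of structural connectomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rich-club analysis of structural connectomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it
implements: the network model and its assumptions, the parameters that
matter, what the synthetic cohort generator does and does not emulate,
and the numerical and design decisions taken where the methodology
leaves room.

## From tractography output to binary networks

The input unit is a symmetric nonnegative N x N matrix of connection
weights per subject (streamline counts from deterministic tractography,
or FA-weighted variants), with node identity given by an atlas table
(the bundled table covers the 90 cortical/subcortical AAL regions).
`ConnectomeMatrix` validity enforces symmetry within 1e-9, a zero
diagonal and unique node identifiers; file input tolerates asymmetries
up to 1e-6 (averaged away) and refuses anything larger as presumably
directed data.

Two thresholding steps turn weights into graphs:

* **Streamline filter** (`streamlineFilter`, default 3): entries at or
  below the threshold are zeroed; the inequality is strict, so a count
  of exactly 3 is removed.  This is the usual guard against spurious
  low-count connections from tractography noise.
* **Sparsity binarization** (`sparsityBinarize`): sparsity is the ratio
  of retained edges to the N(N-1)/2 possible ones, applied as an edge
  count E = round(s * N(N-1)/2) keeping the E strongest weights.  Ties
  at the cut rank are broken by lexicographic node-pair order - an
  arbitrary but reproducible rule; with continuous weights ties are
  measure-zero, with integer streamline counts they do occur and the
  rule makes runs identical.  When fewer than E nonzero weights exist
  the function keeps all of them, warns, and records the achieved
  sparsity.  Binarizing a binary graph at its own sparsity is a no-op.

Because group comparisons at a single arbitrary sparsity are fragile,
metrics are swept over s = 0.05 to 0.20 in steps of 0.01 (16 levels,
`sparsitySweep`) and summarized by the area under the metric-vs-sparsity
curve (`integrateCurve`).  Integration is trapezoidal; a plain
sum-times-step variant sits behind `method = "sum"` for compatibility
with tools that integrate that way.  The sweep warns when the mean
degree 2E/N at the lowest sparsity does not exceed ln(N) - the usual
lower guideline for stable small-world estimation; note that at N = 90
and s = 0.05 the mean degree is 4.44 against ln(90) = 4.50, so the
guideline is advisory, not a hard gate, and the warning never aborts.

## Graph metrics and their null model

Global metrics (`globalMetrics`): mean local clustering C (vertices of
degree < 2 contribute 0), characteristic path length L over connected
pairs only, global efficiency E_g (mean inverse shortest path length;
disconnected pairs contribute 0, which also makes isolated nodes
harmless), local efficiency E_loc (efficiency of each open
neighborhood), and modularity Q.  Normalized variants divide by the
mean over `nRandom` (default 1000) degree-preserving rewired networks:
gamma = C/C_rand, lambda = L/L_rand, sigma = gamma/lambda.  The null
generator is Maslov-Sneppen double-edge swapping (10 x E swap attempts
per network) - it preserves every node's degree exactly, so sigma
measures structure beyond the degree sequence.  All stochastic steps
take a seed and are bit-reproducible.

The disconnected-pair conventions deserve a word: infinite distances
are excluded from L and contribute zero to efficiencies.  This is the
harmonic-mean-style convention that keeps metrics finite on graphs with
isolated vertices, which do occur at the sparsest thresholds.

Nodal metrics (`nodalMetrics`): degree Dc, nodal efficiency
Ne(i) = mean over j of 1/d(i,j), and betweenness Bc, unnormalized and
with even splitting across tied shortest paths.  Bc normalization is a
presentation choice; the raw counts are reported and any rescaling is
left to the caller.

Modularity maximization uses deterministic greedy agglomeration; since
the trivial single-community partition always attains Q = 0, a greedy
result with Q < 0 (which the agglomerative cut can produce on highly
regular graphs) is replaced by that trivial partition.  Tests verify
the greedy optimum against exhaustive partition search on small
structured graphs, and the returned Q against the direct
sum_c (e_cc - a_c^2) formula on random graphs.

Small-worldness compliance (`smallWorldCheck`) flags subjects whose
sigma at the maximum sparsity is at or below 1.1 but never drops them:
the check is a report, and what to do with flagged subjects is a study
decision.

The hemispheric asymmetry index (X_L - X_R)/(X_L + X_R) is positive
for leftward asymmetry, antisymmetric in its arguments, bounded by
[-1, 1], and returned as NA with a warning when both sides are zero.

## Rich club, hubs and edge classes

Phi(k) is the edge density among nodes of degree strictly greater than
k; it is undefined (NA) when fewer than two nodes qualify, and once
undefined it stays undefined for larger k.  `richClubProfile`
normalizes against the same degree-preserving null ensemble
(Phi_norm(k) = Phi(k) / mean null Phi(k)); because rewiring preserves
degrees, the definedness pattern is identical across nulls and the
per-k permutation p-value uses the add-one estimator
(1 + #{null >= observed})/(1 + nRandom), which cannot return zero.  The
profile stores the longest contiguous k-range with Phi_norm > 1 and
p < 0.05 as the significant regime.

Hubs are identified on a group-average network - an edge survives when
present in at least 80 % of subjects' binarized graphs (boundary
inclusive; occurrence 1.0 is the intersection).  The default hub rule
is degree strictly greater than k*, with k* the smallest k of the
significant regime; a mean + SD degree rule is available
(`rule = "meanSD"`).  The regime-minimum rule is deliberately
permissive - the bottom of a well-powered regime sits near the mean
degree, so the hub set can exceed a tightly planted core while still
containing it; analyses that need a sharper core should raise k* or use
the mean + SD rule.  When hub sets are needed across several groups the
pipeline computes them per group and intersects ("common hubs"), the
reading consistent with hubs shared by all individuals; a pooled
average network is equally supported.

Given hubs, every edge is rich (hub-hub), feeder (hub-non-hub) or
local (non-hub-non-hub) - a partition by construction, with
proportions by edge count and strengths summing the supplied weights.
Weighted class strengths over the sweep restrict the subject's
pre-binarization weights to the edges surviving each threshold, then
integrate the per-class curves.

## Inference

Permutation tests (`permTest`) residualize the metric on an intercept
plus covariates, then permute group labels (residualize-then-permute;
Freedman-Lane-style schemes agree to first order at these sample sizes
and the simpler scheme matches common practice in connectome toolboxes).
Covariates are never permuted; sex enters as a 0/1 column.  The
statistic is the mean difference for two groups (two-sided) or the
one-way F for more; p-values use the add-one estimator.  Node-level
control is Bonferroni with strict inequality p < alpha/N (0.05/90 at
the defaults).  Partial correlation residualizes both variables and
refers t = r sqrt(df/(1-r^2)) to df = n - n_cov - 2.

The network-based statistic (`nbs`) runs pooled-variance two-sample t
tests on every (residualized) edge, thresholds at p < p_edge (default
0.01), finds connected components of supra-threshold edges, and
assigns each component the family-wise p-value: the fraction of
label-permuted cohorts whose *largest* component reaches the observed
size.  Component size is the edge count (extent statistic) by default;
the intensity statistic (sum of exceedances |t| - t_crit) is an option.
Edges with zero variance (absent everywhere) are never supra-threshold;
an effect with literally zero within-group variance but different means
is treated as infinitely significant.  Defaults follow the
10 000-permutation, p < 0.01 convention; all three knobs
(p_edge, n_perm, and the component-level alpha applied by the caller)
are explicit configuration because published analyses vary them.

## Circuits

Six depression-related circuits (default mode, salience, negative and
positive affect, attention, cognitive control) are shipped as a YAML
config over AAL-90 labels, transcribed from the circuits' standard
anatomical descriptions; the file is deliberately editable and flagged
as approximate - region membership at atlas granularity is a judgment
call, and circuits overlap (the insula, for instance, appears in
three).  Edges map to a circuit when both endpoints belong to it
(default) or when either does (`rule = "any"`, whose per-circuit sets
are supersets of the former).  Unmatched edges are labeled
`unassigned` rather than dropped.

## Classification

`loocvSvm` holds out each subject in turn; inside every training fold
it (1) keeps features with two-sample t-test p < alpha (default 0.05;
a fold that would keep nothing keeps the single best |t| feature with
a warning), (2) min-max scales to [0, 1] with training statistics,
clipping the held-out row, and (3) trains an RBF-kernel SVM (default
cost 1, gamma 1/n_features - no tuning claim is attached to these
defaults; they are recorded in the report's config).  Decision values
are recalibrated per fold by subtracting the midpoint of the two
training-class mean decision values: leave-one-out folds are
imbalanced against the held-out class, which otherwise shifts the SVM
intercept toward the fold majority and biases AUCs computed from
pooled decision values below chance.  The recalibration uses training
data only.  ROC curves come from the continuous decision values and
AUC from the rank (Mann-Whitney) estimator, invariant under monotone
transforms.  Accuracy-based permutation significance re-runs the whole
pipeline on shuffled labels.

A deliberately leaky variant (`leaky = TRUE`) computes the filter and
scaling once on all subjects, for demonstrating selection leakage; it
is labeled as such in the report.  `leakageCanary` audits the hygiene
the other way around: it adds a feature equal to the training labels
whose held-out entry is replaced by a draw from the label marginal, so
the feature is perfectly informative in every training fold yet
uninformative about the held-out subject.  A leak-free pipeline stays
at chance AUC; any whole-sample shortcut scores near 1.  The audit
uses a strict filter level (0.001) so the canary is essentially the
only retained feature - at looser levels, stray noise features
selected within folds drag the null AUC below chance (ordinary
selection pessimism) and would blur the inflation signal.

## The synthetic cohort generator

`syntheticSpec`/`generateCohort` produce the study conditions the
package is validated under: 90 nodes, three groups of 50/58/69
subjects (CN / MDDNSI / MDDSI), an 11-node planted hub set, overall
template density 0.25, hub-core boost 3, log-normal weight noise
(sdlog 0.3), a 2 % edge presence-flip rate, covariates (age ~ N(40,
11), sex ~ Bernoulli(0.5), education ~ N(10, 3.5), GM volume ~ N(600,
55)) drawn independent of group unless a confound is injected, and
group effects concentrated on feeder and local connections plus one
weakened non-hub node in the MDDSI group.

Planting a detectable rich club requires care: if hub degrees are
simply inflated, degree-preserving nulls reproduce the dense core and
Phi_norm stays at 1.  The template therefore densifies hub-hub pairs
strongly (presence factor boost^1.5, capped at 0.92) while raising
hub-non-hub presence only mildly (boost^0.5), and solves the local
presence probability so the overall density meets its target - the
core is denser than its degrees alone predict, which is what Phi_norm
measures.  At boost 1 presence is uniform and nothing is planted.

Symptom scores follow HAMD = a_g - b * Ne(two designated hub nodes) +
noise, with the slope calibrated to the realistic between-subject
spread of nodal efficiency (about 0.006 at these settings) so the
negative Ne-HAMD association is actually recoverable by partial
correlation; group intercepts keep HAMD near 0-5 for CN and around 30
for the patient groups, with HAMA scaled to roughly half.

What the generator does *not* emulate, and what passing tests
therefore do not show about real data: spatial embedding and
distance-dependent connectivity, the lattice-like local clustering
that makes real connectomes small-world (synthetic subjects sit near
sigma = 1 and are duly flagged by `smallWorldCheck`), hemispheric
organization beyond the node table's bookkeeping, realistic
streamline-count marginals per tract, and any acquisition or
registration artifact.  Calibration and recovery results on synthetic
cohorts validate the *machinery* - null calibration, planted-effect
recovery, leakage hygiene, determinism - not clinical effect sizes.

## Problem sizes used in validation

The shipped validation suite exercises: exact brute-force agreement of
all graph metrics on 200 random graphs of up to 8 nodes; rich-club
calibration on 50 Erdos-Renyi graphs (N = 90, mean degree 14) and
planted-core regime recovery over 40 seeded runs; 100 seeded rewires
of a 90-node graph; 540 covariate-adjusted permutation tests (1000
permutations each) on null cohorts; 200 null and 50 planted-effect NBS
simulations at 1000 permutations; 20 label-permuted LOOCV runs plus
feeder-vs-local comparisons; and byte-identical reruns of the full
pipeline.  The acceptance script regenerates the full 177-subject
default cohort.  These sizes were chosen to make the stochastic checks
statistically meaningful while keeping a full validation run a matter
of minutes; every stochastic assertion is seed-fixed.

## Known limitations

* Binary graphs only: weighted path-length and weighted rich-club
  variants are out of scope, as are directed metrics.
* The greedy modularity optimum is not guaranteed globally; it is
  verified against exhaustive search only at small n.
* The auto hub threshold (regime minimum) is permissive by design; see
  above.
* The circuit config is an approximate transcription at AAL
  granularity, not a voxelwise mask set.
* LOOCV with pooled decision values remains a high-variance estimator
  at small n even after intercept recalibration; permutation
  significance of accuracy is the more robust summary.
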