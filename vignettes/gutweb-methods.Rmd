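---
title: "Methods: models, parameters and design choices in gutweb"
author: "gutweb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in gutweb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

gutweb implements the desk side of a multi-kingdom gut-microbiome study:
screening amplicon count tables for reagent contaminants, inferring sparse
signed co-occurrence networks across bacteria, archaea and fungi,
summarizing network topology down to keystone taxa, quantifying how well
bacterial taxa indicate the presence of a fungal target such as
*Basidiobolus*, and testing host and geography effects on community
composition. This vignette explains each model, its assumptions, the
parameters that matter, and the choices made where the design was open.

## Contaminant screening

**Model.** Reagent contaminants enter a library at a roughly constant
mass, so their *relative* abundance scales as `1/C` with sample DNA
concentration `C`. For each feature, over the non-NTC samples where it
occurs, `frequencyScore()` compares two one-parameter least-squares fits
of `log(frequency)` against `log(C)`: a contaminant model with slope fixed
at −1 and a non-contaminant model with slope fixed at 0. The score is the
upper tail of `F = RSS0 / RSS1` with `(n−1, n−1)` degrees of freedom:
small when the contaminant model fits far better. Features occurring in
fewer than 5 samples are never scored (two one-parameter fits on fewer
points are degenerate) and therefore never flagged; if all concentrations
are equal the score is undefined, with a warning.

**Threshold selection.** `selectThreshold()` encodes an NTC-referenced
sweep over probability thresholds 0.05 to 0.95 in steps of 0.10. In the
default *marginal* mode, the selected threshold is the largest grid value
reachable while every marginal step between consecutive thresholds still
removed strictly more (in percentage points) from NTC libraries than from
sample libraries, requiring at least 10% cumulative NTC removal at the
selected value. The sentence defining this rule admits a second,
cumulative reading — compare the cumulative curves at each threshold —
which is provided as `sweepMode = "cumulative"`; the marginal reading is
the default because it matches the phrase "relative to the next value
tested". When no grid value qualifies the function falls back to 0.1 (a
conventional default for frequency-based screening) and warns loudly.

## Preprocessing

Rarefaction subsamples each retained library without replacement to
exactly the target depth (default 10,000 reads) via `vegan::rrarefy`;
libraries below the depth are dropped and reported, and a zero cell can
never become positive. The prevalence filter keeps features present in
*strictly more than* 20% of samples by default; the boundary is
flag-controlled because both conventions exist. The abundance filter
(`>= 10` reads and `>= 0.5%` relative abundance) is read at the
*dataset-total* level: a per-sample reading at depth 10,000 would remove
nearly everything. The declared stage order is decontaminate → rarefy →
prevalence filter for network inference, with the abundance filter added
for the keystone role analysis. Whether rarefaction should precede
network inference at all is configurable; the default applies it.

## Network inference

**clr.** Counts are mapped to unconstrained space by the centered
log-ratio transform with pseudocount 1 (the convention for count data;
with pseudocount 0 on strictly positive data the transform is exactly
scale-invariant). Rows of the result sum to zero, which means one
direction of variation is lost and a small negative correlation residue
remains among abundant features — see the generator section.

**Neighborhood selection.** A Gaussian graphical model over the clr
variables is estimated node-wise: each feature is lasso-regressed on all
others (columns standardized internally to unit 1/n-variance, so the
penalty acts on standardized coefficients and the empty-graph condition
is `lambda >= max |cov|`). An edge exists when either directed
coefficient is nonzero (OR symmetrization — the default of the reference
implementations and higher recall at fixed penalty); its weight is the
mean of the nonzero coefficients, or the larger-magnitude one when the two
directions disagree in sign (conflicts are counted and carried on the
network object). glmnet's coordinate descent is the lasso engine.

**Stability selection.** StARS draws 20 subsamples of size
`b = min(floor(10 sqrt(n)), floor(0.8 n))` without replacement, fits the
whole lambda path on each, and scores each lambda by the mean of
`2 theta (1 - theta)` over all feature pairs, where `theta` is an edge's
selection frequency. The instability curve is monotonized from the sparse
end by a running supremum, and the smallest lambda (densest model) whose
monotonized instability stays within the 0.05 target is selected; the
final network is a full-data refit at that lambda. If no lambda meets the
target, the closest one is used with a warning. The default path is 30
log-spaced values from `lambda_max` down to `lambda_max/100`.

**Known behavior.** StARS is built to *contain* the true graph: at
moderate sample sizes the selected model is a slight superset of the
planted edges. In the packaged simulations (60 features, 6 modules, ~90
edges, 150 samples) recall of planted edges is high while roughly a third
of selected edges are extras — an inherent property of the stability
target and subsample size at this design, visible even on noiseless
latent-Gaussian draws, not a defect of the data generator. The
acceptance script reports the exact numbers it measures.

## Topology and keystone roles

All topology statistics run on the *unweighted* graph because edge
weights are signed and modularity or shortest paths are undefined for
negative weights; the sign layer is kept for reporting (percent negative
edges). Module detection is fast-greedy modularity maximization
(`igraph::cluster_fast_greedy`); the dendrogram is re-cut at the
maximum recomputed `Q = sum_c (e_cc - a_c^2)`, preferring the coarser
partition on ties so that a zero-gain merge is still taken (igraph
otherwise leaves a complete graph split in two). Within-module degree
z-scores use `zi = 0` when a module's within-degree standard deviation is
0, so singleton modules are peripherals rather than NaN. The role
thresholds `zi >= 2.5` and `pi > 0.62` are the established convention for
microbial networks and are configurable. Hub subnetworks keep the
`ceiling(0.30 n)` highest-degree nodes, ties broken by betweenness then
id, betweenness computed by shortest-path counting on the unweighted
graph.

## Indicator power

`IP = sqrt(a b)` combines positive predictive power
`a = P(target | indicator)` and negative predictive power
`b = P(no target | no indicator)` from the 2×2 contingency table of two
presence/absence vectors. IP is undefined when the indicator is
ubiquitous or absent (one conditional loses its denominator); undefined
values are excluded from all means rather than imputed, with exclusion
counts reported. A target present everywhere gives `b = 0` and hence
`IP = 0`: a ubiquitous target carries no negative indication. TIP is the
mean IP of the indicator assemblage for one target, a definition that
satisfies both directions in which the quantity is usually described.
IP runs on presence/absence; the Pearson heatmap runs on (typically
rarefied) counts, since those are what the corresponding figure panels
display; complete-linkage clustering of Euclidean distances between
correlation profiles orders rows and columns. Note that Euclidean
distances between rows of `1 - r` equal those between rows of `r`, so the
`(1 - r)`-derived and plain-profile orderings coincide.

## Community ecology

Bray-Curtis, PCoA (via classical double-centering and
eigendecomposition; negative eigenvalues reported and their axes
omitted), and dispersion homogeneity (vegan's betadisper/permutest with
the spatial-median center by default) are standard. PERMANOVA is
implemented in the package: the Gower-centered inner-product matrix `G`
is partitioned by hat matrices of the sequential (order-of-entry) model;
term degrees of freedom are rank increments, so rank-deficient designs
with empty factor cells are handled by construction; pseudo-F is
`(SS_term/df_term)/(SS_resid/df_resid)`; p-values come from free
permutation of sample labels with the add-one estimator
`(1 + #{F* >= F}) / (1 + nPerm)`, so with the default 999 permutations
the smallest attainable p is 0.001. The implementation is cross-checked
against vegan's `adonis2` (SS, F, R², df agree to 1e-10) and against full
enumeration of all 720 relabelings on a 6-sample toy; an explicit
permutation matrix can be supplied for such exact tests. Patristic
distances sum branch lengths along tip paths; trees must carry a length
on every edge.

## The synthetic-data generator

The generator exists so that every downstream stage has a recoverable
target at desk scale. It emulates:

- **Dependence from a known graph.** A sparse signed interaction graph is
  realized as a positive-definite precision matrix (diagonal boosting by
  `|min eigenvalue| + 0.2`); counts arise by the normal-to-anything
  construction — a latent multivariate normal pushed through per-feature
  zero-inflated negative binomial quantile functions — then resampled to
  stochastic library depths (log-normal around 10,000), which imposes the
  compositional closure of real libraries. Defaults: log-normal mean grid
  (`meanlog = log 20`, `sdlog = 1`), dispersion 0.5, zero-inflation 0.3,
  all overridable. A Gaussian copula was chosen over Dirichlet-multinomial
  because the inference stage assumes a latent Gaussian graphical model,
  which makes recovery well-posed.
- **Edge strengths.** With diagonal boosting, realized partial
  correlations scale inversely with the spectral radius of the signed
  adjacency, so hub-heavy wiring dilutes every planted effect. Modular
  graphs are therefore wired under a per-node degree cap (default 3,
  relaxed automatically when the requested density cannot be reached) with
  precision magnitudes Uniform(0.4, 1.0), yielding partial correlations of
  roughly 0.2–0.4 — moderate-to-strong interactions that the inference
  stage has a fair chance to recover, which is the generator's purpose.
  90% of edges are positive associations, matching the heavy positive
  skew observed in gut co-occurrence networks.
- **Reagent contamination.** Contaminant features are reagent-derived:
  their counts are Poisson with expectation `c · depth / C`, with `c`
  scaled so a strength-1 contaminant carries about 0.5% of a
  median-concentration library. Appended NTC libraries contain the
  contaminants plus a 5% cross-talk noise rate.
- **Host effects.** The `permanova` preset multiplies a disjoint 10%
  feature block per host group by 3. Its margins use moderate noise
  (dispersion 2, zero-inflation 0.15) so the planted host effect is the
  dominant structure, as in rarefied field data where host explains a
  stable share of community variance; the heavier generator-wide defaults
  would swamp a 10% block shift at 30 samples.
- **Trees.** Random binary topologies with exponential branch lengths;
  ultrametricity is deliberately not enforced, matching trees estimated
  from marker-gene alignments.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: taxonomy-assignment error, chimeras, batch and
primer effects, phylogenetic correlation of abundances, and any relation
between a feature's taxonomy and its network position. One artifact it
*does* share with real data: compositional closure leaves a small
negative clr-correlation residue concentrated on the most abundant
features even when the planted graph is empty, which is why independence
checks bound mean absolute correlation rather than every single pair.

## Problem sizes and determinism

The test suite and acceptance script run the network recovery at its
study design (60 features, 150 samples, 5 seeded replicates), the
modularity oracle against brute-force enumeration over all set partitions
for graphs of up to 8 nodes, PERMANOVA calibration on 500 null
replicates of a 3×10 design with 199 permutations each, and the
decontamination fixture over 10 seeds — sizes chosen so the whole suite
completes in a few minutes on one CPU while still exercising each method
at a scale where its statistical claims are meaningful. Every stochastic
step takes an explicit seed; pipeline stages derive per-stage seeds
deterministically from one run seed, so any stage can be reproduced in
isolation.

## Known limitations

- The network module estimates a single static network; latent-variable,
  time-series and differential-network models are out of scope.
- StARS at the 0.05 stability target deliberately errs dense (see above);
  users who need high edge precision should inspect the instability curve
  and consider sparser path points.
- The decontamination score is a pragmatic fixed-slope contrast, isolated
  behind `frequencyScore()` so an alternative scorer can be swapped
  without touching the threshold-sweep rule.
- PERMANOVA uses free permutation; restricted permutation schemes for
  nested or repeated designs are not implemented.
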