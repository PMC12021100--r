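---
title: "Methods: multi-omics stratification, drivers and networks in stratomics"
author: "stratomics maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics stratification, drivers and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
procedures, their assumptions, the parameters that matter, what the
synthetic cohort generator does and does not emulate, and the numerical
and design choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The problem

Cohorts of treated people-with-HIV (and chronic-disease cohorts
generally) can be molecularly heterogeneous in ways that clinical
variables do not capture. The package stratifies such a cohort from
multi-layer omics alone — blood transcriptomics, plasma proteomics,
plasma metabolomics — and then dissects the strata: which proteins
separate them, which of those behave as network drivers, how features
co-vary across layers, and what the strata imply for metabolic flux.
Because the motivating cohort data are access-restricted, every stage is
exercised on a generator that plants known structure.

## Similarity network fusion

Each layer is variance-filtered (features with variance < 0.2 removed;
the boundary value is retained) and z-scored. Pairwise squared Euclidean
distances feed the locally scaled kernel

$$W(i,j) = \exp\!\left(-\frac{d^2(i,j)}{\alpha\,\varepsilon(i,j)}\right),
\qquad
\varepsilon(i,j) = \tfrac{1}{3}\left(\bar d^2_{K}(i) + \bar d^2_{K}(j)
+ d^2(i,j)\right),$$

where $\bar d^2_K(i)$ is the mean squared distance from $i$ to its $K$
nearest neighbours. Defaults $K = 30$, $\alpha = 0.7$, $T = 20$
diffusion rounds. *Choice:* the distance is squared Euclidean on
z-scored features — the classical SNF formulation — because the source
procedure names only "pairwise sample distances".

Fusion is cross-diffusion: the full kernel is row-normalized to
$P$ (diagonal $1/2$, off-diagonal mass $1/2$ — the numerically stable
variant), the sparse kernel $S$ keeps each row's $K$ nearest neighbours
renormalized, and $P_v \leftarrow S_v \,\overline{P_{u \ne v}}\, S_v^T$
iterates with symmetrization and re-normalization each round. The fused
matrix is the renormalized average of the layer matrices; it is
symmetric and nonnegative with row sums near one (exact row-stochasticity
and exact symmetry cannot hold simultaneously; symmetrization is applied
last).

Ties in neighbour selection are broken by sample order, making every run
reproducible.

### Model selection and concordance

Candidate cluster numbers $C \in \{2,\dots,10\}$ are scored by (i) the
eigengap $\lambda_{C+1}-\lambda_C$ of the symmetric normalized Laplacian
and (ii) a rotation cost. *Choice:* the source toolchain does not state
its rotation-cost formula; we use the eigenvector-alignment cost of
self-tuning spectral clustering,
$J(\theta)=\sum_i\sum_j Z_{ij}^2/\max_j Z_{ij}^2$ for $Z = XR(\theta)$,
minimized over Givens rotations with BFGS from $\theta = 0$ (50
iterations). The quantity is isolated behind the diagnostics interface
precisely because it is a convention, not a contract.

Spectral clustering embeds samples in the bottom $C$ eigenvectors,
row-normalizes, and runs k-means with 20 seeded restarts (best inertia
kept). Per-layer concordance is NMI between each layer's own spectral
labels and the fused labels, normalized by the arithmetic mean of the
two entropies. A graph with more connected components than $C$ is
labelled by component with a warning.

### Split-based validation

The cluster validator is deliberately a *simplified* similarity
classifier (the pathway-level feature scoring of netDx-style validators
is out of scope): per split (train fraction 0.8, 20 splits), a test
sample is scored per cluster by its mean Pearson correlation to the
cluster's training members in each omics view and by negative
range-normalized absolute difference for continuous clinical
covariates, averaged across views. *Choice:* features are mean-centered
per view first; without centering, a one-sided group shift leaves the
reference cluster internally uncorrelated and the argmax degenerates.
ROC/PR curves come from pooled score margins with the second cluster as
positive class.

## Moderated differential abundance

Per feature, OLS on a design with an intercept, the group contrast, and
optionally covariates (three tiers mirroring unadjusted, between-cluster
and covariate-adjusted models; categorical covariates reference-coded on
the first observed level, ordinal intake variables as ordered numeric —
the encoding the source leaves unstated). The empirical-Bayes prior
$(d_0, s_0^2)$ is fitted by method of moments on $\log s^2$ (digamma /
trigamma matching, trigamma inverted by Newton), the posterior variance
is $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0+d)$, and the moderated $t$
uses $d_0 + d$ degrees of freedom. `prior_df = 0` recovers the ordinary
t exactly; an infinite estimated prior collapses all variances to
$s_0^2$. The implementation is the package's own; limma serves only as
an independent cross-check in the tests. Transcript counts pass through
a log-CPM transform documented as an approximation (count-model
differential expression is out of scope).

Set enrichment is a simplified stand-in for the heavyweight tools:
upper-tail hypergeometric over-representation and a directional test
(per-set mean signed statistic, two-sided empirical p from feature-label
permutations, BH across sets, significance at FDR < 0.2 by default;
differential-abundance significance defaults to FDR < 0.05).

## Shadow-feature consensus selection

Each iteration samples 1000 features (without replacement), appends a
permuted shadow copy of every column, and fits a random-forest
importance learner (ranger, permutation importance — the
mean-decrease-accuracy analogue — 100 trees, 20 rounds maximum). A
feature scores a hit when its importance exceeds the round's maximum
shadow importance; confirmation/rejection is a two-sided binomial test
against 0.5 at $\alpha = 0.05$, with early stopping once every feature
is decided. *Choice:* "selected in 70% of iterations" is read with the
denominator equal to the iterations in which the feature was *sampled* —
otherwise no feature could reach 70% when the subset is much smaller
than the feature pool — with a minimum support of 20 sampled iterations.
The final model is a 700-tree forest evaluated by repeated stratified CV
(3 x 10-fold) over an mtry grid of 1..15, sensitivity defined with the
at-risk cluster positive.

## Consensus Gaussian Bayesian network and drivers

The network score is the decomposable Gaussian BIC
$\sum_j \left[\log L_j - \tfrac{k_j}{2}\log n\right]$ with
$k_j = |\mathrm{pa}(j)| + 2$; data are z-scored first so node terms are
comparable. Hill climbing uses best-improvement add/delete/reverse moves
under acyclicity and a parent cap (default 5, for tractability at the
~200-protein scale), with a memoized local-score cache shared across
restarts. The consensus over 150 random-restart results retains an edge
when its direction is supported by more than half of the runs and the
reverse direction is not; direction-conflicted ("undirected") edges are
removed, and any residual cycle is broken at its lowest-support edge.
*Choice:* the source states neither the retention threshold nor the
refinement procedure; refinement is implemented as 1000 random
single-edge perturbations accepted only when they improve the score, and
both conventions sit behind configuration.

The driver score of node $g$ is the network-score drop when $g$ and its
incident edges are removed; by decomposability only $g$'s children
change, so
$\Delta\mathrm{BIC}_g = \sum_{j \in \mathrm{ch}(g)}
[\mathrm{score}_j(G) - \mathrm{score}_j(G - g)]$, and an isolated node
scores exactly 0. The empirical p draws 5 random non-candidate nodes per
iteration (1000 iterations) and counts how often their best score
reaches the candidate's.

## Consensus association network

Per iteration, 400 features from each layer are pooled and all pairwise
Spearman correlations computed (average ranks for ties; p by the t
approximation); pairs below the within-iteration BH FDR of $10^{-6}$ are
recorded. *Choice:* a pair's consensus denominator is the number of
iterations in which both members were co-sampled — a pair that was never
drawn cannot be "found". Pairs at $\ge 90\%$ consensus are re-tested on
the full data with a *global* BH adjustment at FDR $< 5\times10^{-5}$
(the source does not say whether that re-test is global; global was
chosen) and split by sign into positive and negative subnetworks.
Communities come from Leiden modularity (resolution 1, seeded) on the
union network; only communities with more than 30 members are reported
(strictly more: a 30-member community is dropped), their centrality is
the mean within-community degree, and topology is benchmarked against
100 size-matched Erdős–Rényi graphs. The senescence overlay intersects
the union of senescence sources (CellAge / CSgene / SASP-style lists)
with measured proteins, takes those significant in the differential
analysis, and reports the fraction inside the most central community;
the retention check z-scores the significant senescence markers and cuts
a Ward dendrogram at two, reporting ARI against the stratification.

## Toy metabolic model and flux analysis

Full genome-scale reconstruction is out of scope; the packaged model is
a ~25-reaction glycolysis-like network (glucose uptake and transport,
glycolytic chain, fermentation and an abstract oxidative branch, a
tryptophan-to-serotonin transport block, ATP maintenance, biomass) with
three tasks — biomass production, ATP from glucose, amino-acid
assimilation — standing in for full task lists. Contextualization closes
reactions whose gene rule (and = min, or = max) evaluates below the
expression threshold and scales exchange upper bounds by
`bound_scale * level / reference` (the source states no formula; lower
bounds are untouched); a contextualized model is kept only if all tasks
pass.

FBA maximizes the biomass objective under $Sv = 0$ and bounds. The LP is
solved by an in-package deterministic two-phase simplex with Bland's
rule: the general-purpose solver available in the environment returned
unstable results on these models, and determinism matters more here than
scale (the models have tens of variables). Only the objective and the
activity/direction classification are contract-level — the optimal
vertex can be degenerate. Fluxes below $10^{-7}$ are treated as
inactive, the display set is $|v| \ge 250$, and transport fluxes carry a
log2 magnitude. Group-specific classification calls a reaction
target-only when active only in the target context, direction-flipped
when active everywhere with the target sign opposite to both references,
otherwise shared; individual-level differences use a two-sided Fisher
test of activity-by-group with BH across reactions.

## The synthetic cohort generator

The generator plants exactly the structure the analyses assume: 88 + 70
samples; 2000 transcripts as negative-binomial counts (dispersion 0.2,
typical of bulk RNA-seq) with a log-mean group shift of 0 by default;
2500 proteins and 900 metabolites as unit-variance Gaussians with
standardized group shifts 1.0 and 0.3 on affected features; a planted
linear-Gaussian driver DAG (5 drivers x 4 children, path coefficient
0.8) among proteins; cross-layer modules driven by shared latent factors
($x = \lambda f + \sqrt{1-\lambda^2}\,\varepsilon$, so module features
keep unit marginal variance); senescence annotations on 5% of proteins
split into three overlapping sources; and clinically flavoured
covariates (hypertension 0.40 vs 0.61, central obesity 0.57 vs 0.73,
and similar published imbalances).

Two prevalences were calibrated once, then frozen. The protein affected
fraction is 0.40, mirroring the reported scale of differential abundance
(on the order of 1100 of ~2900 proteins). The metabolite affected
fraction is also 0.40: single-layer spectral clustering has a sharp
detectability threshold, and smaller fractions leave a third or more of
generated cohorts with no recoverable metabolite signal at the fixed
per-feature shift of 0.3 — violating the intended layer-information
ordering (protein strong, metabolite weak, transcript absent). The
calibration used its own seed set, disjoint from any seeds used in the
tests; "weak" is carried by the small per-feature effect, not by rarity.
Driver, module and affected blocks are kept disjoint so recovery tests
are unambiguous.

What the generator does **not** emulate: assay chemistry (NPX
normalization, LC-MS artifacts), missingness mechanisms, library-size
effects, batch structure, correlated clinical confounding, or any
nonlinearity in driver effects. Passing recovery tests therefore shows
the chain is correct and well-calibrated under its own assumptions — not
that those assumptions hold in any particular real cohort.

## Problem sizes in the tests and acceptance script

The test suite runs the full study conditions where the contract demands
them (20 cohorts of n = 158 for stratification recovery and NMI
ordering; 543-DAG exhaustive oracles on 4 nodes; every 2x2 table up to
N = 30 against a hypergeometric enumeration) and reduced but
representative sizes elsewhere (selection at 200 iterations x
100-feature subsets over 500 features; driver recovery at 20 nodes, 30
restarts, 10 seeds; association networks at 200 iterations x 50 features
per layer). The acceptance script mirrors these sizes and derives every
random stream from its `--seed`.

## Degenerate inputs and numerical conventions

Zero-variance features are an error where z-scoring is required and are
otherwise filtered; duplicated identifiers are hard errors naming the
identifier; missing values are minimum-imputed per feature (the
convention of the metabolomics pipelines this mirrors) and logged;
contingency tables with a zero margin are errors; a constant covariate
is skipped with a warning; `rho = +/-1` Spearman pairs get p = 0 rather
than a failed t approximation; an all-zero signed statistic yields
direction "none"; infeasible LPs return an explicit status and unbounded
objectives are errors naming the reaction set. All alignment is by
sample identifier, never by position.

## Known limitations

The rotation-cost convention, the consensus-retention threshold, the
refinement move set, and the exchange-bound formula are all
under-determined by the source and are therefore configuration-backed
conventions; alternative readings would change diagnostics but not the
contracts tested. Hill climbing is quadratic per step in the node count
and is intended for the few-hundred-node regime, not thousands. The
validator is not a substitute for pathway-level validators. The toy
metabolic model supports the *logic* of context-specific flux comparison
only; its fluxes have no physiological meaning.
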