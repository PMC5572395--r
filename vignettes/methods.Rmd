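---
title: "Methods: co-expression networks, regulatory overlays and hub-gene targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks, regulatory overlays and hub-gene targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`conet` turns per-condition expression matrices into thresholded
co-expression networks and pushes them through community detection,
physical-network comparison, transcription-factor importance scoring,
metabolic-reaction clustering and hub-gene target prioritization. This
vignette records the statistical model behind each stage, the defaults and
why they are what they are, what the synthetic-data generator does and does
not emulate, and the numerical conventions that make every result
reproducible bit for bit.

## Co-expression networks

All correlation is Pearson's r across the samples of one condition,
computed on TPM values (RPKM input is converted by per-sample rescaling so
each sample sums to 10^6). Before correlating, the lowest-expressed third
of genes (by mean) is dropped: very low-abundance genes contribute mostly
measurement noise, and their pairwise correlations would dilute the top
quantile. Zero-variance genes are excluded outright and recorded — an NA
correlation would silently poison the edge-cutoff quantile.

The network keeps the top `ceiling(q * P)` of the P evaluated pairs by
*signed* r, with `q = 0.01`. Signed (not absolute) ranking is used because
the upper tail of co-expression is the biologically interpreted quantity
and the average published cutoff is strongly positive; an `absolute = TRUE`
option exists. Because the gene filter is applied per condition, the pair
universe P — and hence the edge count — is per condition too. Edge-boundary
ties are broken by r descending, then the lexicographic gene-id pair, so
network construction is invariant to gene input order.

The optional log scale is `log2(x + 1)`; the pseudo-count is the
conventional unit and configurable.

## Communities, key clusters and the cluster graph

Communities come from the walktrap algorithm (short random walks,
agglomeration, cut at maximum modularity) with walk length 4 — the
reference default of the method — on the unweighted thresholded graph. The
graph is treated as unweighted because edges have already passed a hard
correlation cutoff; a `use_weights` flag enables r-weighted walks.

A cluster's *clustering coefficient* is the mean local coefficient of its
members computed on the intra-cluster induced subgraph (nodes of degree < 2
contribute 0). The induced form measures how internally dense a cluster is,
which is what "highly co-expressed key clusters" asks; a flag switches to
full-graph local coefficients, and a `transitivity` method gives the global
triangle/triple ratio instead. Key clusters are the top `ceiling(K/2)` of K
clusters by coefficient — the inclusive rounding is deterministic — with
ties broken by size, then cluster id.

Clusters A, B are linked in the cluster graph when the observed
inter-cluster edge count satisfies `O_AB >= 2 * E_AB` with
`E_AB = sum_{a in A, b in B} k_a k_b / (2N)`; degrees k and the edge total
N are taken in the full network (not the induced subgraphs), matching the
configuration-model reading of "expected connections". Pairs with `O = 0`
are never linked, whatever E is.

Gene-set enrichment throughout the package is the upper-tail hypergeometric
probability `P[X >= k]` over an explicit universe; term sets are
intersected with the universe first. Default significance levels follow the
use sites: 0.01 for tissue-gene and subsystem enrichment, 1e-4 for GO-style
sets, 0.05 for TF enrichment.

## Physical networks against co-expression

The permutation null for a set of edges redraws, 1,000 times, the same
number of edges with both endpoints uniform over the actual network's node
set, rejecting self-loops and duplicates. This endpoint-resampling scheme
follows the "permutated among genes in respective actual networks" recipe
rather than degree-preserving rewiring; permuted edges may collide with
observed ones (pure resampling) and the collision rate is reported. The
empirical p uses the add-one rule `(1 + #{null >= obs}) / (1 + n_perm)` and
can never be 0 — with 1,000 permutations the smallest attainable p is
1/1001.

Co-regulator counts are shared-TF counts (regulatory networks, over the
universe of target genes) or shared-interactor counts (PPINs, over all
proteins; the pair members themselves are never counted as partners). The
top stratum is the top `ceiling(0.001 * P)` pairs by count; the zero
stratum is all pairs with no co-regulator. The co-regulator-count curve
reports the mean r of pairs at or above each threshold.

Regulator selection compares the correlations between a regulator and its
bound genes against *all* evaluated pairs of the correlation table (not
just network edges) with a two-sided two-sample KS test — the comparison is
"co-expression of these pairs vs overall levels" — and additionally
requires |mean r| > 0.1. Regulators with fewer than 3 usable pairs are
reported untested. Note that under a true null the |mean r| floor almost
never passes, so the *joint* selection rate is far below the KS alpha; the
calibration quantity worth tracking is the rate of KS p < alpha, which the
acceptance suite checks.

## TF importance

The feature matrix has one row per top-1% co-expressed pair and one binary
column per TF (1 = the TF binds both genes). All-zero columns are dropped
and logged; all-zero rows are kept because they anchor the baseline
response level. A 500-tree regression forest with default feature
subsampling predicts pair r; importance is the total impurity (variance)
reduction per TF, the convention of the era the method comes from. Impurity
importance is biased towards dense binary columns, so a permutation
(out-of-bag) importance option exists and is what the negative-control
tests use for ranking under a shuffled response. The forest seed is stored
in the result; identical seeds give identical scores. The top 1% of TFs by
score (ties by score, then id) are reported as most influential.

## Reaction clusters and differential Fisher-Z scores

A reaction pair's co-expression is the maximum r over its enzyme pairs — a
deliberate optimistic projection through the gene-protein-reaction mapping;
an enzyme shared between two distinct reactions yields r_max = 1 by
identity. Reactions with no expressed enzyme are excluded and listed.

Reactions are clustered by average-linkage hierarchical clustering on
`1 - r_max`, cut to exactly `k = 100` clusters (the linkage is not
prescribed by the source method; single/complete are available). The
dissimilarity matrix is assembled in canonical (sorted) reaction order and
cluster labels are canonicalized by each cluster's smallest member, so the
clustering is invariant to input order. The clustering is computed once on
the reference condition and *frozen*: every comparison scores the same
clusters in another condition's correlation table.

Cluster-level co-expression per condition is the mean Fisher Z
(`z = atanh(r)`, with r clamped to ±(1 − 1e−7) so identical-enzyme pairs
stay finite) over within-cluster reaction pairs. The differential score is
`Δz̄ = z̄_ref − z̄_other`, so positive values mean co-expression *specific
to* the reference condition, and in a disease comparison the flagged
clusters are those that lose reference co-expression. The top
`ceiling(0.01 k)` clusters per comparison are flagged; a cluster flagged in
a disease comparison and in at least one tissue comparison carries a
combined flag. Clusters with fewer than two reactions mappable in a
condition are excluded from that comparison's ranking rather than scored 0.

TF enrichment of clusters uses the enzyme genes of all clustered reactions
as the universe — the question is about regulation within the metabolic
gene space, not the genome. *Highly regulated* clusters are those whose
enriched TFs (enrichment p < 0.05, at least two scored) have importance
scores stochastically greater than the full importance distribution by a
one-sided two-sample KS test at p < 0.25 — a deliberately permissive screen.

## Hub-gene targets

Per condition, the hub neighborhood is the `top_n = 100` genes by r with
the hub among genes whose mean expression exceeds 1 TPM. "Expressed more
than 1 TPM" is read as mean-over-samples (median is configurable); the
robustness set intersects the raw-scale and log-scale top lists. The
specificity filter keeps robust genes that appear in the top lists of fewer
than three conditions — the focal condition itself counts, so a strictly
focal-only gene has count 1 — and that belong to a user-supplied
tissue-enriched annotation set (a GMT standing in for atlas-style
"tissue-enriched/enhanced" labels). Without an annotation set the filter
runs on the count criterion alone and warns.

Quartile stratification assigns `round(n/4)` samples (0.5 rounds up) to
each of the high and low groups, which reproduces the published cohort
arithmetic 371 → 93 + 93. Expression ties are broken by sample id.

The differential-expression stage is a self-contained negative-binomial
Wald test: median-of-ratios size factors (computed over genes with
all-positive counts), a pooled method-of-moments dispersion per gene from
`Var(K_j/s_j) = mu/s_j + a mu^2` floored at 1e−8, a Wald statistic on the
log mean difference with a 0.5 pseudo-mean to keep zero-mean groups finite,
and BH adjustment. Equivalence with any external engine is not claimed; the
test is validated by calibration (type-I error within 0.07 of nominal 0.05
at n = 93 vs 93) and power (≥ 95% for 4-fold changes at the same sizes)
simulation, and one unit test cross-checks fold-change agreement against an
independent NB implementation.

## The synthetic-data generator

The generator is the package's ground-truth instrument. Its defaults are
the study conditions used by the test and acceptance suites: 300 genes plus
33 TF genes, 3 conditions (two tissues and one disease) × 200 samples, five
30-gene correlation modules at latent within-module correlation 0.8, three
causal TFs (10% of 33) with additive effect 2.0 on a 45-gene target pool,
250 reactions in 100 clusters, 12 condition-specific hub partners per
condition plus 6 ubiquitous ones, 10% DE genes at 4-fold with NB dispersion
0.1. These sizes make one full study generate in well under a second while
leaving each planted signal comfortably above its detection threshold.

Design points worth knowing:

* **Factor model.** Module members follow
  `x = sqrt(rho) f_m + sqrt(1 - rho) eps` on a latent normal scale, so the
  within-module latent correlation is exactly rho. Module 1 is generated
  without its factor in the disease condition — the planted deregulation.
* **Positive scale.** Expression is `exp(2 + 0.5 z)` of the standardized
  latent. Two choices matter here. First, each gene's latent is
  standardized by its theoretical sd before exponentiation: additive TF
  factors inflate latent variance, and unstandardized high-variance genes
  would lose disproportionately much of their Pearson correlation to the
  exponential transform. Second, the log-sd of 0.5 keeps the transform's
  attenuation mild; with a log-sd of 1 the sampling noise of
  expression-scale correlations becomes so heavy-tailed that a top-1% edge
  cut selects winner's-curse noise rather than planted structure. Tests
  therefore assert recovery of the planted ordering, not exact rho, on the
  expression scale.
* **Causal TF design.** The TF target pool is partitioned over pairs of
  causal TFs, so every pool gene is bound by exactly two of them. With a
  homogeneous number of bound TFs per gene, the pair correlation under the
  additive model is `j b^2 / (1 + 2 b^2)` for j shared TFs — cleanly
  increasing in j, which makes the co-regulator-count curve monotone in
  expectation and lets pairs sharing both TFs clear the top-1% cutoff at
  the default `b = 2`. Decoy TFs bind half as many genes, sampled outside
  the modules and the pool, so decoy binding carries no co-expression
  signal.
* **Reaction map.** The planted subsystem draws its enzymes from module 1;
  up to three more subsystems align with stable modules as realistic
  distractors (co-expressed everywhere, so their differential score is ~0);
  the rest draw from genes outside those modules. Within each block,
  enzymes are dealt from a shuffled cycle without reuse until the pool is
  exhausted: promiscuous shared enzymes pin reaction pairs at r_max = 1 in
  *every* condition, and at high sharing rates those degenerate pairs
  consume the whole agglomeration budget of a 100-cluster cut. The default
  of 250 reactions leaves 150 merges below the cut — enough for genuine
  correlation-driven clusters to form.
* **RNG discipline.** Six named RNG streams (expression, RN, PPIN,
  reactions, hub, counts) are derived from the master seed at configuration
  time. Each generator seeds its own stream, so adding or rerunning one
  generator never changes another's draws, and identical seeds give
  bit-identical studies.

What the generator does **not** emulate: batch and covariate structure,
library-size effects on TPM (only on counts), isoform-level signal, count
noise in the expression matrices (they are noiseless transforms of the
latent field), realistic gene-gene correlation beyond the planted blocks,
and scale — real tissue compendia have two orders of magnitude more genes
and pairs. Passing the planted-recovery suite therefore shows the
pipeline's statistics behave as designed under their own assumptions, not
that any particular biological dataset will yield the same rankings.

## Numerical conventions

* All "top fraction" selections use `ceiling(q * n)` with deterministic tie
  breaks (primary statistic, then identifier), so results are reproducible
  across platforms and input orders.
* Fisher Z clamps r to ±(1 − 1e−7) (z ≈ 8.41) rather than propagating
  infinities.
* Quartile group size is `floor(n/4 + 0.5)` — round half up.
* Empirical p-values always use the add-one rule.
* The permutation and forest stages take explicit integer seeds and record
  them in their outputs.
* Degenerate inputs fail loudly: all-zero samples in unit conversion,
  fewer than 3 samples for correlation, empty universes in enrichment,
  constant responses in the forest, overlapping DE groups.

## Problem sizes in the test and acceptance suites

The suites run the pipeline at the generator defaults above; the
deregulated-cluster recovery rate is estimated over 100 replicate studies,
permutation-null calibration over 200 replicate datasets (40 genes × 30
samples, 20 edges, 199 permutations each), KS-regulator calibration over
150 null regulators in one 150-gene table, and NB calibration over three
replicate 333-gene count matrices at 93 vs 93 samples. These sizes were
chosen so each estimate's Monte-Carlo error is small relative to the margin
it is compared against.

## Known limitations

* Walktrap on a thresholded graph can split a sparse planted module when
  the edge density within the module is low; module recovery is exact in
  the well-covered regime and degrades gracefully (ARI ~0.95+) near it.
* The max-over-enzymes reaction projection is intentionally optimistic and
  inherits the upward bias of a maximum over noisy correlations; clusters
  of reactions with many enzymes are slightly favored.
* Impurity-based forest importance is biased for features with very
  different marginal frequencies; rankings across TFs with similar binding
  breadth are trustworthy, absolute score comparisons across very different
  breadths are not (use permutation importance there).
* The NB Wald test uses a pooled moment dispersion without shrinkage; at
  very small group sizes (< ~20 per group) a shrinkage estimator would be
  preferable to control its type-I error.
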