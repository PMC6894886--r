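---
title: "Methods: models, rules and design choices in crossimmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and design choices in crossimmune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossimmune)
```

crossimmune re-implements, as a tested and reusable toolkit, the analysis
procedures used to map and compare the immune systems of the naked mole-rat
and the mouse from droplet single-cell RNA-seq and comparative genomics:
distributional droplet QC, iterative resolution-searched clustering,
marker-based cell-type annotation, hurdle mixed-model differential
expression, ISH puncta statistics, and gene-family phyletic patterns with
maximum-parsimony ancestral gene counts. Every stage is exercised end to end
on synthetic data with planted ground truth, so the package needs no
external download to validate itself. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where the
procedures were underdetermined.

## Droplet QC by distributional rules

A droplet run yields a sparse genes x barcodes UMI matrix in which most
barcodes captured no cell. Three rules, all operating on kernel density
estimates of log10-transformed summaries, clean it up:

1. **Cell-less barcodes.** The distribution of `log10(#UMIs)` across
   barcodes is bimodal: an ambient (empty-droplet) mode and a cell mode.
   Barcodes below the first density valley above `x0 = 2` (i.e. 100 UMIs)
   are dropped.
2. **Sparse genes.** Symmetrically, genes below the first valley above
   `x0 = 3` in the distribution of `log10(#detecting barcodes)` are
   dropped. The published bound implies detection in ~1000 barcodes, which
   is strict for small experiments; `x0` is a parameter. Genes detected
   nowhere are always removed.
3. **Multiplets.** Barcodes containing more than one cell are inflated in
   both `#UMIs` and `#genes`. The rule looks for secondary density modes
   that are (a) located beyond `ratio = 1.5` times the global mode and
   (b) hold fewer than `max_frac = 5%` of barcodes, and removes the
   barcodes above the valley separating such a mode from the global one,
   taking the union over the two distributions.

Two numerical choices matter here. First, the *scale* on which the 1.5x
location ratio is read. A doublet carries roughly twice a singlet's UMIs, so
its mode sits `+log10(2) ~ 0.30` above the cell mode on the log10 axis;
comparing raw log10 positions (`x > 1.5 * x_global`) would demand a mode at
e.g. `10^5.25` UMIs against a cell mode at `10^3.5`, which no real doublet
population can reach — under that literal reading the rule can never fire at
realistic depths. The default therefore compares mode locations on the
linear count scale (`10^x > 1.5 * 10^x_global`, i.e. 1.5-fold more UMIs or
genes), which a doublet mode clears; `ratio_scale = "log10"` restores the
literal reading. Second, *what counts as a mode*: finite-sample KDEs ripple
in their tails, so maxima below 1% of the global maximum height are ignored
(`min_height_frac`), and a valley qualifies only if it dips below 90% of the
smaller adjacent mode (`min_dip`). A genuine minority mode — empties are
~half the barcodes, planted multiplets a few percent — sits far above both
floors; the floors only suppress noise bumps that would otherwise shave off
stray barcodes from clean unimodal data.

Density estimation itself is a Gaussian KDE with Silverman's bandwidth on a
512-point grid padded by three bandwidths (`estimate_log10_density()`); the
smoother is standard and deliberately not novel.

## Depth scaling, variable genes, PCA

Counts are rescaled per barcode to the median barcode total
(`x_gc = u_gc / U_c * median(U)`), making column sums equal and profiles
depth-invariant. Genes are binned into 20 equal-occupancy mean-expression
bins; the log dispersion (variance/mean) is z-scored within bins and genes
with `z >= 1` are kept — the classic mean-dispersion selection. If all means
coincide the z-scoring falls back to a single global bin. PCA retains the
top 50 components of the centered, unit-scaled variable-gene matrix. Exact
SVD is used rather than a randomized solver: at the problem sizes this
package targets the exact decomposition costs little and is deterministic
without bookkeeping a seed.

## SNN graph, Louvain, and the resolution search

Cells are connected by the Jaccard overlap of their Euclidean k-nearest
neighbor sets in PC space (self included), pruning edges with similarity
below 1/15 — the conventional cutoff. The published neighborhood size is
`k = min(750, n - 1)`; crossimmune caps it at `min(750, floor(0.75 (n-1)))`.
The cap is invisible for any dataset with at least 1000 cells, but matters
in the small subsets that iterative subclustering reaches: as k approaches
`n - 1` every neighbor set converges to the whole cell set, all Jaccard
weights saturate near 1, and the graph carries no community structure at
all (we verified that a 600-cell dataset with three well-separated planted
populations yields a single Louvain community at `k = 599` and clean
recovery at `k <= 0.75 n`).

Louvain modularity clustering is run over the resolution grid 0.05 to 1.225
in steps of 0.025. Each candidate labelling is scored by the mean over
clusters of that cluster's mean silhouette width in PC space — rewarding
cohesive, isolated clusters — and the argmax wins, ties going to the lowest
resolution. The published "mean unifiability isolability" metric has no
public definition or citation; the silhouette-based stand-in matches its
apparent intent (isolation versus cohesion) and is pluggable. A labelling
must also beat `min_metric = 0.10` to be accepted; below that the trivial
one-cluster labelling is returned. The threshold sits below the
conventional 0.25 "weak structure" silhouette line, so only
near-structureless data refuses to split — this is what makes convergence
("the search returns one cluster") reachable on homogeneous data, where
Louvain would otherwise always carve communities out of noise.

Iterative clustering runs the whole pipeline on all cells, then recursively
within each cluster, recording lineage labels (`3`, `3.1`, `3.1.2`).
A branch stops when the search returns one cluster or fewer than
`min_cells = 50` cells remain (a guard the original description leaves
unstated; degenerate splits of tiny groups carry no signal); a recursion
depth of 10 aborts with a diagnostic. Converged labels refine
first-iteration labels by construction. Note that the mean silhouette is
evaluated in each subset's own re-derived PC space: with 50 retained
components the ~46 noise dimensions dilute silhouette values (a perfectly
separated planted trio scores around 0.2-0.3, not 0.5+), which is why
`min_metric` is set where it is.

## Marker genes and annotation

Markers are found by a bimodal likelihood-ratio test: each group's
expression is a point mass at zero with probability `1 - pi` plus a
log-normal over the positives with a group mean and pooled variance; the
alternative frees `pi` and the positive mean per group (2 df). The test has
a closed-form MLE solution, which the implementation vectorizes over genes.
A gene is a marker of a converged cluster when it is overexpressed with
BH-adjusted `p < 0.05` against *every* other converged cluster
(all-pairwise, the adjustment applied per pairwise comparison across genes
— the published description fixes neither the positive-part family nor the
adjustment scope; log-normal positives and per-comparison adjustment follow
the originating toolkit's conventions).

Annotation intersects each cluster's markers with a reference cell-type TPM
compendium: a marker is retained if its top reference type has
`TPM >= 50` and at least 4-fold the runner-up, and the cluster takes the
plurality type among retained markers (ties or no survivors leave it
unassigned). Both thresholds are parameters; the source text says only
"strongly and specifically expressed". Heatmap downsampling reduces cells
to at most 2500, allocated to clusters proportionally by largest-remainder
rounding with every non-empty cluster keeping at least one cell.

## Hurdle differential expression

Per-gene UMI counts within a cell type are bimodal: a zero mode and a
positive mode. A condition effect can change the *fraction of cells
expressing* the gene (expression-induction) or the *level among expressing
cells* (expression-level), and the two are biologically distinct. The
hurdle GLMM separates them:

* **Induction:** logistic mixed regression of the binarized outcome on
  condition (control baseline) with a per-sample random intercept. The
  implementation aggregates cells to per-sample binomial counts — an
  identical likelihood, an order of magnitude faster.
* **Level:** gamma mixed regression with log link on the depth-scaled
  values of expressing cells only, same fixed and random structure; the
  effect is a natural-log fold change. The component is reported absent
  with fewer than 2 expressing cells per condition. Dispersion is
  estimated per gene.

Both fits use Laplace-approximated ML (lme4). On non-convergence the model
falls back to a fixed-effects GLM with sample as a covariate; on complete
separation the induction effect falls back to the Haldane-corrected 2x2 log
odds ratio with Woolf standard error. Every fallback is flagged in the
output. BH adjustment is applied across genes within each cell type and
component. With the sample random-intercept variance at zero the mixed
estimates coincide with plain GLM estimates, and under planted single-
component effects the other component stays centered at zero — both checked
in the test suite.

Cell-type proportion shifts are tested by a baseline-category multinomial
logit of cluster membership on condition (no random effect), with a 0.5
pseudo-count on the cluster-by-condition table when a cluster is absent
from one condition. For two clusters this reduces exactly to the 2x2 log
odds ratio.

Preranked GSEA uses the classic weighted Kolmogorov-Smirnov running sum
(weight = |statistic|), with gene-label permutations and a two-sided p from
the permutation distribution of |ES|. The source ranks genes "by the
p-value of the estimated effect"; a two-sided enrichment needs a sign, so
the ranking statistic is `sign(effect) * -log10(p)` (`gsea_rank_stat()`).
Adjustment is per call — run one call per cell type to match per-cell-type
adjustment. The running sum is checked in the tests against an independent
loop implementation and against fgsea to machine precision.

## ISH puncta statistics

Automated ISH image analysis reports, per slide and probe, how many cells
carry 1..9 or "10+" fluorescent puncta. Because a single punctum does not
prove a cell positive, the species comparison is repeated at every
binarization threshold `b = 2..10` ("at least b puncta" = positive,
pooled over samples within species), giving nine log-odds species effects
against the mouse baseline, each with a Woolf standard error (0.5
continuity correction when a table cell is zero, flagged).

The nine effects are then averaged and the mean divided by a standard error
to give one z statistic. The nine binarizations re-use the *same cells*, so
the effects are strongly positively correlated; the naive
`sd(effects)/sqrt(9)` measures only bin-to-bin differences, ignores the
shared sampling component, and in null simulations rejects at |z| > 1.96
more than half the time. The default standard error is therefore the mean
of the per-bin standard errors — the exact limit under perfect correlation
and conservative otherwise (measured null exceedance ~1-3%, full power at a
log-odds-2 species effect). The naive between-bin estimate and an
inverse-variance combination remain available via `se_method`.

## Gene-family evolution

**Orthology.** One-to-one orthologs are reciprocal best hits between the two
species' transcript/protein forms, after discarding hits with
`e-value >= 0.1` or `identity <= 80%` (both bounds strict per the published
thresholds), aggregating forms to genes by best bitscore. Annotated
pseudogenes join a family orthogroup when they hit any protein-coding
member past the same thresholds; multi-family hits resolve to the best
e-value, ties to identity, and residual ties are flagged.

**Putative pseudogenes.** Old, unannotated family relics are recovered from
EST-style genomic homology hits in five stages: keep hits with >= 40%
identity; merge interval-overlapping hits whose queries share a family
(1-based inclusive coordinates, >= 1 shared base, strand ignored); require
the merged hit's conserved-domain confirmation to pass `e < 0.1` *and*
`identity > 60%`; restrict to the family's locus scaffolds; and drop
anything overlapping an annotated gene. The merge step is idempotent. A
benchmark counts, among merged hits covering annotated genes, the fraction
landing on a *different* family than the query; families at or above 5%
false positives are flagged and their putative-pseudogene calls suppressed
— in the real data this removes the LILR and KIR families, whose defining
immunoglobulin domain is shared, and the phyletic pattern zeroes their
putative counts accordingly.

**Phyletic pattern and ancestral counts.** Per species and family the
pattern counts protein-coding genes (P), annotated pseudogenes (Psi) and
putative pseudogenes (psi), with explicit zeros. Ancestral family sizes are
reconstructed on a rooted species phylogeny by Sankoff parsimony with cost
`|i - j|` — linear in the change of gene number, the natural reading of a
cost "proportional to the number of genes" (any positive proportionality
constant leaves the optimum unchanged). Branch lengths are ignored, as
parsimony requires. The dynamic program runs over states `0..s_max`
(default: the maximum tip count) and is checked exactly against exhaustive
enumeration. Per-node state probabilities are the marginals of the uniform
distribution over *globally* minimum-cost full assignments, computed by an
inside-outside pass over optimal-assignment counts; the original figures'
pie-chart probabilities are not formally defined, and a simpler alternative
(uniform over a node's co-optimal states) is selectable via `prob_method`.
Unrooted input trees are rooted at a supplied outgroup or by midpoint, with
a warning.

## The synthetic data generators

The generators plant every piece of ground truth the pipeline is tested
against; their defaults are the package's study conditions.

* `simulate_droplet_experiment()`: 2000 cells in 3 populations
  (negative-binomial counts, dispersion 0.1, 10 markers per population at
  natural-log fold change 2), 2000 empty droplets drawing the
  population-average ambient profile, 3% doublets that are sums of two
  freshly drawn cells, and two ambient "hemoglobin-like" genes added as
  Poisson background to every barcode in proportion to its depth —
  mirroring the observation that hemoglobin transcripts from lysed red
  blood cells are captured by essentially all barcodes. Cell depths are
  log10-normal (3.5, 0.05), empties (1.5, 0.20). The tight cell-depth sd
  is what makes the doublet mode (displaced by +log10 2) a *separate*
  density mode rather than a shoulder; at sd 0.10 no local maximum exists
  there and no mode-based rule could detect the planted doublets. Real
  datasets have broader depth spreads, so passing these tests shows the
  rules recover planted structure, not that depth-based doublet detection
  is powerful on arbitrary real data.
* `simulate_nested_populations()`: a 3 x 2 hierarchy (strong top-level
  markers, weaker subpopulation markers) for the iterative clustering.
* `simulate_condition_effects()`: the hurdle generative model itself —
  per-gene expression probability `logit^-1(logit(pi0) + delta t + b_s)`
  and gamma levels with log-mean `log(mu0) + beta t + b'_s`, discretized to
  positive counts; per-sample random intercepts on both scales; two
  samples per condition by default. Because the level values are rounded
  to integers, gamma-model recovery is tested against the planted beta and
  is accurate to a few percent at the default mean level of 5.
* `simulate_puncta_table()`: zero-inflated geometric puncta counts (the
  original work defines only the bins, not a generative model), species
  shifting the positivity log-odds.
* `simulate_gene_count_history()`: a birth-death jump process along
  branches (gains at `gain_rate`, losses at `loss_rate` while the count is
  positive), labelling every node.
* `simulate_homology_tables()`: two species, six families on three locus
  scaffolds; orthologs are reciprocal best hits at 92% identity with
  within-family off-diagonal hits at 83%; decayed unannotated copies sit
  intergenically at ~52% identity with passing domain confirmation; a
  configurable fraction of genomic hits is redirected to a partner family
  (LILR/KIR-style domain confusion), with the realized confusion recorded
  in the truth so the false-positive benchmark can be checked exactly.
* `make_reference_profiles()`: a TPM reference where each type's markers
  exceed every other type by a fixed factor and columns sum to one
  million; planting equal marker counts per type keeps normalization from
  distorting the specificity ratios.

What these generators deliberately do *not* emulate: batch effects,
ambient contamination beyond the hemoglobin-style genes, cell-cycle or
doublet expression structure, mappability and annotation artifacts in the
homology tables, and overdispersion between ISH slides. Passing tests
therefore demonstrates correctness of the procedures against their own
model assumptions, not robustness to everything real data does.

## Problem sizes and determinism

The test-suite and acceptance-script problem sizes (2000 + 2000 barcodes
for QC over tens of seeds, 2000 cells for the nested clustering, 200 null
and 50 effect genes at 1000 cells per condition for the hurdle model, 100-
200 replicates for the ISH and Sankoff checks) were chosen so the full
validation completes on a single CPU in a few minutes while keeping Monte
Carlo error well inside the asserted bounds. Every stochastic routine takes
an explicit integer seed, and all generators are bit-reproducible under a
fixed seed.

## Known limitations

* The clustering quality metric is a stand-in for an undefined published
  metric; different metrics can change the chosen resolution on marginal
  data.
* Depth-based multiplet detection is intrinsically weak when the cell
  depth spread is wide; the generator's tight spread represents the
  best case.
* The gamma level model inherits lme4's occasional convergence fragility
  at very low expressing-cell counts; fallbacks are flagged rather than
  hidden.
* Sankoff parsimony ignores branch lengths by construction; a birth-death
  likelihood model would use them but is a different method.
* The ISH combined statistic treats samples as poolable within species; a
  slide-level random effect is outside the published procedure.
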