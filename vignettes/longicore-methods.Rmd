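---
title: "Mining longevity-associated core gut microbiota: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining longevity-associated core gut microbiota: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longicore)
```

## The problem

Cohort studies of long-lived populations repeatedly find that the gut
microbiota of people over 90 differs from that of younger adults, but
abundance comparisons alone are fragile across geography and ethnicity, and
low-abundance taxa can matter more than their counts suggest. `longicore`
implements a discovery chain that addresses this by working on the
*interaction structure* of the community instead of marginal abundances:

1. build a weighted co-abundance network over OTUs,
2. decompose it into modules and correlate module summaries (eigengenes)
   with a binary longevity trait,
3. extract hub taxa of the significant module by maximal neighbourhood
   component (MNC) centrality,
4. cross-validate the hubs against dual random-forest importance rankings at
   the genus level, and keep the intersection as the core genera.

Two satellite workflows support the downstream strain work: a PCA composite
score that ranks candidate probiotic isolates from three phenotypic assays,
and the 2^-ddCt arithmetic for qPCR relative expression of target genera.

## Weighted co-abundance network

Counts are transformed to `log1p` of counts-per-10k by default (a variance
stabilisation for overdispersed, compositional amplicon counts; Hellinger
and identity transforms are available). OTUs are then pre-filtered by median
absolute deviation, keeping the most variable half — MAD is robust to the
long zero-tails of amplicon data, and mostly-zero OTUs (MAD 0) drop out
first. Ties at the keep boundary are resolved by original column order so
the filter is deterministic.

The network is unsigned by default: \(a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta\).
The soft threshold \(\beta\) is chosen per dataset as the smallest value on
the grid whose signed scale-free topology fit \(R^2\) reaches 0.85 (falling
back to the argmax when no value reaches it). On synthetic cohorts of
150 samples by 2,000 OTUs the selection typically lands between 14 and 20
with mean connectivity near zero — the regime expected for sparse
microbiome tables. Adjacency is augmented into the topological overlap
matrix

\[
TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
                {\min(k_i, k_j) + 1 - a_{ij}},
\]

which credits shared neighbours and stabilises the clustering.

### Module detection

Modules are branches of the average-linkage dendrogram of \(1 - TOM\). The
published dynamic hybrid tree cut is simplified here in a way that keeps its
two tunables (minimum module size 25, split sensitivity `deep_split` 3) but
replaces the branch-shape analysis with an adaptive static cut: soft
thresholding compresses dissimilarities towards 1, and on the
\(-\log_{10}(1 - h)\) scale of merge heights the joins inside modules sit
orders of magnitude below the band of joins among unclustered taxa. The cut
is placed inside the widest gap of that scale; `deep_split` (0–4) moves it
towards the noise band, splitting more aggressively. Clusters below the
minimum size fall back to the reserved `grey` label, and a reassignment
stage then attaches leftover OTUs to the nearest module when their average
dissimilarity to its members is within the module's own 95th-percentile
internal scatter — the role the PAM-like stage plays in the hybrid cut.
This simplification is validated behaviourally: planted two-block designs
are recovered with purity above 95%, independent-OTU nulls stay grey, and
the planted trait module is the minimum-p module in essentially all seeds
at the 150 × 2,000 study scale (see `tests/testthat/test-acceptance.R`).

Module labels are colour names assigned by decreasing size from a fixed
palette, ties by first member, so runs are comparable. Eigengenes are first
principal components of the standardised member profiles, unit variance,
oriented to correlate non-negatively with the mean member profile (for the
degenerate anti-correlated pair the first member is the reference). Modules
whose eigengenes are closer than `merge_cut = 0.25` (dissimilarity
\(1 - \mathrm{cor}\)) are merged iteratively until stable.

### Module–trait statistics

Eigengenes are Pearson-correlated with each numeric trait; p-values use the
asymptotic t distribution on \(n - 2\) degrees of freedom. Mirroring the
conventional workflow, no multiple-testing correction is applied to the
module–trait p-values by default (`adjust = "BH"` is available). Gene
significance (GS, OTU–trait correlation) and module membership (MM,
OTU–eigengene correlation) are reported per OTU, and the per-module
correlation of |MM| with |GS| follows the field's absolute-value plotting
convention. Whether the binary longevity flag or continuous age is the
trait of interest is left to the caller — both are supported, and flipping
the 0/1 coding exactly negates every correlation while preserving p.

## Hubs and the random-forest cross-check

The significant module is exported as a weighted network. Because no
published absolute TOM cutoff generalises across module sizes, the default
export is density-controlled: the strongest \(3 \times |\mathrm{module}|\)
edges (an absolute threshold mode exists). MNC — the size of the largest
connected component among a node's neighbours — is computed on the
thresholded, unweighted graph, matching how hub scores behave on imported
edge lists; hubs are ranked by (MNC, weighted connectivity, id).

The random forest is a 500-tree regression forest on genus-level relative
abundances with the binary group coded 0/1, a maximum depth of 7
(implemented as a cap of \(2^7\) terminal nodes, the closest control the
forest implementation exposes), and a mandatory seed. Regression on the 0/1
outcome is deliberate: it reproduces the %IncMSE (out-of-bag permutation)
panel alongside IncNodePurity (impurity) importance. Features default to
the genera of the significant module. The core set is
\((\mathrm{top}_{perm} \cap \mathrm{top}_{imp}) \cap \mathrm{hubs}\),
reported in hub order; the union of the two forest lists is attached for
inspection since published accounts are ambiguous between union and
intersection at the middle step — the intersection is used because it is
the stricter reading consistent with a five-genus final result.

## Composite strain scoring

Assay arithmetic: GI survival \(= 100 \cdot \mathrm{CFU}_{after} /
\mathrm{CFU}_{before}\); self-aggregation and hydrophobicity
\(= (1 - A/A_0) \times 100\) — note the percentage multiplies the whole
complement, the only reading that yields positive percentages for real
absorbances. Indicators are z-scored per column, so the score is invariant
to affine rescaling of any raw assay.

The Kaiser–Meyer–Olkin statistic gates the PCA (warning at \(\le 0.6\)).
Components of the \(3\times3\) indicator correlation matrix are retained up
to 90% cumulative explained variance; loadings are eigenvectors scaled by
\(\sqrt{\mathrm{root}}\) with the dominant loading of each component made
positive (a deterministic resolution of eigenvector sign). The composite
score weights each retained component's loading contrast by its share of
the cumulative variance:

\[
F_{sum} = \sum_{c=1}^{m} \frac{v_c}{M} \sum_i \ell_{ic} X_i .
\]

The inner sum runs over the three indicators and the outer over the
retained components — the only dimensionally consistent reading of the
published formula, whose printed index limits are garbled. The coefficients
are the loadings as printed in load-factor tables (a score-coefficient mode,
\(\ell_{ic}/\mathrm{root}_c\), is available behind a flag).

## qPCR relative expression

\(\Delta Ct = Ct_{target} - Ct_{ref}\) per sample;
\(\Delta\Delta Ct\) subtracts the control group's mean \(\Delta Ct\)
(arithmetic mean, the standard convention; median optional), and the fold
change is \(2^{-\Delta\Delta Ct}\) with efficiency fixed at 2 (an
efficiency-corrected mode exists). Centring makes the geometric mean of
control folds exactly 1, and shifting all Ct values by a constant leaves
folds unchanged — both are tested invariants.

## What the synthetic cohorts emulate

The generator produces the statistical structure the analysis assumes, at
the scale of the motivating study: ~135 stool samples, thousands of OTUs,
correlated OTU blocks driven by latent factors (default five modules of
80/60/50/40/30 OTUs with loading 0.8), one block whose factor correlates
0.5 with a balanced binary longevity flag, lognormal–Poisson counts
(negative-binomial optional), and background OTUs with 60–90% zeros.
`core_recovery_design()` additionally aliases half of the trait module to
the five core genus names with a boosted loading and a 0.8-SD class shift,
which is what makes genus-level recovery a meaningful end-to-end test.
Taxonomy is assigned deterministically in genus blocks of ten OTUs across
four common phyla.

What it does *not* emulate: phylogenetic correlation, read-level artifacts
(chimeras, denoising), uneven sequencing depth beyond Poisson variation,
and realistic rank-abundance tails. Passing the recovery suites therefore
shows the chain is correct and well-calibrated under its own assumptions,
not that any particular real cohort will yield a module with the same
statistics.

One emergent behaviour worth knowing: because relative abundances are
compositional, a strong trait-linked module depresses the relative share of
every other taxon in trait-positive samples, so unlinked modules can show
(weaker) significant negative correlations. The planted module remains the
minimum-p module; the extra selections are a faithful property of
closed compositions, not a bug.

## Numerical choices and degenerate inputs

* Chao1 uses the bias-corrected denominator \(F_2 + 1\), so doubleton-free
  samples are defined; Shannon defaults to natural log (base is
  configurable); Simpson is Gini–Simpson.
* PERMANOVA p-values are \((1 + \#\{F_\pi \ge F\})/(1 + n_\pi)\); perfectly
  separated groups give an infinite pseudo-F and the minimal attainable p.
* All-zero samples, zero-variance OTUs, singleton groups, constant traits,
  singular correlation matrices and sub-minimum module counts raise errors
  (or a warning plus an all-grey partition where the spec of the workflow
  calls for degradation rather than failure).
* Every stochastic step takes an explicit seed; generators restore the
  caller's RNG state. Stage seeds are derived from the pipeline's global
  seed, and repeated runs are byte-identical.

## Problem sizes used in the checks

The test and acceptance suites run the trait-module recovery at 150 samples
by 2,000 OTUs over 50 seeds, end-to-end core-genus recovery at 135 samples
by 800 OTUs over 20 seeds, PERMANOVA calibration over 500 null simulations
at n = 20, and exhaustive MNC verification over all labelled graphs on up
to five nodes plus random graphs on six to eight. These sizes were chosen
as the smallest at which the planted effects operate at study-like
signal-to-noise.

## Known limitations

* The dynamic cut is a behavioural simplification of the hybrid algorithm;
  on dendrograms with nested module scales a single gap-based cut can merge
  sub-modules that the full branch analysis would separate (the eigengene
  merge step partially compensates in the opposite direction).
* No block-wise decomposition: networks beyond ~20k OTUs will be slow and
  memory-hungry.
* PERMANOVA assumes exchangeable samples; no strata support.
* The RF importance ranking is not a calibrated test; it is used only as a
  ranked filter, as in the motivating workflow.
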