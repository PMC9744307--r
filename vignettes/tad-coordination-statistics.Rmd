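---
title: "TAD-level coordination statistics: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TAD-level coordination statistics: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadcoord)
```

# Scope

`tadcoord` implements the statistical layer used to analyse nascent
transcription after perturbing the cohesin regulators NIPBL and WAPL:
whether differentially expressed genes (DEGs) cluster within topologically
associating domains (TADs), whether DEGs sharing a TAD change expression in
a coordinated direction, whether DEG promoters sit near chromatin-loop
anchors, whether two DEG sets overlap more than chance, whether a
double-knockdown rescues single-knockdown misexpression, and how Oligopaint
FISH domain geometries summarise cross-boundary contact. Upstream machinery
(alignment, differential-expression model fitting, Hi-C processing, peak
calling, image segmentation) is out of scope: the package consumes their
standard outputs (BED, BEDPE, bedGraph, TSV tables).

# The statistics

## DEG status

A gene is a DEG when its adjusted p-value is present and `padj <= alpha`
(`alpha = 0.01` by default, inclusive at the boundary). Genes with missing
`padj` are kept in tables — the rescue classifier needs them — but never
count as DEGs. Direction is the sign of the shrunken log2 fold change.

## Clustering within TADs

Each active gene is assigned to the TAD containing its dominant TSS
(half-open intervals, BED convention; TADs must partition each chromosome).
The clustering statistic is the unweighted mean over TADs, among TADs with
at least one gene of the relevant universe, of the percentage of that TAD's
genes carrying the label (DEG among active genes, or active among all
genes). The null is built by shuffling the labels uniformly across the gene
universe, keeping category counts fixed, and the p-value is the percentile
rank of the observed statistic: the fraction of null values at or above it.
Ties between observed and null count toward the null tail (the conservative
choice), and p can be exactly 0.

An algebraic property of this statistic deserves emphasis. When every TAD
holds the same number of universe genes, the mean of per-TAD fractions
equals the global label fraction *identically*, so the statistic is
invariant under label shuffling and cannot detect clustering at all. It
responds to clustering only through covariance between label placement and
per-TAD gene density: concentrating DEGs into gene-poor TADs raises the
mean of fractions above the global rate. We implement the statistic
literally as defined and document this behaviour rather than substituting a
different score; consequently, demonstrations of the "exact test, p = 0"
regime (including `scripts/acceptance.R`) place all DEG labels in the
gene-poorest tenth of TADs — ten 5-gene TADs against ninety 20-gene TADs —
which is the configuration in which the test has power. With equal per-TAD
gene counts the same pipeline provably returns an uninformative p, and a
unit test asserts that invariance.

## Coordination within TADs

For each TAD holding at least two DEGs (the score is undefined below two;
the eligibility threshold is configurable), the coordination score is the
majority fraction of its DEG directions, `100 * max(#up, #down) / n`, so
50% is an even split and 100% is unanimity. The genome-level summary is the
unweighted mean over eligible TADs, plus counts in five 10-point bins
(upper-inclusive; a score of exactly 50 joins the 50–60 bin). The null
shuffles the up/down directions among DEG slots with TAD membership fixed;
the per-bin comparison reports percentile-rank p in both directions
(enrichment and depletion). If all DEGs share one direction the permutation
cannot vary and p = 1 is returned with a warning rather than an error.

## Enrichment and overlap

Loop-anchor proximity uses edge distance: 0 for a TSS inside an anchor,
otherwise the gap to the nearer interval edge, minimised over both anchors
of every loop. Groups are dichotomised at a threshold (5 kb primary,
200 kb secondary) and compared by Fisher's exact test; both one-tailed
(enrichment) and two-sided p-values are reported, with the groups' own
totals as margins. The distance–fold-change relation is a Spearman
correlation of anchor distance against `|log2fc|` by default — figures in
this literature plot unsigned "fold change", and magnitude is the monotone
notion compatible with "closer genes change more" — with a signed mode
available. Gene-set overlap uses the one-tailed upper hypergeometric tail
with a fixed 20,000-gene universe filling the non-overlap cells.

## Rescue classification

A single-knockdown DEG is **fully** rescued when it is no longer
significant in the double knockdown (`padj > alpha` or missing; a gene
absent from the double table also counts as fully rescued, with a warning,
since it passed no significance call); **partially** rescued when still
significant in the same direction with strictly smaller `|log2fc|`
(equality is not "diminished"); otherwise **not rescued**. Significant sign
flips are not silently merged: they are classed not rescued and flagged.
The three categories always partition the single-knockdown DEG set, and
raising `alpha` can only move genes out of the fully-rescued class.

## Dominant-TSS calling

3′-end signal is summed over a promoter window from the annotated TSS to
150 nt downstream. The window is taken inclusive of both the TSS base and
position TSS+150 (151 positions), mirrored on the minus strand; the
upstream source describes the window only as "TSS to +150 nt downstream",
so the inclusivity convention is fixed here and configurable — off-by-one
drift is the classic failure mode, and a fixed convention is testable.
TSSs with 9 or fewer counts are inactive; each gene's active TSSs collapse
to one dominant call by a deterministic cascade: highest window count, then
furthest-upstream TSS (strand-aware), then longest transcript, then lowest
numeric portion of the gene id, with a final numeric-transcript-id
comparison appended so the order is total within a gene. Dominant TSSs of
different genes sharing a start are all kept (one call per gene) and
flagged, since the upstream description does not say a gene is dropped.
Pooling across samples is a separate helper (`sum_signal_tracks()`),
keeping the caller single-track.

## FISH contact statistics

Alleles are summarised post-segmentation as spheres (centroid + radius, in
nm). Contact means surface-to-surface separation at or below 250 nm
(boundary inclusive; overlapping domains always contact). The written
methods of the source study state the colocalisation rule with an
inequality that contradicts its own results ("contact defined by > 250 nm
colocalization"); we adopt the ≤ 250 nm separation reading, the only one
under which cohesin loss can reduce contact frequency as observed.
Overlap volume is the closed-form sphere–sphere lens; the overlap fraction
normalises by the smaller domain's volume by default (union or either
domain are selectable — the upstream normalisation is unstated, so none is
asserted as "the" published choice). Distribution comparisons use the
two-sided Mann–Whitney test with mid-rank ties. Gene–domain configurations
are *interacting* when strictly more than half of the gene-probe volume
lies inside the union of the flanking domains, computed by a deterministic
midpoint-lattice integration over the gene sphere (closed forms do not
exist for the three-sphere union); exactly one half is *exclusion*.

# The synthetic-data generator

The generator emulates the statistical structure each stage assumes, not
the raw data: non-overlapping TADs on one chromosome with 1–3 transcripts
per gene (duplicate TSSs included, to exercise tie-breaking); DEG labels
with an exact marginal count, a tunable clustering weight toward a
designated (gene-poorest) fraction of TADs, and per-TAD latent directions
adopted with probability `coordination`; adjusted p-values drawn
log-uniform below `alpha` for DEGs and uniform above it otherwise (only
threshold crossings matter downstream); negative-binomial promoter-window
totals spread multinomially at single-base resolution, with inactive TSSs
capped at 9 counts; and two-sphere FISH alleles whose boundary gap falls at
or below the 250 nm cutoff with probability `contact_prob`. Everything is
reproducible from its seed.

Default scales reflect the study system: megabase TADs, ~150 nt promoter
windows, ~10% DEG rates, 0.01 significance, 400 nm domain radii and a
250 nm contact cutoff. What the generator does *not* emulate: inter-gene
count correlation, expression-level-dependent power, realistic TAD length
or gene-density distributions across chromosomes, segmentation error in
FISH, or any genome-build specifics (the package is build-agnostic and
performs no liftover). Passing tests therefore validate the statistical
machinery, not biological discovery on real data.

# Numerical and calibration choices

* Permutation p-values are raw proportions (`#null >= obs / n_perm`), so
  p = 0 is reportable, matching the "exact test, p = 0" convention; a
  `(r+1)/(n+1)` style estimator is deliberately not the default.
* Permutations are sampled uniformly, never enumerated, in the
  implementation; exhaustive enumeration lives only in the test oracles
  (all instances with ≤ 8 genes, hypergeometric universes ≤ 50,
  Mann–Whitney at 3-vs-3, sphere-lens quadrature).
* Calibration tests run 200 replicate null simulations (clustering weight
  1, coordination 0.5) on a 40-TAD × ~8-gene genome with a 40% DEG rate at
  200 permutations each, and check p-uniformity by Kolmogorov–Smirnov at
  the 1% level. The genome is sized so the permuted statistic is
  effectively continuous: on much smaller genomes the statistic's discrete
  atoms plus the conservative ≥-tie rule visibly distort the p
  distribution, which is a property of percentile-rank p-values on
  discrete statistics, not an implementation defect.
* Worked-example and simulation problem sizes throughout the tests and the
  acceptance script (hundreds to a few thousand genes, 1,000 permutations)
  were chosen as the smallest scales at which each property is
  unambiguous.

# Known limitations

* The clustering statistic's blindness to equal-density clustering
  (above) is inherited from its definition; detecting density-independent
  clustering would need a different statistic (e.g. DEG-pair co-membership
  counts), which is intentionally not provided.
* Percentile-rank p-values are granular at 1/`n_perm` and conservative
  under heavy ties.
* The genome-wide published quantities (≈1,900 DEGs per knockdown, 80.5%
  and 84.8% average coordination, 62.5% fully rescued) depend on the full
  experimental datasets and are not reproducible from synthetic inputs;
  the package reproduces the printed worked examples and the behaviour of
  the machinery instead.

# Interfaces

The exported functions are the interface; a typical session is shown in the
README. Reading and writing use plain BED/BEDPE/bedGraph/TSV so the
pipeline composes with standard genomics tooling.
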