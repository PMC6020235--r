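---
title: "Methods: differential acetylation and expression from consensus regions"
author: "diffacet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential acetylation and expression from consensus regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`diffacet` implements an integrative two-group analysis of histone
acetylation (ChIP-seq) and gene expression (RNA-seq). This vignette is the
package's account of the statistical methods, the choices that were open in
their design, and what the synthetic-data tests do and do not demonstrate.

## Consensus region construction

Peak callers produce per-sample region lists that differ in boundaries and
in which peaks are detected. To compare samples on a common footing, the
package builds a consensus reference:

1. every per-sample peak shorter than `min_len` (default 2,000 bp) is
   stretched to exactly `min_len`, symmetrically about its midpoint;
2. all stretched peaks are pooled and overlapping intervals are merged on
   their outermost coordinates;
3. merged regions supported by fewer than `min_support` samples (default 2)
   or lying outside the autosome allowlist (`chr1`–`chr22` by default) are
   discarded.

Coordinates are 0-based, half-open (BED convention) end to end. Two
intervals merge only if they share at least one base: bookended intervals
(`end == start`) stay separate. These conventions are stated because common
interval libraries differ exactly here (1-based closed ranges merge
bookended intervals), and reproducibility of the consensus depends on them.

Two choices were genuinely open. The stretch anchor is not dictated by the
procedure's description; symmetric extension about the midpoint is the
least biased option and is what `stretch_regions()` does, shifting the
window into the chromosome when it would cross an end (and truncating only
when the chromosome itself is shorter than `min_len`). Second, sample
support is computed against the *stretched* peaks — the same objects that
were merged — rather than the raw calls, for internal consistency of the
collapsed list.

## Quantification

Each read contributes its 5' position; a region's count for a sample is the
number of positions falling in `[start, end)`. Because consensus regions
are disjoint, each read is counted at most once. No fragment extension is
applied (extension belongs to peak calling, upstream of this package), and
input is assumed duplicate-collapsed. Reads on chromosomes absent from the
region list are tallied and ignored.

## The negative-binomial Wald engine

Both arms (region counts, gene counts) use the same engine.

**Normalization.** Median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_i \; k_{ij} / (\prod_j k_{ij})^{1/n}$ over features
positive in every sample. Size factors are scale equivariant in the ratio
sense: multiplying one sample's counts by $c$ multiplies its factor by $c$
relative to every other sample (the absolute factors all shift by
$c^{1/n}$ because the geometric means rescale).

**Dispersion.** Per feature, a method-of-moments estimate on normalized
counts, $\hat\alpha_i = \max\{(v_i - m_i)/m_i^2,\ 10^{-8}\}$, where $v_i$
is the within-group pooled variance (df $= n - 2$) and $m_i$ the overall
normalized mean. A mean–dispersion trend $\alpha(m) = a_0 + a_1/m$ is
fitted by least squares across features, and the working dispersion is
$\hat\alpha^*_i = (1-w)\hat\alpha_i + w\,\alpha(m_i)$ with $w = 0.5$. This
is a deliberately simple stand-in for the moderated estimators of the
established count-model packages: no Cox–Reid adjustment, no outlier
replacement, no independent filtering. Calibration, not equality with any
particular package, is the design goal; one test nevertheless cross-checks
fold-change estimates against DESeq2 on a small simulated matrix.

**Testing.** Per feature, an NB GLM with log link,
$\log \mu_{ij} = \log s_j + \beta_{0i} + \beta_{1i} x_j$ ($x_j$ the case
indicator), is fitted by iteratively reweighted least squares with the
dispersion held fixed (at most 100 iterations, convergence at
$10^{-8}$, linear predictor clamped to $\pm 30$; non-converged features
get `p = NA` and are excluded from the multiple-testing denominator). The
Wald statistic $\hat\beta_1 / \mathrm{SE}(\hat\beta_1)$, with the standard
error from the observed Fisher information, is referred to a standard
normal, two-sided; no fold-change shrinkage is applied. Benjamini–Hochberg
adjustment uses `stats::p.adjust` on the non-`NA` p-values. Features with
zero counts in all samples are dropped (and logged) before testing.

Direction calls default to the adjusted p-value at 0.05 for both arms. The
raw-p variant is available via `use_padj = FALSE`, since thresholding
conventions differ between the two arms in parts of the literature this
workflow mirrors; the adjusted threshold governs all headline counts here.

**Calibration, honestly stated.** On a null simulation (no planted effects,
5,000 features, n = 5 vs 4, $\alpha = 0.05$) the fraction of raw p < 0.05
is about 0.06: the plug-in Wald test is mildly anti-conservative at these
sample sizes, as is well known for this test family. Consequently the
realized false discovery proportion at padj < 0.05 on the default synthetic
study is around 0.07–0.13 depending on the seed — close to, but not always
below, 0.10. Sensitivity for the planted |log2FC| = 2 effects is
essentially 1. Users who need stricter FDR control at this design size
should tighten the threshold or use a heavier-tailed reference.

## Exploratory structure

For visualization and clustering the counts are quantile-normalized, then
log2-transformed with a pseudocount of one read per region, then row
median-centered — in that order. Quantile normalization by default assigns
sorted target values in stable sort order, which makes the transform
exactly idempotent and every column's multiset of values identical; the
alternative `ties = "mean"` averages tied targets (equal inputs map to
equal outputs) at the price of those exact properties on discrete data.
The pseudocount of 1 is the natural "one read" choice for count data.

Hierarchical clustering uses average linkage on Euclidean distances
(defaults, configurable; nothing in the workflow constrains them), applied
to the differential regions. PCA takes the `n_top = 500` most variable
regions, row-centered, via SVD. Outlier flagging operationalizes "extreme
PCA outlier" as a PC1/PC2 score more than `k_sd = 3` MAD-based robust
standard deviations from its group mean; the package only reports flags —
sample exclusion is an analyst's decision.

## Annotation and integration

A gene links to a region when the region overlaps the window
±20 kb around its TSS, i.e. the minimal TSS-to-region distance is at most
`window`. Distance is measured to the nearest region base (0 when the TSS
lies inside the region); strand is ignored for distance and kept for
reporting. Genes near both hyper- and hypoacetylated regions stay in both
gene sets and are listed as conflicts. Concordance compares the expression
log2FC of genes near hyper (resp. hypo) regions with all genes by one-sided
Wilcoxon rank-sum tests in the expected direction, and the overlap lists
intersect the annotated gene sets with the up/down RNA calls.

## Motif enrichment

PWMs are read from minimal MEME files (probability rows floored at
$10^{-4}$ before log-odds). A sequence is a hit for a motif when the best
window on either strand scores at least `score_fraction = 0.8` of the
motif's maximum attainable log2-odds score; windows containing `N` (masked
bases) are skipped. This thresholded best-site rule is a deliberate,
deterministic simplification of the scoring used by motif-enrichment suites
such as AME — it is closed-form verifiable and preserves the enrichment
contract, but it is not a reimplementation of any particular tool's
default. Per motif, a 2×2 table of hit counts in foreground vs background
sequences is tested by one-sided Fisher's exact test (enrichment only),
BH-corrected across motifs. The scanning background is uniform by default;
`background_model = "empirical"` uses the background set's base
composition. Enriched motifs are joined to differentially expressed
transcription factors through a user-supplied motif-to-gene map.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
defaults fixed at the emulated study design:

| parameter | default | meaning |
|---|---|---|
| `n_case`, `n_control` | 5, 4 | samples per group |
| `n_chromosomes`, `chrom_length` | 5, 10 Mb | autosomes `chr1..chr5` |
| `n_true_regions` | 3000 | true signal regions, ≥ 5 kb apart |
| `frac_hyper`, `frac_hypo` | 0.015, 0.015 | planted differential fractions |
| `planted_lfc` | 2.0 | planted |log2FC| (regions and genes) |
| `base_mean_range` | 20–500 | per-feature base means (counts) |
| `dispersion` | 0.05 | NB $\alpha$, Var $= \mu + \alpha\mu^2$ |
| `peak_dropout` | 0.2 | per-sample peak miss probability |
| `n_genes` | 5000 | TSS catalog size |
| `coupling_prob` | 0.7 | P(concordant expression LFC | TSS within 20 kb) |
| `bg_de_rate` | 0.02 | background DE rate among uncoupled genes |
| `n_motifs` | 10 | PWMs (about half planted) |
| `motif_plant_rate_fg`, `_bg` | 0.5, 0.05 | consensus insertion rates |
| `n_sequences`, `seq_length` | 200, 500 bp | per sequence set |

Choices the design left open, fixed once: true-region widths are uniform on
500–1500 bp (typical peak scale before the 2-kb stretch); regions are
placed with ≥ 5 kb gaps so the consensus-to-truth mapping is unambiguous
and region-level sensitivity/FDR are well defined; regions not overlapping
a true region draw their background mean from the low decile of
`base_mean_range` (uniform on [20, 68] at defaults); sample size factors
are log-uniform on [0.5, 2] (overridable to 1 for moment checks); when a
gene's TSS lies within 20 kb of several differential regions the closest
region sets its direction; of the 10 motifs, 3 are planted in the
hyper-direction sequence set and 2 in the hypo set, and the motif-to-gene
map points planted motifs at correspondingly regulated genes so end-to-end
TF linkage has a recoverable truth. Peak jitter is ±200 bp at both ends.
All stages are deterministic given the seed (stage-specific derived seeds),
and written bundles are byte-identical across repeat runs.

What the generator does *not* model: read-level data (FASTQ/BAM), fragment
length and GC effects, copy-number structure, overdispersion trends beyond
$\alpha$ constant in $\mu$, correlated genes, and realistic sequence
composition (backgrounds are i.i.d. uniform ACGT). Passing tests therefore
demonstrate the correctness and calibration of the algorithms under the
assumed model, not robustness to the artifacts of real sequencing data.

## Problem sizes and numerical notes

The test suite and the acceptance script run the full design above (3,000
regions × 9 samples, 5,000 genes, 10 motifs × 400 sequences), sizes chosen
so the complete study runs in seconds while estimates (dispersion trend,
calibration fractions) are stable. IRLS is initialized from group-mean
ratios with means floored at $10^{-3}$; the dispersion floor is $10^{-8}$;
degenerate inputs (all-equal counts, constant features, empty classes,
sequences shorter than a motif) are exercised in the unit tests. Ties in
quantile normalization and bookended intervals in merging are the two
places where superficially equivalent conventions change results; both are
pinned by tests.
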