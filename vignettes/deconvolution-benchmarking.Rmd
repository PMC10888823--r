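---
title: "Benchmarking cell-type deconvolution with Mean Ratio markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cell-type deconvolution with Mean Ratio markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconvbench)
```

## The problem

Bulk RNA-seq measures a mixture: the expression of a tissue sample is,
to first order, a composition-weighted combination of the expression
profiles of its constituent cell types. Reference-based deconvolution
inverts that mixture using single-cell or single-nucleus reference
profiles. Three practical complications dominate accuracy in complex
tissue such as cortex:

1. **Marker quality.** Estimators are only as good as the genes that
   distinguish cell types. Genes chosen by a one-vs-all differential
   test can still be expressed in a second cell type, leaking signal
   between the corresponding proportion estimates.
2. **Cell size.** Cell types differ in RNA content — neurons carry
   substantially more RNA than glia — so expression-based estimators
   recover the fraction of *RNA* attributable to each type, not the
   fraction of *cells*.
3. **Library-preparation bias.** The same tissue quantified with polyA
   enrichment versus ribosomal depletion, or from cytoplasmic versus
   nuclear RNA, yields systematically different counts for many genes
   ("differentially quantified genes", DQGs). When a cell type's
   markers are over-quantified in one library type, its estimated
   proportion inflates there.

`deconvbench` implements a marker statistic addressing (1), an
adjustment for (2), enrichment diagnostics and a bias generator for
(3), and the evaluation and sensitivity machinery to quantify all
three against known truth.

## The Mean Ratio statistic

For gene $g$ and target type $k$, with $\mu_{g,k}$ the arithmetic mean
expression of $g$ over cells of type $k$,

$$\mathrm{MeanRatio}(g,k) =
  \frac{\mu_{g,k}}{\max_{j \neq k}\ \mu_{g,j}}.$$

A value above 1 means no other type expresses the gene as highly;
large values mean the *closest competitor* is far below the target,
which is precisely the property deconvolution markers need. Degenerate
cases are defined explicitly: when the non-target maximum is zero the
ratio is $+\infty$ if the target mean is positive and 0 if both are
zero. A direct consequence used as a test invariant: for a fixed gene
at most one cell type can have a ratio above 1, so marker sets built
from a `ratio > 1` requirement are disjoint across types.

`rank_ratio` orders genes per type by descending ratio. Ties are
broken by descending target mean, then lexicographic gene id, making
the ranking fully deterministic; the tie-break is our own convention
(ties are measure-zero on real data but common in small fixtures).

Means are taken on **linear CPM** by default. A ratio of means on the
linear scale directly measures relative abundance; the
`ratio_assay = "logcpm"` switch in `marker_stats()` is provided
because reasonable implementations disagree here, and the choice
matters mostly for heavy-tailed genes.

The comparison method, `one_vs_all()`, pools all non-target cells and
computes a per-gene Welch $t$ on log2(CPM+1), ranking by the mean
log difference. Zero-variance cases follow a declared convention:
equal constant groups give $t = 0$, $p = 1$; constant groups with
different means give $p = 0$ and a `zero_var` flag rather than an
error, so rankings remain total.

## Marker-set rules

Five rules are implemented in `build_marker_sets()`:

| rule | selection | parameters |
|---|---|---|
| `full` | all common genes, every type | — |
| `one_vs_all_top_n` | best `n` by `rank_fc`, then ∩ common genes | `n = 25` |
| `mean_ratio_top_n` | best `n` by `rank_ratio`, then ∩ common genes | `n = 25` |
| `mean_ratio_over_t` | all genes with ratio > `t` | `t = 2` |
| `mean_ratio_mad_k` | ratio > median + `k`·MAD of ratios > 1 | `k = 3` |

Two conventions worth making explicit: top-N rules select **before**
intersecting with the common-gene list, so sets can hold fewer than
`n` genes (mirroring how a 7 × 25 selection can land on fewer genes
after filtering to a bulk dataset); and both threshold rules use
strict inequalities. The MAD uses the 1.4826 consistency constant
throughout the package. A type with no ratios above 1 yields an empty
set recorded in the result's `warnings` attribute — a data problem to
surface, not an error to stop on.

## Estimators

Two baselines ship in-package; anything else enters through
`register_deconv_method()` with the same contract (counts-scale bulk
and reference, annotation, marker sets in; a proportion table out).

**NNLS.** Per sample, $\min_w \lVert y - S w \rVert_2$ subject to
$w \ge 0$, solved by the Lawson–Hanson active-set method, then
$p = w / \sum_k w_k$. The signature $S$ holds per-type mean CPM over
the sorted union of marker genes; it must have full column rank
(checked). Normalisation makes the estimate invariant to the overall
scale of the bulk column. An all-zero solution (e.g. an empty bulk
sample) falls back to uniform proportions with a machine-readable
warning so batch runs never silently drop samples.

**Marker ratio.** Per type, the mean over its markers of
$y_g / S_{g,k}$ (zero-signature terms skipped), normalised across
types. With perfectly type-specific markers this is algebraically
exact for RNA fractions; it is also fast enough to run hundreds of
resampling replicates.

Both operate on linear CPM; log-scale estimation is deliberately out
of scope. Whether cell-size adjustment belongs inside an estimator or
after it cannot be distinguished from composition-level ground truth,
so it is implemented as the post-hoc transform
$q_k \propto p_k / s_k$ (`cell_size_adjust()`), the exact inverse of
how RNA fractions arise from cell fractions,
$p_k \propto c_k s_k$. Equal sizes are the identity.

## Evaluation conventions

`compare_proportions()` pools the matched (unit, cell type) pairs
within a scope and reports Pearson correlation, rmse, and relative
rmse. Pooling (rather than averaging per-sample correlations) matches
the single annotation a predicted-vs-measured scatter panel carries;
per-stratum and per-cell-type scopes are explicit options. The rrmse
denominator is the mean of the *reference* proportions within the
evaluated scope. Correlation on a constant vector is reported as
missing with a reason, never as `NaN`.

`neuronal_rsd()` uses the sample (n−1) standard deviation in
$\sigma/\mu$; the divisor is our choice and is stated here because
the quantity is scale-free either way.

`fisher_enrichment()` computes the one-sided (enrichment) p-value as
the hypergeometric upper tail and reports the *sample* odds ratio
$ad/bc$ ($\infty$ when $bc = 0$ with $a, d > 0$). The conditional-MLE
odds ratio used by some exact-test implementations differs; the
convention is recorded in the output to prevent silent disagreement.
`bh_adjust()` is standard step-up Benjamini–Hochberg.

QC flagging (`mad_flag()`) marks a sample as failing a metric when it
lies beyond median ± k·MAD within its stratum (library type being the
natural stratum), in the direction declared failing for that metric.
The grade rule — `drop` at ≥ 2 failing metrics, `warn` below that — is
configurable because observed drop decisions in practice reflect
multiple simultaneous failures but no single published cutoff.

## Sensitivity experiments

`equal_proportion_resample()` downsamples the reference to the same
number of nuclei per type (defaulting to the rarest type's count, the
only balanced choice that uses all of the rarest type), redraws
without replacement `n_reps` times, and deconvolves each draw.
Replicate $r$ uses seed `seed + r`, so any single replicate can be
reproduced in isolation. Only the reference is resampled; the bulk
side is fixed. The mean-over-replicates table and the per-(unit, type)
across-replicate standard deviation summarise stability; dispersion
shrinks as the per-type subset grows, and for the marker-ratio
estimator the mean converges to the full-reference run (both are
asserted in the test suite).

`reference_swap()` reruns one bulk dataset against several references
after harmonising label vocabularies through per-reference maps (e.g.
merging endothelial and pericyte labels into one vascular class);
references that cannot be mapped onto a common type set are an error.

## Imaging quantification

Segmented-cell tables (one row per cell: section, phenotype, nuclear
area, total-RNA puncta) are read through a configurable column map
because export schemas vary. Three conventions:

- **Radius.** Exports carry nuclear area; when no radius column
  exists it is derived as $\sqrt{A/\pi}$ (circular nucleus). The
  filter removes radius strictly greater than 5 μm — merged-nuclei
  artefacts — and is idempotent.
- **Denominator.** Section proportions divide by *all* segmented
  cells after filtering, including unlabeled nuclei; the explicit
  `other` column keeps rows summing to 1. Whether the denominator
  should instead include pre-filter totals is not decidable from
  composition data alone; post-filter is used and logged.
- **Size metrics.** Per-type medians of area, puncta, and the
  per-cell area × puncta product (the median of products, not the
  product of medians), pooled across sections by default with a
  per-section-first option.

## The synthetic generator

The generator exists so that every stage has a known truth. Its
defaults describe the tissue the toolkit is aimed at: seven broad
cortical cell types with composition Excit 0.44, Oligo 0.20, Inhib
0.11, Astro 0.10, OPC 0.07, EndoMural 0.05, Micro 0.03 (excitatory
neurons most common, microglia rarest), per-type RNA-content factors
giving neurons roughly 2–3× the RNA of small glia, log-normal
baseline gene means (meanlog 1, sdlog 1, a realistically heavy tail),
and negative-binomial reference counts (size 2) at ~2000 expected
counts per cell before size scaling. Planted markers multiply the
baseline mean by `marker_fold` in exactly one type, disjointly across
types.

Bulk expectation for sample $j$:
$$\lambda_{gj} \propto b^{(\ell_j)}_g \sum_k c_{kj}\, s_k\,
  \frac{m_{gk}}{\sum_g m_{gk}},$$
rescaled to the library depth — each cell of type $k$ contributes RNA
proportional to its size factor with the type's relative profile, and
$b^{(\ell)}_g$ is a per-gene multiplicative bias of library type
$\ell$ (baseline log-normal, plus an optional planted factor on one
type's markers in one library, the simplest mechanism reproducing the
over-quantification of a cell type's markers in one preparation and
its knock-on proportion shift). Consequently noiseless unbiased bulks
are exact mixtures: NNLS recovers RNA fractions to machine precision,
and size adjustment recovers cell fractions — the algebraic identity
the acceptance checks exercise. Bulk noise is Poisson by default
(negative binomial optional); the generator makes no claim that real
bulk libraries are Poisson, only that a one-parameter noise floor is
the right default for recovery experiments.

What the generator deliberately does **not** emulate: gene–gene
correlation, batch effects beyond library bias, doublets, ambient
RNA, length-dependent coverage bias, or realistic dropout structure.
Passing tests on this generator therefore demonstrate correctness of
the algorithms and their algebra, not performance on real tissue; the
package's value on real data is exactly that its diagnostics (DQG
enrichment, resampling dispersion, size-metric comparisons) quantify
the effects the generator idealises.

Segmented-cell simulation draws phenotypes multinomially, areas from
per-type log-normals truncated so every regular cell passes the
radius filter (tail redraws), puncta from per-type Poissons, and
plants an exact count of oversized cells so filter tests can assert
equality, not approximation.

## Problem sizes and numerical choices

The test suite and acceptance script run entirely on synthetic data
at desk scale, chosen once: the end-to-end recovery study uses 2,000
genes, 7 × 300 reference cells, 25 planted markers per type at fold
8, and 24 Poisson bulks; the resampling study uses 500 genes, 120
cells per type, 200 replicates at subset sizes 15/30/60; the imaging
study uses 50,000 cells with 1% planted oversized. Tolerances follow
the sources of error: machine-precision bounds (1e-6 to 1e-10) where
the computation is exact algebra (NNLS on noiseless mixtures,
size-adjustment inversion, log round trips), and sampling-scale
bounds (0.01–0.05) where Monte Carlo noise enters. Proportion tables
validate row sums at 1e-8. CPM totals are checked at 1e-8 relative.
All-zero units are preserved by normalisation and handled by the
uniform fallback downstream; dropping them is an explicit filter,
never a side effect.

## Known limitations

- The in-repo estimators are baselines for studying the surrounding
  machinery, not competitors to purpose-built deconvolution methods;
  external methods plug in through the registry.
- Mean Ratio operates on type means and therefore ignores
  within-type expression variance; a gene with a high ratio but huge
  target-type variance can still be a poor marker. The one-vs-all
  $t$ ranking is the complementary view.
- Cell-size adjustment assumes one scalar RNA-content factor per
  type; types whose size varies with state violate this.
- The library-bias model is multiplicative and gene-wise;
  extraction-specific (cytoplasmic/nuclear) biases can be planted
  the same way but compositional interactions between biases are not
  modelled.
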