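# deconvbench

Reference-based cellular deconvolution estimates the cell-type
composition of a bulk RNA-seq sample from single-cell or single-nucleus
reference expression. In heterogeneous tissues such as human cortex the
results depend heavily on which marker genes feed the estimator, on
differences in RNA content between cell types, and on technical biases
between RNA library preparations (polyA enrichment vs. ribosomal RNA
depletion) and RNA extractions (cytoplasmic, nuclear, whole cell).
`deconvbench` is a toolkit for studying exactly those effects. It is
aimed at method developers and analysts who want to benchmark
deconvolution pipelines against orthogonal, imaging-derived cell
counts — or against fully synthetic data with known truth — without
committing to any single external estimator.

The package provides:

- **Mean Ratio marker selection.** For gene *g* and target cell type
  *k*, with per-type mean expression μ<sub>g,k</sub> (linear CPM),

  MeanRatio(g, k) = μ<sub>g,k</sub> / max<sub>j≠k</sub> μ<sub>g,j</sub>.

  Genes with MeanRatio > 1 are expressed most highly in the target
  type; ranking by descending ratio (`rank_ratio`) yields markers with
  minimal signal in the runner-up type. The classical one-vs-all Welch
  *t* ranking is implemented alongside for comparison, plus five
  marker-set construction rules (full common genes, 1vALL top-N,
  MeanRatio top-N, MeanRatio > t, and a per-type
  median + k·MAD cutoff over ratios above 1).
- **Baseline estimators with a plug-in contract.** A non-negative
  least squares estimator (min ‖y − S·w‖₂, w ≥ 0, proportions
  w/Σw) and a marker-ratio estimator, both behind a registry so
  external methods can be swapped in with the same interface.
- **Cell-size adjustment.** Estimators on expression recover *RNA
  fractions*; dividing by per-type size factors (nuclear area, total-RNA
  puncta, or their product, measured from imaging) and renormalising
  converts them to cell-count fractions.
- **Evaluation metrics.** Pooled Pearson correlation, rmse, relative
  rmse against reference proportions; pairwise method correlations;
  within-block relative standard deviation of the neuronal fraction;
  one-sided Fisher enrichment of marker sets in differentially
  quantified gene (DQG) sets with BH correction.
- **Sensitivity experiments.** Equal-proportion reference resampling
  (downsampling every cell type to the rarest type's count, many
  seeded replicates) and reference swapping with label harmonisation.
- **Imaging quantification.** Readers and filters for segmented-cell
  tables (HALO-style CSV): radius filtering, section QC grades,
  per-section proportions with an explicit unlabeled column, and
  per-type size metrics.
- **A synthetic-data generator** producing references with planted
  markers, bulk mixtures with known cell/RNA fractions and planted
  library biases, and segmented-cell tables — so every stage above is
  testable end to end with no downloads.

## Worked example

Simulate a seven-cell-type study, select MeanRatio top-25 markers,
deconvolve with NNLS, convert RNA fractions to cell fractions, and
score against the known truth:

```r
library(deconvbench)

cfg  <- generator_config(n_genes = 1000, n_cells = 1400)
ref  <- simulate_reference(cfg, seed = 1)
bulk <- simulate_bulk(ref, n_samples = 12, seed = 2)

stats <- marker_stats(ref$expr, ref$annotation)
dplyr::filter(stats, cell_type == "Oligo", rank_ratio <= 3)
#> # A tibble: 3 x 12
#>   gene_id cell_type target_mean second_type second_mean mean_ratio rank_ratio
#>   <chr>   <chr>           <dbl> <chr>             <dbl>      <dbl>      <int>
#> 1 g0858   Oligo           1680. Excit              186.       9.04          1
#> 2 g0047   Oligo           6510. EndoMural          776.       8.39          2
#> 3 g0187   Oligo          18744. Micro             2259.       8.30          3
```

The top oligodendrocyte genes have 8–9× the expression of their closest
non-target type, close to the planted fold of 8. Build the marker sets
and estimate proportions:

```r
sets  <- build_marker_sets(stats, "mean_ratio_top_n", n = 25)
props <- deconvolve("nnls", bulk$expr, ref$expr, ref$annotation, sets,
                    metadata = bulk$metadata)
glance(props)
#> # A tibble: 1 x 5
#>   n_units n_cell_types method marker_rule      max_rowsum_dev
#>     <int>        <int> <chr>  <chr>                     <dbl>
#> 1      12            7 nnls   mean_ratio_top_n       2.22e-16

cells <- cell_size_adjust(props, ref$truth$size_factors)
compare_proportions(cells, bulk$truth$cell_props)
#> # A tibble: 1 x 5
#>     cor cor_undefined_reason    rmse  rrmse n_pairs
#>   <dbl> <chr>                  <dbl>  <dbl>   <int>
#> 1 0.999 <NA>                 0.00795 0.0557      84
```

Over the 84 pooled (sample, cell type) pairs the size-adjusted NNLS
estimates correlate 0.999 with the true cell fractions at rmse 0.008:
with clean markers and a matched reference, the pipeline recovers
composition almost exactly, so any degradation observed on real data
reflects the biases the rest of the package measures (library-type
DQGs, reference composition shifts, cell-size mismatch).

`run_benchmark()` wraps this recipe (markers × estimators grid,
optional collapsing to imaging resolution, checksummed output
manifest), and `inst/cli/deconvbench.R` exposes the stages as shell
subcommands. `vignettes/deconvolution-benchmarking.Rmd` documents the
model, the generator's assumptions, and the numerical conventions.

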