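#' Compare predicted to reference proportions
#'
#' Pools the matched (unit, cell type) pairs within each evaluation
#' scope and computes Pearson correlation, root mean squared error,
#' and relative rmse (rmse divided by the mean of the reference
#' proportions in that scope). The single pooled correlation per scope
#' matches how deconvolution accuracy is conventionally annotated on
#' predicted-vs-measured scatter plots.
#'
#' @param pred,truth `proportion_tbl` objects sharing cell-type
#'   columns (collapse first if resolutions differ) and matched on
#'   `match_on`.
#' @param match_on unit key column (default `"unit_id"`).
#' @param group_by optional character vector of metadata columns of
#'   `pred` defining evaluation strata; `NULL` gives one overall
#'   scope.
#' @param by_cell_type also stratify by cell type.
#' @return a tibble with one row per scope: grouping columns, `cor`
#'   (`NA` with `cor_undefined_reason` when either side is constant),
#'   `rmse`, `rrmse` (`NA` when the truth mean is 0), `n_pairs`.
#' @export
compare_proportions <- function(pred, truth, match_on = "unit_id",
                                group_by = NULL, by_cell_type = FALSE) {
  cts_p <- sort(prop_cell_types(pred))
  cts_t <- sort(prop_cell_types(truth))
  if (!identical(cts_p, cts_t)) {
    abort("pred and truth must share cell-type columns; collapse first.")
  }
  pl <- tidy(pred)
  tl <- tidy(truth)[, c(match_on, "cell_type", "proportion")]
  names(tl)[names(tl) == "proportion"] <- "truth"
  joined <- dplyr::inner_join(pl, tl, by = c(match_on, "cell_type"))
  if (nrow(joined) == 0) abort("no matched units between pred and truth.")
  keys <- c(group_by, if (by_cell_type) "cell_type")
  grouped <- if (length(keys) > 0) {
    dplyr::group_by(joined, dplyr::across(dplyr::all_of(keys)))
  } else {
    joined
  }
  out <- dplyr::summarise(
    grouped,
    cor = if (dplyr::n() >= 2 && stats::sd(.data$proportion) > 0 &&
              stats::sd(.data$truth) > 0) {
      stats::cor(.data$proportion, .data$truth)
    } else NA_real_,
    cor_undefined_reason = if (dplyr::n() < 2) {
      "fewer than 2 pairs"
    } else if (stats::sd(.data$proportion) == 0 ||
               stats::sd(.data$truth) == 0) {
      "zero variance"
    } else NA_character_,
    rmse = sqrt(mean((.data$proportion - .data$truth)^2)),
    rrmse = if (mean(.data$truth) > 0) {
      sqrt(mean((.data$proportion - .data$truth)^2)) / mean(.data$truth)
    } else NA_real_,
    n_pairs = dplyr::n(),
    .groups = "drop"
  )
  as_tibble(out)
}

#' Pairwise correlation between methods
#'
#' Pearson correlation between every pair of proportion tables over
#' their pooled (unit, cell type) values, e.g. to ask which estimators
#' produce the most similar predictions.
#'
#' @param tables named list of `proportion_tbl` objects sharing units
#'   and cell types.
#' @return a symmetric correlation matrix with unit diagonal.
#' @export
method_correlation_matrix <- function(tables) {
  if (is.null(names(tables))) {
    names(tables) <- paste0("method", seq_along(tables))
  }
  ref <- tables[[1]]
  units <- sort(ref$unit_id)
  cts <- sort(prop_cell_types(ref))
  vecs <- map(tables, function(tb) {
    if (!setequal(tb$unit_id, units) ||
        !setequal(prop_cell_types(tb), cts)) {
      abort("all tables must share units and cell types.")
    }
    m <- prop_matrix(tb)[units, cts, drop = FALSE]
    as.vector(m)
  })
  mat <- stats::cor(do.call(cbind, vecs))
  dimnames(mat) <- list(names(tables), names(tables))
  mat
}

#' Within-block consistency of the neuronal fraction
#'
#' Samples from the same tissue block measured under different library
#' preparations should agree on composition. Per block, this sums the
#' neuronal cell-type proportions per sample and reports the relative
#' standard deviation RSD = sigma / mu (sample standard deviation)
#' across the block's samples.
#'
#' @param props a `proportion_tbl` whose metadata includes
#'   `block_key`.
#' @param neuron_types cell-type columns summed into the neuronal
#'   fraction (default the excitatory + inhibitory classes).
#' @param block_key metadata column identifying the tissue block.
#' @return a tibble with `block`, `n_samples`, `mean_fraction`, `rsd`
#'   (`NA` when the mean fraction is 0). Blocks with a single sample
#'   are skipped with a warning.
#' @export
neuronal_rsd <- function(props, neuron_types = c("Excit", "Inhib"),
                         block_key = "block_id") {
  cts <- prop_cell_types(props)
  missing <- setdiff(neuron_types, cts)
  if (length(missing) > 0) {
    abort(paste0("neuron types absent: ", paste(missing, collapse = ", ")))
  }
  if (!block_key %in% names(props)) {
    abort(paste0("missing block column: ", block_key))
  }
  frac <- rowSums(prop_matrix(props)[, neuron_types, drop = FALSE])
  df <- tibble(block = as.character(props[[block_key]]), frac = frac)
  singletons <- names(which(table(df$block) < 2))
  if (length(singletons) > 0) {
    warn(paste0("blocks with a single sample skipped: ",
                paste(singletons, collapse = ", ")))
    df <- df[!df$block %in% singletons, , drop = FALSE]
  }
  df %>%
    group_by(.data$block) %>%
    summarise(
      n_samples = dplyr::n(),
      mean_fraction = mean(.data$frac),
      rsd = if (mean(.data$frac) > 0) {
        stats::sd(.data$frac) / mean(.data$frac)
      } else NA_real_,
      .groups = "drop"
    )
}

#' One-sided Fisher enrichment of a marker set in a gene set
#'
#' Tests whether a marker set overlaps a target gene set (e.g. genes
#' over-quantified in one library preparation) more than expected by
#' chance within a declared gene universe. The one-sided (greater)
#' p-value is the hypergeometric upper tail; the odds ratio is the
#' sample OR `ad / bc` (reported as `Inf` when `bc = 0` with
#' `a, d > 0`), a convention recorded in the output to avoid silent
#' disagreement with conditional-MLE implementations.
#'
#' @param marker_set,target_set character vectors, subsets of
#'   `universe`.
#' @param universe character vector of all eligible genes.
#' @return a one-row tibble: the 2x2 counts `a` (overlap), `b`, `c`,
#'   `d`, `odds_ratio`, `p_value`, `or_convention`.
#' @export
fisher_enrichment <- function(marker_set, target_set, universe) {
  if (length(universe) == 0) abort("empty universe.")
  universe <- unique(universe)
  marker_set <- intersect(unique(marker_set), universe)
  target_set <- intersect(unique(target_set), universe)
  a <- length(intersect(marker_set, target_set))
  b <- length(marker_set) - a
  c_ <- length(target_set) - a
  d <- length(universe) - a - b - c_
  p <- phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
  or <- if (b * c_ == 0) {
    if (a > 0 && d > 0) Inf else if (a == 0 || d == 0) 0 else NaN
  } else {
    (a * d) / (b * c_)
  }
  if (b * c_ == 0 && (a == 0 && d == 0)) or <- NaN
  tibble(a = a, b = b, c = c_, d = d,
         odds_ratio = or, p_value = p,
         or_convention = "sample (ad/bc)")
}

#' Marker-set enrichment across cell types and gene sets
#'
#' Applies [fisher_enrichment()] to every (marker cell type, target
#' set) pair and adjusts the p-values with Benjamini--Hochberg.
#'
#' @param markers a `marker_sets` tibble.
#' @param target_sets named list of gene-id character vectors (e.g.
#'   per-contrast over-quantified gene lists).
#' @param universe character vector of all expressed genes.
#' @return a tibble with `cell_type`, `target_set`, the 2x2 counts,
#'   `odds_ratio`, `p_value`, `fdr`.
#' @export
enrichment_table <- function(markers, target_sets, universe) {
  sets <- marker_list(markers)
  grid <- tidyr::expand_grid(cell_type = names(sets),
                             target_set = names(target_sets))
  rows <- purrr::pmap(grid, function(cell_type, target_set) {
    res <- fisher_enrichment(sets[[cell_type]], target_sets[[target_set]],
                             universe)
    dplyr::bind_cols(tibble(cell_type = cell_type,
                            target_set = target_set), res)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_adjust(out$p_value)
  out
}

#' Benjamini--Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control: adjusted values are
#' at least the raw values, order-preserving, and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}
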