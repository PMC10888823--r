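#' Equal-proportion reference resampling
#'
#' Cell composition in a single-cell reference is itself biased, and
#' some estimators inherit that bias. This experiment downsamples the
#' reference to the same number of nuclei per cell type (by default
#' the count of the rarest type), repeats the draw-and-deconvolve
#' cycle `n_reps` times, and reports per-replicate proportion tables,
#' their mean, and the across-replicate dispersion. Cells are drawn
#' without replacement within type; the replicate r uses seed
#' `seed + r` so any single replicate is reproducible in isolation.
#'
#' @param ref counts-scale reference `expr_matrix`.
#' @param annotation a [cell_annotation()] for `ref`.
#' @param bulk counts-scale bulk `expr_matrix`.
#' @param markers a `marker_sets` tibble.
#' @param estimator registered method name (default
#'   `"marker_ratio"`).
#' @param n_per_type cells drawn per type, or `"auto"` for the size of
#'   the rarest type.
#' @param n_reps number of replicates (>= 1).
#' @param seed base integer seed.
#' @param metadata optional bulk sample metadata.
#' @return an object of class `resample_result`: list with
#'   `replicates` (list of `proportion_tbl`), `seeds`, `mean_table`
#'   (a `proportion_tbl`), `dispersion` (long tibble of
#'   across-replicate standard deviations per unit and cell type),
#'   `n_per_type`, `estimator`.
#' @export
equal_proportion_resample <- function(ref, annotation, bulk, markers,
                                      estimator = "marker_ratio",
                                      n_per_type = "auto", n_reps = 100,
                                      seed = 1, metadata = NULL) {
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  fn <- get_deconv_method(estimator)
  ann <- align_annotation(annotation, ref)
  counts <- table(ann$cell_type)
  if (identical(n_per_type, "auto")) n_per_type <- min(counts)
  if (n_per_type > min(counts)) {
    abort(sprintf(
      "n_per_type = %d exceeds the rarest type's %d cells.",
      n_per_type, min(counts)))
  }
  types <- names(counts)
  seeds <- seed + seq_len(n_reps)
  replicates <- map(seeds, function(s) {
    ids <- withr::with_seed(s, {
      unlist(lapply(types, function(ct) {
        pool <- ann$unit_id[ann$cell_type == ct]
        sample(pool, n_per_type, replace = FALSE)
      }), use.names = FALSE)
    })
    sub_ref <- expr_subset(ref, units = ids)
    sub_ann <- ann[match(ids, ann$unit_id), , drop = FALSE]
    fn(bulk, sub_ref, sub_ann, markers, metadata)
  })
  cts <- prop_cell_types(replicates[[1]])
  stack <- vapply(replicates,
                  function(tb) prop_matrix(tb)[, cts, drop = FALSE],
                  FUN.VALUE = prop_matrix(replicates[[1]])[, cts,
                                                           drop = FALSE])
  mean_m <- apply(stack, c(1, 2), mean)
  sd_m <- apply(stack, c(1, 2), stats::sd)
  units <- replicates[[1]]$unit_id
  mean_df <- dplyr::bind_cols(tibble(unit_id = units),
                              as_tibble(as.data.frame(mean_m)))
  mean_table <- proportion_tbl(mean_df, cts,
                               method = paste0(estimator, "_resample_mean"))
  dispersion <- tibble(
    unit_id = rep(units, times = length(cts)),
    cell_type = rep(cts, each = length(units)),
    sd = as.vector(sd_m)
  )
  structure(
    list(replicates = replicates, seeds = seeds, mean_table = mean_table,
         dispersion = dispersion, n_per_type = as.integer(n_per_type),
         estimator = estimator),
    class = "resample_result"
  )
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf(
    "<resample_result> %d replicates, %d cells/type, estimator %s\n",
    length(x$replicates), x$n_per_type, x$estimator))
  invisible(x)
}

#' Tidy a resampling result
#'
#' @param x a `resample_result`.
#' @param ... unused.
#' @return a long tibble: `replicate`, `seed`, `unit_id`, `cell_type`,
#'   `proportion`.
#' @export
tidy.resample_result <- function(x, ...) {
  purrr::imap_dfr(x$replicates, function(tb, i) {
    mutate(tidy(tb), replicate = i, seed = x$seeds[i],
           .before = 1)
  })
}

#' One-line summary of a resampling result
#'
#' @param x a `resample_result`.
#' @param ... unused.
#' @return one-row tibble with replicate count, cells per type,
#'   estimator, and the mean across-replicate standard deviation.
#' @export
glance.resample_result <- function(x, ...) {
  tibble(
    n_reps = length(x$replicates),
    n_per_type = x$n_per_type,
    estimator = x$estimator,
    mean_dispersion = mean(x$dispersion$sd)
  )
}

#' Deconvolve one bulk dataset against several references
#'
#' Runs the same estimator with each reference in turn, after
#' harmonising cell-type vocabularies through per-reference label
#' maps (e.g. merging endothelial and pericyte labels into a combined
#' vascular type). All references must map onto the same final type
#' set.
#'
#' @param bulk counts-scale bulk `expr_matrix`.
#' @param references named list; each element a list with `ref`,
#'   `annotation`, `markers`, and optional `label_map` (named
#'   character vector, source label -> harmonised label).
#' @param estimator registered method name.
#' @param metadata optional bulk sample metadata.
#' @return a named list of `proportion_tbl`, one per reference, over
#'   the harmonised cell-type set.
#' @export
reference_swap <- function(bulk, references, estimator = "nnls",
                           metadata = NULL) {
  fn <- get_deconv_method(estimator)
  harmonized <- NULL
  out <- imap(references, function(r, nm) {
    ann <- r$annotation
    markers <- r$markers
    if (!is.null(r$label_map)) {
      unknown <- setdiff(names(r$label_map), unique(ann$cell_type))
      if (length(unknown) > 0) {
        abort(paste0("label map covers absent labels in ", nm, ": ",
                     paste(unknown, collapse = ", ")))
      }
      remap <- function(x) {
        ifelse(x %in% names(r$label_map), r$label_map[x], x)
      }
      ann$cell_type <- unname(remap(ann$cell_type))
      markers$cell_type <- unname(remap(markers$cell_type))
      markers <- markers[!duplicated(markers[c("cell_type", "gene_id")]), ]
    }
    types <- sort(unique(ann$cell_type))
    if (is.null(harmonized)) {
      harmonized <<- types
    } else if (!identical(types, harmonized)) {
      abort(paste0("unmappable labels in reference ", nm, ": ",
                   paste(c(setdiff(types, harmonized),
                           setdiff(harmonized, types)), collapse = ", ")))
    }
    fn(bulk, r$ref, ann, markers, metadata)
  })
  out
}
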