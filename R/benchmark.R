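#' Run the end-to-end benchmark recipe
#'
#' Ties the stages together: obtain reference and bulk data (from the
#' synthetic generator, or from files), build each requested marker
#' set, run each registered estimator with each set, optionally
#' cell-size-adjust and collapse cell types, evaluate against the
#' truth, and write every artifact with a checksum manifest. The run
#' is deterministic given the seed; failure of one estimator is
#' recorded and does not abort the others.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{seed}{integer seed (default 1).}
#'     \item{out_dir}{output directory (default `tempdir()` subdir).}
#'     \item{simulate}{named list of [generator_config()] overrides;
#'       present (possibly empty) to simulate inputs.}
#'     \item{inputs}{alternatively, paths: `ref_mtx`, `ref_genes`,
#'       `ref_units`, `ref_labels` (TSV unit_id/cell_type), `bulk`
#'       (TSV), `truth` (TSV unit_id + type columns).}
#'     \item{markers}{list of rule specs, each a list with `rule` and
#'       its parameters (default MeanRatio top-25).}
#'     \item{estimators}{method names (default nnls and
#'       marker_ratio).}
#'     \item{cell_sizes}{`NULL`, `"true"` (simulation truth sizes), or
#'       a named vector used for RNA-to-cell-fraction adjustment.}
#'     \item{collapse}{optional named mapping for
#'       [collapse_cell_types()].}
#'     \item{bulk_noise}{noise model for simulated bulks
#'       (default "poisson").}
#'   }
#' @return a list with `proportions` (named list of
#'   `proportion_tbl`), `evaluation` (tibble of metrics per run),
#'   `errors` (named character vector of failed runs), `manifest`
#'   (tibble of files and md5 checksums), `out_dir`.
#' @export
run_benchmark <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% file.path(tempdir(), "deconvbench_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  estimators <- config$estimators %||% c("nnls", "marker_ratio")
  marker_specs <- config$markers %||%
    list(list(rule = "mean_ratio_top_n", n = 25))
  unknown <- setdiff(estimators, list_deconv_methods())
  if (length(unknown) > 0) {
    abort(paste0("unregistered estimator(s): ",
                 paste(unknown, collapse = ", ")))
  }

  if (!is.null(config$inputs)) {
    inp <- config$inputs
    ref <- read_expression(inp$ref_mtx, inp$ref_genes, inp$ref_units)
    labels <- readr::read_tsv(inp$ref_labels, show_col_types = FALSE,
                              progress = FALSE)
    annotation <- cell_annotation(labels$unit_id, labels$cell_type)
    bulk <- read_expression(inp$bulk)
    metadata <- NULL
    truth_props <- NULL
    sizes_true <- NULL
    if (!is.null(inp$truth)) {
      tr <- readr::read_tsv(inp$truth, show_col_types = FALSE,
                            progress = FALSE)
      truth_props <- proportion_tbl(tr, setdiff(names(tr), "unit_id"),
                                    method = "truth")
    }
  } else {
    cfg <- do.call(generator_config, config$simulate %||% list())
    ref_sim <- simulate_reference(cfg, seed = seed)
    bulk_sim <- simulate_bulk(ref_sim, seed = seed + 1,
                              noise = config$bulk_noise %||% "poisson")
    ref <- ref_sim$expr
    annotation <- ref_sim$annotation
    bulk <- bulk_sim$expr
    metadata <- bulk_sim$metadata
    truth_props <- bulk_sim$truth$cell_props
    sizes_true <- ref_sim$truth$size_factors
  }

  stats <- marker_stats(ref, annotation)
  sizes <- config$cell_sizes
  if (identical(sizes, "true")) sizes <- sizes_true

  runs <- list()
  errors <- character(0)
  eval_rows <- list()
  for (spec in marker_specs) {
    sets <- do.call(build_marker_sets,
                    c(list(stats = stats), spec,
                      list(common_genes = intersect(gene_ids(ref),
                                                    gene_ids(bulk)))))
    rule_tag <- spec$rule
    for (est in estimators) {
      tag <- paste(est, rule_tag, sep = ".")
      res <- tryCatch(
        deconvolve(est, bulk, ref, annotation, sets, metadata = metadata),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        errors[tag] <- conditionMessage(res)
        next
      }
      if (!is.null(sizes)) res <- cell_size_adjust(res, sizes)
      if (!is.null(config$collapse)) {
        res <- collapse_cell_types(res, unlist(config$collapse))
      }
      runs[[tag]] <- res
      if (!is.null(truth_props)) {
        truth_cmp <- truth_props
        if (!is.null(config$collapse)) {
          truth_cmp <- collapse_cell_types(truth_cmp,
                                           unlist(config$collapse))
        }
        ev <- compare_proportions(res, truth_cmp)
        ev <- mutate(ev, estimator = est, marker_rule = rule_tag,
                     .before = 1)
        eval_rows[[tag]] <- ev
      }
    }
  }

  files <- character(0)
  for (tag in names(runs)) {
    f <- file.path(out_dir, paste0("props_", gsub("\\.", "_", tag), ".tsv"))
    readr::write_tsv(as_tibble(runs[[tag]]), f, progress = FALSE)
    files <- c(files, f)
  }
  evaluation <- if (length(eval_rows) > 0) bind_rows(eval_rows) else tibble()
  if (nrow(evaluation) > 0) {
    f <- file.path(out_dir, "evaluation.tsv")
    readr::write_tsv(evaluation, f, progress = FALSE)
    files <- c(files, f)
  }
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  list(proportions = runs, evaluation = evaluation, errors = errors,
       manifest = manifest, out_dir = out_dir)
}
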