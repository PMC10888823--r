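#' Per-cell-type mean expression
#'
#' Arithmetic mean of each gene over the cells of each type, on the
#' linear scale supplied (typically CPM). This is the quantity whose
#' target / best-non-target ratio defines the Mean Ratio marker
#' statistic.
#'
#' @param expr an `expr_matrix` (cpm scale expected for marker work,
#'   but any scale is accepted and recorded).
#' @param annotation a [cell_annotation()] covering all units.
#' @return an object of class `type_means`: a list with `means`
#'   (cell-type x gene matrix), `scale`, and `n_cells` (named count of
#'   cells per type).
#' @export
type_means <- function(expr, annotation) {
  annotation <- align_annotation(annotation, expr)
  types <- sort(unique(annotation$cell_type))
  counts <- table(annotation$cell_type)
  if (any(counts == 0)) abort("empty cell type in annotation.")
  v <- expr$values
  m <- matrix(0, nrow = length(types), ncol = nrow(v),
              dimnames = list(types, rownames(v)))
  for (ct in types) {
    cols <- which(annotation$cell_type == ct)
    m[ct, ] <- as.vector(rowSums(v[, cols, drop = FALSE])) / length(cols)
  }
  structure(
    list(means = m, scale = expr$scale,
         n_cells = setNames(as.integer(counts[types]), types)),
    class = "type_means"
  )
}

#' @export
print.type_means <- function(x, ...) {
  cat(sprintf("<type_means> %d cell types x %d genes [%s]\n",
              nrow(x$means), ncol(x$means), x$scale))
  invisible(x)
}

#' Mean Ratio marker statistic for one target cell type
#'
#' For each gene, the ratio of its mean expression in the target cell
#' type to the highest mean among the non-target cell types. Values
#' above 1 indicate target-specific expression; the best markers have
#' the highest ratios. When the non-target maximum is zero the ratio
#' is `Inf` if the target mean is positive and 0 if it is also zero.
#'
#' @param means a [type_means()] object (linear scale).
#' @param target a cell-type label present in `means`.
#' @return a tibble with one row per gene: `gene_id`, `cell_type`
#'   (the target), `target_mean`, `second_type` (the non-target type
#'   attaining the maximum), `second_mean`, `mean_ratio`, and
#'   `rank_ratio` (1 = best; ordered by descending ratio, ties broken
#'   by descending target mean then gene id).
#' @export
mean_ratio <- function(means, target) {
  m <- means$means
  if (!target %in% rownames(m)) {
    abort(paste0("unknown target cell type: ", target))
  }
  if (nrow(m) < 2) abort("mean_ratio needs at least 2 cell types.")
  tgt <- m[target, ]
  rest <- m[setdiff(rownames(m), target), , drop = FALSE]
  second_idx <- apply(rest, 2, which.max)
  second_mean <- rest[cbind(second_idx, seq_len(ncol(rest)))]
  ratio <- ifelse(second_mean > 0, tgt / second_mean,
                  ifelse(tgt > 0, Inf, 0))
  out <- tibble(
    gene_id = colnames(m),
    cell_type = target,
    target_mean = as.numeric(tgt),
    second_type = rownames(rest)[second_idx],
    second_mean = as.numeric(second_mean),
    mean_ratio = as.numeric(ratio)
  )
  ord <- order(-out$mean_ratio, -out$target_mean, out$gene_id)
  out$rank_ratio <- integer(nrow(out))
  out$rank_ratio[ord] <- seq_len(nrow(out))
  out
}

#' One-vs-all differential ranking for one target cell type
#'
#' Pools all non-target cells into a single group and computes, per
#' gene, the mean difference on the log scale (`logFC`), a Welch
#' two-sample t statistic, and a two-sided p-value. Genes are ranked
#' by descending logFC (ties by ascending p then gene id). When both
#' groups are constant with equal means the convention t = 0, p = 1 is
#' used; constant groups with different means report p = 0 with
#' `zero_var = TRUE`.
#'
#' @param expr a log-scale `expr_matrix`.
#' @param annotation a [cell_annotation()] covering all units.
#' @param target a cell-type label; both the target group and the rest
#'   must contain at least 2 cells.
#' @return a tibble with columns `gene_id`, `cell_type`,
#'   `logFC_1vall`, `t_stat`, `p_value`, `rank_fc`, `zero_var`.
#' @export
one_vs_all <- function(expr, annotation, target) {
  if (expr$scale != "log") abort("`expr` must be log scale.")
  annotation <- align_annotation(annotation, expr)
  in_target <- annotation$cell_type == target
  if (!any(in_target)) abort(paste0("unknown target cell type: ", target))
  n1 <- sum(in_target)
  n2 <- sum(!in_target)
  if (n1 < 2) abort(paste0("target group has <2 cells: ", target))
  if (n2 < 2) abort(paste0("rest group has <2 cells for target: ", target))
  v <- expr_values(expr, dense = TRUE)
  g1 <- v[, in_target, drop = FALSE]
  g2 <- v[, !in_target, drop = FALSE]
  m1 <- rowMeans(g1)
  m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t_stat <- ifelse(se2 > 0, diff / sqrt(se2),
                   ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(
    se2 > 0 & v1 + v2 > 0,
    se2^2 / (ifelse(v1 > 0, (v1 / n1)^2 / (n1 - 1), 0) +
             ifelse(v2 > 0, (v2 / n2)^2 / (n2 - 1), 0)),
    1
  )
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              ifelse(t_stat == 0, 1, 0))
  p <- ifelse(se2 == 0 & diff == 0, 1, p)
  out <- tibble(
    gene_id = rownames(v),
    cell_type = target,
    logFC_1vall = as.numeric(diff),
    t_stat = as.numeric(t_stat),
    p_value = as.numeric(p),
    zero_var = se2 == 0
  )
  ord <- order(-out$logFC_1vall, out$p_value, out$gene_id)
  out$rank_fc <- integer(nrow(out))
  out$rank_fc[ord] <- seq_len(nrow(out))
  out
}

#' Marker statistics for all cell types
#'
#' Convenience wrapper computing, from raw reference counts, the Mean
#' Ratio statistic (on linear CPM type means by default) and the
#' one-vs-all Welch ranking (on log2(CPM + 1)) for every cell type.
#'
#' @param expr a counts-scale reference `expr_matrix`.
#' @param annotation a [cell_annotation()].
#' @param ratio_assay assay on which Mean Ratio type means are taken:
#'   `"cpm"` (linear, the default) or `"logcpm"`.
#' @return a long tibble, one row per (gene, cell type), combining the
#'   columns of [mean_ratio()] and [one_vs_all()].
#' @export
marker_stats <- function(expr, annotation, ratio_assay = c("cpm", "logcpm")) {
  ratio_assay <- match.arg(ratio_assay)
  check_scale(expr, "counts")
  cpm <- cpm_normalize(expr)
  logcpm <- log_transform(cpm)
  ratio_expr <- if (ratio_assay == "cpm") cpm else logcpm
  means <- type_means(ratio_expr, annotation)
  types <- rownames(means$means)
  ratio_tbl <- purrr::map_dfr(types, function(ct) mean_ratio(means, ct))
  de_tbl <- purrr::map_dfr(types, function(ct) {
    one_vs_all(logcpm, annotation, ct)
  })
  left_join(ratio_tbl, de_tbl, by = c("gene_id", "cell_type"))
}

#' Build marker gene sets
#'
#' Derives named per-cell-type marker gene sets from marker statistics
#' under one of five rules:
#' \describe{
#'   \item{`full`}{every common gene, for every cell type.}
#'   \item{`one_vs_all_top_n`}{the `n` best genes per type by
#'     one-vs-all fold-change rank, then intersected with
#'     `common_genes` (so sets may hold fewer than `n` genes).}
#'   \item{`mean_ratio_top_n`}{the `n` best genes per type by Mean
#'     Ratio rank, then intersected with `common_genes`.}
#'   \item{`mean_ratio_over_t`}{all genes with Mean Ratio > `t`,
#'     intersected with `common_genes`.}
#'   \item{`mean_ratio_mad_k`}{per type, among genes with Mean
#'     Ratio > 1, all genes whose ratio exceeds
#'     `median + k * MAD` of those ratios (MAD with the 1.4826
#'     constant), intersected with `common_genes`.}
#' }
#'
#' @param stats a [marker_stats()] tibble (needs `rank_ratio` /
#'   `rank_fc` / `mean_ratio` as the rule requires).
#' @param rule one of the five rule names.
#' @param n,t,k rule parameters (top-N size, ratio threshold, MAD
#'   multiplier).
#' @param common_genes optional character vector of genes present in
#'   both reference and bulk; `NULL` means all genes qualify.
#' @return a tibble of class `marker_sets` with columns `cell_type`,
#'   `gene_id`, `set_rank` and attributes `rule`, `params`, and
#'   `warnings` (cell types whose qualifying pool was empty).
#' @export
build_marker_sets <- function(stats,
                              rule = c("mean_ratio_top_n", "one_vs_all_top_n",
                                       "mean_ratio_over_t", "mean_ratio_mad_k",
                                       "full"),
                              n = 25, t = 2, k = 3, common_genes = NULL) {
  rule <- match.arg(rule)
  types <- sort(unique(stats$cell_type))
  in_common <- function(g) {
    if (is.null(common_genes)) g else intersect(g, common_genes)
  }
  warnings <- character(0)
  pick <- function(ct) {
    s <- stats[stats$cell_type == ct, , drop = FALSE]
    genes <- switch(
      rule,
      full = {
        g <- if (is.null(common_genes)) sort(unique(stats$gene_id))
             else intersect(sort(unique(stats$gene_id)), common_genes)
        g
      },
      mean_ratio_top_n = in_common(s$gene_id[order(s$rank_ratio)][
        seq_len(min(n, nrow(s)))]),
      one_vs_all_top_n = in_common(s$gene_id[order(s$rank_fc)][
        seq_len(min(n, nrow(s)))]),
      mean_ratio_over_t = {
        keep <- s[s$mean_ratio > t, , drop = FALSE]
        in_common(keep$gene_id[order(keep$rank_ratio)])
      },
      mean_ratio_mad_k = {
        ratios <- s$mean_ratio[s$mean_ratio > 1]
        if (length(ratios) == 0) {
          warnings <<- c(warnings, ct)
          character(0)
        } else {
          thr <- median(ratios) + k * mad(ratios, constant = 1.4826)
          keep <- s[s$mean_ratio > 1 & s$mean_ratio > thr, , drop = FALSE]
          in_common(keep$gene_id[order(keep$rank_ratio)])
        }
      }
    )
    if (length(genes) == 0) {
      return(tibble(cell_type = character(0), gene_id = character(0),
                    set_rank = integer(0)))
    }
    tibble(cell_type = ct, gene_id = genes,
           set_rank = seq_along(genes))
  }
  out <- purrr::map_dfr(types, pick)
  structure(out,
            class = c("marker_sets", class(tibble())),
            rule = rule,
            params = list(n = n, t = t, k = k),
            warnings = warnings)
}

#' Marker sets as a named list
#'
#' @param sets a [build_marker_sets()] result.
#' @return a named list, cell type -> ordered character vector of
#'   gene ids.
#' @export
marker_list <- function(sets) {
  split(sets$gene_id, sets$cell_type)
}

#' Write / read marker sets as two-column TSV
#'
#' @param sets a `marker_sets` tibble.
#' @param path output TSV path; a JSON manifest recording the rule and
#'   parameters is written alongside as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_marker_sets <- function(sets, path) {
  readr::write_tsv(as_tibble(sets)[, c("cell_type", "gene_id")], path,
                   progress = FALSE)
  manifest <- list(rule = attr(sets, "rule"), params = attr(sets, "params"))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_marker_sets
#' @export
read_marker_sets <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  df$set_rank <- stats::ave(seq_len(nrow(df)), df$cell_type,
                            FUN = seq_along)
  structure(as_tibble(df), class = c("marker_sets", class(tibble())))
}
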