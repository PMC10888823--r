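#' Expression matrix container
#'
#' A light wrapper around a gene x unit numeric matrix (dense or
#' `Matrix` sparse) carrying gene identifiers, unit identifiers (cells
#' or samples) and a scale tag recording whether the values are raw
#' counts, counts-per-million, or log2-transformed.
#'
#' @param values numeric matrix or `Matrix::Matrix` with genes in rows
#'   and units (cells or samples) in columns. Row and column names are
#'   used as identifiers; alternatively supply `gene_ids` / `unit_ids`.
#' @param gene_ids,unit_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @param scale one of `"counts"`, `"cpm"`, `"log"`.
#'
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, gene_ids = NULL, unit_ids = NULL,
                        scale = c("counts", "cpm", "log")) {
  scale <- match.arg(scale)
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(unit_ids)) colnames(values) <- unit_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene and unit identifiers (dimnames).")
  }
  x <- structure(list(values = values, scale = scale),
                 class = "expr_matrix")
  validate_expr_matrix(x)
}

validate_expr_matrix <- function(x) {
  v <- x$values
  if (length(rownames(v)) != nrow(v) || length(colnames(v)) != ncol(v)) {
    abort("identifier length does not match matrix dimensions.")
  }
  if (anyDuplicated(rownames(v))) abort("duplicate gene ids.")
  if (anyDuplicated(colnames(v))) abort("duplicate unit ids.")
  if (min_value(v) < 0 && x$scale != "log") {
    abort("expression values must be non-negative.")
  }
  x
}

min_value <- function(v) {
  if (length(v) == 0) return(0)
  if (inherits(v, "sparseMatrix")) {
    entries <- methods::slot(methods::as(v, "generalMatrix"), "x")
    min(c(0, entries))
  } else {
    min(v)
  }
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d units [%s]\n",
              n_genes(x), n_units(x), x$scale))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
unit_ids <- function(x) colnames(x$values)

#' @rdname expr_matrix
#' @export
expr_scale <- function(x) x$scale

#' @rdname expr_matrix
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname expr_matrix
#' @export
n_units <- function(x) ncol(x$values)

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Extract the underlying matrix
#'
#' @param x an `expr_matrix`.
#' @param dense coerce sparse storage to a base dense matrix.
#' @return the gene x unit numeric matrix.
#' @export
expr_values <- function(x, dense = FALSE) {
  v <- x$values
  if (dense && !is.matrix(v)) v <- as.matrix(v)
  v
}

#' Tidy an expression matrix into long format
#'
#' @param x an `expr_matrix`.
#' @param ... unused.
#' @return a tibble with columns `gene_id`, `unit_id`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  v <- expr_values(x, dense = TRUE)
  tibble(
    gene_id = rep(rownames(v), times = ncol(v)),
    unit_id = rep(colnames(v), each = nrow(v)),
    value = as.vector(v)
  )
}

#' Subset an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param genes,units character vectors of identifiers to keep (in the
#'   given order); `NULL` keeps all.
#' @return an `expr_matrix`.
#' @export
expr_subset <- function(x, genes = NULL, units = NULL) {
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing) > 0) {
      abort(paste0("genes absent from matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(units)) {
    missing <- setdiff(units, colnames(v))
    if (length(missing) > 0) {
      abort(paste0("units absent from matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    v <- v[, units, drop = FALSE]
  }
  expr_matrix(v, scale = x$scale)
}

# ---- file I/O ----------------------------------------------------------

#' Read an expression matrix from disk
#'
#' Reads either a Matrix Market coordinate file plus line-aligned gene
#' and unit (barcode/sample) annotation files, or a dense TSV/CSV with
#' gene ids in the first column and unit ids in the header.
#'
#' @param matrix_path path to a `.mtx` file or a dense delimited table.
#' @param gene_path,unit_path for MTX input, paths to files whose first
#'   (tab-separated, header-less) column holds gene / unit ids,
#'   line-aligned to the matrix rows / columns.
#' @return a counts-scale `expr_matrix`. A mismatch between annotation
#'   length and matrix dimension is an error, never a truncation.
#' @export
read_expression <- function(matrix_path, gene_path = NULL, unit_path = NULL) {
  if (!file.exists(matrix_path)) {
    abort(paste0("file not found: ", matrix_path))
  }
  if (grepl("\\.mtx$", matrix_path)) {
    if (is.null(gene_path) || is.null(unit_path)) {
      abort("MTX input requires `gene_path` and `unit_path`.")
    }
    m <- as(readMM(matrix_path), "CsparseMatrix")
    genes <- read_id_column(gene_path)
    units <- read_id_column(unit_path)
    if (length(genes) != nrow(m)) {
      abort(sprintf("gene annotation has %d entries but matrix has %d rows.",
                    length(genes), nrow(m)))
    }
    if (length(units) != ncol(m)) {
      abort(sprintf("unit annotation has %d entries but matrix has %d columns.",
                    length(units), ncol(m)))
    }
    dimnames(m) <- list(genes, units)
  } else {
    df <- readr::read_tsv(matrix_path, show_col_types = FALSE,
                          progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  expr_matrix(m, scale = "counts")
}

read_id_column <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  as.character(df[[1]])
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: writes MTX + id files when
#' `matrix_path` ends in `.mtx`, otherwise a dense TSV.
#'
#' @param expr an `expr_matrix`.
#' @inheritParams read_expression
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expr, matrix_path, gene_path = NULL,
                             unit_path = NULL) {
  if (grepl("\\.mtx$", matrix_path)) {
    if (is.null(gene_path) || is.null(unit_path)) {
      abort("MTX output requires `gene_path` and `unit_path`.")
    }
    m <- expr$values
    if (!inherits(m, "sparseMatrix")) m <- Matrix(m, sparse = TRUE)
    writeMM(m, matrix_path)
    writeLines(gene_ids(expr), gene_path)
    writeLines(unit_ids(expr), unit_path)
  } else {
    df <- as.data.frame(expr_values(expr, dense = TRUE))
    df <- cbind(gene_id = gene_ids(expr), df)
    readr::write_tsv(df, matrix_path, progress = FALSE)
  }
  invisible(matrix_path)
}

# ---- normalisation -----------------------------------------------------

#' Counts-per-million normalisation
#'
#' Scales every column with nonzero total to sum to 1e6. All-zero
#' columns are preserved untouched; dropping empty units is an explicit
#' separate filtering step, never a side effect of normalisation.
#'
#' @param expr a counts-scale `expr_matrix`.
#' @return a cpm-scale `expr_matrix`.
#' @export
cpm_normalize <- function(expr) {
  check_scale(expr, "counts")
  totals <- colSums(expr$values)
  factors <- ifelse(totals > 0, 1e6 / totals, 0)
  v <- sweep_cols(expr$values, factors)
  out <- expr_matrix(v, scale = "cpm")
  out
}

sweep_cols <- function(m, factors) {
  if (inherits(m, "sparseMatrix")) {
    out <- m %*% Matrix::Diagonal(x = factors, names = FALSE)
    dimnames(out) <- dimnames(m)
    out
  } else {
    sweep(m, 2, factors, `*`)
  }
}

#' Log2 transformation
#'
#' Elementwise `log2(x + pseudocount)`; monotone in the input.
#'
#' @param expr a counts- or cpm-scale `expr_matrix`.
#' @param pseudocount positive shift added before taking logs
#'   (default 1, so zeros map to zero).
#' @return a log-scale `expr_matrix` (densified).
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (!expr$scale %in% c("counts", "cpm")) {
    abort("`expr` must be counts or cpm scale.")
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be a positive number.")
  }
  v <- log2(expr_values(expr, dense = TRUE) + pseudocount)
  expr_matrix(v, scale = "log")
}

#' Pseudobulk a single-cell matrix
#'
#' Sums raw counts over groups of cells (e.g. per sample, or per
#' cell-type x sample), emulating a bulk library. Total counts are
#' conserved exactly.
#'
#' @param expr a counts-scale `expr_matrix` of cells.
#' @param annotation a data frame with a `unit_id` column matching
#'   `expr` plus grouping columns (see [cell_annotation()]).
#' @param group_by name(s) of annotation column(s) defining the groups;
#'   multiple columns are pasted with `"_"`.
#' @return a counts-scale `expr_matrix` with one column per group.
#' @export
pseudobulk <- function(expr, annotation, group_by = "sample_id") {
  check_scale(expr, "counts")
  annotation <- align_annotation(annotation, expr)
  missing_cols <- setdiff(group_by, names(annotation))
  if (length(missing_cols) > 0) {
    abort(paste0("unknown group_by field(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  keys <- do.call(paste, c(annotation[group_by], sep = "_"))
  groups <- unique(keys)
  design <- sparseMatrix(
    i = seq_along(keys),
    j = match(keys, groups),
    x = 1,
    dims = c(length(keys), length(groups)),
    dimnames = list(NULL, groups)
  )
  v <- expr$values %*% design
  if (inherits(v, "Matrix")) v <- as.matrix(v)
  rownames(v) <- gene_ids(expr)
  expr_matrix(v, scale = "counts")
}

#' Filter genes by mean expression
#'
#' Keeps genes whose mean RPKM (when `gene_lengths` is supplied) or
#' mean CPM (otherwise) across units exceeds `min_mean`. The RPKM for
#' gene g in unit j is `count / (length_kb * depth_millions)`.
#'
#' @param expr a counts-scale `expr_matrix`.
#' @param gene_lengths optional named numeric vector of gene lengths in
#'   bp, covering all genes of `expr`.
#' @param min_mean non-negative threshold on the mean normalised
#'   expression (default 0.1, the conventional low-expression cutoff).
#' @return a list with `expr` (the filtered matrix) and `kept` (a named
#'   logical mask over the input genes).
#' @export
filter_low_expression <- function(expr, gene_lengths = NULL, min_mean = 0.1) {
  check_scale(expr, "counts")
  if (!is.numeric(min_mean) || min_mean < 0) {
    abort("`min_mean` must be non-negative.")
  }
  depth <- colSums(expr$values)
  scale_per_unit <- ifelse(depth > 0, 1e6 / depth, 0)
  normed <- sweep_cols(expr$values, scale_per_unit)
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths)) ||
        !all(gene_ids(expr) %in% names(gene_lengths))) {
      abort("`gene_lengths` must be named and cover all genes.")
    }
    len_kb <- gene_lengths[gene_ids(expr)] / 1e3
    if (any(!is.finite(len_kb)) || any(len_kb <= 0)) {
      abort("gene lengths must be positive and finite.")
    }
    normed <- normed / len_kb
  }
  means <- rowSums(normed) / ncol(normed)
  kept <- as.vector(means > min_mean)
  names(kept) <- gene_ids(expr)
  filtered <- expr_matrix(expr$values[kept, , drop = FALSE],
                          scale = "counts")
  list(expr = filtered, kept = kept)
}

check_scale <- function(expr, expected) {
  if (!inherits(expr, "expr_matrix")) {
    abort("`expr` must be an expr_matrix.")
  }
  if (expr$scale != expected) {
    abort(sprintf("`expr` must be %s scale, got %s.", expected, expr$scale))
  }
  invisible(expr)
}

# ---- cell annotation ---------------------------------------------------

#' Per-cell annotation table
#'
#' Builds and validates the annotation tibble aligned to a reference
#' expression matrix: one row per cell with a non-missing cell type.
#'
#' @param unit_id character vector of cell identifiers.
#' @param cell_type character/factor vector of cell-type labels.
#' @param donor_id,sample_id optional character vectors.
#' @return a tibble with class `cell_annotation`.
#' @export
cell_annotation <- function(unit_id, cell_type, donor_id = NA_character_,
                            sample_id = NA_character_) {
  out <- tibble(
    unit_id = as.character(unit_id),
    cell_type = as.character(cell_type),
    donor_id = as.character(donor_id),
    sample_id = as.character(sample_id)
  )
  if (anyDuplicated(out$unit_id)) abort("duplicate unit_id in annotation.")
  if (anyNA(out$cell_type)) abort("every cell must have a cell_type.")
  class(out) <- c("cell_annotation", class(out))
  out
}

align_annotation <- function(annotation, expr) {
  if (!all(c("unit_id") %in% names(annotation))) {
    abort("annotation must have a unit_id column.")
  }
  ids <- unit_ids(expr)
  missing <- setdiff(ids, annotation$unit_id)
  if (length(missing) > 0) {
    abort(paste0("annotation missing units: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  annotation[match(ids, annotation$unit_id), , drop = FALSE]
}
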