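#' Proportion table
#'
#' A tibble of cell-type composition: one row per unit (bulk sample or
#' tissue section), a `unit_id` column, one numeric column per cell
#' type, and any number of metadata columns (library type, RNA
#' extraction, tissue block). Cell-type columns are non-negative and
#' each row sums to 1 (within 1e-8).
#'
#' @param data a data frame with a `unit_id` column and the cell-type
#'   columns.
#' @param cell_types character vector naming the cell-type columns.
#' @param method,marker_rule optional tags recording provenance.
#' @return a tibble of class `proportion_tbl`.
#' @export
proportion_tbl <- function(data, cell_types, method = NA_character_,
                           marker_rule = NA_character_) {
  if (!"unit_id" %in% names(data)) abort("`data` needs a unit_id column.")
  missing <- setdiff(cell_types, names(data))
  if (length(missing) > 0) {
    abort(paste0("cell-type columns absent: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(data[, cell_types, drop = FALSE])
  if (any(m < -1e-12)) abort("negative proportions.")
  sums <- rowSums(m)
  if (any(abs(sums - 1) > 1e-8)) {
    abort("proportion rows must sum to 1 (within 1e-8).")
  }
  structure(as_tibble(data),
            class = c("proportion_tbl", class(tibble())),
            cell_types = cell_types,
            method = method,
            marker_rule = marker_rule)
}

#' @rdname proportion_tbl
#' @param x a `proportion_tbl`.
#' @export
prop_cell_types <- function(x) attr(x, "cell_types")

#' Proportions as a unit x cell-type matrix
#'
#' @param x a `proportion_tbl`.
#' @return a numeric matrix with unit ids as row names.
#' @export
prop_matrix <- function(x) {
  m <- as.matrix(as_tibble(x)[, prop_cell_types(x), drop = FALSE])
  rownames(m) <- x$unit_id
  m
}

#' Tidy a proportion table into long format
#'
#' @param x a `proportion_tbl`.
#' @param ... unused.
#' @return a long tibble with `unit_id`, `cell_type`, `proportion`,
#'   plus the metadata columns.
#' @export
tidy.proportion_tbl <- function(x, ...) {
  cts <- prop_cell_types(x)
  tidyr::pivot_longer(as_tibble(x), cols = all_of(cts),
                      names_to = "cell_type", values_to = "proportion")
}

#' One-line summary of a proportion table
#'
#' @param x a `proportion_tbl`.
#' @param ... unused.
#' @return a one-row tibble: units, cell types, method and marker-rule
#'   tags, and the largest absolute deviation of a row sum from 1.
#' @export
glance.proportion_tbl <- function(x, ...) {
  m <- prop_matrix(x)
  tibble(
    n_units = nrow(m),
    n_cell_types = ncol(m),
    method = attr(x, "method"),
    marker_rule = attr(x, "marker_rule"),
    max_rowsum_dev = max(abs(rowSums(m) - 1))
  )
}

#' Convert RNA-fraction proportions to cell-count proportions
#'
#' Deconvolution estimators working on expression recover the fraction
#' of RNA contributed by each cell type. Because cell types differ in
#' RNA content ("cell size"), the RNA fraction over-represents large
#' cells. Dividing each proportion by its type's size factor and
#' renormalising converts RNA fractions to cell-count fractions:
#' `q_k = (p_k / s_k) / sum_j (p_j / s_j)`.
#'
#' @param props a `proportion_tbl` of RNA-fraction proportions.
#' @param sizes named numeric vector of strictly positive size factors
#'   covering every cell-type column of `props`.
#' @return a `proportion_tbl` of the same shape.
#' @export
cell_size_adjust <- function(props, sizes) {
  cts <- prop_cell_types(props)
  missing <- setdiff(cts, names(sizes))
  if (length(missing) > 0) {
    abort(paste0("missing size factors: ", paste(missing, collapse = ", ")))
  }
  s <- sizes[cts]
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("size factors must be positive and finite.")
  }
  m <- prop_matrix(props)
  adj <- sweep(m, 2, s, `/`)
  adj <- adj / rowSums(adj)
  out <- as_tibble(props)
  out[, cts] <- as.data.frame(adj)
  proportion_tbl(out, cts, method = attr(props, "method"),
                 marker_rule = attr(props, "marker_rule"))
}

#' Merge cell-type columns
#'
#' Sums groups of cell-type columns into merged classes, e.g. adding
#' Oligo and OPC proportions into a combined OligoOPC class to match
#' the resolution of an imaging panel. Rows still sum to 1.
#'
#' @param props a `proportion_tbl`.
#' @param mapping named character vector, source type -> merged name.
#'   Types absent from `mapping` keep their own name.
#' @return a `proportion_tbl` over the merged type set.
#' @export
collapse_cell_types <- function(props, mapping) {
  cts <- prop_cell_types(props)
  unknown <- setdiff(names(mapping), cts)
  if (length(unknown) > 0) {
    abort(paste0("mapping covers absent types: ",
                 paste(unknown, collapse = ", ")))
  }
  target <- ifelse(cts %in% names(mapping), mapping[cts], cts)
  names(target) <- cts
  collide <- intersect(setdiff(unique(mapping), names(mapping)),
                       cts[!cts %in% names(mapping)])
  if (length(collide) > 0) {
    abort(paste0("merged name collides with existing type: ",
                 paste(collide, collapse = ", ")))
  }
  m <- prop_matrix(props)
  new_types <- unique(unname(target))
  merged <- sapply(new_types, function(nt) {
    rowSums(m[, cts[target == nt], drop = FALSE])
  })
  if (is.null(dim(merged))) merged <- matrix(merged, nrow = 1,
                                             dimnames = list(NULL, new_types))
  out <- as_tibble(props)[, setdiff(names(props), cts), drop = FALSE]
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(merged)))
  proportion_tbl(out, new_types, method = attr(props, "method"),
                 marker_rule = attr(props, "marker_rule"))
}
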