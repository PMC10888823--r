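#' Signature matrix from a single-cell reference
#'
#' Per-cell-type mean CPM over the union of all marker genes: the
#' reference profile against which bulk samples are decomposed.
#'
#' @param ref a cpm-scale reference `expr_matrix`.
#' @param annotation a [cell_annotation()] for the reference cells.
#' @param markers a `marker_sets` tibble; the signature uses the union
#'   of all its genes (sorted, for a deterministic gene order).
#' @return an object of class `signature_matrix`: list with `values`
#'   (gene x cell-type matrix), `markers`, and `n_cells`.
#' @export
signature_from_reference <- function(ref, annotation, markers) {
  check_scale(ref, "cpm")
  genes <- sort(unique(markers$gene_id))
  absent <- setdiff(genes, gene_ids(ref))
  if (length(absent) > 0) {
    abort(paste0("marker genes absent from reference: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  means <- type_means(ref, annotation)
  values <- Matrix::t(means$means[, genes, drop = FALSE])
  values <- as.matrix(values)
  structure(list(values = values, markers = markers,
                 n_cells = means$n_cells),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d cell types\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

restrict_bulk <- function(bulk, sig) {
  check_scale(bulk, "cpm")
  genes <- rownames(sig$values)
  absent <- setdiff(genes, gene_ids(bulk))
  if (length(absent) > 0) {
    abort(paste0("signature genes absent from bulk: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  expr_values(expr_subset(bulk, genes = genes), dense = TRUE)
}

finalize_props <- function(w, sample_ids, cell_types, method, metadata,
                           marker_rule = NA_character_) {
  sums <- rowSums(w)
  degenerate <- sums == 0
  if (any(degenerate)) {
    warn(paste0("all-zero solution; uniform fallback for: ",
                paste(sample_ids[degenerate], collapse = ", ")))
    w[degenerate, ] <- 1
    sums[degenerate] <- ncol(w)
  }
  p <- w / sums
  out <- dplyr::bind_cols(tibble(unit_id = sample_ids),
                          as_tibble(as.data.frame(p)))
  if (!is.null(metadata)) {
    meta <- as_tibble(metadata)
    if ("sample_id" %in% names(meta) && !"unit_id" %in% names(meta)) {
      meta <- rename(meta, unit_id = "sample_id")
    }
    out <- left_join(out, meta, by = "unit_id")
  }
  res <- proportion_tbl(out, cell_types, method = method,
                        marker_rule = marker_rule)
  attr(res, "degenerate_units") <- sample_ids[degenerate]
  res
}

#' Non-negative least squares deconvolution
#'
#' For each bulk sample y, solves `min || y - S w ||_2` subject to
#' `w >= 0` over the signature genes (Lawson--Hanson active set), then
#' normalises `p = w / sum(w)`. The normalisation makes the estimate
#' invariant to the overall scale of the bulk column. An all-zero
#' solution falls back to uniform proportions with a warning so batch
#' runs never silently drop samples.
#'
#' @param bulk a cpm-scale bulk `expr_matrix`.
#' @param sig a [signature_from_reference()] result; must have full
#'   column rank over its genes.
#' @param metadata optional per-sample metadata joined onto the output
#'   (by `sample_id` or `unit_id`).
#' @return a [proportion_tbl()] of RNA-fraction proportions, method
#'   tag `"nnls"`.
#' @export
deconvolve_nnls <- function(bulk, sig, metadata = NULL) {
  S <- sig$values
  if (qr(S)$rank < ncol(S)) {
    abort("signature matrix is rank deficient.")
  }
  Y <- restrict_bulk(bulk, sig)
  w <- t(apply(Y, 2, function(y) pracma::lsqnonneg(S, y)$x))
  if (ncol(S) == 1) w <- matrix(w, ncol = 1)
  colnames(w) <- colnames(S)
  finalize_props(w, colnames(Y), colnames(S), "nnls", metadata,
                 marker_rule = attr(sig$markers, "rule") %||% NA_character_)
}

#' Marker-ratio deconvolution
#'
#' A simple marker-average estimator: for each cell type k, the score
#' is the mean over its marker genes of `bulk_g / sig_{g,k}` (terms
#' with a zero signature entry are skipped), and proportions are the
#' normalised scores. With perfectly type-specific markers this
#' recovers the RNA-fraction proportions exactly.
#'
#' @inheritParams deconvolve_nnls
#' @param markers a `marker_sets` tibble; every cell type of `sig`
#'   needs at least one marker present in the bulk.
#' @return a [proportion_tbl()] of RNA-fraction proportions, method
#'   tag `"marker_ratio"`.
#' @export
deconvolve_marker_ratio <- function(bulk, sig, markers = NULL,
                                    metadata = NULL) {
  if (is.null(markers)) markers <- sig$markers
  S <- sig$values
  Y <- restrict_bulk(bulk, sig)
  sets <- marker_list(markers)
  cts <- colnames(S)
  empty <- setdiff(cts, names(sets))
  if (length(empty) > 0 || any(lengths(sets[cts]) == 0)) {
    abort(paste0("empty marker set for cell type(s): ",
                 paste(c(empty, cts[lengths(sets[cts]) == 0]),
                       collapse = ", ")))
  }
  w <- sapply(cts, function(ct) {
    genes <- intersect(sets[[ct]], rownames(S))
    s <- S[genes, ct]
    usable <- s > 0
    if (!any(usable)) return(rep(0, ncol(Y)))
    colMeans(Y[genes[usable], , drop = FALSE] / s[usable])
  })
  if (is.null(dim(w))) w <- matrix(w, nrow = 1, dimnames = list(NULL, cts))
  finalize_props(w, colnames(Y), cts, "marker_ratio", metadata,
                 marker_rule = attr(markers, "rule") %||% NA_character_)
}

# ---- estimator registry ------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Deconvolution method registry
#'
#' External deconvolution methods plug in through a declared contract:
#' a function `f(bulk, ref, annotation, markers, metadata)` taking
#' counts-scale bulk and reference matrices plus cell annotation and a
#' `marker_sets` tibble, returning a [proportion_tbl()]. The two
#' in-repo baselines are pre-registered as `"nnls"` and
#' `"marker_ratio"`.
#'
#' @param name method name.
#' @param fn the estimator function.
#' @return `register_deconv_method` returns `name` invisibly;
#'   `get_deconv_method` the function; `list_deconv_methods` a
#'   character vector.
#' @export
register_deconv_method <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = the_registry)
  invisible(name)
}

#' @rdname register_deconv_method
#' @export
get_deconv_method <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE)) {
    abort(paste0("unregistered deconvolution method: ", name))
  }
  get(name, envir = the_registry, inherits = FALSE)
}

#' @rdname register_deconv_method
#' @export
list_deconv_methods <- function() {
  sort(ls(envir = the_registry))
}

#' Run a registered estimator from raw counts
#'
#' Normalises bulk and reference to CPM, builds the signature over the
#' marker union, and dispatches to the named estimator.
#'
#' @param method registered method name (see
#'   [register_deconv_method()]).
#' @param bulk,ref counts-scale `expr_matrix` objects.
#' @param annotation a [cell_annotation()] for `ref`.
#' @param markers a `marker_sets` tibble.
#' @param metadata optional per-sample metadata.
#' @return a [proportion_tbl()].
#' @export
deconvolve <- function(method, bulk, ref, annotation, markers,
                       metadata = NULL) {
  fn <- get_deconv_method(method)
  fn(bulk, ref, annotation, markers, metadata)
}

builtin_nnls <- function(bulk, ref, annotation, markers, metadata = NULL) {
  sig <- signature_from_reference(cpm_normalize(ref), annotation, markers)
  deconvolve_nnls(cpm_normalize(bulk), sig, metadata = metadata)
}

builtin_marker_ratio <- function(bulk, ref, annotation, markers,
                                 metadata = NULL) {
  sig <- signature_from_reference(cpm_normalize(ref), annotation, markers)
  deconvolve_marker_ratio(cpm_normalize(bulk), sig, markers,
                          metadata = metadata)
}

.onLoad <- function(libname, pkgname) {
  register_deconv_method("nnls", builtin_nnls)
  register_deconv_method("marker_ratio", builtin_marker_ratio)
}
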