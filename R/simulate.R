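#' Generator configuration
#'
#' Parameters of the synthetic multi-donor brain reference and bulk
#' mixtures used throughout testing. Defaults describe a
#' seven-cell-type cortical tissue: excitatory neurons the most
#' common class and microglia the rarest, neurons carrying more RNA
#' per cell than glia, log-normal baseline expression, and
#' negative-binomial reference counts.
#'
#' @param n_genes number of genes.
#' @param cell_types cell-type labels.
#' @param composition named per-type cell fractions (sums to 1).
#' @param n_cells total reference cells when `cells_per_type` is not
#'   given.
#' @param cells_per_type optional named integer vector overriding
#'   `composition * n_cells`.
#' @param n_markers_per_type planted marker genes per type.
#' @param marker_fold fold elevation of a planted marker's mean in its
#'   type (> 1).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline gene means.
#' @param dispersion negative-binomial size (inverse dispersion) of
#'   reference counts; `Inf` gives Poisson.
#' @param size_factors named per-type RNA-content multipliers (the
#'   "cell size" in deconvolution terms).
#' @param cell_depth expected counts per reference cell before the
#'   size factor.
#' @param n_donors donors the reference cells are assigned to.
#' @param n_bulk_samples bulk mixtures to simulate.
#' @param bulk_depth expected counts per bulk sample.
#' @param prop_alpha Dirichlet concentration used to draw true
#'   compositions when none are supplied (`composition * prop_alpha`).
#' @param library_bias_sdlog log-normal spread of the per-gene
#'   multiplicative library bias (0 = no baseline bias).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(
    n_genes = 2000,
    cell_types = c("Astro", "EndoMural", "Micro", "Oligo", "OPC",
                   "Excit", "Inhib"),
    composition = c(Astro = 0.10, EndoMural = 0.05, Micro = 0.03,
                    Oligo = 0.20, OPC = 0.07, Excit = 0.44, Inhib = 0.11),
    n_cells = 2100,
    cells_per_type = NULL,
    n_markers_per_type = 25,
    marker_fold = 8,
    baseline_meanlog = 1,
    baseline_sdlog = 1,
    dispersion = 2,
    size_factors = c(Astro = 1, EndoMural = 0.8, Micro = 0.6,
                     Oligo = 0.9, OPC = 0.9, Excit = 1.8, Inhib = 1.5),
    cell_depth = 2000,
    n_donors = 4,
    n_bulk_samples = 24,
    bulk_depth = 1e6,
    prop_alpha = 20,
    library_bias_sdlog = 0) {
  cfg <- list(
    n_genes = n_genes, cell_types = cell_types,
    composition = composition[cell_types],
    n_cells = n_cells, cells_per_type = cells_per_type,
    n_markers_per_type = n_markers_per_type, marker_fold = marker_fold,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion, size_factors = size_factors[cell_types],
    cell_depth = cell_depth, n_donors = n_donors,
    n_bulk_samples = n_bulk_samples, bulk_depth = bulk_depth,
    prop_alpha = prop_alpha, library_bias_sdlog = library_bias_sdlog
  )
  if (anyNA(cfg$composition) || abs(sum(cfg$composition) - 1) > 1e-8) {
    abort("composition must cover all cell types and sum to 1.")
  }
  if (marker_fold <= 1) abort("marker_fold must exceed 1.")
  if (n_markers_per_type * length(cell_types) > n_genes) {
    abort("more planted markers than genes.")
  }
  if (any(is.na(cfg$size_factors)) || any(cfg$size_factors <= 0)) {
    abort("size_factors must cover all cell types and be positive.")
  }
  structure(cfg, class = "generator_config")
}

dirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a single-nucleus reference with planted markers
#'
#' Draws a baseline mean per gene from a log-normal, elevates each
#' planted marker's mean by `marker_fold` in its assigned type only,
#' and samples negative-binomial counts per cell with per-type total
#' RNA scaled by the size factors. Marker assignments are disjoint
#' across types.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; the output is bit-reproducible.
#' @param truth optional `truth` element of a previous run: reuses its
#'   gene profiles and marker map and only redraws cells, so two
#'   references from the same generative truth can be compared.
#' @return a list with `expr` (counts `expr_matrix`), `annotation`
#'   (a [cell_annotation()]), and `truth` (list: `profiles` gene x
#'   type relative mean matrix, `marker_map` tibble, `size_factors`,
#'   `config`).
#' @export
simulate_reference <- function(config = generator_config(), seed = 1,
                               truth = NULL) {
  cfg <- config
  withr::with_seed(seed, {
    types <- cfg$cell_types
    if (is.null(truth)) {
      genes <- sprintf("g%04d", seq_len(cfg$n_genes))
      baseline <- rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                         cfg$baseline_sdlog)
      names(baseline) <- genes
      marker_genes <- sample(genes,
                             cfg$n_markers_per_type * length(types))
      marker_map <- tibble(
        gene_id = marker_genes,
        cell_type = rep(types, each = cfg$n_markers_per_type)
      )
      profiles <- matrix(baseline, nrow = cfg$n_genes,
                         ncol = length(types),
                         dimnames = list(genes, types))
      idx <- cbind(match(marker_map$gene_id, genes),
                   match(marker_map$cell_type, types))
      profiles[idx] <- profiles[idx] * cfg$marker_fold
    } else {
      profiles <- truth$profiles
      marker_map <- truth$marker_map
      baseline <- truth$baseline
      genes <- rownames(profiles)
    }

    n_per <- cfg$cells_per_type
    if (is.null(n_per)) {
      n_per <- round(cfg$composition * cfg$n_cells)
      n_per <- pmax(n_per, 2L)
    }
    n_per <- setNames(as.integer(n_per[types]), types)
    total <- sum(n_per)
    cell_type <- rep(types, times = n_per)
    ids <- sprintf("c%05d", seq_len(total))
    counts <- matrix(0L, nrow = cfg$n_genes, ncol = total,
                     dimnames = list(genes, ids))
    for (ct in types) {
      cols <- which(cell_type == ct)
      p <- profiles[, ct] / sum(profiles[, ct])
      mu <- cfg$cell_depth * cfg$size_factors[[ct]] * p
      n_draw <- length(cols) * cfg$n_genes
      draws <- if (is.finite(cfg$dispersion)) {
        rnbinom(n_draw, size = cfg$dispersion, mu = rep(mu, length(cols)))
      } else {
        rpois(n_draw, lambda = rep(mu, length(cols)))
      }
      counts[, cols] <- draws
    }
    annotation <- cell_annotation(
      unit_id = ids,
      cell_type = cell_type,
      donor_id = paste0("donor", (seq_len(total) %% cfg$n_donors) + 1),
      sample_id = paste0("refsample",
                         ((seq_len(total) %% cfg$n_donors) + 1))
    )
    list(
      expr = expr_matrix(counts, scale = "counts"),
      annotation = annotation,
      truth = list(profiles = profiles, marker_map = marker_map,
                   size_factors = cfg$size_factors, baseline = baseline,
                   config = cfg)
    )
  })
}

#' Simulate bulk mixtures from a reference truth
#'
#' Expected expression for sample j is
#' `lambda_gj = bias_g(lib_j) * sum_k c_kj * s_k * profile_gk / T_k`
#' (each cell of type k contributes RNA proportional to its size
#' factor `s_k`, with the type's relative profile), rescaled to the
#' target library depth. Counts are Poisson (default),
#' negative-binomial, or noise-free expectations.
#'
#' @param truth the `truth` element of [simulate_reference()] (or the
#'   whole reference list).
#' @param n_samples number of bulk samples (ignored when `true_props`
#'   is given).
#' @param true_props optional sample x cell-type matrix of true
#'   cell-count proportions (rows sum to 1); `NULL` draws them from a
#'   Dirichlet centred on the configured composition.
#' @param library_types per-sample library labels (recycled; default
#'   alternating polyA / RiboZeroGold).
#' @param rna_extractions per-sample extraction labels (recycled).
#' @param bias optional planted multiplicative bias: a list with
#'   `library_type`, `factor`, and either `genes` or `cell_type`
#'   (whose planted markers are biased). Applied on top of the
#'   baseline per-gene log-normal bias (`library_bias_sdlog`).
#' @param noise `"poisson"`, `"nb"` (with `nb_size`), or `"none"` for
#'   exact expectations.
#' @param nb_size negative-binomial size when `noise = "nb"`.
#' @param seed integer seed.
#' @return a list with `expr` (counts `expr_matrix`), `metadata`
#'   (tibble: sample_id, library_type, rna_extraction, block_id), and
#'   `truth` (list: `cell_props`, `rna_props` tibbles, `bias_factors`
#'   gene x library matrix).
#' @export
simulate_bulk <- function(truth, n_samples = NULL, true_props = NULL,
                          library_types = c("polyA", "RiboZeroGold"),
                          rna_extractions = c("Cyto", "Total", "Nuc"),
                          bias = NULL,
                          noise = c("poisson", "nb", "none"),
                          nb_size = 50, seed = 1) {
  noise <- match.arg(noise)
  if (!is.null(truth$truth)) truth <- truth$truth
  cfg <- truth$config
  profiles <- truth$profiles
  s <- truth$size_factors
  types <- colnames(profiles)
  withr::with_seed(seed, {
    if (is.null(true_props)) {
      if (is.null(n_samples)) n_samples <- cfg$n_bulk_samples
      true_props <- dirichlet(n_samples,
                              cfg$composition * cfg$prop_alpha)
      colnames(true_props) <- types
    } else {
      true_props <- as.matrix(true_props)[, types, drop = FALSE]
      if (any(abs(rowSums(true_props) - 1) > 1e-8)) {
        abort("true proportion rows must sum to 1.")
      }
      n_samples <- nrow(true_props)
    }
    sample_ids <- sprintf("bulk%03d", seq_len(n_samples))
    lib <- rep_len(library_types, n_samples)
    extr <- rep_len(rna_extractions, n_samples)
    block <- paste0("block", ((seq_len(n_samples) - 1) %/%
                                length(library_types)) + 1)

    libs <- unique(lib)
    bias_factors <- matrix(1, nrow = nrow(profiles), ncol = length(libs),
                           dimnames = list(rownames(profiles), libs))
    if (cfg$library_bias_sdlog > 0) {
      for (l in libs) {
        bias_factors[, l] <- rlnorm(nrow(profiles), 0,
                                    cfg$library_bias_sdlog)
      }
    }
    if (!is.null(bias)) {
      genes <- bias$genes
      if (is.null(genes)) {
        genes <- truth$marker_map$gene_id[
          truth$marker_map$cell_type == bias$cell_type]
      }
      if (!bias$library_type %in% libs) {
        abort("bias library_type not among simulated libraries.")
      }
      bias_factors[genes, bias$library_type] <-
        bias_factors[genes, bias$library_type] * bias$factor
    }

    # RNA-weighted mixture of per-type relative profiles
    rel <- sweep(profiles, 2, colSums(profiles), `/`)
    rna_w <- sweep(true_props, 2, s[types], `*`)
    rna_props <- rna_w / rowSums(rna_w)
    lambda <- rel %*% Matrix::t(rna_w)
    lambda <- as.matrix(lambda)
    lambda <- lambda * bias_factors[, lib, drop = FALSE]
    lambda <- sweep(lambda, 2, colSums(lambda), `/`) * cfg$bulk_depth
    colnames(lambda) <- sample_ids

    counts <- switch(
      noise,
      none = lambda,
      poisson = matrix(rpois(length(lambda), lambda),
                       nrow = nrow(lambda), dimnames = dimnames(lambda)),
      nb = matrix(rnbinom(length(lambda), size = nb_size, mu = lambda),
                  nrow = nrow(lambda), dimnames = dimnames(lambda))
    )
    metadata <- tibble(sample_id = sample_ids, library_type = lib,
                       rna_extraction = extr, block_id = block)
    prop_tbl <- function(m) {
      dplyr::bind_cols(tibble(unit_id = sample_ids),
                       as_tibble(as.data.frame(m)))
    }
    list(
      expr = expr_matrix(counts, scale = "counts"),
      metadata = metadata,
      truth = list(
        cell_props = proportion_tbl(prop_tbl(true_props), types,
                                    method = "truth_cells"),
        rna_props = proportion_tbl(prop_tbl(rna_props), types,
                                   method = "truth_rna"),
        bias_factors = bias_factors
      )
    )
  })
}

#' Simulate a segmented-cell imaging table
#'
#' Phenotypes are multinomial with the given composition (an `other`
#' entry stands for segmented-but-unlabeled nuclei), nuclear areas
#' are per-type log-normal truncated so every regular cell's derived
#' radius stays at or below `max_radius`, puncta counts are per-type
#' Poisson, and a fraction of cells is planted with an oversized
#' radius to exercise the size filter.
#'
#' @param p named composition over phenotypes (may include `other`);
#'   sums to 1.
#' @param n_cells number of segmented cells.
#' @param area_meanlog,area_sdlog named per-phenotype log-normal
#'   parameters of nuclear area in square microns (defaults: larger
#'   neuronal nuclei).
#' @param puncta_mean named per-phenotype Poisson means of the
#'   total-RNA puncta count.
#' @param oversize_fraction fraction of cells planted with radius
#'   above `max_radius`.
#' @param max_radius the filter threshold the oversized cells must
#'   exceed (default 5 microns).
#' @param section_ids section labels cells are spread over uniformly.
#' @param seed integer seed.
#' @return a [cells_table()] with an `oversized` logical attribute
#'   marking the planted cells.
#' @export
simulate_cells_table <- function(p, n_cells = 10000,
                                 area_meanlog = NULL, area_sdlog = NULL,
                                 puncta_mean = NULL,
                                 oversize_fraction = 0,
                                 max_radius = 5,
                                 section_ids = c("s1", "s2"),
                                 seed = 1) {
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    abort("`p` must be a non-negative composition summing to 1.")
  }
  phen <- names(p)
  neurons <- c("Excit", "Inhib")
  default_by_type <- function(neuron_val, glia_val) {
    setNames(ifelse(phen %in% neurons, neuron_val, glia_val), phen)
  }
  if (is.null(area_meanlog)) area_meanlog <- default_by_type(log(45), log(28))
  if (is.null(area_sdlog)) area_sdlog <- default_by_type(0.25, 0.25)
  if (is.null(puncta_mean)) puncta_mean <- default_by_type(40, 15)
  max_area <- pi * max_radius^2
  withr::with_seed(seed, {
    phenotype <- sample(phen, n_cells, replace = TRUE, prob = p)
    area <- numeric(n_cells)
    puncta <- integer(n_cells)
    for (ct in phen) {
      idx <- which(phenotype == ct)
      a <- rlnorm(length(idx), area_meanlog[[ct]], area_sdlog[[ct]])
      # redraw the tail so regular cells never trip the radius filter
      bad <- which(a > max_area)
      while (length(bad) > 0) {
        a[bad] <- rlnorm(length(bad), area_meanlog[[ct]], area_sdlog[[ct]])
        bad <- which(a > max_area)
      }
      area[idx] <- a
      puncta[idx] <- rpois(length(idx), puncta_mean[[ct]])
    }
    n_over <- round(oversize_fraction * n_cells)
    oversized <- rep(FALSE, n_cells)
    radius <- rep(NA_real_, n_cells)
    if (n_over > 0) {
      over_idx <- sample(n_cells, n_over)
      oversized[over_idx] <- TRUE
      radius[over_idx] <- runif(n_over, max_radius * 1.1, max_radius * 1.6)
      area[over_idx] <- pi * radius[over_idx]^2
    }
    out <- cells_table(tibble(
      section_id = sample(section_ids, n_cells, replace = TRUE),
      combination = "synthetic",
      phenotype = ifelse(phenotype == "other", NA_character_, phenotype),
      nuclear_area = area,
      puncta = puncta,
      radius = radius
    ))
    attr(out, "oversized") <- oversized
    out
  })
}
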