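# Small fixtures built in code; all randomness goes through explicit
# seeds so the suite is reproducible.

random_counts <- function(n_genes, n_units, seed = 1, max_count = 50,
                          zero_frac = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_units, lambda = max_count / 5),
                nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("u%03d", seq_len(n_units))))
    zero <- matrix(runif(length(m)) < zero_frac, nrow = n_genes)
    m[zero] <- 0
    expr_matrix(m, scale = "counts")
  })
}

random_annotation <- function(expr, n_types = 3, seed = 1) {
  withr::with_seed(seed, {
    types <- paste0("T", seq_len(n_types))
    ct <- sample(rep_len(types, n_units(expr)))
    cell_annotation(unit_id = unit_ids(expr), cell_type = ct,
                    donor_id = "d1", sample_id = "s1")
  })
}

# reference with perfectly type-specific markers: marker genes of each
# type are expressed only in that type, so closed-form recovery holds
specific_marker_reference <- function(n_types = 3, markers_per_type = 4,
                                      n_background = 6) {
  types <- paste0("T", seq_len(n_types))
  marker_genes <- unlist(lapply(types, function(t) {
    paste0(t, "_m", seq_len(markers_per_type))
  }))
  genes <- c(marker_genes, paste0("bg", seq_len(n_background)))
  profiles <- matrix(0, nrow = length(genes), ncol = n_types,
                     dimnames = list(genes, types))
  for (i in seq_along(types)) {
    rows <- ((i - 1) * markers_per_type + 1):(i * markers_per_type)
    profiles[rows, i] <- 100 + 10 * seq_len(markers_per_type)
  }
  profiles[(length(marker_genes) + 1):length(genes), ] <- 20
  sets <- structure(
    tibble::tibble(
      cell_type = rep(types, each = markers_per_type),
      gene_id = marker_genes,
      set_rank = rep(seq_len(markers_per_type), n_types)
    ),
    class = c("marker_sets", class(tibble::tibble())),
    rule = "fixture"
  )
  list(profiles = profiles, types = types, genes = genes, markers = sets)
}

# turn a per-type profile matrix into a cpm signature_matrix fixture
signature_from_profiles <- function(profiles, markers) {
  cpm <- sweep(profiles, 2, colSums(profiles), `/`) * 1e6
  structure(list(values = cpm, markers = markers,
                 n_cells = setNames(rep(10L, ncol(profiles)),
                                    colnames(profiles))),
            class = "signature_matrix")
}

random_prop_tbl <- function(n_units, types, seed = 1, method = "x") {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n_units * length(types), 2), nrow = n_units)
    m <- m / rowSums(m)
    colnames(m) <- types
    df <- dplyr::bind_cols(
      tibble::tibble(unit_id = sprintf("s%03d", seq_len(n_units))),
      tibble::as_tibble(as.data.frame(m))
    )
    proportion_tbl(df, types, method = method)
  })
}
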