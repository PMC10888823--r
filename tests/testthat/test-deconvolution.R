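test_that("signature_from_reference matches per-type mean computation", {
  expr <- cpm_normalize(random_counts(60, 30, seed = 8))
  ann <- random_annotation(expr, n_types = 3, seed = 8)
  stats <- tibble::tibble(gene_id = gene_ids(expr)[c(5, 10, 20)],
                          cell_type = c("T1", "T2", "T3"),
                          mean_ratio = 2, rank_ratio = 1)
  sets <- build_marker_sets(stats, "mean_ratio_over_t", t = 1)
  sig <- signature_from_reference(expr, ann, sets)
  v <- expr_values(expr, dense = TRUE)
  for (g in rownames(sig$values)) {
    for (ct in colnames(sig$values)) {
      cells <- ann$unit_id[ann$cell_type == ct]
      expect_equal(sig$values[g, ct], mean(v[g, cells]))
    }
  }
  expect_identical(rownames(sig$values), sort(rownames(sig$values)))
  bad <- sets
  bad$gene_id[1] <- "not_a_gene"
  expect_error(signature_from_reference(expr, ann, bad), "absent")
})

test_that("NNLS recovers exact mixtures and pure columns", {
  fx <- specific_marker_reference(n_types = 2)
  sig <- signature_from_profiles(fx$profiles, fx$markers)
  p_true <- c(0.7, 0.3)
  y <- sig$values %*% p_true
  bulk <- expr_matrix(cbind(mix = y[, 1] / sum(y) * 1e6,
                            pure = sig$values[, 1] / sum(sig$values[, 1]) * 1e6),
                      gene_ids = rownames(sig$values),
                      scale = "cpm")
  props <- deconvolve_nnls(bulk, sig)
  m <- prop_matrix(props)
  expect_equal(unname(m["mix", ]), p_true, tolerance = 1e-6)
  expect_equal(unname(m["pure", ]), c(1, 0), tolerance = 1e-6)
})

test_that("NNLS matches a grid-search oracle on 2-type sub-problems", {
  fx <- specific_marker_reference(n_types = 2, markers_per_type = 3,
                                  n_background = 4)
  sig <- signature_from_profiles(fx$profiles, fx$markers)
  S <- sig$values
  withr::with_seed(12, {
    for (rep in 1:20) {
      p1 <- runif(1)
      y <- S %*% c(p1, 1 - p1)
      # exhaustive grid over the single mixing weight
      grid <- seq(0, 1, by = 1e-4)
      sse <- vapply(grid, function(a) {
        sum((y - S %*% c(a, 1 - a))^2)
      }, numeric(1))
      best <- grid[which.min(sse)]
      bulk <- expr_matrix(matrix(y, ncol = 1,
                                 dimnames = list(rownames(S), "s1")),
                          scale = "cpm")
      est <- prop_matrix(deconvolve_nnls(bulk, sig))[1, 1]
      expect_lt(abs(est - best), 1e-4)  # grid resolution bound
      expect_equal(est, p1, tolerance = 1e-6)
    }
  })
})

test_that("NNLS proportions are scale invariant in the bulk column", {
  fx <- specific_marker_reference(n_types = 3)
  sig <- signature_from_profiles(fx$profiles, fx$markers)
  y <- sig$values %*% c(0.2, 0.5, 0.3)
  bulk1 <- expr_matrix(matrix(y, ncol = 1,
                              dimnames = list(rownames(sig$values), "s")),
                       scale = "cpm")
  bulk2 <- expr_matrix(matrix(y * 37.5, ncol = 1,
                              dimnames = list(rownames(sig$values), "s")),
                       scale = "cpm")
  expect_equal(prop_matrix(deconvolve_nnls(bulk1, sig)),
               prop_matrix(deconvolve_nnls(bulk2, sig)))
})

test_that("NNLS rejects rank-deficient signatures, falls back on zeros", {
  S <- matrix(c(1, 2, 2, 4), nrow = 2,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  sig <- structure(list(values = S, markers = NULL), class = "signature_matrix")
  bulk <- expr_matrix(matrix(c(1, 2), ncol = 1,
                             dimnames = list(c("g1", "g2"), "s")),
                      scale = "cpm")
  expect_error(deconvolve_nnls(bulk, sig), "rank deficient")

  fx <- specific_marker_reference(n_types = 2)
  sig2 <- signature_from_profiles(fx$profiles, fx$markers)
  zero_bulk <- expr_matrix(
    matrix(0, nrow = nrow(sig2$values), ncol = 1,
           dimnames = list(rownames(sig2$values), "s")),
    scale = "cpm")
  expect_warning(res <- deconvolve_nnls(zero_bulk, sig2), "uniform")
  expect_equal(unname(prop_matrix(res)[1, ]), c(0.5, 0.5))
})

test_that("marker_ratio recovers RNA fractions with specific markers", {
  fx <- specific_marker_reference(n_types = 3)
  sig <- signature_from_profiles(fx$profiles, fx$markers)
  withr::with_seed(5, {
    for (rep in 1:10) {
      p <- as.vector(rgamma(3, 2)); p <- p / sum(p)
      y <- sig$values %*% p
      bulk <- expr_matrix(matrix(y, ncol = 1,
                                 dimnames = list(rownames(sig$values), "s")),
                          scale = "cpm")
      est <- prop_matrix(deconvolve_marker_ratio(bulk, sig))[1, ]
      expect_equal(unname(est), p, tolerance = 1e-8)
    }
  })
})

test_that("marker_ratio symmetry and empty-marker error", {
  fx <- specific_marker_reference(n_types = 2)
  sig <- signature_from_profiles(fx$profiles, fx$markers)
  y <- sig$values %*% c(0.5, 0.5)
  bulk <- expr_matrix(matrix(y, ncol = 1,
                             dimnames = list(rownames(sig$values), "s")),
                      scale = "cpm")
  est <- prop_matrix(deconvolve_marker_ratio(bulk, sig))[1, ]
  expect_equal(unname(est), c(0.5, 0.5))

  half <- sig$markers[sig$markers$cell_type == "T1", ]
  expect_error(deconvolve_marker_ratio(bulk, sig, half), "empty marker")
})

test_that("estimators return valid simplex rows on arbitrary input", {
  ref <- simulate_reference(generator_config(n_genes = 150, n_cells = 140,
                                             n_markers_per_type = 5),
                            seed = 3)
  bulk <- simulate_bulk(ref, n_samples = 4, seed = 6)
  stats <- marker_stats(ref$expr, ref$annotation)
  sets <- build_marker_sets(stats, "mean_ratio_top_n", n = 5)
  for (method in c("nnls", "marker_ratio")) {
    props <- deconvolve(method, bulk$expr, ref$expr, ref$annotation, sets)
    m <- prop_matrix(props)
    expect_true(all(m >= 0))
    expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-8)
  }
})

test_that("cell size adjustment inverts the RNA-fraction construction", {
  types <- c("A", "B", "C")
  sizes <- c(A = 2, B = 1, C = 0.5)
  withr::with_seed(10, {
    cells <- random_prop_tbl(8, types, seed = 10)
    c_m <- prop_matrix(cells)
    rna <- sweep(c_m, 2, sizes[types], `*`)
    rna <- rna / rowSums(rna)
    rna_tbl <- proportion_tbl(
      dplyr::bind_cols(tibble::tibble(unit_id = cells$unit_id),
                       tibble::as_tibble(as.data.frame(rna))),
      types)
    back <- cell_size_adjust(rna_tbl, sizes)
    expect_equal(prop_matrix(back), c_m, tolerance = 1e-10)
  })
  # equal sizes act as the identity
  tbl <- random_prop_tbl(5, types, seed = 11)
  same <- cell_size_adjust(tbl, c(A = 3, B = 3, C = 3))
  expect_equal(prop_matrix(same), prop_matrix(tbl), tolerance = 1e-12)
  # p = (0.5, 0.5), sizes (2, 1) -> (1/3, 2/3)
  two <- proportion_tbl(tibble::tibble(unit_id = "u", A = 0.5, B = 0.5),
                        c("A", "B"))
  adj <- cell_size_adjust(two, c(A = 2, B = 1))
  expect_equal(unname(prop_matrix(adj)[1, ]), c(1 / 3, 2 / 3))
  expect_error(cell_size_adjust(two, c(A = 2)), "missing size")
  expect_error(cell_size_adjust(two, c(A = 2, B = -1)), "positive")
})

test_that("collapsing cell types sums sources and preserves row sums", {
  types <- c("Oligo", "OPC", "Excit")
  tbl <- proportion_tbl(
    tibble::tibble(unit_id = "s1", Oligo = 0.10, OPC = 0.02, Excit = 0.88),
    types)
  merged <- collapse_cell_types(tbl, c(Oligo = "OligoOPC",
                                       OPC = "OligoOPC"))
  expect_equal(merged$OligoOPC, 0.12)
  expect_setequal(prop_cell_types(merged), c("OligoOPC", "Excit"))

  rnd <- random_prop_tbl(10, c("A", "B", "C", "D"), seed = 14)
  m <- collapse_cell_types(rnd, c(A = "AB", B = "AB", C = "CD", D = "CD"))
  expect_equal(unname(rowSums(prop_matrix(m))), rep(1, 10))
  expect_equal(unname(prop_matrix(m)[, "AB"]),
               unname(rowSums(prop_matrix(rnd)[, c("A", "B")])))
  expect_error(collapse_cell_types(rnd, c(A = "B")), "collides")
})

test_that("the method registry round-trips and rejects unknown names", {
  expect_setequal(intersect(list_deconv_methods(),
                            c("nnls", "marker_ratio")),
                  c("nnls", "marker_ratio"))
  register_deconv_method("custom_test", function(bulk, ref, ann, mk, md)
    stop("not called"))
  expect_true("custom_test" %in% list_deconv_methods())
  expect_error(get_deconv_method("never_registered"), "unregistered")
})
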