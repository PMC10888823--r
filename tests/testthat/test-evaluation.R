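test_that("compare_proportions reproduces the metric definitions", {
  types <- c("A", "B")
  pred <- proportion_tbl(
    tibble::tibble(unit_id = "s1", A = 0.2, B = 0.8), types)
  truth <- proportion_tbl(
    tibble::tibble(unit_id = "s1", A = 0.1, B = 0.9), types)
  res <- compare_proportions(pred, truth)
  expect_equal(res$rmse, 0.1)
  expect_equal(res$rrmse, 0.2)  # mean truth = 0.5 over the two pairs

  # identity: cor 1, rmse 0, rrmse 0
  same <- compare_proportions(truth, truth)
  expect_equal(same$cor, 1)
  expect_equal(same$rmse, 0)
  expect_equal(same$rrmse, 0)

  # random tables against elementwise recomputation from definitions
  p <- random_prop_tbl(9, c("A", "B", "C"), seed = 20)
  t_ <- random_prop_tbl(9, c("A", "B", "C"), seed = 21)
  res2 <- compare_proportions(p, t_)
  pv <- as.vector(prop_matrix(p))
  tv <- as.vector(prop_matrix(t_))
  expect_equal(res2$cor, cor(pv, tv))
  expect_equal(res2$rmse, sqrt(mean((pv - tv)^2)))
  expect_equal(res2$rrmse, sqrt(mean((pv - tv)^2)) / mean(tv))
  expect_identical(res2$n_pairs, length(pv))
})

test_that("compare_proportions handles strata, cell-type scope, zero variance", {
  types <- c("A", "B")
  pred <- proportion_tbl(
    tibble::tibble(unit_id = c("s1", "s2"), A = c(0.2, 0.4),
                   B = c(0.8, 0.6), lib = c("polyA", "Ribo")), types)
  truth <- proportion_tbl(
    tibble::tibble(unit_id = c("s1", "s2"), A = c(0.1, 0.5),
                   B = c(0.9, 0.5)), types)
  by_lib <- compare_proportions(pred, truth, group_by = "lib")
  expect_identical(nrow(by_lib), 2L)
  by_ct <- compare_proportions(pred, truth, by_cell_type = TRUE)
  expect_identical(nrow(by_ct), 2L)

  # constant predictions: cor undefined with a reason, rmse still real
  flat <- proportion_tbl(
    tibble::tibble(unit_id = c("s1", "s2"), A = 0.5, B = 0.5), types)
  res <- compare_proportions(flat, truth)
  expect_true(is.na(res$cor))
  expect_identical(res$cor_undefined_reason, "zero variance")
  expect_false(is.na(res$rmse))
  expect_error(compare_proportions(pred,
                                   random_prop_tbl(2, c("X", "Y"))),
               "share cell-type")
})

test_that("compare_proportions is invariant to unit order and rmse obeys the triangle bound", {
  a <- random_prop_tbl(7, c("A", "B", "C"), seed = 30)
  b <- random_prop_tbl(7, c("A", "B", "C"), seed = 31)
  c_ <- random_prop_tbl(7, c("A", "B", "C"), seed = 32)
  shuffled <- a[withr::with_seed(1, sample(nrow(a))), ]
  attr(shuffled, "cell_types") <- prop_cell_types(a)
  expect_equal(compare_proportions(a, b)$rmse,
               compare_proportions(shuffled, b)$rmse)
  r_ac <- compare_proportions(a, c_)$rmse
  r_ab <- compare_proportions(a, b)$rmse
  r_bc <- compare_proportions(b, c_)$rmse
  expect_lte(r_ac, r_ab + r_bc + 1e-12)
})

test_that("method correlation matrix is symmetric with unit diagonal", {
  tabs <- list(m1 = random_prop_tbl(6, c("A", "B"), seed = 40),
               m2 = random_prop_tbl(6, c("A", "B"), seed = 41),
               m3 = random_prop_tbl(6, c("A", "B"), seed = 42))
  mat <- method_correlation_matrix(tabs)
  expect_equal(mat, base::t(mat))
  expect_equal(unname(diag(mat)), rep(1, 3))

  # constructed anticorrelation on 2 units x 2 types
  up <- proportion_tbl(tibble::tibble(unit_id = c("u1", "u2"),
                                      A = c(0.1, 0.4), B = c(0.9, 0.6)),
                       c("A", "B"))
  down <- proportion_tbl(tibble::tibble(unit_id = c("u1", "u2"),
                                        A = c(0.9, 0.6), B = c(0.1, 0.4)),
                         c("A", "B"))
  m2 <- method_correlation_matrix(list(up = up, down = down))
  expect_equal(m2["up", "down"], -1)
  bad <- random_prop_tbl(5, c("A", "B"), seed = 43)
  expect_error(method_correlation_matrix(list(up, bad)), "share units")
})

test_that("neuronal RSD follows sigma over mu within blocks", {
  types <- c("Excit", "Inhib", "Glia")
  tbl <- proportion_tbl(
    tibble::tibble(
      unit_id = paste0("s", 1:5),
      Excit = c(0.2, 0.2, 0.2, 0.1, 0.2),
      Inhib = c(0.2, 0.2, 0.2, 0.1, 0.2),
      Glia = c(0.6, 0.6, 0.6, 0.8, 0.6),
      block_id = c("b1", "b1", "b1", "b2", "b2")
    ), types)
  res <- neuronal_rsd(tbl)
  # block b1 constant at 0.4 -> RSD 0
  expect_equal(res$rsd[res$block == "b1"], 0)
  # block b2 fractions (0.2, 0.4): sd/mean with the n-1 divisor
  expect_equal(res$rsd[res$block == "b2"],
               sd(c(0.2, 0.4)) / 0.3, tolerance = 1e-12)
  expect_equal(res$rsd[res$block == "b2"], 0.4714, tolerance = 1e-4)

  # doubling neuronal fractions within a block leaves RSD unchanged
  tbl2 <- proportion_tbl(
    tibble::tibble(unit_id = c("a", "b"),
                   Excit = c(0.2, 0.4), Inhib = c(0.2, 0.4),
                   Glia = c(0.6, 0.2), block_id = "b1"),
    types)
  half <- proportion_tbl(
    tibble::tibble(unit_id = c("a", "b"),
                   Excit = c(0.1, 0.2), Inhib = c(0.1, 0.2),
                   Glia = c(0.8, 0.6), block_id = "b1"),
    types)
  expect_equal(neuronal_rsd(tbl2)$rsd, neuronal_rsd(half)$rsd)

  # singleton blocks skipped with a warning
  single <- proportion_tbl(
    tibble::tibble(unit_id = paste0("s", 1:3),
                   Excit = 0.3, Inhib = 0.1, Glia = 0.6,
                   block_id = c("b1", "b1", "lonely")),
    types)
  expect_warning(r2 <- neuronal_rsd(single), "lonely")
  expect_identical(r2$block, "b1")
})

fisher_enumerate <- function(a, b, c_, d) {
  # brute force over all tables with the same margins
  m <- a + b; n_ <- c_ + d; k <- a + c_
  support <- max(0, k - n_):min(k, m)
  probs <- choose(m, support) * choose(n_, k - support) / choose(m + n_, k)
  sum(probs[support >= a])
}

test_that("one-sided Fisher p equals exhaustive enumeration", {
  res <- fisher_enrichment(paste0("g", 1:5), paste0("g", 1:5),
                           paste0("g", 1:10))
  expect_equal(res$a, 5)
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_identical(res$odds_ratio, Inf)

  withr::with_seed(8, {
    for (rep in 1:25) {
      n_univ <- sample(5:20, 1)
      univ <- paste0("g", seq_len(n_univ))
      mk <- sample(univ, sample(0:n_univ, 1))
      tg <- sample(univ, sample(0:n_univ, 1))
      res <- fisher_enrichment(mk, tg, univ)
      expect_equal(res$p_value,
                   fisher_enumerate(res$a, res$b, res$c, res$d),
                   tolerance = 1e-12)
      # cross-check against the standard exact test when defined
      tab <- matrix(c(res$a, res$b, res$c, res$d), nrow = 2, byrow = TRUE)
      expect_equal(res$p_value,
                   fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-12)
    }
  })

  # disjoint sets: overlap at its minimum, p = 1
  res0 <- fisher_enrichment(paste0("g", 1:3), paste0("g", 4:6),
                            paste0("g", 1:20))
  expect_equal(res0$p_value, 1)
  expect_error(fisher_enrichment("a", "b", character(0)), "empty universe")
})

test_that("enrichment_table covers every pair and adds BH FDR", {
  sets <- structure(
    tibble::tibble(cell_type = c("A", "A", "B"),
                   gene_id = c("g1", "g2", "g3"), set_rank = c(1, 2, 1)),
    class = c("marker_sets", class(tibble::tibble())))
  targets <- list(dq1 = c("g1", "g2", "g9"), dq2 = c("g5"))
  res <- enrichment_table(sets, targets, paste0("g", 1:12))
  expect_identical(nrow(res), 4L)
  expect_true(all(res$fdr >= res$p_value))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # hand step-up on an unsorted vector: p_(i) * m / i with cummin
  p <- c(0.9, 0.01, 0.04, 0.03, 0.002)
  o <- order(p, decreasing = TRUE)
  hand <- numeric(5)
  hand[o] <- pmin(1, cummin(p[o] * 5 / (5:1)))
  expect_equal(bh_adjust(p), hand)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output is monotone and dominates raw p-values", {
  withr::with_seed(77, {
    for (rep in 1:50) {
      p <- runif(sample(2:30, 1))
      adj <- bh_adjust(p)
      expect_true(all(adj >= p - 1e-12))
      s <- sort(p)
      expect_true(all(diff(bh_adjust(s)) >= -1e-12))
    }
  })
})
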