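test_that("spec validation rejects inconsistent planted structure", {
  expect_error(synthetic_spec(n_genes = 3, planted_correlates =
    data.frame(gene = c("A", "B", "C"), r = c(0.5, 0.4, 0.3))),
    "configuration error")
  expect_error(synthetic_spec(planted_correlates =
    data.frame(gene = c("A", "A"), r = c(0.5, 0.4))), "distinct")
  expect_error(synthetic_spec(planted_correlates =
    data.frame(gene = "A", r = 1.2)), "\\[-1, 1\\]")
  # a pivot that is a member of its own ratio pair also violates the
  # all-planted-symbols-distinct rule, which is checked first
  expect_error(synthetic_spec(
    planted_ratio_pairs = data.frame(a = "A", b = "B", shift = 1),
    planted_pivots = list(list(pivot = "A", pairs = 1L))),
    "distinct")
})

test_that("identical spec and seed give bit-identical cohorts and graphs", {
  spec <- small_spec(seed = 11L)
  m1 <- generate_cohort(spec, 1L)
  m2 <- generate_cohort(spec, 1L)
  expect_identical(m1$values, m2$values)
  e1 <- ppi_edges(generate_ppi(spec))
  e2 <- ppi_edges(generate_ppi(spec))
  expect_identical(e1, e2)
  # the two cohorts use different substreams
  expect_false(identical(generate_cohort(spec, 2L)$values[, 1:60], m1$values))
})

test_that("planted correlations are recovered on the log scale", {
  # degenerate r = 1: perfect linear dependence after offset-log recovery
  spec1 <- synthetic_spec(n_samples_per_cohort = c(50, 50), n_genes = 10,
                          anchor_id = "RUNX3",
                          planted_correlates = data.frame(gene = "COPY", r = 1),
                          seed = 3L)
  lm <- preprocess_cohort(generate_cohort(spec1, 1L),
                          preprocess_config(-1, "strictly_greater"))
  expect_equal(unname(cor(lm$values["COPY", ], lm$values["RUNX3", ])), 1,
               tolerance = 1e-12)

  # r = 0.7 at n = 1000 recovered within +/- 0.05 (empirical Pearson oracle)
  spec2 <- synthetic_spec(n_samples_per_cohort = c(1000, 100), n_genes = 20,
                          anchor_id = "RUNX3",
                          planted_correlates = data.frame(gene = "COR", r = 0.7),
                          seed = 5L)
  lm2 <- preprocess_cohort(generate_cohort(spec2, 1L),
                           preprocess_config(-1, "strictly_greater"))
  r_hat <- cor(lm2$values["COR", ], lm2$values["RUNX3", ])
  expect_lt(abs(r_hat - 0.7), 0.05)
})

test_that("planting error shrinks as the cohort grows", {
  rs <- c(0.75, 0.5, -0.55, 0.3)
  mad_at <- function(n) {
    spec <- synthetic_spec(n_samples_per_cohort = c(n, 10), n_genes = 30,
                           anchor_id = "RUNX3",
                           planted_correlates = data.frame(
                             gene = paste0("P", seq_along(rs)), r = rs),
                           seed = 21L)
    lm <- preprocess_cohort(generate_cohort(spec, 1L),
                            preprocess_config(-1, "strictly_greater"))
    est <- sapply(paste0("P", seq_along(rs)),
                  function(g) cor(lm$values[g, ], lm$values["RUNX3", ]))
    mean(abs(est - rs))
  }
  expect_lt(mad_at(1000), mad_at(100))
})

test_that("per-gene substreams isolate planted entities from background draws", {
  base <- synthetic_spec(n_samples_per_cohort = c(40, 40), n_genes = 30,
                         anchor_id = "RUNX3", seed = 9L)
  more <- synthetic_spec(n_samples_per_cohort = c(40, 40), n_genes = 30,
                         anchor_id = "RUNX3",
                         planted_correlates = data.frame(gene = "NEWCOR", r = 0.6),
                         seed = 9L)
  m_base <- generate_cohort(base, 1L)
  m_more <- generate_cohort(more, 1L)
  expect_identical(m_base$values["G0005", ], m_more$values["G0005", ])
  expect_identical(m_base$values["RUNX3", ], m_more$values["RUNX3", ])
})

test_that("planted PPI wiring is exact with zero background", {
  spec <- synthetic_spec(
    n_samples_per_cohort = c(20, 20), n_genes = 20, anchor_id = "RUNX3",
    planted_ratio_pairs = data.frame(a = c("A1", "A2", "A3"),
                                     b = c("B1", "B2", "B3"),
                                     shift = c(1, 1, 1)),
    planted_pivots = list(list(pivot = "PIV", pairs = 1:3)),
    background_edge_prob = 0, seed = 2L)
  g <- generate_ppi(spec)
  expect_equal(unname(ppi_degree(g)["PIV"]), 6)
  expect_equal(nrow(ppi_edges(g)), 6)
  expect_setequal(ppi_neighbors(g, "PIV"),
                  c("A1", "A2", "A3", "B1", "B2", "B3"))
})

test_that("background edge probability 1 yields the complete graph", {
  spec <- synthetic_spec(n_samples_per_cohort = c(10, 10), n_genes = 12,
                         anchor_id = "RUNX3", background_edge_prob = 1, seed = 4L)
  g <- generate_ppi(spec)
  expect_equal(nrow(ppi_edges(g)), 12 * 11 / 2)
})

test_that("truth tables enumerate exactly the planted entities", {
  empty <- synthetic_spec(n_samples_per_cohort = c(10, 10), n_genes = 5,
                          anchor_id = "RUNX3", seed = 1L)
  tr0 <- generate_truth(empty)
  expect_equal(nrow(tr0$correlates), 0)
  expect_equal(nrow(tr0$ratio_pairs), 0)
  expect_equal(nrow(tr0$pivots), 0)

  spec <- synthetic_spec(
    n_samples_per_cohort = c(10, 10), n_genes = 30, anchor_id = "RUNX3",
    planted_correlates = data.frame(gene = paste0("C", 1:5), r = rep(0.4, 5)),
    planted_ratio_pairs = data.frame(a = c("A1", "A2", "A3"),
                                     b = c("B1", "B2", "B3"), shift = rep(1, 3)),
    planted_pivots = list(list(pivot = "PIV", pairs = 1:2)),
    seed = 1L)
  tr <- generate_truth(spec)
  expect_equal(nrow(tr$correlates), 5)
  # pivot wired to both members of 2 pairs, degree 4 -> intermediary ratio 0.5
  expect_equal(tr$pivots$hits, 2)
  expect_equal(tr$pivots$degree, 4)
  expect_equal(tr$pivots$intermediary_ratio, 0.5)
})
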