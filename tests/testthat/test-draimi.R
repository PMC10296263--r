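decile_cfg <- function(genes = c("A", "B", "C", "D"), ...) {
  draimi_config(gene_set = genes, ...)
}

test_that("decile split sizes follow floor arithmetic with a minimum of 1", {
  mk <- function(n) {
    v <- named_matrix(matrix(seq_len(2 * n), 2, n), genes = c("ANC", "other"))
    log_em(v)
  }
  s20 <- split_deciles(mk(20), "ANC", decile_cfg())
  expect_length(s20$upper, 2); expect_length(s20$lower, 2)
  s10 <- suppressWarnings(split_deciles(mk(10), "ANC", decile_cfg()))
  expect_length(s10$upper, 1); expect_length(s10$lower, 1)
  expect_length(intersect(s20$upper, s20$lower), 0)
})

test_that("decile split selects the extreme anchor samples, ties by id", {
  v <- named_matrix(matrix(0, 2, 100), genes = c("ANC", "other"),
                    samples = sprintf("s%03d", 1:100))
  v["ANC", ] <- 1:100
  s <- split_deciles(log_em(v), "ANC", decile_cfg())
  expect_setequal(s$upper, sprintf("s%03d", 91:100))
  expect_setequal(s$lower, sprintf("s%03d", 1:10))

  # boundary ties resolved by sample-id lexicographic order
  v["ANC", ] <- rep(c(1, 2), each = 50)
  s2 <- split_deciles(log_em(v), "ANC", decile_cfg())
  expect_equal(s2$upper, sprintf("s%03d", 51:60))
  expect_equal(s2$lower, sprintf("s%03d", 1:10))
})

test_that("ratio statistics: zero difference, sign symmetry, planted pair wins", {
  # pair with identical upper/lower difference distributions -> t_abs = 0
  n <- 10
  v <- named_matrix(rbind(rep(1:5, 2), rep(2:6, 2), rnorm(n), rnorm(n)),
                    genes = c("A", "B", "C", "D"))
  m <- log_em(v)
  up <- colnames(v)[1:5]; lo <- colnames(v)[6:10]
  st <- ratio_stats(m, up, lo, decile_cfg(n_bootstrap = 10, per_bootstrap_k = 6, seed = 1))
  expect_equal(st$t_abs[st$a == "A" & st$b == "B"], 0)
  expect_true(all(st$a < st$b))  # canonical pair ordering

  # planted shift of 3 pooled SDs on exactly one pair, unit noise elsewhere
  set.seed(42)
  ng <- 30
  vals <- named_matrix(matrix(rnorm(4 * 2 * ng), 4, 2 * ng),
                       genes = c("A", "B", "C", "D"))
  upper <- colnames(vals)[1:ng]; lower <- colnames(vals)[(ng + 1):(2 * ng)]
  vals["A", upper] <- vals["A", upper] + 1.5
  vals["A", lower] <- vals["A", lower] - 1.5
  vals["B", upper] <- vals["B", upper] - 1.5
  vals["B", lower] <- vals["B", lower] + 1.5
  st2 <- ratio_stats(log_em(vals), upper, lower,
                     decile_cfg(n_bootstrap = 100, per_bootstrap_k = 1, seed = 5))
  expect_equal(st2$a[1], "A"); expect_equal(st2$b[1], "B")
  expect_equal(st2$final_rank[1], 1)
  expect_equal(st2$consistency[1], 1.0)
  # all six unordered pairs enumerated
  expect_equal(nrow(st2), 6)
})

test_that("ratio statistics are invariant to swapping the genes of a pair", {
  set.seed(7)
  v <- named_matrix(matrix(rnorm(40), 4, 10), genes = c("A", "B", "C", "D"))
  m <- log_em(v)
  up <- colnames(v)[1:5]; lo <- colnames(v)[6:10]
  st <- ratio_stats(m, up, lo, decile_cfg(n_bootstrap = 5, seed = 2))
  # relabel A <-> B: the (A,B) statistic must be unchanged
  v2 <- v[c("B", "A", "C", "D"), ]
  rownames(v2) <- c("A", "B", "C", "D")
  st2 <- ratio_stats(log_em(v2), up, lo, decile_cfg(n_bootstrap = 5, seed = 2))
  expect_equal(st2$t_abs[st2$a == "A" & st2$b == "B"],
               st$t_abs[st$a == "A" & st$b == "B"])
})

test_that("more bootstrap replicates cannot shake an always-top pair", {
  set.seed(9)
  ng <- 25
  vals <- named_matrix(matrix(rnorm(3 * 2 * ng, sd = 0.1), 3, 2 * ng),
                       genes = c("A", "B", "C"))
  upper <- colnames(vals)[1:ng]; lower <- colnames(vals)[(ng + 1):(2 * ng)]
  vals["A", upper] <- vals["A", upper] + 2.5
  vals["B", upper] <- vals["B", upper] - 2.5
  m <- log_em(vals)
  for (nb in c(10, 50)) {
    st <- ratio_stats(m, upper, lower,
                      decile_cfg(genes = c("A", "B", "C"), n_bootstrap = nb,
                                 per_bootstrap_k = 1, seed = 3))
    expect_equal(st$consistency[st$a == "A" & st$b == "B"], 1.0)
  }
})

test_that("select_top_ratios truncates by final rank", {
  st <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                   t_abs = c(3, 2, 1), consistency = c(1, 0.5, 0.2),
                   final_rank = 1:3)
  expect_equal(nrow(select_top_ratios(st, decile_cfg(top_k = 1000))), 3)
  top1 <- select_top_ratios(st, decile_cfg(top_k = 1))
  expect_equal(top1$a, "A"); expect_equal(top1$b, "B")
  expect_identical(select_top_ratios(st, decile_cfg(top_k = 2)),
                   select_top_ratios(st, decile_cfg(top_k = 2)))
})

test_that("pivot scoring counts interactions with both ratio members", {
  edges <- data.frame(from = c("P", "P", "P", "X"),
                      to = c("A", "B", "C", "D"), score = 900)
  g <- ppi_graph(edges)
  top <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "D"),
                    stringsAsFactors = FALSE)
  sc <- score_pivots(top, g)
  p_row <- sc[sc$gene == "P", ]
  expect_equal(p_row$hits, 2)        # (A,B) and (A,C); (B,D) lacks D
  expect_equal(p_row$degree, 3)
  expect_equal(p_row$intermediary_ratio, 2 / 3)
  # zero-hit nodes retained with score 0
  expect_true(all(c("X", "D") %in% sc$gene))
  expect_equal(sc$intermediary_ratio[sc$gene == "X"], 0)

  empty <- score_pivots(top[0, ], g)
  expect_true(all(empty$intermediary_ratio == 0))
})

test_that("pivot scores equal the brute-force oracle on random toys", {
  for (seed in 1:40) {
    toy <- random_toy_instance(1000 + seed)
    if (!nrow(toy$edges)) next
    g <- ppi_graph(toy$edges, nodes = toy$nodes)
    got <- score_pivots(toy$top, g)
    want <- brute_force_pivots(toy$top, toy$edges, toy$nodes)
    expect_equal(got$gene, want$gene)
    expect_equal(got$hits, want$hits)
    expect_equal(got$degree, want$degree)
    expect_equal(got$intermediary_ratio, want$intermediary_ratio)
    expect_true(all(got$intermediary_ratio >= 0))
    expect_true(all(got$hits <= nrow(toy$top)))
  }
})

test_that("gene relabeling permutes pivot scores identically", {
  toy <- random_toy_instance(77)
  g <- ppi_graph(toy$edges, nodes = toy$nodes)
  base <- score_pivots(toy$top, g)
  perm <- setNames(sprintf("M%02d", rev(seq_along(toy$nodes))), toy$nodes)
  edges2 <- data.frame(from = unname(perm[toy$edges$from]),
                       to = unname(perm[toy$edges$to]), score = toy$edges$score)
  top2 <- data.frame(a = unname(perm[toy$top$a]), b = unname(perm[toy$top$b]))
  # canonicalize a < b after relabeling
  swap <- top2$a > top2$b
  tmp <- top2$a[swap]; top2$a[swap] <- top2$b[swap]; top2$b[swap] <- tmp
  relabeled <- score_pivots(top2, ppi_graph(edges2, nodes = unname(perm)))
  m <- match(unname(perm[base$gene]), relabeled$gene)
  expect_equal(relabeled$hits[m], base$hits)
  expect_equal(relabeled$intermediary_ratio[m], base$intermediary_ratio)
})

test_that("cross-cohort pivot merge joins and reports like the ranked table", {
  a <- data.frame(gene = c("NGF", "RAP1B", "MET", "ONLYA"),
                  intermediary_ratio = c(0.24, 0.28, 0.17, 0.9),
                  hits = c(6, 7, 4, 9), degree = c(25, 25, 24, 10))
  b <- data.frame(gene = c("NGF", "RAP1B", "MET"),
                  intermediary_ratio = c(0.23, 0.10, 0.11),
                  hits = c(5, 2, 3), degree = c(22, 20, 27))
  out <- draimi_cross_cohort(a, b)
  expect_false("ONLYA" %in% out$gene)   # inner join
  ngf <- out[out$gene == "NGF", ]
  expect_equal(ngf$score_a, 0.24); expect_equal(ngf$score_b, 0.23)
  expect_equal(out$mean_reported[out$gene == "RAP1B"], 0.19)
  expect_equal(out$mean_reported[out$gene == "MET"], 0.14)
  expect_warning(draimi_cross_cohort(a, data.frame(gene = "Z", intermediary_ratio = 1)),
                 "no pivot genes shared")
})

test_that("the per-cohort DRAIMI wrapper is deterministic end to end", {
  spec <- small_spec(seed = 23L, n = c(80, 80))
  lm <- preprocess_cohort(generate_cohort(spec, 1L), preprocess_config())
  g <- generate_ppi(spec)
  cfg <- draimi_config(c("RPA", "RPB", sprintf("G%04d", 1:8)),
                       n_bootstrap = 30, seed = 11L)
  r1 <- draimi_cohort(lm, "RUNX3", g, cfg)
  r2 <- draimi_cohort(lm, "RUNX3", g, cfg)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$pivots, r2$pivots)
  # planted pivot attains the truth-table score exactly
  truth <- generate_truth(spec)$pivots
  expect_equal(r1$pivots$intermediary_ratio[r1$pivots$gene == "PIVOT"],
               truth$intermediary_ratio)
  expect_equal(r1$pivots$gene[1], "PIVOT")
})
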