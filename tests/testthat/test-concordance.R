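test_that("ratio pair classification covers the condition table", {
  # both within the closed band
  expect_true(ratio_pair_match(1.2, 1.4, 1.5))
  # boundary ratios count as within
  expect_true(ratio_pair_match(1.5, 1 / 1.5, 1.5))
  # both up / both down beyond the cut-off
  expect_true(ratio_pair_match(2.5, 3.0, 1.5))
  expect_true(ratio_pair_match(0.3, 0.5, 1.5))
  # one within, one beyond: a mismatch under the strict rule
  expect_false(ratio_pair_match(1.2, 2.5, 1.5))
  # opposite directions
  expect_false(ratio_pair_match(2.5, 0.4, 1.5))
  # NOT monotone in the cut-off: matches at 1.5, mismatches at 2.0
  expect_true(ratio_pair_match(1.6, 3.0, 1.5))
  expect_false(ratio_pair_match(1.6, 3.0, 2.0))
  expect_error(ratio_pair_match(1, 1, 1), class = "ffpeqc_invalid_input")
})

test_that("replicate-ratio concordance reproduces the hand-worked cases", {
  # (10, 20, 10) vs (3, 9, 3): basis 1 pairs (2, 3) both up and (1, 1)
  # both within at c = 1.5 -> concordant on every basis.
  es_conc <- make_eset(matrix(c(10, 20, 10), 1), matrix(c(3, 9, 3), 1))
  r1 <- replicate_ratio_concordance(es_conc, "FF", "FFPE", cutoff = 1.5)
  expect_equal(r1$overall, 100)
  expect_true(r1$per_gene$concordant_all)

  # (10, 20, 10) vs (9, 3, 9): basis 1 pair (2, 1/3) points in opposite
  # directions -> discordant.
  es_disc <- make_eset(matrix(c(10, 20, 10), 1), matrix(c(9, 3, 9), 1))
  r2 <- replicate_ratio_concordance(es_disc, "FF", "FFPE", cutoff = 1.5)
  expect_equal(r2$overall, 0)
  expect_equal(r2$per_gene$n_bases_concordant, 0)

  # identical groups are 100% concordant at every cut-off
  m <- matrix(2^rnorm(15, 6), 5, 3)
  es_same <- make_eset(m, m)
  for (cc in c(1.3, 1.5, 1.7, 2.0)) {
    expect_equal(replicate_ratio_concordance(es_same, "FF", "FFPE",
                                             cutoff = cc)$overall, 100)
  }
})

test_that("concordance agrees exactly with the exhaustive enumeration oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n_genes <- sample(2:5, 1)
    a <- matrix(2^rnorm(n_genes * 3, 6, 1.5), n_genes, 3)
    b <- matrix(2^rnorm(n_genes * 3, 6, 1.5), n_genes, 3)
    es <- make_eset(a, b)
    for (cc in c(1.3, 2.0)) {
      got <- replicate_ratio_concordance(es, "FF", "FFPE", cutoff = cc)
      want <- oracle_replicate_concordance(a, b, cc)
      expect_equal(got$per_basis$rate, want$per_basis)
      expect_equal(got$overall, want$overall)
    }
  }
})

test_that("concordance is invariant to a positive scalar on one group", {
  set.seed(10)
  a <- matrix(2^rnorm(60, 6), 20, 3)
  b <- matrix(2^rnorm(60, 6), 20, 3)
  base <- replicate_ratio_concordance(make_eset(a, b), "FF", "FFPE", 1.5)
  scaled <- replicate_ratio_concordance(make_eset(a, b * 42), "FF", "FFPE", 1.5)
  expect_equal(base$overall, scaled$overall)
  expect_equal(base$per_gene, scaled$per_gene)
})

test_that("per-pair aggregation reports the pair-level match rate", {
  # one gene: basis 1 has pairs match+mismatch -> gene fails under
  # all_pairs but contributes 50% under per_pair
  es <- make_eset(matrix(c(10, 20, 10), 1), matrix(c(3, 9, 40), 1))
  all_pairs <- replicate_ratio_concordance(es, "FF", "FFPE", 1.5,
                                           aggregation = "all_pairs")
  per_pair <- replicate_ratio_concordance(es, "FF", "FFPE", 1.5,
                                          aggregation = "per_pair")
  expect_lte(all_pairs$overall, per_pair$overall)
})

test_that("unpaired or unequal designs are rejected", {
  a <- matrix(2^rnorm(9, 6), 3, 3)
  vals <- data.frame(gene_id = c("g1", "g2", "g3"), a, a[, 1:2])
  names(vals) <- c("gene_id", paste0("FF_", 1:3), paste0("PE_", 1:2))
  sheet <- data.frame(sample_id = names(vals)[-1],
                      group = c(rep("FF", 3), rep("FFPE", 2)),
                      replicate_index = c(1:3, 1:2))
  es <- expression_set(vals, sheet, scale = "linear")
  expect_error(replicate_ratio_concordance(es, "FF", "FFPE", 1.5),
               class = "ffpeqc_invalid_input")
})

test_that("group-mean cross-platform concordance follows the same rule", {
  # constant replicates make the group-mean ratios exact
  build <- function(case_mean, ctrl_mean) {
    make_eset(cbind(case_mean, case_mean), cbind(ctrl_mean, ctrl_mean),
              groups = c("MGD", "CO"))
  }
  # ratios per gene: (1.2, 2.5, 2.5) on platform 1; (1.4, 3.0, 0.4) on 2
  p1 <- build(c(1.2, 2.5, 2.5), c(1, 1, 1))
  p2 <- build(c(1.4, 3.0, 0.4), c(1, 1, 1))
  res <- group_mean_concordance(p1, p2, "MGD", "CO", cutoff = 1.5)
  expect_equal(res$per_gene$concordant, c(TRUE, TRUE, FALSE))
  expect_equal(res$overall, 100 * 2 / 3)
  expect_equal(res$overall,
               oracle_group_mean_concordance(res$per_gene$ratio_1,
                                             res$per_gene$ratio_2, 1.5))

  no_overlap <- make_eset(matrix(2, 1, 2), matrix(1, 1, 2),
                          groups = c("MGD", "CO"), gene_ids = "other")
  expect_error(group_mean_concordance(p1, no_overlap, "MGD", "CO", 1.5),
               class = "ffpeqc_invalid_input")
})

test_that("de_filter applies the fold-change and p-value gates", {
  # case == control: nothing selected
  m <- matrix(2^(rnorm(30, 6, 0.1)), 10, 3)
  same <- make_eset(m, m, groups = c("case", "ctrl"))
  expect_equal(sum(de_filter(same, "case", "ctrl")$selected), 0L)

  # clear 4-fold shift with tight replicates: selected, t matches t.test
  case <- 2^matrix(c(5.0, 5.1, 4.9), 1)
  ctrl <- 2^matrix(c(3.0, 3.1, 2.9), 1)
  es <- make_eset(case, ctrl, groups = c("case", "ctrl"))
  de <- de_filter(es, "case", "ctrl")
  expect_equal(de$fold_change, 4, tolerance = 1e-12)
  ref <- t.test(c(5.0, 5.1, 4.9), c(3.0, 3.1, 2.9), var.equal = TRUE)
  expect_equal(de$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(de$p.value, ref$p.value, tolerance = 1e-10)
  expect_true(de$selected)

  # 1.5-fold shift with tiny p still fails the fold-change gate
  case15 <- 2^matrix(c(5.000, 5.001, 4.999) + log2(1.5), 1)
  ctrl15 <- 2^matrix(c(5.000, 5.001, 4.999), 1)
  de15 <- de_filter(make_eset(case15, ctrl15, groups = c("case", "ctrl")),
                    "case", "ctrl")
  expect_lt(de15$p.value, 0.001)
  expect_false(de15$selected)

  # down-regulation encoded as a negative fold-change
  dn <- de_filter(make_eset(ctrl, case, groups = c("case", "ctrl")),
                  "case", "ctrl")
  expect_equal(dn$fold_change, -4, tolerance = 1e-12)

  # zero variance in both groups: flagged, not an error
  flat <- make_eset(matrix(4, 1, 3), matrix(8, 1, 3),
                    groups = c("case", "ctrl"))
  deg <- de_filter(flat, "case", "ctrl")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p.value))
  expect_false(deg$selected)
})

test_that("top-N rank comparison matches the recount oracle", {
  # identical vectors: everything in the top N at zero rank difference
  m <- setNames(1000 - seq_len(1000) + runif(1000, 0, 0.5),
                sprintf("g%04d", 1:1000))
  same <- top_n_rank_comparison(m, m, n = 100)
  expect_equal(same$per_gene$abs_diff, rep(0, 100))
  expect_equal(same$bins$n_genes[1], 100L)
  expect_equal(sum(same$bins$n_genes), 100L)

  # swapping two adjacent top genes moves each by exactly one rank
  m2 <- m
  o <- order(-m)
  m2[o[c(1, 2)]] <- m[o[c(2, 1)]]
  swap <- top_n_rank_comparison(m, m2, n = 10)
  expect_equal(sort(swap$per_gene$abs_diff), c(rep(0, 8), 1, 1))

  # random permutation vs brute-force recount, several bin layouts
  set.seed(20)
  mb <- setNames(sample(m), names(m))
  for (edges in list(400, c(100, 400))) {
    got <- top_n_rank_comparison(m, mb, n = 100, bin_edges = edges)
    expect_equal(got$bins$n_genes,
                 oracle_rank_bins(m, mb, 100, edges))
    expect_equal(sum(got$bins$n_genes), 100L)
  }

  expect_error(top_n_rank_comparison(m, mb, n = 2000),
               class = "ffpeqc_invalid_input")
})
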