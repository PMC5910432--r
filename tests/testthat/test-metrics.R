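test_that("cv_percent matches the sd/mean definition", {
  es <- make_single_group(matrix(c(5, 5, 5,
                                   1, 2, 3), 2, byrow = TRUE))
  cv <- cv_percent(es, "FF")
  expect_equal(cv$cv_percent, c(0, 50))

  # sample sd with n-1 denominator: sd = sqrt(32/7), mean = 5
  es8 <- make_single_group(matrix(c(2, 4, 4, 4, 5, 5, 7, 9), 1))
  expect_equal(round(cv_percent(es8, "FF")$cv_percent, 2), 42.76)
  expect_equal(cv_percent(es8, "FF")$cv_percent,
               100 * sqrt(32 / 7) / 5, tolerance = 1e-12)
})

test_that("cv_percent is invariant to positive rescaling and counts exclusions", {
  m <- matrix(2^rnorm(30, 5), 10, 3)
  es1 <- make_single_group(m)
  es2 <- make_single_group(m * 17.3)
  expect_equal(cv_percent(es1, "FF")$cv_percent,
               cv_percent(es2, "FF")$cv_percent, tolerance = 1e-12)

  # log2-scale CV: a gene with negative mean log2 signal is excluded, and
  # genes in = genes kept + genes excluded.
  mneg <- matrix(c(0.1, 0.2, 0.3, 4, 5, 6), 2, byrow = TRUE)
  esneg <- make_single_group(mneg)
  expect_message(cvl <- cv_percent(esneg, "FF", scale = "log2"),
                 "excluded 1 gene")
  expect_equal(nrow(cvl) + attr(cvl, "n_excluded"), 2L)

  expect_error(cv_percent(es1, "nope"), class = "ffpeqc_invalid_input")
  singleton <- make_single_group(matrix(1:2, 2, 1))
  expect_error(cv_percent(singleton, "FF"), class = "ffpeqc_invalid_input")
})

test_that("cv_compare reproduces the textbook pooled t and Cohen's d", {
  tab <- function(v) tibble::tibble(cv_percent = v)
  same <- cv_compare(tab(c(1, 2, 3, 4)), tab(c(1, 2, 3, 4)))
  expect_equal(same$statistic, 0)
  expect_equal(same$cohens_d, 0)

  set.seed(42)
  a <- abs(rnorm(1000, 20, 6))
  b <- abs(rnorm(1000, 24, 8))
  got <- cv_compare(tab(a), tab(b))
  # independent route: stats::t.test on the cube-root transformed values
  ref <- t.test(a^(1 / 3), b^(1 / 3), var.equal = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
  expect_equal(got$df, unname(ref$parameter))
  # Cohen's d by definition from the pooled sd
  sp <- sqrt((999 * var(a^(1 / 3)) + 999 * var(b^(1 / 3))) / 1998)
  expect_equal(got$cohens_d, (mean(a^(1 / 3)) - mean(b^(1 / 3))) / sp,
               tolerance = 1e-12)

  expect_error(cv_compare(tab(1), tab(c(1, 2))), class = "ffpeqc_invalid_input")
})

test_that("pearson_matrix matches the covariance/sd oracle and is well formed", {
  set.seed(1)
  m <- matrix(rnorm(400, 8, 2), 100, 4)
  es <- make_single_group(m, scale = "log2")
  res <- pearson_matrix(es)
  expect_equal(unname(res$r), unname(oracle_pearson(m)), tolerance = 1e-12)
  expect_equal(res$r, t(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 4))
  expect_true(all(res$pairs$r >= -1 & res$pairs$r <= 1))

  # duplicated samples correlate at exactly 1, inverted ones at -1
  a <- rnorm(50)
  dup <- make_single_group(cbind(a, a, -a), scale = "log2")
  rdup <- pearson_matrix(dup)$r
  expect_equal(rdup[1, 2], 1)
  expect_equal(rdup[1, 3], -1)

  const <- make_single_group(cbind(a, rep(2, 50)), scale = "log2")
  expect_error(pearson_matrix(const), class = "ffpeqc_undefined_metric")
})

test_that("intra/inter group averages summarise the right pairs", {
  set.seed(2)
  es <- make_eset(matrix(rnorm(30, 8), 10, 3), matrix(rnorm(30, 8), 10, 3),
                  scale = "log2")
  res <- pearson_matrix(es)
  expect_equal(sum(res$summary$n_pairs), choose(6, 2))
  intra <- res$summary[res$summary$type == "intra", ]
  expect_equal(intra$n_pairs, c(3L, 3L))        # 3 pairs per triplicate group
  inter <- res$summary[res$summary$type == "inter", ]
  expect_equal(inter$n_pairs, 9L)               # 3 x 3 cross pairs
  expect_equal(glance(res)$mean_intra_r,
               mean(res$pairs$r[res$pairs$type == "intra"]))
})

test_that("hcluster reproduces UPGMA heights and clusters planted structure", {
  set.seed(3)
  m <- matrix(rnorm(400, 8, 2), 100, 4)
  es <- make_single_group(m, scale = "log2")
  hc <- hcluster(es)
  d <- 1 - oracle_pearson(m)
  expect_equal(sort(hc$height), oracle_upgma_heights(as.dist(d)),
               tolerance = 1e-12)

  # duplicated samples merge first at height 0
  base <- rnorm(60)
  dup <- make_single_group(cbind(base, base, rnorm(60)), scale = "log2")
  hc2 <- hcluster(dup)
  expect_equal(hc2$height[1], 0)
  expect_setequal(-hc2$merge[1, ], 1:2)

  # planted blocks: within-block correlation high, between low
  sig <- rnorm(200)
  blk <- cbind(sig + rnorm(200, 0, 0.1), sig + rnorm(200, 0, 0.1),
               -sig + rnorm(200, 0, 0.1), -sig + rnorm(200, 0, 0.1))
  esb <- make_single_group(blk, scale = "log2")
  hcb <- hcluster(esb)
  top_split <- cutree(hcb, k = 2)
  expect_equal(length(unique(top_split[1:2])), 1L)
  expect_equal(length(unique(top_split[3:4])), 1L)
  expect_false(top_split[1] == top_split[3])
})

test_that("hcluster is invariant to sample input order", {
  set.seed(4)
  m <- matrix(rnorm(500, 8, 2), 100, 5)
  colnames(m) <- sprintf("s%d", 1:5)
  build <- function(cols) {
    vals <- data.frame(gene_id = sprintf("g%03d", 1:100), m[, cols])
    sheet <- data.frame(sample_id = colnames(m)[cols], group = "FF",
                        replicate_index = seq_len(5))
    expression_set(vals, sheet, scale = "log2")
  }
  h1 <- hcluster(build(1:5))
  h2 <- hcluster(build(c(3, 5, 1, 4, 2)))
  expect_equal(h1$height, h2$height)
  expect_identical(h1$labels, h2$labels)
  expect_identical(h1$merge, h2$merge)
})

test_that("three_prime_ratio computes last/first log10 ratios", {
  tab <- data.frame(gene_id = rep(c("a", "b"), each = 2),
                    position_index = c(1, 2, 1, 2),
                    signal = c(100, 100, 100, 1000))
  res <- three_prime_ratio(tab)
  expect_equal(res$log10_ratio, c(0, 1))

  single <- rbind(tab, data.frame(gene_id = "c", position_index = 1,
                                  signal = 5))
  expect_message(res2 <- three_prime_ratio(single), "excluded 1")
  expect_equal(attr(res2, "n_excluded"), 1L)
  expect_false("c" %in% res2$gene_id)

  expect_error(three_prime_ratio(transform(tab, signal = signal - 100)),
               class = "ffpeqc_invalid_input")
})

test_that("three_prime_ratio is antisymmetric under position reversal", {
  tab <- simulate_exon_table(n_genes = 50, probe_sets_per_gene = 5,
                             gradient_log10 = 0.3, noise_sd = 0.2, seed = 8)
  rev_tab <- tab |>
    dplyr::group_by(gene_id) |>
    dplyr::mutate(position_index = max(position_index) - position_index + 1L) |>
    dplyr::ungroup()
  fwd <- three_prime_ratio(tab)
  bwd <- three_prime_ratio(rev_tab)
  expect_equal(fwd$log10_ratio, -bwd$log10_ratio, tolerance = 1e-12)
})
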