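#' Classify a pair of fold-change ratios as concordant or not
#'
#' The elementary rule behind both concordance statistics. Two linear
#' ratios match at cut-off `c` if (i) both lie within the closed band
#' `[1/c, c]` (no relevant change in either dataset), (ii) both exceed `c`
#' (up-regulated in both), or (iii) both fall below `1/c` (down-regulated
#' in both). A pair with one ratio inside the band and the other beyond it
#' — or with opposite directions — is a mismatch.
#'
#' @param r1,r2 Positive linear ratios (vectorised).
#' @param cutoff Fold-change cut-off `c > 1`.
#' @return Logical vector: `TRUE` for a match.
#' @export
ratio_pair_match <- function(r1, r2, cutoff) {
  if (!is_number(cutoff) || cutoff <= 1) {
    stop_invalid("The fold-change cutoff must be > 1.")
  }
  within1 <- r1 >= 1 / cutoff & r1 <= cutoff
  within2 <- r2 >= 1 / cutoff & r2 <= cutoff
  (within1 & within2) | (r1 > cutoff & r2 > cutoff) | (r1 < 1 / cutoff & r2 < 1 / cutoff)
}

# Linear replicate matrix of one group, columns ordered by replicate index.
linear_group_matrix <- function(x, group, min_n = 2L) {
  cols <- group_columns(x, group, min_n = min_n)
  m <- expr_matrix(x, scale = "linear")[, cols, drop = FALSE]
  if (any(m <= 0)) stop_invalid("Linear signals must be strictly positive.")
  m
}

#' Concordance of replicate fold-changes between two paired groups
#'
#' Measures whether the relative expression structure among biological
#' replicates is preserved between two groups that cannot be compared on
#' absolute signal (e.g. fresh-frozen vs FFPE arrays). With each replicate
#' serving as basis once: for basis `b` and every other replicate `j`, the
#' within-group ratios `a_j / a_b` and `b_j / b_b` form a pair classified
#' by [ratio_pair_match()]. Under the default aggregation a gene counts as
#' concordant for a basis only if every `j`-pair matches; the per-basis
#' rate is the percentage of concordant genes, and the overall rate is the
#' mean over bases.
#'
#' @param x An [expression_set()] holding both groups.
#' @param group_a,group_b Group labels; equal replicate counts (n >= 2),
#'   paired by `replicate_index`.
#' @param cutoff Fold-change cut-off `c > 1`. Conventional values are 1.3,
#'   1.5, 1.7 and 2.0 (see [concordance_curve()]).
#' @param aggregation `"all_pairs"` (a gene is concordant for a basis iff
#'   all its ratio pairs match) or `"per_pair"` (rate over individual
#'   ratio pairs; offered because the combination of a basis's pairs into
#'   one gene call is a convention).
#' @return Object of class `concordance_result`: `per_basis` rates (%),
#'   `overall` rate, `per_gene` (n bases on which the gene was concordant),
#'   plus the cut-off and dimensions.
#' @examples
#' sim <- simulate_expression_pair(sim_params(n_genes = 200, seed = 3))
#' replicate_ratio_concordance(sim$expr, "FF", "FFPE", cutoff = 2)
#' @export
replicate_ratio_concordance <- function(x, group_a, group_b, cutoff = 2,
                                        aggregation = c("all_pairs", "per_pair")) {
  aggregation <- match.arg(aggregation)
  a <- linear_group_matrix(x, group_a)
  b <- linear_group_matrix(x, group_b)
  if (ncol(a) != ncol(b)) {
    stop_invalid(sprintf("Unequal replicate counts: %s has %d, %s has %d.",
                         group_a, ncol(a), group_b, ncol(b)))
  }
  ra_idx <- sort(sample_info(x)$replicate_index[sample_info(x)$group == group_a])
  rb_idx <- sort(sample_info(x)$replicate_index[sample_info(x)$group == group_b])
  if (!identical(ra_idx, rb_idx)) {
    stop_invalid("Replicate indices of the two groups do not pair up.")
  }

  n <- ncol(a)
  n_genes <- nrow(a)
  conc <- matrix(NA, n_genes, n)          # gene x basis concordance
  pair_rates <- numeric(n)

  for (basis in seq_len(n)) {
    others <- setdiff(seq_len(n), basis)
    match_mat <- vapply(others, function(j) {
      ratio_pair_match(a[, j] / a[, basis], b[, j] / b[, basis], cutoff)
    }, logical(n_genes))
    match_mat <- matrix(match_mat, nrow = n_genes)
    conc[, basis] <- rowSums(match_mat) == length(others)
    pair_rates[basis] <- 100 * mean(match_mat)
  }

  basis_rates <- if (aggregation == "all_pairs") {
    100 * colMeans(conc)
  } else {
    pair_rates
  }

  structure(
    list(
      per_basis = tibble(basis = seq_len(n), rate = basis_rates),
      overall = mean(basis_rates),
      per_gene = tibble(gene_id = rownames(a),
                        n_bases_concordant = rowSums(conc),
                        concordant_all = rowSums(conc) == n),
      cutoff = cutoff, aggregation = aggregation,
      groups = c(group_a, group_b), n_genes = n_genes, n_replicates = n,
      kind = "replicate_ratio"
    ),
    class = "concordance_result"
  )
}

#' Concordance of group-mean fold-changes across two platforms
#'
#' Cross-platform variant of the concordance statistic: per gene, the
#' ratio of case-group mean to control-group mean is formed in each
#' dataset and the two ratios are classified by [ratio_pair_match()]. The
#' gene universes are intersected first.
#'
#' @param x1,x2 Two [expression_set()] objects (e.g. microarray and
#'   RNA-seq) sharing gene identifiers.
#' @param case_group,control_group Group labels present in both sets.
#' @param cutoff Fold-change cut-off `c > 1`.
#' @return A `concordance_result`; `per_gene` carries both ratios and the
#'   match flag, `overall` the percentage of concordant shared genes.
#' @export
group_mean_concordance <- function(x1, x2, case_group, control_group, cutoff = 2) {
  shared <- intersect(gene_ids(x1), gene_ids(x2))
  if (length(shared) == 0L) {
    stop_invalid("The two datasets share no gene identifiers.")
  }
  ratio_of <- function(x) {
    case <- group_means(x, case_group, scale = "linear")
    ctrl <- group_means(x, control_group, scale = "linear")
    unname(case[shared] / ctrl[shared])
  }
  r1 <- ratio_of(x1)
  r2 <- ratio_of(x2)
  ok <- ratio_pair_match(r1, r2, cutoff)

  structure(
    list(
      per_basis = tibble(basis = 1L, rate = 100 * mean(ok)),
      overall = 100 * mean(ok),
      per_gene = tibble(gene_id = shared, ratio_1 = r1, ratio_2 = r2,
                        concordant = ok),
      cutoff = cutoff, aggregation = "group_mean",
      groups = c(case_group, control_group),
      n_genes = length(shared), n_replicates = NA_integer_,
      kind = "group_mean"
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %s, cutoff %.2f: %.1f%% of %d genes\n",
              x$kind, x$cutoff, x$overall, x$n_genes))
  invisible(x)
}

#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) {
  x$per_basis |> mutate(cutoff = x$cutoff, kind = x$kind)
}

#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  tibble(kind = x$kind, cutoff = x$cutoff, aggregation = x$aggregation,
         overall_rate = x$overall, n_genes = x$n_genes,
         n_replicates = x$n_replicates)
}

#' Concordance rates over a set of fold-change cut-offs
#'
#' Convenience wrapper evaluating [replicate_ratio_concordance()] (or
#' [group_mean_concordance()] when `x2` is supplied) at several cut-offs.
#'
#' @inheritParams replicate_ratio_concordance
#' @param cutoffs Numeric vector of cut-offs (default the conventional
#'   1.3, 1.5, 1.7, 2.0).
#' @param x2,case_group,control_group When `x2` is given, the group-mean
#'   cross-platform statistic is computed instead.
#' @return Tibble: `cutoff`, `rate` (%).
#' @export
concordance_curve <- function(x, group_a, group_b,
                              cutoffs = c(1.3, 1.5, 1.7, 2.0),
                              aggregation = c("all_pairs", "per_pair"),
                              x2 = NULL, case_group = NULL, control_group = NULL) {
  aggregation <- match.arg(aggregation)
  rates <- purrr::map_dbl(cutoffs, function(cc) {
    if (is.null(x2)) {
      replicate_ratio_concordance(x, group_a, group_b, cutoff = cc,
                                  aggregation = aggregation)$overall
    } else {
      group_mean_concordance(x, x2, case_group, control_group, cutoff = cc)$overall
    }
  })
  tibble(cutoff = cutoffs, rate = rates)
}

#' Filter differentially expressed genes by fold-change and t-test
#'
#' The conventional pre-filter feeding pathway over-representation
#' analysis: per gene, an unpaired two-tailed two-sample t-test on log2
#' signals between a case and a control group, together with the linear
#' fold-change `2^(mean case - mean control)` reported as a signed value
#' (negative encodes down-regulation as -1/ratio). A gene is selected when
#' `|signed FC| >= fc_cutoff` and `p <= alpha`. No multiple-testing
#' correction is applied; the filter is a screening rule, not an
#' inferential claim.
#'
#' @param x An [expression_set()].
#' @param case_group,control_group Group labels, each with >= 2 replicates.
#' @param fc_cutoff Linear fold-change gate (default 2).
#' @param alpha P-value gate (default 0.05).
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return Tibble of class `de_result`, ordered by p-value: `gene_id`,
#'   `log2_fc`, `fold_change` (signed), `statistic`, `df`, `p.value`,
#'   `selected`, `degenerate` (no within-group variance in either group).
#' @export
de_filter <- function(x, case_group, control_group, fc_cutoff = 2,
                      alpha = 0.05, var_equal = TRUE) {
  mc <- log2(linear_group_matrix(x, case_group))
  mk <- log2(linear_group_matrix(x, control_group))
  n1 <- ncol(mc); n2 <- ncol(mk)

  m1 <- rowMeans(mc); m2 <- rowMeans(mk)
  v1 <- rowSums((mc - m1)^2) / (n1 - 1)
  v2 <- rowSums((mk - m2)^2) / (n2 - 1)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }

  degenerate <- se == 0
  t_stat <- ifelse(degenerate, NA_real_, (m1 - m2) / se)
  p <- ifelse(degenerate, NA_real_, 2 * pt(-abs(t_stat), df))

  log2_fc <- m1 - m2
  ratio <- 2^log2_fc
  signed_fc <- ifelse(ratio >= 1, ratio, -1 / ratio)

  out <- tibble(
    gene_id = rownames(mc),
    log2_fc = unname(log2_fc),
    fold_change = unname(signed_fc),
    statistic = unname(t_stat),
    df = unname(df),
    p.value = unname(p),
    selected = !is.na(p) & abs(signed_fc) >= fc_cutoff & p <= alpha,
    degenerate = degenerate
  ) |>
    arrange(.data$p.value)

  structure(out, fc_cutoff = fc_cutoff, alpha = alpha,
            class = c("de_result", "tbl_df", "tbl", "data.frame"))
}

#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = nrow(x), n_selected = sum(x$selected),
         n_degenerate = sum(x$degenerate),
         fc_cutoff = attr(x, "fc_cutoff"), alpha = attr(x, "alpha"))
}

#' Write a selected gene list for external pathway analysis
#'
#' One gene id per line, the format accepted by web-based
#' over-representation services.
#'
#' @param de A [de_filter()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(de, path) {
  writeLines(de$gene_id[de$selected], path)
  invisible(path)
}
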