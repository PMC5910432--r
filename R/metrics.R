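#' Per-gene coefficient of variation within one group
#'
#' The %CV — 100 times the sample standard deviation over the mean across a
#' group's replicates — is the standard intra-platform reproducibility
#' measure for expression data. It is computed on linear-scale signals by
#' default (log2 input is back-transformed first), because sd/mean of
#' log-scale values is not the conventional quantity; a `scale = "log2"`
#' option is provided for comparison. Genes with non-finite values or
#' non-positive group mean are excluded and counted.
#'
#' @param x An [expression_set()].
#' @param group Group label (>= 2 replicates required).
#' @param scale Scale on which sd/mean is formed.
#' @return Tibble of class `gene_variation` with columns `gene_id`,
#'   `cv_percent`; attributes `group`, `scale`, `n_excluded`.
#' @examples
#' vals <- data.frame(gene_id = "g1", s1 = 1, s2 = 2, s3 = 3)
#' sheet <- data.frame(sample_id = c("s1", "s2", "s3"), group = "FF")
#' cv_percent(expression_set(vals, sheet, scale = "linear"), "FF")
#' @export
cv_percent <- function(x, group, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  cols <- group_columns(x, group, min_n = 2L)
  m <- expr_matrix(x, scale = scale)[, cols, drop = FALSE]

  ok_finite <- apply(is.finite(m), 1L, all)
  mu <- rowMeans(m)
  ok <- ok_finite & mu > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0L) {
    inform(sprintf("cv_percent: excluded %d gene(s) with non-finite values or non-positive mean in group '%s'.",
                   n_excluded, group))
  }

  sub <- m[ok, , drop = FALSE]
  k <- ncol(sub)
  sdv <- sqrt(rowSums((sub - rowMeans(sub))^2) / (k - 1))

  structure(
    tibble(gene_id = rownames(sub),
           cv_percent = unname(100 * sdv / rowMeans(sub))),
    group = group, scale = scale, n_excluded = n_excluded,
    class = c("gene_variation", "tbl_df", "tbl", "data.frame")
  )
}

#' @method glance gene_variation
#' @export
glance.gene_variation <- function(x, ...) {
  tibble(
    group = attr(x, "group"),
    n_genes = nrow(x),
    n_excluded = attr(x, "n_excluded"),
    median_cv = median(x$cv_percent),
    q1_cv = unname(quantile(x$cv_percent, 0.25)),
    q3_cv = unname(quantile(x$cv_percent, 0.75))
  )
}

#' Compare two %CV distributions with a cube-root-transformed t-test
#'
#' %CV distributions are right-skewed, so each set is cube-root transformed
#' before an unpaired two-tailed two-sample t-test (pooled variance). The
#' practical magnitude of a difference that is trivially "significant" at
#' transcriptome sample sizes is reported as Cohen's d, the difference of
#' transformed means over the pooled standard deviation.
#'
#' @param table_a,table_b [cv_percent()] outputs (or data frames with a
#'   `cv_percent` column), each with >= 2 values.
#' @return One-row tibble: `statistic` (t), `df`, `p.value`, `cohens_d`,
#'   `mean_a`, `mean_b` (transformed scale), `n_a`, `n_b`.
#' @export
cv_compare <- function(table_a, table_b) {
  a <- cv_values(table_a)
  b <- cv_values(table_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop_invalid("Each CV table needs at least 2 values.")
  }
  ta <- a^(1 / 3)
  tb <- b^(1 / 3)
  na <- length(ta); nb <- length(tb)
  va <- stats::var(ta); vb <- stats::var(tb)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (sp2 <= 0) {
    stop_undefined("Zero pooled variance; t statistic undefined.")
  }
  t_stat <- (mean(ta) - mean(tb)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  tibble(
    statistic = t_stat,
    df = df,
    p.value = 2 * pt(-abs(t_stat), df),
    cohens_d = (mean(ta) - mean(tb)) / sqrt(sp2),
    mean_a = mean(ta), mean_b = mean(tb),
    n_a = na, n_b = nb
  )
}

cv_values <- function(table) {
  if (is.data.frame(table)) {
    if (!"cv_percent" %in% names(table)) {
      stop_invalid("Expected a cv_percent column.")
    }
    return(table$cv_percent)
  }
  if (is.numeric(table)) return(table)
  stop_invalid("CV input must be a data frame or numeric vector.")
}

#' Pairwise Pearson correlation of samples
#'
#' All sample-sample Pearson coefficients on log2 signals over the shared
#' gene set, with within-group and between-group averages summarising the
#' matrix (each unordered sample pair counted once).
#'
#' @param x An [expression_set()] with >= 2 samples.
#' @return Object of class `cor_result`: list with `r` (correlation
#'   matrix), `pairs` (long tibble of unordered pairs with their group
#'   comparison), and `summary` (mean and sd of r per group comparison).
#' @export
pearson_matrix <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  if (nrow(x$samples) < 2L) stop_invalid("At least 2 samples are required.")
  m <- expr_matrix(x, scale = "log2")

  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    stop_undefined(sprintf("Constant sample vector(s): %s; correlation undefined.",
                           paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  r <- cor(m)

  info <- x$samples
  grp <- setNames(info$group, info$sample_id)
  ids <- colnames(m)
  pairs <- tidyr::expand_grid(sample_a = ids, sample_b = ids) |>
    filter(match(.data$sample_a, ids) < match(.data$sample_b, ids)) |>
    mutate(
      r = r[cbind(.data$sample_a, .data$sample_b)],
      group_a = unname(grp[.data$sample_a]),
      group_b = unname(grp[.data$sample_b]),
      type = if_else(.data$group_a == .data$group_b, "intra", "inter"),
      comparison = if_else(
        .data$group_a == .data$group_b, .data$group_a,
        paste(pmin(.data$group_a, .data$group_b),
              pmax(.data$group_a, .data$group_b), sep = " vs ")
      )
    )

  summary <- pairs |>
    group_by(.data$type, .data$comparison) |>
    summarise(mean_r = mean(.data$r),
              sd_r = if (n() > 1L) sd(.data$r) else NA_real_,
              n_pairs = n(), .groups = "drop") |>
    arrange(desc(.data$type), .data$comparison)

  structure(list(r = r, pairs = pairs, summary = summary),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("<cor_result> %d samples, %d pairs\n", ncol(x$r), nrow(x$pairs)))
  print(x$summary)
  invisible(x)
}

#' @method tidy cor_result
#' @export
tidy.cor_result <- function(x, ...) x$pairs

#' @method glance cor_result
#' @export
glance.cor_result <- function(x, ...) {
  tibble(
    n_samples = ncol(x$r),
    mean_intra_r = mean(x$pairs$r[x$pairs$type == "intra"]),
    mean_inter_r = mean(x$pairs$r[x$pairs$type == "inter"])
  )
}

#' Unsupervised hierarchical clustering of samples
#'
#' Average-linkage (UPGMA) agglomerative clustering of samples with
#' distance 1 - Pearson r on log2 signals. Samples are ordered
#' lexicographically before clustering so that distance ties resolve
#' deterministically regardless of input column order.
#'
#' @param x An [expression_set()] with >= 3 samples.
#' @return An [stats::hclust] object.
#' @seealso [write_newick()] to export the dendrogram.
#' @export
hcluster <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  if (nrow(x$samples) < 3L) stop_invalid("At least 3 samples are required.")
  m <- expr_matrix(x, scale = "log2")
  m <- m[, order(colnames(m)), drop = FALSE]
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    stop_undefined(sprintf("Constant sample vector(s): %s; correlation undefined.",
                           paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  d <- as.dist(1 - cor(m))
  hclust(d, method = "average")
}

#' Export a dendrogram in Newick format
#'
#' @param hc An [stats::hclust] object (e.g. from [hcluster()]).
#' @param path File path; the tree is written as a single Newick line.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Transcriptome-wide 3'/5' signal ratios
#'
#' Degraded RNA loses 5'-end representation, so the per-gene log10 ratio of
#' the most 3'-located probe-set signal to the most 5'-located one
#' quantifies positional bias: positive values mean 3' excess. Genes with
#' a single position are excluded (and counted), not an error; only genes
#' with at least two positions carry a ratio.
#'
#' @param table Exon-level signal table: columns `gene_id`,
#'   `position_index` (1 = most 5' position, increasing in transcription
#'   direction), `signal` (> 0, linear scale).
#' @return Tibble of class `three_prime_tbl`: `gene_id`, `log10_ratio`,
#'   `n_positions`; attribute `n_excluded` counts single-position genes.
#' @examples
#' tab <- data.frame(gene_id = "g", position_index = 1:2, signal = c(100, 1000))
#' three_prime_ratio(tab)  # log10_ratio = 1
#' @export
three_prime_ratio <- function(table) {
  table <- as_tibble(table)
  need <- c("gene_id", "position_index", "signal")
  if (!all(need %in% names(table))) {
    stop_invalid("Exon table needs columns gene_id, position_index, signal.")
  }
  if (any(!is.finite(table$signal)) || any(table$signal <= 0)) {
    stop_invalid("Exon signals must be finite and > 0.")
  }

  per_gene <- table |>
    group_by(.data$gene_id) |>
    summarise(
      n_positions = n(),
      log10_ratio = log10(.data$signal[which.max(.data$position_index)] /
                          .data$signal[which.min(.data$position_index)]),
      .groups = "drop"
    )

  n_excluded <- sum(per_gene$n_positions < 2L)
  if (n_excluded > 0L) {
    inform(sprintf("three_prime_ratio: excluded %d single-position gene(s).",
                   n_excluded))
  }
  structure(
    per_gene |> filter(.data$n_positions >= 2L) |>
      select("gene_id", "log10_ratio", "n_positions"),
    n_excluded = n_excluded,
    class = c("three_prime_tbl", "tbl_df", "tbl", "data.frame")
  )
}

#' @method glance three_prime_tbl
#' @export
glance.three_prime_tbl <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_excluded = attr(x, "n_excluded"),
    median_log10_ratio = median(x$log10_ratio),
    q1_log10_ratio = unname(quantile(x$log10_ratio, 0.25)),
    q3_log10_ratio = unname(quantile(x$log10_ratio, 0.75))
  )
}
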