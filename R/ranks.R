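#' Compare expression ranks of the top-expressed genes in two datasets
#'
#' Genes are ranked by mean expression within each dataset (rank 1 = most
#' highly expressed; ties break lexicographically by gene id). For the top
#' `n` genes of dataset A, the rank each holds in dataset B and the
#' absolute rank difference are reported, and genes are binned: the
#' special category "found within the top n of B", then absolute rank
#' differences cut at `bin_edges`.
#'
#' @param means_a,means_b Named numeric vectors of per-gene mean
#'   expression (names = gene ids) over the same gene universe, e.g. from
#'   [group_means()].
#' @param n Number of top genes of A to follow (<= number of genes).
#' @param bin_edges Ascending positive cut points on the absolute rank
#'   difference for genes outside B's top n. The default single edge of
#'   400 yields the bins "|drank| <= 400" and "|drank| > 400".
#' @return Object of class `rank_comparison`: `per_gene` tibble
#'   (`gene_id`, `rank_a`, `rank_b`, `abs_diff`, `category`) and `bins`
#'   (category counts and percentages, summing to `n`).
#' @examples
#' m <- setNames(100:1, sprintf("g%02d", 1:100))
#' top_n_rank_comparison(m, m, n = 10)$bins
#' @export
top_n_rank_comparison <- function(means_a, means_b, n = 100, bin_edges = 400) {
  if (is.null(names(means_a)) || is.null(names(means_b))) {
    stop_invalid("means_a and means_b must be named by gene id.")
  }
  shared <- intersect(names(means_a), names(means_b))
  if (length(shared) == 0L) stop_invalid("No shared gene ids.")
  if (!is_count(n) || n < 1 || n > length(shared)) {
    stop_invalid("n must be a positive integer no larger than the gene universe.")
  }
  if (any(diff(bin_edges) <= 0) || any(bin_edges <= 0)) {
    stop_invalid("bin_edges must be positive and ascending.")
  }

  rank_of <- function(v) {
    ids <- names(v)
    ord <- order(-v[shared], shared)
    setNames(seq_along(shared), shared[ord])
  }
  rank_a <- rank_of(means_a)
  rank_b <- rank_of(means_b)

  top <- names(sort(rank_a))[seq_len(n)]
  top_rank_a <- unname(rank_a[top])
  top_rank_b <- unname(rank_b[top])
  per_gene <- tibble(
    gene_id = top,
    rank_a = top_rank_a,
    rank_b = top_rank_b,
    abs_diff = abs(top_rank_b - top_rank_a)
  )

  edges <- c(0, bin_edges, Inf)
  labels <- c(
    sprintf("in top %d of B", n),
    sprintf("|drank| <= %g", bin_edges),
    sprintf("|drank| > %g", bin_edges[length(bin_edges)])
  )
  per_gene$category <- ifelse(
    per_gene$rank_b <= n, labels[1],
    labels[-1][findInterval(per_gene$abs_diff, edges[-1], left.open = TRUE) + 1L]
  )
  per_gene$category <- factor(per_gene$category, levels = labels)

  bins <- per_gene |>
    count(.data$category, name = "n_genes", .drop = FALSE) |>
    mutate(percent = 100 * .data$n_genes / n)

  structure(
    list(per_gene = per_gene, bins = bins, n = n, bin_edges = bin_edges,
         n_universe = length(shared)),
    class = "rank_comparison"
  )
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("<rank_comparison> top %d of %d genes\n", x$n, x$n_universe))
  print(x$bins)
  invisible(x)
}

#' @method tidy rank_comparison
#' @export
tidy.rank_comparison <- function(x, ...) x$per_gene

#' @method glance rank_comparison
#' @export
glance.rank_comparison <- function(x, ...) {
  tibble(
    n = x$n, n_universe = x$n_universe,
    pct_in_top_n = x$bins$percent[1],
    median_abs_diff = median(x$per_gene$abs_diff)
  )
}
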