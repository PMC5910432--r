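#' qPCR quantification-cycle table
#'
#' Long-format replicate Cq values with a designated reference gene used
#' for delta-Cq normalisation.
#'
#' @param x Data frame with columns `gene_id`, `replicate`, `cq` (cq > 0).
#' @param reference Reference gene symbol; must appear in `gene_id`.
#' @return A tibble of class `cq_table`.
#' @export
cq_table <- function(x, reference) {
  x <- as_tibble(x)
  if (!all(c("gene_id", "cq") %in% names(x))) {
    stop_invalid("A Cq table needs columns gene_id and cq.")
  }
  if (!"replicate" %in% names(x)) {
    x <- x |> group_by(.data$gene_id) |> mutate(replicate = row_number()) |> ungroup()
  }
  if (any(!is.finite(x$cq)) || any(x$cq <= 0)) {
    stop_invalid("Cq values must be finite and > 0.")
  }
  if (!reference %in% x$gene_id) {
    stop_invalid(sprintf("Reference gene '%s' not found in the table.", reference))
  }
  structure(x, reference = reference,
            class = c("cq_table", "tbl_df", "tbl", "data.frame"))
}

#' @rdname cq_table
#' @param table A `cq_table`.
#' @return For `cq_reference()`, the reference gene symbol.
#' @export
cq_reference <- function(table) attr(table, "reference")

#' Per-gene geometric mean and spread of Cq values
#'
#' qPCR replicates are conventionally reported as the geometric mean of the
#' Cq values, `exp(mean(log(cq)))`, with the spread as the ordinary sample
#' standard deviation on the cycle scale. Single-replicate genes get
#' `sd = 0` and are flagged.
#'
#' @param table A [cq_table()] (or plain data frame with `gene_id`, `cq`).
#' @return Tibble: `gene_id`, `geo_mean_cq`, `sd_cq`, `n`, `single_replicate`.
#' @examples
#' tab <- cq_table(data.frame(gene_id = "g", replicate = 1:2, cq = c(4, 16)),
#'                 reference = "g")
#' cq_summary(tab)  # geometric mean 8
#' @export
cq_summary <- function(table) {
  if (!is.data.frame(table) || !all(c("gene_id", "cq") %in% names(table))) {
    stop_invalid("A Cq table needs columns gene_id and cq.")
  }
  if (any(!is.finite(table$cq)) || any(table$cq <= 0)) {
    stop_invalid("Cq values must be finite and > 0.")
  }
  as_tibble(table) |>
    group_by(.data$gene_id) |>
    summarise(
      geo_mean_cq = exp(mean(log(.data$cq))),
      sd_cq = if (n() > 1L) sd(.data$cq) else 0,
      n = n(),
      single_replicate = n() == 1L,
      .groups = "drop"
    )
}

#' Rank genes by abundance from reference-normalised delta-Cq
#'
#' Normalises each gene of interest against the table's reference gene,
#' `delta_cq = mean Cq(reference) - mean Cq(gene)`, so larger values mean
#' more abundant transcripts (fewer cycles to detection). Genes are sorted
#' by delta-Cq in decreasing order and the most abundant gene gets rank 1;
#' ties break lexicographically by gene id. The reference gene itself
#' (delta-Cq 0 by construction) is excluded from the ranking.
#'
#' @param table A [cq_table()].
#' @param reference Optional override of the table's reference gene.
#' @return Tibble: `gene_id`, `mean_cq`, `delta_cq`, `rank`.
#' @export
delta_cq_rank <- function(table, reference = NULL) {
  reference <- reference %||% cq_reference(table)
  if (is.null(reference) || !reference %in% table$gene_id) {
    stop_invalid("A valid reference gene is required for delta-Cq ranking.")
  }
  means <- as_tibble(table) |>
    group_by(.data$gene_id) |>
    summarise(mean_cq = mean(.data$cq), .groups = "drop")
  ref_cq <- means$mean_cq[means$gene_id == reference]

  means |>
    filter(.data$gene_id != reference) |>
    mutate(delta_cq = ref_cq - .data$mean_cq) |>
    arrange(desc(.data$delta_cq), .data$gene_id) |>
    mutate(rank = row_number())
}
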