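#' Bundle an expression table with its sample sheet
#'
#' An `expression_set` couples a genes-by-samples signal table with the
#' sample annotation needed by every downstream metric: the experimental
#' group of each array and, for paired designs, the replicate index that
#' links biological pairs across groups (e.g. fresh-frozen and FFPE
#' material cut from the same case). The signal scale is declared, never
#' guessed: fold-change style statistics convert to the linear scale,
#' correlation and clustering work on log2.
#'
#' @param values Data frame whose first column (named `gene_id`) holds unique
#'   gene identifiers; every other column is one sample's numeric signal.
#' @param samples Data frame with columns `sample_id`, `group` and
#'   optionally `replicate_index` (defaults to 1, 2, ... within each group,
#'   in the column order of `values`).
#' @param scale Either `"log2"` or `"linear"`. Linear signals must be
#'   strictly positive.
#'
#' @return An `expression_set` object.
#' @examples
#' vals <- data.frame(gene_id = c("g1", "g2"),
#'                    ff_1 = c(8, 5), ff_2 = c(8.1, 5.2),
#'                    pe_1 = c(7, 4), pe_2 = c(7.2, 4.1))
#' sheet <- data.frame(sample_id = c("ff_1", "ff_2", "pe_1", "pe_2"),
#'                     group = c("FF", "FF", "FFPE", "FFPE"))
#' es <- expression_set(vals, sheet, scale = "log2")
#' es
#' @export
expression_set <- function(values, samples, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as_tibble(values)
  samples <- as_tibble(samples)

  if (ncol(values) < 2L) {
    stop_invalid("`values` needs a gene_id column plus at least one sample column.")
  }
  names(values)[1L] <- "gene_id"
  values$gene_id <- as.character(values$gene_id)

  dup_genes <- unique(values$gene_id[duplicated(values$gene_id)])
  if (length(dup_genes) > 0L) {
    stop_invalid(sprintf("Duplicate gene ids: %s",
                         paste(head(dup_genes, 5L), collapse = ", ")))
  }

  sample_cols <- names(values)[-1L]
  not_num <- sample_cols[!vapply(values[sample_cols], is.numeric, logical(1))]
  if (length(not_num) > 0L) {
    stop_invalid(sprintf("Non-numeric sample columns: %s",
                         paste(not_num, collapse = ", ")))
  }

  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop_invalid("`samples` must have columns sample_id and group.")
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  if (anyDuplicated(samples$sample_id)) {
    stop_invalid("Duplicate sample ids in the sample sheet.")
  }

  missing_sheet <- setdiff(sample_cols, samples$sample_id)
  if (length(missing_sheet) > 0L) {
    stop_invalid(sprintf("Samples present in the matrix but absent from the sheet: %s",
                         paste(missing_sheet, collapse = ", ")))
  }
  samples <- samples[match(sample_cols, samples$sample_id), , drop = FALSE]

  if (!"replicate_index" %in% names(samples) || all(is.na(samples$replicate_index))) {
    samples$replicate_index <- stats::ave(
      seq_along(samples$group), samples$group, FUN = seq_along
    )
  }
  samples$replicate_index <- as.integer(samples$replicate_index)

  vmat <- as.matrix(values[sample_cols])
  if (anyNA(vmat) || any(!is.finite(vmat))) {
    stop_invalid("Expression values must be finite and non-missing.")
  }
  if (scale == "linear" && any(vmat <= 0)) {
    stop_invalid("Linear-scale signals must be strictly positive.")
  }

  structure(
    list(values = values, samples = samples, scale = scale),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  grp <- table(x$samples$group)
  cat(sprintf("<expression_set> %d genes x %d samples (%s scale)\n",
              nrow(x$values), nrow(x$samples), x$scale))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(grp), as.integer(grp)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) c(nrow(x$values), nrow(x$samples))

#' Extract the signal matrix of an expression set
#'
#' @param x An [expression_set()].
#' @param scale Target scale; signals are converted via `2^x` / `log2(x)`
#'   when the stored scale differs.
#' @return Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
expr_matrix <- function(x, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(inherits(x, "expression_set"))
  m <- as.matrix(x$values[-1L])
  rownames(m) <- x$values$gene_id
  if (x$scale == scale) return(m)
  if (scale == "linear") 2^m else log2(m)
}

#' Sample annotation of an expression set
#'
#' @param x An [expression_set()].
#' @return Tibble with `sample_id`, `group`, `replicate_index`, ordered as
#'   the matrix columns.
#' @export
sample_info <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  x$samples
}

#' @rdname sample_info
#' @return For `gene_ids()`, the character vector of gene identifiers.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  x$values$gene_id
}

# Columns of one group ordered by replicate index; errors name the group.
group_columns <- function(x, group, min_n = 1L) {
  info <- x$samples[x$samples$group == group, , drop = FALSE]
  if (nrow(info) == 0L) {
    stop_invalid(sprintf("Group '%s' is not present in the sample sheet.", group))
  }
  if (nrow(info) < min_n) {
    stop_invalid(sprintf("Group '%s' has %d sample(s); at least %d required.",
                         group, nrow(info), min_n))
  }
  info$sample_id[order(info$replicate_index)]
}

#' Per-gene group means of an expression set
#'
#' Convenience used by rank comparisons: the mean signal of each gene over
#' one group's replicates, on the requested scale.
#'
#' @inheritParams expr_matrix
#' @param group Group label from the sample sheet.
#' @return Named numeric vector (names = gene ids).
#' @export
group_means <- function(x, group, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  cols <- group_columns(x, group, min_n = 1L)
  m <- expr_matrix(x, scale = scale)[, cols, drop = FALSE]
  rowMeans(m)
}
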