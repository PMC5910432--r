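#' Read an expression matrix with its sample sheet
#'
#' The matrix is a TSV whose first column is `gene_id` and whose remaining
#' columns are samples. The sample sheet is a CSV with columns
#' `sample_id,group,replicate_index` preceded by a metadata comment line
#' declaring the signal scale (`# scale=log2` or `# scale=linear`); the
#' scale is declared, never inferred, because a silently misread scale
#' corrupts every downstream ratio.
#'
#' @param values_path Path to the expression TSV.
#' @param samples_path Path to the sample sheet CSV.
#' @return An [expression_set()].
#' @export
read_expression <- function(values_path, samples_path) {
  if (!file.exists(values_path)) {
    stop_invalid(sprintf("Expression file not found: %s", values_path))
  }
  if (!file.exists(samples_path)) {
    stop_invalid(sprintf("Sample sheet not found: %s", samples_path))
  }
  values <- readr::read_tsv(values_path, show_col_types = FALSE,
                            progress = FALSE)
  if (!is.character(values[[1]])) values[[1]] <- as.character(values[[1]])

  header <- readLines(samples_path, n = 5L)
  scale_line <- grep("^#\\s*scale\\s*=", header, value = TRUE)
  if (length(scale_line) == 0L) {
    stop_invalid(sprintf("%s: missing '# scale=log2|linear' metadata line.",
                         samples_path))
  }
  scale <- trimws(sub("^#\\s*scale\\s*=", "", scale_line[1]))
  if (!scale %in% c("log2", "linear")) {
    stop_invalid(sprintf("%s: scale must be 'log2' or 'linear', got '%s'.",
                         samples_path, scale))
  }
  samples <- readr::read_csv(samples_path, comment = "#",
                             show_col_types = FALSE, progress = FALSE)
  expression_set(values, samples, scale = scale)
}

#' Write an expression set to TSV + sample sheet CSV
#'
#' Inverse of [read_expression()]: round-trips content exactly for valid
#' sets.
#'
#' @param x An [expression_set()].
#' @param values_path,samples_path Output paths.
#' @return Invisibly, `c(values_path, samples_path)`.
#' @export
write_expression <- function(x, values_path, samples_path) {
  stopifnot(inherits(x, "expression_set"))
  readr::write_tsv(x$values, values_path, progress = FALSE)
  writeLines(sprintf("# scale=%s", x$scale), samples_path)
  readr::write_csv(x$samples, samples_path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(c(values_path, samples_path))
}

#' Read / write an electropherogram trace CSV
#'
#' Dialect: header `size_nt,fluorescence`, one row per grid point.
#'
#' @param path CSV path.
#' @param window Analysis window passed to [electropherogram()].
#' @return An [electropherogram()].
#' @export
read_trace <- function(path, window = c(25, Inf)) {
  if (!file.exists(path)) stop_invalid(sprintf("Trace file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("size_nt", "fluorescence") %in% names(df))) {
    stop_invalid(sprintf("%s: expected columns size_nt,fluorescence.", path))
  }
  electropherogram(df$size_nt, df$fluorescence, window = window)
}

#' @rdname read_trace
#' @param trace An [electropherogram()].
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[c("size_nt", "fluorescence")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read / write an exon-level signal table TSV
#'
#' Dialect: columns `gene_id`, `position_index`, `signal`; positions are
#' pre-oriented in 5' to 3' transcription order.
#'
#' @param path TSV path.
#' @return Tibble suitable for [three_prime_ratio()].
#' @export
read_exon_table <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("Exon table not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "position_index", "signal")
  if (!all(need %in% names(df))) {
    stop_invalid(sprintf("%s: expected columns %s.", path,
                         paste(need, collapse = ", ")))
  }
  df
}

#' @rdname read_exon_table
#' @param table Exon-level signal table.
#' @export
write_exon_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Read / write a qPCR Cq table CSV
#'
#' Dialect: columns `gene_id`, `replicate`, `cq`, preceded by a
#' `# reference=<gene>` metadata line naming the normalisation gene.
#'
#' @param path CSV path.
#' @return A [cq_table()].
#' @export
read_cq <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("Cq table not found: %s", path))
  header <- readLines(path, n = 5L)
  ref_line <- grep("^#\\s*reference\\s*=", header, value = TRUE)
  if (length(ref_line) == 0L) {
    stop_invalid(sprintf("%s: missing '# reference=<gene>' metadata line.", path))
  }
  reference <- trimws(sub("^#\\s*reference\\s*=", "", ref_line[1]))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  cq_table(df, reference = reference)
}

#' @rdname read_cq
#' @param table A [cq_table()].
#' @export
write_cq <- function(table, path) {
  writeLines(sprintf("# reference=%s", cq_reference(table)), path)
  readr::write_csv(as_tibble(table), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
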