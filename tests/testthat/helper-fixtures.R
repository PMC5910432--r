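# Build a two-group expression_set from replicate matrices (genes x n).
make_eset <- function(a, b, scale = "linear", groups = c("FF", "FFPE"),
                      gene_ids = sprintf("g%02d", seq_len(nrow(a)))) {
  n <- ncol(a)
  stopifnot(ncol(b) == n, nrow(b) == nrow(a))
  cn <- c(sprintf("%s_%d", groups[1], seq_len(n)),
          sprintf("%s_%d", groups[2], seq_len(n)))
  vals <- data.frame(gene_id = gene_ids, cbind(a, b))
  names(vals) <- c("gene_id", cn)
  sheet <- data.frame(sample_id = cn,
                      group = rep(groups, each = n),
                      replicate_index = rep(seq_len(n), 2L))
  expression_set(vals, sheet, scale = scale)
}

# Single-group set (for CV / correlation fixtures).
make_single_group <- function(m, scale = "linear", group = "FF",
                              gene_ids = sprintf("g%02d", seq_len(nrow(m)))) {
  cn <- sprintf("%s_%d", group, seq_len(ncol(m)))
  vals <- data.frame(gene_id = gene_ids, m)
  names(vals) <- c("gene_id", cn)
  sheet <- data.frame(sample_id = cn, group = group,
                      replicate_index = seq_len(ncol(m)))
  expression_set(vals, sheet, scale = scale)
}

# Random positive trace on a grid containing the 200 nt boundary.
random_trace <- function(seed) {
  set.seed(seed)
  size <- seq(25, 6000, by = 25)
  flu <- abs(stats::filter(runif(length(size)), rep(1 / 5, 5),
                           sides = 2, circular = TRUE)) + 0.01
  electropherogram(size, as.numeric(flu), window = c(25, Inf))
}
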