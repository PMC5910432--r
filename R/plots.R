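#' Plot an electropherogram
#'
#' Fluorescence against fragment size with the sub-200 nt region (the
#' fragments DV200 counts against quality) shaded.
#'
#' @param object An [electropherogram()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot electropherogram
#' @export
autoplot.electropherogram <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size_nt, y = .data$fluorescence)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = 200, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "firebrick") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fragment size [nt]", y = "fluorescence [FU]") +
    ggplot2::theme_minimal()
}

#' Plot %CV distributions
#'
#' @param object A [cv_percent()] table.
#' @param ... Further `gene_variation` tables to overlay.
#' @return A ggplot (box plot per group, whiskers at 1.5 IQR, outliers
#'   hidden as is conventional for transcriptome-sized sets).
#' @method autoplot gene_variation
#' @export
autoplot.gene_variation <- function(object, ...) {
  tables <- c(list(object), Filter(function(t) inherits(t, "gene_variation"),
                                   list(...)))
  df <- bind_rows(lapply(tables, function(t) {
    tibble(group = attr(t, "group"), cv_percent = t$cv_percent)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$cv_percent)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::coord_cartesian(
      ylim = c(0, stats::quantile(df$cv_percent, 0.95) * 1.2)) +
    ggplot2::labs(x = NULL, y = "%CV") +
    ggplot2::theme_minimal()
}

#' Plot a sample correlation matrix
#'
#' @param object A [pearson_matrix()] result.
#' @param ... Ignored.
#' @return A ggplot heat map of pairwise Pearson r.
#' @method autoplot cor_result
#' @export
autoplot.cor_result <- function(object, ...) {
  r <- object$r
  df <- as_tibble(as.data.frame.table(r, responseName = "r"))
  names(df)[1:2] <- c("sample_a", "sample_b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(min(df$r), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a concordance curve
#'
#' @param object A tibble from [concordance_curve()] (columns `cutoff`,
#'   `rate`) or a single `concordance_result`.
#' @param ... Ignored.
#' @return A ggplot of concordance rate against fold-change cut-off.
#' @export
plot_concordance_curve <- function(object, ...) {
  df <- if (inherits(object, "concordance_result")) {
    tibble(cutoff = object$cutoff, rate = object$overall)
  } else {
    as_tibble(object)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "fold-change cut-off", y = "concordance [%]") +
    ggplot2::theme_minimal()
}

#' Plot rank-comparison bins
#'
#' @param object A [top_n_rank_comparison()] result.
#' @param ... Ignored.
#' @return A ggplot bar chart of the category percentages.
#' @method autoplot rank_comparison
#' @export
autoplot.rank_comparison <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = sprintf("%% of top %d genes", object$n)) +
    ggplot2::theme_minimal()
}
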