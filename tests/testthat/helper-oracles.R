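# Independent brute-force oracles. Each reimplements the quantity under
# test from first principles (or via an unrelated library routine) so the
# package code path is never checked against itself.

# DV200 oracle: pracma's trapezoid rule on the trace, split at the
# boundary; the grid is required to contain the boundary point.
oracle_dv200 <- function(size, flu, boundary = 200) {
  stopifnot(boundary %in% size)
  total <- pracma::trapz(size, flu)
  above <- pracma::trapz(size[size >= boundary], flu[size >= boundary])
  100 * above / total
}

# UPGMA oracle: naive agglomeration with size-weighted average linkage,
# returning the sorted merge heights.
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA)
    bestv <- Inf
    for (i in active) {
      for (j in active) {
        if (i < j && d[i, j] < bestv) {
          bestv <- d[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestv)
    for (k in setdiff(active, c(i, j))) {
      v <- (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
      d[i, k] <- d[k, i] <- v
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Pearson oracle from the covariance/sd definition, one pair at a time.
oracle_pearson <- function(m) {
  p <- ncol(m)
  r <- diag(1, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- m[, i] - mean(m[, i])
      xj <- m[, j] - mean(m[, j])
      r[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  dimnames(r) <- list(colnames(m), colnames(m))
  r
}

# Replicate-ratio concordance oracle: explicit loops over genes, bases and
# partner replicates, with the three-way condition table written out.
oracle_replicate_concordance <- function(a, b, cutoff) {
  n <- ncol(a)
  rates <- numeric(n)
  for (basis in seq_len(n)) {
    conc <- logical(nrow(a))
    for (g in seq_len(nrow(a))) {
      ok_all <- TRUE
      for (j in setdiff(seq_len(n), basis)) {
        ra <- a[g, j] / a[g, basis]
        rb <- b[g, j] / b[g, basis]
        in_a <- ra >= 1 / cutoff && ra <= cutoff
        in_b <- rb >= 1 / cutoff && rb <= cutoff
        up_both <- ra > cutoff && rb > cutoff
        down_both <- ra < 1 / cutoff && rb < 1 / cutoff
        if (!((in_a && in_b) || up_both || down_both)) {
          ok_all <- FALSE
          break
        }
      }
      conc[g] <- ok_all
    }
    rates[basis] <- 100 * mean(conc)
  }
  list(per_basis = rates, overall = mean(rates))
}

oracle_group_mean_concordance <- function(r1, r2, cutoff) {
  ok <- logical(length(r1))
  for (g in seq_along(r1)) {
    in1 <- r1[g] >= 1 / cutoff && r1[g] <= cutoff
    in2 <- r2[g] >= 1 / cutoff && r2[g] <= cutoff
    ok[g] <- (in1 && in2) || (r1[g] > cutoff && r2[g] > cutoff) ||
      (r1[g] < 1 / cutoff && r2[g] < 1 / cutoff)
  }
  100 * mean(ok)
}

# Top-N rank bins oracle: rank by sorting a data frame, then recount the
# categories with an explicit ifelse chain.
oracle_rank_bins <- function(means_a, means_b, n, bin_edges) {
  df_a <- data.frame(id = names(means_a), v = unname(means_a))
  df_a <- df_a[order(-df_a$v, df_a$id), ]
  df_a$rank <- seq_len(nrow(df_a))
  df_b <- data.frame(id = names(means_b), v = unname(means_b))
  df_b <- df_b[order(-df_b$v, df_b$id), ]
  df_b$rank <- seq_len(nrow(df_b))

  top <- df_a$id[seq_len(n)]
  rank_a <- df_a$rank[match(top, df_a$id)]
  rank_b <- df_b$rank[match(top, df_b$id)]
  dd <- abs(rank_b - rank_a)

  counts <- integer(length(bin_edges) + 2L)
  for (g in seq_along(top)) {
    if (rank_b[g] <= n) {
      counts[1] <- counts[1] + 1L
    } else {
      placed <- FALSE
      for (e in seq_along(bin_edges)) {
        if (dd[g] <= bin_edges[e]) {
          counts[e + 1L] <- counts[e + 1L] + 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) counts[length(counts)] <- counts[length(counts)] + 1L
    }
  }
  counts
}
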