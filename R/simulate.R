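#' Simulation parameters for a paired two-group expression experiment
#'
#' Describes the paired design the generator emulates: two experimental
#' groups (fresh-frozen-like "A" and FFPE-like "B") measured on the same
#' biological cases, three replicates per group, log-normal expression
#' signals, group-specific replicate noise (the FFPE-like group noisier),
#' and a controllable fraction of genes whose injected replicate
#' fold-change structure points in opposite directions in the two groups
#' ("discordant" genes, which violate the concordance rule by
#' construction).
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per group (>= 2; the emulated design uses
#'   biological triplicates).
#' @param base_log2_mean,base_log2_sd Hyperparameters of the per-gene base
#'   expression level on the log2 scale.
#' @param noise_sd_a,noise_sd_b Replicate noise standard deviation (log2
#'   scale) of groups A and B. The defaults give the A group a median
#'   linear-scale %CV near 10% and the B group roughly double that,
#'   mirroring the fresh-frozen vs FFPE reproducibility gap.
#' @param frac_discordant Fraction of genes given opposite-direction
#'   replicate structure between the groups.
#' @param fc_injected Linear fold-change magnitude of the injected replicate
#'   structure (>= 1; 1 disables it).
#' @param group_offset_log2 Constant log2 offset added to group B, emulating
#'   the global signal shift between the two data entities. Does not affect
#'   within-group ratios.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(n_genes = 20000, n_replicates = 3,
                       base_log2_mean = 7, base_log2_sd = 2,
                       noise_sd_a = 0.15, noise_sd_b = 0.30,
                       frac_discordant = 0.05, fc_injected = 4,
                       group_offset_log2 = -0.5, seed = 1) {
  if (!is_count(n_genes) || n_genes < 1) {
    stop_invalid("n_genes must be a positive integer.")
  }
  if (!is_count(n_replicates) || n_replicates < 2) {
    stop_invalid("n_replicates must be an integer >= 2.")
  }
  if (!is_number(noise_sd_a) || noise_sd_a < 0 ||
      !is_number(noise_sd_b) || noise_sd_b < 0) {
    stop_invalid("Noise standard deviations must be >= 0.")
  }
  if (!is_number(frac_discordant) || frac_discordant < 0 || frac_discordant > 1) {
    stop_invalid("frac_discordant must lie in [0, 1].")
  }
  if (!is_number(fc_injected) || fc_injected < 1) {
    stop_invalid("fc_injected must be >= 1.")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
         base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
         noise_sd_a = noise_sd_a, noise_sd_b = noise_sd_b,
         frac_discordant = frac_discordant, fc_injected = fc_injected,
         group_offset_log2 = group_offset_log2, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Simulate a paired two-group expression experiment with known truth
#'
#' Generates log2 signals for two groups over an identical gene set, paired
#' by replicate index. Discordant genes receive an injected replicate
#' fold-change pattern (magnitude `fc_injected`, applied to even-numbered
#' replicates) whose direction is inverted in group B only, so their
#' replicate ratios disagree between the groups by construction; all other
#' genes differ only by replicate noise and the constant group offset.
#'
#' @param params A [sim_params()] object.
#' @param group_labels Length-2 character, the labels of groups A and B.
#' @return List with elements `expr` (an [expression_set()] on the log2
#'   scale holding both groups) and `truth` (tibble: `gene_id`,
#'   `base_log2`, `discordant`).
#' @examples
#' sim <- simulate_expression_pair(sim_params(n_genes = 100, seed = 42))
#' sim$expr
#' table(sim$truth$discordant)
#' @export
simulate_expression_pair <- function(params = sim_params(),
                                     group_labels = c("FF", "FFPE")) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    gene_id <- sprintf("gene_%05d", seq_len(p$n_genes))
    base <- rnorm(p$n_genes, p$base_log2_mean, p$base_log2_sd)

    n_disc <- round(p$frac_discordant * p$n_genes)
    disc <- rep(FALSE, p$n_genes)
    if (n_disc > 0) disc[sample.int(p$n_genes, n_disc)] <- TRUE

    # Injected replicate structure: even replicates carry the fold-change.
    effect <- log2(p$fc_injected) * as.numeric(seq_len(p$n_replicates) %% 2 == 0)

    a <- matrix(base, p$n_genes, p$n_replicates) +
      outer(as.numeric(disc), effect) +
      matrix(rnorm(p$n_genes * p$n_replicates, 0, p$noise_sd_a),
             p$n_genes, p$n_replicates)
    b <- matrix(base + p$group_offset_log2, p$n_genes, p$n_replicates) -
      outer(as.numeric(disc), effect) +
      matrix(rnorm(p$n_genes * p$n_replicates, 0, p$noise_sd_b),
             p$n_genes, p$n_replicates)

    la <- group_labels[1]; lb <- group_labels[2]
    cn <- c(sprintf("%s_%d", la, seq_len(p$n_replicates)),
            sprintf("%s_%d", lb, seq_len(p$n_replicates)))
    values <- as_tibble(cbind(a, b), .name_repair = ~cn)
    values <- tibble(gene_id = gene_id, values)

    samples <- tibble(
      sample_id = cn,
      group = rep(c(la, lb), each = p$n_replicates),
      replicate_index = rep(seq_len(p$n_replicates), 2L)
    )

    list(
      expr = expression_set(values, samples, scale = "log2"),
      truth = tibble(gene_id = gene_id, base_log2 = base, discordant = disc)
    )
  })
}

#' Parameters of a simulated electropherogram
#'
#' @param profile `"ffpe"` (fragment smear with a target DV200, optional
#'   high-molecular-weight cross-link peak) or `"ff"` (intact-RNA profile
#'   with ribosomal peaks riding on a low smear; its DV200 is an outcome,
#'   not a target).
#' @param target_dv200 Target DV200 in percent (FFPE profile only).
#' @param rrna_peaks Data frame (`size_nt`, `height`) of ribosomal peaks for
#'   the FF profile. Defaults to 18S at 1,900 nt and 28S at 4,700 nt, the
#'   standard eukaryotic ribosomal RNA lengths.
#' @param crosslink_peak Optional `c(center, height)` for an FFPE
#'   cross-link peak; residual cross-linked species typically appear around
#'   3,000-4,000 nt. `NULL` for none.
#' @param smear_shape,smear_scale Gamma shape/scale (nt) of the fragment
#'   length density; the defaults give a smooth unimodal smear with a long
#'   plateau.
#' @param size_grid Fragment-size grid (nt), strictly increasing. The
#'   default covers 25-6,000 nt in 5 nt steps and contains the 200 nt
#'   boundary exactly.
#' @param noise_sd Relative multiplicative noise on the trace.
#' @param seed Integer seed.
#' @return A `trace_params` list.
#' @export
trace_params <- function(profile = c("ffpe", "ff"), target_dv200 = 75,
                         rrna_peaks = data.frame(size_nt = c(1900, 4700),
                                                 height = c(1, 0.8)),
                         crosslink_peak = NULL,
                         smear_shape = 2, smear_scale = 300,
                         size_grid = seq(25, 6000, by = 5),
                         noise_sd = 0.02, seed = 1) {
  profile <- match.arg(profile)
  if (!is_number(target_dv200) || target_dv200 < 0 || target_dv200 > 100) {
    stop_invalid("target_dv200 must lie in [0, 100].")
  }
  if (any(size_grid <= 0) || any(diff(size_grid) <= 0)) {
    stop_invalid("size_grid must be positive and strictly increasing.")
  }
  if (!is.null(crosslink_peak) &&
      (length(crosslink_peak) != 2L || any(crosslink_peak <= 0))) {
    stop_invalid("crosslink_peak must be c(center, height), both positive, or NULL.")
  }
  structure(
    list(profile = profile, target_dv200 = target_dv200,
         rrna_peaks = as_tibble(rrna_peaks), crosslink_peak = crosslink_peak,
         smear_shape = smear_shape, smear_scale = smear_scale,
         size_grid = as.numeric(size_grid), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "trace_params"
  )
}

#' Simulate an electropherogram trace
#'
#' The FFPE profile is a two-component mixture of a gamma-shaped fragment
#' smear split at the 200 nt boundary: the below-200 and above-200
#' components (the optional cross-link Gaussian is folded into the latter)
#' are separately normalised by trapezoidal area and mixed with weights
#' `1 - d` and `d`, `d = target_dv200 / 100`. At `noise_sd = 0` the DV200
#' measured by [dv200()] therefore equals the target up to floating-point
#' error; multiplicative noise perturbs it by well under a percentage
#' point at the default level.
#'
#' The FF profile adds ribosomal Gaussian peaks (width 60 nt) on a broad
#' low smear; it is qualitative, with no controlled DV200.
#'
#' @param params A [trace_params()] object.
#' @return An [electropherogram()] on the parameter grid.
#' @examples
#' tr <- simulate_electropherogram(trace_params(target_dv200 = 60, seed = 7))
#' dv200(tr)
#' @export
simulate_electropherogram <- function(params = trace_params()) {
  stopifnot(inherits(params, "trace_params"))
  p <- params
  s <- p$size_grid

  withr::with_seed(p$seed, {
    smear <- dgamma(s, shape = p$smear_shape, scale = p$smear_scale)

    if (p$profile == "ffpe") {
      below <- ifelse(s < 200, smear, 0)
      above <- ifelse(s > 200, smear, 0)
      if (!is.null(p$crosslink_peak)) {
        above <- above + p$crosslink_peak[2] * max(smear) *
          dnorm(s, p$crosslink_peak[1], 120) / dnorm(0, 0, 120)
      }
      a_below <- trapezoid_area(s, below)
      a_above <- trapezoid_area(s, above)
      if (a_below <= 0 || a_above <= 0) {
        stop_invalid("size_grid must cover both sides of the 200 nt boundary.")
      }
      d <- p$target_dv200 / 100
      y <- (1 - d) * below / a_below + d * above / a_above
    } else {
      # Intact profile: low broad smear plus ribosomal peaks.
      broad <- dgamma(s, shape = 3, scale = 600)
      y <- 0.3 * broad / max(broad)
      for (i in seq_len(nrow(p$rrna_peaks))) {
        y <- y + p$rrna_peaks$height[i] *
          dnorm(s, p$rrna_peaks$size_nt[i], 60) / dnorm(0, 0, 60)
      }
    }

    if (p$noise_sd > 0) {
      y <- pmax(y * (1 + rnorm(length(y), 0, p$noise_sd)), 0)
    }
    # Scale to a Bioanalyzer-like fluorescence range.
    if (max(y) > 0) y <- 10 * y / max(y)

    electropherogram(s, y, window = c(min(s), max(s)))
  })
}

#' Simulate an exon-level signal table with a positional 3'/5' gradient
#'
#' Per gene, probe-set signals ordered in transcription direction whose
#' expected log10 ratio of the most 3'-located to the most 5'-located
#' position equals `gradient_log10`; degraded material yields positive
#' gradients because fragments retain their 3' ends preferentially under
#' oligo(dT)-primed chemistry.
#'
#' @param n_genes Number of genes.
#' @param probe_sets_per_gene Positions per gene (>= 2).
#' @param gradient_log10 Ground-truth expected log10(3'/5') signal ratio.
#' @param noise_sd Per-position noise sd on the log10 scale.
#' @param base_log10_mean,base_log10_sd Per-gene base signal level
#'   hyperparameters (log10 scale).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `position_index`, `signal` (linear scale).
#' @export
simulate_exon_table <- function(n_genes = 1000, probe_sets_per_gene = 4,
                                gradient_log10 = 0.1, noise_sd = 0.1,
                                base_log10_mean = 2, base_log10_sd = 0.5,
                                seed = 1) {
  if (!is_count(probe_sets_per_gene) || probe_sets_per_gene < 2) {
    stop_invalid("probe_sets_per_gene must be an integer >= 2.")
  }
  if (!is_count(n_genes) || n_genes < 1) {
    stop_invalid("n_genes must be a positive integer.")
  }
  k <- as.integer(probe_sets_per_gene)
  withr::with_seed(seed, {
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    base <- rnorm(n_genes, base_log10_mean, base_log10_sd)
    pos_frac <- (seq_len(k) - 1) / (k - 1)
    log10_signal <- outer(base, rep(1, k)) +
      outer(rep(1, n_genes), gradient_log10 * pos_frac) +
      matrix(rnorm(n_genes * k, 0, noise_sd), n_genes, k)
    tibble(
      gene_id = rep(gene_id, each = k),
      position_index = rep(seq_len(k), n_genes),
      signal = 10^as.numeric(t(log10_signal))
    )
  })
}

#' Simulate paired qPCR Cq tables for FF-like and FFPE-like templates
#'
#' FFPE-derived templates amplify later than fresh-frozen counterparts; the
#' FFPE table's expected Cq per gene is the FF expectation plus
#' `ffpe_offset_cycles` (several cycles in practice).
#'
#' @param genes Character vector of gene symbols.
#' @param n_replicates Technical replicates per gene (>= 1).
#' @param ffpe_offset_cycles Cq offset of the FFPE-like table (>= 0).
#' @param noise_sd Replicate noise sd in cycles.
#' @param cq_range Range of per-gene base Cq values (cycles).
#' @param reference Reference gene for downstream delta-Cq ranking; must be
#'   in `genes` (defaults to the first entry).
#' @param seed Integer seed.
#' @return List of two `cq_table` tibbles (`ff`, `ffpe`), columns `gene_id`,
#'   `replicate`, `cq`, with the reference gene stored as an attribute.
#' @export
simulate_cq_table <- function(genes = c("Gapdh", "Pgk1", "Actb", "Gfap",
                                        "Atrn", "Mbp", "Mag", "Cx3cr1"),
                              n_replicates = 3, ffpe_offset_cycles = 5,
                              noise_sd = 0.3, cq_range = c(18, 30),
                              reference = genes[1], seed = 1) {
  if (!is_count(n_replicates) || n_replicates < 1) {
    stop_invalid("n_replicates must be an integer >= 1.")
  }
  if (!is_number(ffpe_offset_cycles) || ffpe_offset_cycles < 0) {
    stop_invalid("ffpe_offset_cycles must be >= 0.")
  }
  if (!reference %in% genes) {
    stop_invalid("The reference gene must be among `genes`.")
  }
  n <- length(genes)
  withr::with_seed(seed, {
    base <- runif(n, cq_range[1], cq_range[2])
    make <- function(offset) {
      cq_table(tibble(
        gene_id = rep(genes, each = n_replicates),
        replicate = rep(seq_len(n_replicates), n),
        cq = rep(base + offset, each = n_replicates) +
          rnorm(n * n_replicates, 0, noise_sd)
      ), reference = reference)
    }
    list(ff = make(0), ffpe = make(ffpe_offset_cycles))
  })
}
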