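# Extract mean Ct for one gene in one condition; errors when absent.
mean_ct <- function(ct, gene, condition) {
  x <- ct$ct[ct$gene_id == gene & ct$condition == condition]
  if (length(x) == 0)
    stop("no Ct wells for gene '", gene, "' in condition '", condition, "'")
  mean(x)
}

#' Relative quantification by the comparative CT method
#'
#' \eqn{\Delta C_T} is the mean target Ct minus the mean reference Ct per
#' condition; \eqn{\Delta\Delta C_T} is the treatment \eqn{\Delta C_T}
#' minus the control \eqn{\Delta C_T}; the fold expression is
#' \eqn{E^{-\Delta\Delta C_T}} with amplification efficiency `E` (the
#' classic assumption is perfect doubling, `E = 2`).
#'
#' @param ct a Ct table: columns `gene_id`, `condition`, `replicate`, `ct`.
#' @param target_gene,reference_gene gene ids (the reference is the
#'   normalizer, e.g. `mdh`).
#' @param treatment,control condition labels.
#' @param efficiency amplification efficiency per cycle.
#' @return list with `fold`, `ddct`, `dct_treatment`, `dct_control`,
#'   `target_gene`, `reference_gene`.
#' @export
#' @examples
#' ct <- generate_ct_table(planted_ratio = 4, ct_noise_sd = 0)
#' ddct_fold(ct, "target")$fold  # 4
ddct_fold <- function(ct, target_gene, reference_gene = "mdh",
                      treatment = "treatment", control = "control",
                      efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must be > 1")
  dct_t <- mean_ct(ct, target_gene, treatment) -
    mean_ct(ct, reference_gene, treatment)
  dct_c <- mean_ct(ct, target_gene, control) -
    mean_ct(ct, reference_gene, control)
  ddct <- dct_t - dct_c
  list(fold = efficiency^(-ddct), ddct = ddct,
       dct_treatment = dct_t, dct_control = dct_c,
       target_gene = target_gene, reference_gene = reference_gene)
}

# All k-subsets of n wells as an index matrix (k rows per column).
all_splits <- function(n, k) utils::combn(n, k)

#' Permutation test for a qPCR expression ratio
#'
#' A randomization test of the null hypothesis that the expression ratio
#' is 1: condition labels are reallocated independently within the
#' target-gene wells and within the reference-gene wells (both pools are
#' exchangeable under the null), the \eqn{\Delta\Delta C_T} statistic is
#' recomputed for each reallocation, and the two-sided P-value is the
#' fraction of reallocations at least as extreme as the observed one.
#' When the number of distinct reallocations is within `n_permutations`
#' they are enumerated exhaustively (the observed allocation is included,
#' so p > 0); otherwise random reallocations are drawn and the +1
#' correction applied. This is a documented generic randomization test in
#' the spirit of ratio-randomization qPCR software, not a
#' re-implementation of any published tool.
#'
#' @inheritParams ddct_fold
#' @param n_permutations number of random reallocations (and the ceiling
#'   below which exhaustive enumeration is used).
#' @param seed integer seed for the sampled case.
#' @return list with `p_value`, `ddct_observed`, `n_used` (reallocations
#'   evaluated) and `exhaustive`.
#' @export
permutation_ratio_test <- function(ct, target_gene, reference_gene = "mdh",
                                   treatment = "treatment",
                                   control = "control",
                                   n_permutations = 2000, seed = 1L) {
  tw <- list(t = ct$ct[ct$gene_id == target_gene & ct$condition == treatment],
             c = ct$ct[ct$gene_id == target_gene & ct$condition == control])
  rw <- list(t = ct$ct[ct$gene_id == reference_gene & ct$condition == treatment],
             c = ct$ct[ct$gene_id == reference_gene & ct$condition == control])
  if (min(lengths(tw)) < 3 || min(lengths(rw)) < 3)
    stop("permutation test needs >= 3 replicates per condition per gene")

  tpool <- c(tw$t, tw$c); kt <- length(tw$t)
  rpool <- c(rw$t, rw$c); kr <- length(rw$t)
  stat <- function(tidx, ridx) {
    (mean(tpool[tidx]) - mean(tpool[-tidx])) -
      (mean(rpool[ridx]) - mean(rpool[-ridx]))
  }
  obs <- stat(seq_len(kt), seq_len(kr))
  eps <- 1e-12

  n_t <- choose(length(tpool), kt)
  n_r <- choose(length(rpool), kr)
  if (n_t * n_r <= n_permutations) {
    ts <- all_splits(length(tpool), kt)
    rs <- all_splits(length(rpool), kr)
    tdiff <- apply(ts, 2, function(i) mean(tpool[i]) - mean(tpool[-i]))
    rdiff <- apply(rs, 2, function(i) mean(rpool[i]) - mean(rpool[-i]))
    S <- outer(tdiff, rdiff, "-")
    p <- mean(abs(S) >= abs(obs) - eps)
    list(p_value = p, ddct_observed = obs,
         n_used = length(S), exhaustive = TRUE)
  } else {
    count <- with_local_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_permutations)) {
        s <- stat(sample(length(tpool), kt), sample(length(rpool), kr))
        if (abs(s) >= abs(obs) - eps) hits <- hits + 1L
      }
      hits
    })
    list(p_value = (1 + count) / (n_permutations + 1),
         ddct_observed = obs, n_used = n_permutations, exhaustive = FALSE)
  }
}
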