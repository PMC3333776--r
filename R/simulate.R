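#' Simulation configuration
#'
#' Collects all parameters of the synthetic-data generator: cohort size,
#' replication, the mixture of planted specificity categories, the
#' replicate noise on log2 ratios, the amplitude of the intensity-dependent
#' dye-bias curve, and the seed from which every random sub-stream is
#' derived.
#'
#' @param n_genes number of genes on the simulated array.
#' @param n_replicates biological replicates per contrast (>= 2, so that
#'   replicate-level P-values can be computed).
#' @param category_proportions named numeric vector of planted category
#'   fractions over `ALL`, `PEA_ONLY`, `ALFALFA_ONLY`, `SUGARBEET_ONLY`,
#'   `LEGUME`, `ALFALFA_SUGARBEET`, `PEA_SUGARBEET`, `DOWN_ALL`, `NONE`;
#'   must be non-negative and sum to 1.
#' @param noise_sd_log2 standard deviation (log2 units) of the i.i.d.
#'   Gaussian replicate noise added to every spot's log-ratio.
#' @param dye_bias_amplitude maximum absolute log2 bias of the smooth
#'   intensity-dependent dye-bias curve (see [dye_bias_curve()]).
#' @param baseline_intensity_range interval (log2 units) from which each
#'   spot's mean log2 intensity A is drawn.
#' @param none_fold_range interval from which planted folds are drawn for
#'   rhizospheres in which a gene is *not* elevated (and for all folds of
#'   `NONE` genes). The default is symmetric on the log2 scale so the
#'   unchanged bulk of each slide is centred on ratio 1, the standard
#'   assumption behind loess normalization. Set to `c(1, 1)` for an exact
#'   null cohort.
#' @param baseline_condition label of the common reference condition
#'   (free-living glucose-grown culture) used by indirect contrasts.
#' @param seed integer seed; every generator output is a deterministic
#'   function of the config including this seed.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 42)
#' truth <- generate_truth(cfg)
#' table(truth$category)
sim_config <- function(n_genes = 2000,
                       n_replicates = 4,
                       category_proportions = c(
                         ALL = 0.03, PEA_ONLY = 0.03, ALFALFA_ONLY = 0.02,
                         SUGARBEET_ONLY = 0.02, LEGUME = 0.02,
                         ALFALFA_SUGARBEET = 0.015, PEA_SUGARBEET = 0.015,
                         DOWN_ALL = 0.05, NONE = 0.80
                       ),
                       noise_sd_log2 = 0.25,
                       dye_bias_amplitude = 0.3,
                       baseline_intensity_range = c(6, 14),
                       none_fold_range = c(0.8, 1.25),
                       baseline_condition = "glucose",
                       seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("n_genes must be a positive count")
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L || n_replicates < 2)
    stop("n_replicates must be >= 2 for P-value computation")
  p <- category_proportions
  if (is.null(names(p)) || !all(names(p) %in% CATEGORIES))
    stop("category_proportions must be named with known categories")
  if (any(p < 0)) stop("category_proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("category_proportions must sum to 1 (within 1e-9)")
  if (!is.numeric(noise_sd_log2) || noise_sd_log2 < 0)
    stop("noise_sd_log2 must be >= 0")
  if (dye_bias_amplitude < 0) stop("dye_bias_amplitude must be >= 0")
  if (length(baseline_intensity_range) != 2L ||
      diff(baseline_intensity_range) <= 0)
    stop("baseline_intensity_range must be an increasing interval")
  if (length(none_fold_range) != 2L || any(none_fold_range <= 0) ||
      none_fold_range[1] > none_fold_range[2])
    stop("none_fold_range must be a positive, non-decreasing interval")

  structure(list(
    n_genes = as.integer(n_genes),
    n_replicates = as.integer(n_replicates),
    category_proportions = p,
    noise_sd_log2 = noise_sd_log2,
    dye_bias_amplitude = dye_bias_amplitude,
    baseline_intensity_range = baseline_intensity_range,
    none_fold_range = none_fold_range,
    rhizospheres = RHIZOSPHERES,
    baseline_condition = baseline_condition,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Largest-remainder apportionment of n among proportions p (named).
# Ties in the fractional remainders are broken by category name order.
largest_remainder <- function(n, p) {
  quota <- n * p
  base <- floor(quota)
  rem <- quota - base
  leftover <- n - sum(base)
  if (leftover > 0) {
    ord <- order(-rem, names(p))
    take <- ord[seq_len(leftover)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Generate the planted ground truth for a synthetic cohort
#'
#' Assigns each gene a specificity category (by deterministic
#' largest-remainder apportionment of the configured proportions, ties
#' broken by category name order), a replicon, and a planted expression
#' ratio versus the free-living baseline for each rhizosphere. Folds are
#' constructed *from* the category so the truth is unambiguous under the
#' classifier's thresholds: within a category one member rhizosphere is
#' "primary" (fold in \[3.5, 30\]), remaining members are "secondary"
#' (fold in \[2.2, 2.9\]), excluded rhizospheres draw from
#' `none_fold_range`, and `DOWN_ALL` genes draw all folds in \[0.1, 0.3\].
#'
#' Replicons mimic the Rlv3841 genome (a chromosome and plasmids
#' pRL7-pRL12); pea-specific genes are planted on pRL8 with probability
#' 0.37, echoing the enrichment the pipeline is designed to detect.
#'
#' @param config a [sim_config()] object.
#' @return a data.frame of class `synthetic_truth` with columns `gene_id`,
#'   `category`, `replicon`, and one `fold_<rhizosphere>` column per
#'   rhizosphere; the config is attached as attribute `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  counts <- largest_remainder(n, config$category_proportions)

  replicons <- c("chromosome", paste0("pRL", 7:12))
  repl_w <- c(0.60, rep(0.40 / 6, 6))
  # pea-specific genes carry the plasmid-borne host-specificity bias
  repl_w_pea <- repl_w
  repl_w_pea[replicons == "pRL8"] <- 0.37
  repl_w_pea[replicons != "pRL8"] <-
    repl_w[replicons != "pRL8"] / sum(repl_w[replicons != "pRL8"]) * 0.63

  lo <- log2(config$none_fold_range[1])
  hi <- log2(config$none_fold_range[2])

  with_local_seed(substream_seed(config$seed, "truth"), {
    category <- sample(rep(names(counts), counts))
    replicon <- ifelse(
      category == "PEA_ONLY",
      sample(replicons, n, replace = TRUE, prob = repl_w_pea),
      sample(replicons, n, replace = TRUE, prob = repl_w)
    )
    folds <- matrix(2^stats::runif(n * 3, lo, hi), nrow = n,
                    dimnames = list(NULL, RHIZOSPHERES))
    for (i in seq_len(n)) {
      cat_i <- category[i]
      if (cat_i == "DOWN_ALL") {
        folds[i, ] <- stats::runif(3, 0.1, 0.3)
      } else if (cat_i != "NONE") {
        members <- category_members(cat_i)
        primary <- if (length(members) == 1L) members else sample(members, 1L)
        folds[i, primary] <- stats::runif(1, 3.5, 30)
        secondary <- setdiff(members, primary)
        if (length(secondary))
          folds[i, secondary] <- stats::runif(length(secondary), 2.2, 2.9)
      }
    }
    truth <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(n)),
      category = category,
      replicon = replicon,
      stringsAsFactors = FALSE
    )
    for (r in RHIZOSPHERES) truth[[paste0("fold_", r)]] <- folds[, r]
    attr(truth, "config") <- config
    class(truth) <- c("synthetic_truth", "data.frame")
    truth
  })
}

#' Build the default hybridization design
#'
#' One slide per replicate per contrast. Indirect contrasts hybridize each
#' rhizosphere sample against the common free-living baseline; direct
#' contrasts hybridize pairs of rhizospheres on the same slide. Even
#' replicates are dye-swapped (channel assignment reversed), the standard
#' two-color design for cancelling dye-specific bias.
#'
#' @param config a [sim_config()] object.
#' @param include_direct include the three pairwise rhizosphere contrasts.
#' @param include_indirect include the three rhizosphere-versus-baseline
#'   contrasts.
#' @return data.frame with columns `slide_id`, `condition_ch1`,
#'   `condition_ch2`, `replicate`, `dye_swap`.
#' @export
default_design <- function(config, include_direct = TRUE,
                           include_indirect = TRUE) {
  pairs <- list()
  if (include_indirect)
    for (r in config$rhizospheres)
      pairs <- c(pairs, list(c(r, config$baseline_condition)))
  if (include_direct) {
    rs <- config$rhizospheres
    for (i in seq_along(rs)) for (j in seq_along(rs)) if (i < j)
      pairs <- c(pairs, list(c(rs[i], rs[j])))
  }
  rows <- lapply(pairs, function(pr) {
    data.frame(
      slide_id = sprintf("%s_vs_%s_r%d", pr[1], pr[2],
                         seq_len(config$n_replicates)),
      condition_ch1 = ifelse(seq_len(config$n_replicates) %% 2L == 0L,
                             pr[2], pr[1]),
      condition_ch2 = ifelse(seq_len(config$n_replicates) %% 2L == 0L,
                             pr[1], pr[2]),
      replicate = seq_len(config$n_replicates),
      dye_swap = seq_len(config$n_replicates) %% 2L == 0L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Intensity-dependent dye-bias curve
#'
#' The planted dye bias is a smooth cubic (a Chebyshev polynomial of
#' degree 3, \eqn{4x^3 - 3x}, on the intensity range rescaled to
#' \[-1, 1\]) scaled so its maximum absolute value equals `amplitude`.
#' The same curve is applied to every slide of a batch, emulating the
#' intensity-dependent dye effect that loess normalization removes.
#'
#' @param A mean log2 intensity.
#' @param amplitude maximum absolute log2 bias.
#' @param intensity_range the interval over which the curve is defined.
#' @return bias (log2 units) added to the raw log-ratio at each intensity.
#' @export
dye_bias_curve <- function(A, amplitude,
                           intensity_range = c(6, 14)) {
  if (amplitude == 0) return(rep(0, length(A)))
  x <- 2 * (A - intensity_range[1]) / diff(intensity_range) - 1
  amplitude * (4 * x^3 - 3 * x)
}

#' Generate raw two-channel slide tables
#'
#' For each slide of the design, every gene's two channel intensities
#' encode the planted fold (ratio of planted condition folds; the baseline
#' condition has fold 1), multiplied by the intensity-dependent dye bias
#' and lognormal replicate noise, plus an additive local background.
#' Channel 1 carries `condition_ch1`: on dye-swapped slides the channel
#' assignment is reversed, so the raw ratio is reciprocal before
#' orientation correction.
#'
#' @param truth output of [generate_truth()].
#' @param design a design data.frame as from [default_design()].
#' @param config a [sim_config()] object.
#' @return a named list of `slide_table` data.frames (columns `gene_id`,
#'   `ch1_fg`, `ch1_bg`, `ch2_fg`, `ch2_bg`) carrying attributes
#'   `slide_id`, `condition_ch1`, `condition_ch2`, `dye_swap`.
#' @export
generate_slides <- function(truth, design, config) {
  stopifnot(inherits(config, "sim_config"))
  conditions <- c(config$rhizospheres, config$baseline_condition)
  bad <- setdiff(unique(c(design$condition_ch1, design$condition_ch2)),
                 conditions)
  if (length(bad))
    stop("design references unknown condition(s): ", paste(bad, collapse = ", "))

  n <- nrow(truth)
  fold <- cbind(
    as.matrix(truth[paste0("fold_", config$rhizospheres)]),
    rep(1, n)
  )
  colnames(fold) <- conditions

  lo <- config$baseline_intensity_range[1]
  hi <- config$baseline_intensity_range[2]

  slides <- lapply(seq_len(nrow(design)), function(k) {
    row <- design[k, ]
    with_local_seed(substream_seed(config$seed, paste0("slide_", row$slide_id)), {
      A <- stats::runif(n, lo, hi)
      m_true <- log2(fold[, row$condition_ch1] / fold[, row$condition_ch2])
      m <- m_true +
        dye_bias_curve(A, config$dye_bias_amplitude,
                       config$baseline_intensity_range) +
        stats::rnorm(n, 0, config$noise_sd_log2)
      sig1 <- 2^(A + m / 2)
      sig2 <- 2^(A - m / 2)
      bg1 <- stats::runif(n, 30, 70)
      bg2 <- stats::runif(n, 30, 70)
      slide <- data.frame(
        gene_id = truth$gene_id,
        ch1_fg = sig1 + bg1, ch1_bg = bg1,
        ch2_fg = sig2 + bg2, ch2_bg = bg2,
        stringsAsFactors = FALSE
      )
      attr(slide, "slide_id") <- row$slide_id
      attr(slide, "condition_ch1") <- row$condition_ch1
      attr(slide, "condition_ch2") <- row$condition_ch2
      attr(slide, "dye_swap") <- row$dye_swap
      class(slide) <- c("slide_table", "data.frame")
      slide
    })
  })
  stats::setNames(slides, design$slide_id)
}

#' Simulate CFU counts for a competition assay
#'
#' Per-plant wild-type and mutant colony counts are drawn binomially with
#' expected wild-type recovery percentage `baseline_pct / true_rci_target`
#' (the RCI formula inverted), so that [compute_rci()] on the output
#' estimates `true_rci_target` up to binomial sampling error.
#'
#' @param true_rci_target the planted colonization index (> 0).
#' @param baseline_pct wild-type recovery in the wild-type-versus-wild-type
#'   control, percent (0 < baseline_pct < 100).
#' @param n_plants number of plant replicates.
#' @param cfu_scale total dilution-corrected CFU recovered per plant.
#' @param seed integer seed.
#' @param mutant_id,rhizosphere labels carried into the output.
#' @return a `competition_assay` data.frame with columns `mutant_id`,
#'   `rhizosphere`, `plant`, `wildtype_cfu`, `mutant_cfu`; attributes
#'   `baseline_pct` and `true_rci_target`.
#' @export
generate_competition_counts <- function(true_rci_target, baseline_pct,
                                        n_plants = 8, cfu_scale = 1e4,
                                        seed = 1L,
                                        mutant_id = "mutant",
                                        rhizosphere = "pea") {
  if (true_rci_target <= 0) stop("true_rci_target must be > 0")
  if (baseline_pct <= 0 || baseline_pct >= 100)
    stop("baseline_pct must be strictly between 0 and 100")
  expected_pct <- baseline_pct / true_rci_target
  if (expected_pct >= 100 || expected_pct <= 0)
    stop("implied wild-type recovery percentage (", round(expected_pct, 2),
         "%) must be strictly between 0 and 100")
  with_local_seed(seed, {
    wt <- stats::rbinom(n_plants, size = as.integer(cfu_scale),
                        prob = expected_pct / 100)
    assay <- data.frame(
      mutant_id = mutant_id,
      rhizosphere = rhizosphere,
      plant = seq_len(n_plants),
      wildtype_cfu = wt,
      mutant_cfu = as.integer(cfu_scale) - wt,
      stringsAsFactors = FALSE
    )
    attr(assay, "baseline_pct") <- baseline_pct
    attr(assay, "true_rci_target") <- true_rci_target
    class(assay) <- c("competition_assay", "data.frame")
    assay
  })
}

#' Simulate a qPCR Ct table with a planted expression ratio
#'
#' The target gene's Ct in the treatment condition is offset from its
#' control value by \eqn{-\log_2(\mathrm{planted\_ratio})} (perfect
#' amplification efficiency 2), the reference gene is constant across
#' conditions, and every well receives Gaussian cycle noise.
#'
#' @param planted_ratio true expression ratio (treatment / control, > 0).
#' @param ref_gene reference (normalizer) gene id.
#' @param n_replicates technical replicates per (gene, condition).
#' @param ct_noise_sd well-level Gaussian noise, cycles.
#' @param seed integer seed.
#' @param target_gene target gene id.
#' @param ref_ct,target_ct_control noise-free baseline cycle values.
#' @return a data.frame with columns `gene_id`, `condition`, `replicate`,
#'   `ct`, `is_reference`.
#' @export
generate_ct_table <- function(planted_ratio, ref_gene = "mdh",
                              n_replicates = 3, ct_noise_sd = 0.1,
                              seed = 1L, target_gene = "target",
                              ref_ct = 18, target_ct_control = 22) {
  if (planted_ratio <= 0) stop("planted_ratio must be > 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  with_local_seed(seed, {
    grid <- expand.grid(
      gene_id = c(target_gene, ref_gene),
      condition = c("treatment", "control"),
      replicate = seq_len(n_replicates),
      stringsAsFactors = FALSE
    )
    base_ct <- ifelse(grid$gene_id == ref_gene, ref_ct,
                      ifelse(grid$condition == "treatment",
                             target_ct_control - log2(planted_ratio),
                             target_ct_control))
    grid$ct <- base_ct + stats::rnorm(nrow(grid), 0, ct_noise_sd)
    grid$is_reference <- grid$gene_id == ref_gene
    grid[order(grid$gene_id, grid$condition, grid$replicate), ,
         drop = FALSE]
  })
}
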