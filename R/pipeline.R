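#' End-to-end run configuration
#'
#' A single validated configuration driving [run_all()]: simulation
#' parameters, processing knobs, classification thresholds and the
#' planted competition/qPCR effect sizes. Thresholds default to the
#' study's rules: 3-fold primary / 2-fold secondary elevation at
#' P <= 0.05, down-regulation at 0.3-fold with the 0.5-fold
#' all-rhizosphere extension and the 0.4-0.8 slightly-down band.
#'
#' @param n_genes,n_replicates,category_proportions,noise_sd_log2,dye_bias_amplitude,none_fold_range
#'   passed to [sim_config()].
#' @param primary_fold,secondary_fold,alpha elevation thresholds.
#' @param down_threshold,down_all_threshold,slight_range repression
#'   thresholds.
#' @param span loess span.
#' @param background_floor background-correction floor.
#' @param focal_rhizosphere rhizosphere whose specific set is reconciled
#'   against direct contrasts and summarized per replicon.
#' @param focal_replicon replicon highlighted in the summary.
#' @param rci_targets named vector of planted colonization indices, one
#'   simulated competition assay per entry.
#' @param competition_baseline_pct planted control (wild-type vs
#'   wild-type) recovery percentage.
#' @param n_plants,cfu_scale competition assay sampling parameters.
#' @param qpcr_ratios named vector of planted qPCR expression ratios.
#' @param ct_noise_sd qPCR cycle noise.
#' @param out_dir optional directory for stage TSVs and `summary.json`.
#' @param seed master seed; all stage sub-streams derive from it.
#' @return a validated `run_config` list.
#' @export
run_config <- function(n_genes = 2000, n_replicates = 4,
                       category_proportions = NULL,
                       noise_sd_log2 = 0.25, dye_bias_amplitude = 0.3,
                       none_fold_range = c(0.8, 1.25),
                       primary_fold = 3, secondary_fold = 2, alpha = 0.05,
                       down_threshold = 0.3, down_all_threshold = 0.5,
                       slight_range = c(0.4, 0.8),
                       span = 0.3, background_floor = 0.5,
                       focal_rhizosphere = "pea", focal_replicon = "pRL8",
                       rci_targets = c(thiM = 0.14, nifH = 0.97),
                       competition_baseline_pct = 9.7,
                       n_plants = 8, cfu_scale = 1e4,
                       qpcr_ratios = c(RL0996 = 3.4, RL4274 = 135),
                       ct_noise_sd = 0.1,
                       out_dir = NULL, seed = 1L) {
  if (primary_fold < secondary_fold || secondary_fold < 1)
    stop("thresholds must satisfy primary_fold >= secondary_fold >= 1")
  if (down_threshold <= 0 || down_all_threshold <= 0)
    stop("down thresholds must be positive")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  sim_args <- list(n_genes = n_genes, n_replicates = n_replicates,
                   noise_sd_log2 = noise_sd_log2,
                   dye_bias_amplitude = dye_bias_amplitude,
                   none_fold_range = none_fold_range, seed = seed)
  if (!is.null(category_proportions))
    sim_args$category_proportions <- category_proportions
  structure(list(
    sim = do.call(sim_config, sim_args),
    primary_fold = primary_fold, secondary_fold = secondary_fold,
    alpha = alpha, down_threshold = down_threshold,
    down_all_threshold = down_all_threshold, slight_range = slight_range,
    span = span, background_floor = background_floor,
    focal_rhizosphere = focal_rhizosphere, focal_replicon = focal_replicon,
    rci_targets = rci_targets,
    competition_baseline_pct = competition_baseline_pct,
    n_plants = n_plants, cfu_scale = cfu_scale,
    qpcr_ratios = qpcr_ratios, ct_noise_sd = ct_noise_sd,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full pipeline: simulate, process, classify, RCI, qPCR
#'
#' Generates a synthetic cohort with planted ground truth, processes the
#' two-color slides (background subtraction, MA transform, robust loess
#' normalization), aggregates indirect and direct contrasts, classifies
#' every gene's specificity, reconciles the focal rhizosphere's specific
#' set against the direct contrasts, summarizes replicon enrichment and
#' Venn overlaps, scores simulated competition assays with the RCI, and
#' confirms planted qPCR ratios by the comparative-CT method with a
#' permutation P-value. Every stage draws from a sub-stream of the single
#' config seed, so identical configs give byte-identical summaries.
#'
#' @param config a [run_config()] object.
#' @param verbose log stage progress and parameters to stderr.
#' @return a list with `truth`, `calls`, `indirect`, `direct`,
#'   `reconciled`, `rci`, `qpcr` and `summary`; when `config$out_dir` is
#'   set, stage TSVs and `summary.json` are written there.
#' @export
run_all <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_ <- function(...) if (verbose) message("[rhizoclass] ", ...)
  sim <- config$sim

  log_("simulate: n_genes=", sim$n_genes, " n_replicates=",
       sim$n_replicates, " noise_sd_log2=", sim$noise_sd_log2,
       " seed=", sim$seed)
  truth <- generate_truth(sim)
  design <- default_design(sim)
  slides <- generate_slides(truth, design, sim)

  log_("process: span=", config$span, " floor=", config$background_floor)
  norm <- process_slides(slides, floor = config$background_floor,
                         span = config$span)
  rs <- sim$rhizospheres
  indirect <- stats::setNames(lapply(rs, function(r)
    aggregate_contrast(norm, r, sim$baseline_condition)), rs)
  pairs <- utils::combn(rs, 2, simplify = FALSE)
  direct <- lapply(pairs, function(pr)
    aggregate_contrast(norm, pr[1], pr[2]))

  log_("classify: primary=", config$primary_fold, " secondary=",
       config$secondary_fold, " alpha=", config$alpha)
  calls <- classify_genes(
    indirect, replicon_map = truth[c("gene_id", "replicon")],
    primary_threshold = config$primary_fold,
    secondary_threshold = config$secondary_fold, alpha = config$alpha,
    down_threshold = config$down_threshold,
    down_all_threshold = config$down_all_threshold,
    slight_range = config$slight_range
  )
  reconciled <- reconcile_specific(
    calls, direct, focal = config$focal_rhizosphere,
    threshold = config$primary_fold, alpha = config$alpha,
    rhizospheres = rs
  )
  focal_cat <- category_label(config$focal_rhizosphere, rs)
  repl <- replicon_report(calls, focal_cat, config$focal_replicon,
                          genes = reconciled)
  elevated_sets <- stats::setNames(lapply(rs, function(r)
    calls$gene_id[calls[[paste0("fold_", r)]] >= config$primary_fold &
                  calls[[paste0("p_", r)]] <= config$alpha]), rs)
  venn <- venn_regions(elevated_sets)

  log_("rci: ", length(config$rci_targets), " assays, baseline ",
       config$competition_baseline_pct, "%")
  control <- generate_competition_counts(
    1.0, config$competition_baseline_pct, n_plants = config$n_plants,
    cfu_scale = config$cfu_scale,
    seed = substream_seed(config$seed, "competition_control"),
    mutant_id = "control"
  )
  baseline_est <- mean(recovery_percentage(control$wildtype_cfu,
                                           control$mutant_cfu))
  rci <- do.call(rbind, lapply(names(config$rci_targets), function(id) {
    assay <- generate_competition_counts(
      config$rci_targets[[id]], config$competition_baseline_pct,
      n_plants = config$n_plants, cfu_scale = config$cfu_scale,
      seed = substream_seed(config$seed, paste0("competition_", id)),
      mutant_id = id
    )
    r <- compute_rci(wildtype_cfu = assay$wildtype_cfu,
                     mutant_cfu = assay$mutant_cfu,
                     baseline_pct = baseline_est, mutant_id = id)
    data.frame(mutant_id = id, true_rci = config$rci_targets[[id]],
               mean_recovery_pct = r$mean_recovery_pct,
               sem_recovery_pct = r$sem_recovery_pct,
               rci = r$rci, n_plants = r$n_plants,
               stringsAsFactors = FALSE)
  }))

  log_("qpcr: ", length(config$qpcr_ratios), " genes, reference mdh")
  qpcr <- do.call(rbind, lapply(names(config$qpcr_ratios), function(g) {
    ct <- generate_ct_table(
      config$qpcr_ratios[[g]], ref_gene = "mdh", n_replicates = 3,
      ct_noise_sd = config$ct_noise_sd,
      seed = substream_seed(config$seed, paste0("qpcr_", g)),
      target_gene = g
    )
    dd <- ddct_fold(ct, g, "mdh")
    pt_ <- permutation_ratio_test(
      ct, g, "mdh", seed = substream_seed(config$seed, paste0("perm_", g)))
    data.frame(gene_id = g, planted_ratio = config$qpcr_ratios[[g]],
               ddct = dd$ddct, fold = dd$fold, p_value = pt_$p_value,
               stringsAsFactors = FALSE)
  }))

  up_counts <- table(factor(calls$up_category,
                            levels = setdiff(CATEGORIES, "DOWN_ALL")))
  down_counts <- table(factor(calls$down_category,
                              levels = c("DOWN_ALL", "DOWN_SOME",
                                         "SLIGHT_DOWN", "NONE")))
  summary <- list(
    parameters = list(
      n_genes = sim$n_genes, n_replicates = sim$n_replicates,
      noise_sd_log2 = sim$noise_sd_log2,
      dye_bias_amplitude = sim$dye_bias_amplitude,
      primary_fold = config$primary_fold,
      secondary_fold = config$secondary_fold, alpha = config$alpha,
      seed = config$seed
    ),
    category_counts = as.list(up_counts),
    down_counts = as.list(down_counts),
    venn_regions = stats::setNames(as.list(venn$count), venn$region),
    reconciled = list(
      rhizosphere = config$focal_rhizosphere, n_genes = length(reconciled)),
    replicon = repl,
    baseline_recovery_pct = baseline_est,
    rci = rci,
    qpcr = qpcr
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_truth_table(truth, file.path(config$out_dir, "truth.tsv"))
    write_slide_tables(slides, design, file.path(config$out_dir, "slides"))
    for (r in rs)
      write_contrast_table(indirect[[r]],
        file.path(config$out_dir, paste0("contrast_", r, "_vs_glucose.tsv")))
    for (d in direct)
      write_contrast_table(d, file.path(config$out_dir,
        paste0("contrast_", attr(d, "numerator"), "_vs_",
               attr(d, "denominator"), ".tsv")))
    write_tsv(as.data.frame(calls), file.path(config$out_dir, "gene_calls.tsv"))
    write_tsv(rci, file.path(config$out_dir, "rci.tsv"))
    write_tsv(qpcr, file.path(config$out_dir, "qpcr.tsv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(truth = truth, calls = calls, indirect = indirect,
                 direct = direct, reconciled = reconciled, rci = rci,
                 qpcr = qpcr, summary = summary))
}
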