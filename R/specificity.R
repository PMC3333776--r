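#' Score a gene as elevated in a set of rhizospheres
#'
#' Implements the multi-rhizosphere elevation rule: a gene is elevated in
#' more than one rhizosphere if it is up-regulated by `primary_threshold`
#' (3-fold) or more in one and `secondary_threshold` (2-fold) or more in
#' one or two others. A rhizosphere enters the elevated set iff
#' (fold >= primary and p <= alpha), or (fold >= secondary and some other
#' rhizosphere meets the primary condition). The set is empty when no
#' rhizosphere reaches the primary threshold.
#'
#' @param folds named numeric vector of fold-changes (one per rhizosphere,
#'   versus the free-living baseline).
#' @param pvals named numeric vector of P-values, same names as `folds`.
#' @param primary_threshold,secondary_threshold fold cutoffs.
#' @param alpha P-value cutoff.
#' @param secondary_requires_p also require `p <= alpha` for secondary
#'   (two-fold) membership. The published rule states fold thresholds
#'   only; requiring P for symmetry with the primary call is the default,
#'   with the fold-only behaviour available via this flag.
#' @return character vector: the rhizospheres in which the gene is scored
#'   as elevated.
#' @export
#' @examples
#' call_elevated(c(pea = 135, alfalfa = 3.5, sugarbeet = 2.8),
#'               c(pea = 0.01, alfalfa = 0.01, sugarbeet = 0.01))
call_elevated <- function(folds, pvals, primary_threshold = 3,
                          secondary_threshold = 2, alpha = 0.05,
                          secondary_requires_p = TRUE) {
  if (is.null(names(folds)) || !identical(sort(names(folds)),
                                          sort(names(pvals))))
    stop("folds and pvals must be named identically by rhizosphere")
  pvals <- pvals[names(folds)]
  primary <- folds >= primary_threshold & pvals <= alpha
  if (!any(primary)) return(character(0))
  secondary <- folds >= secondary_threshold &
    (if (secondary_requires_p) pvals <= alpha else TRUE)
  names(folds)[primary | secondary]
}

#' Score a gene's down-regulation category
#'
#' A gene is down-regulated in a rhizosphere iff fold <= `down_threshold`
#' (0.3) with p <= alpha; this extends to `DOWN_ALL` when every remaining
#' rhizosphere has fold <= `down_all_threshold` (0.5). A gene whose folds
#' all fall in `slight_range` (0.4 to 0.8) without meeting the down rule
#' is `SLIGHT_DOWN`; otherwise `NONE`. Genes down-regulated somewhere but
#' not everywhere are `DOWN_SOME`.
#'
#' @inheritParams call_elevated
#' @param down_threshold fold cutoff for a down call in one rhizosphere.
#' @param down_all_threshold fold cutoff for the remaining rhizospheres in
#'   the all-rhizosphere extension.
#' @param slight_range fold interval for the slightly-down band.
#' @return list with `category` (one of `DOWN_ALL`, `DOWN_SOME`,
#'   `SLIGHT_DOWN`, `NONE`) and `rhizospheres` (where the strict down rule
#'   holds).
#' @export
call_repressed <- function(folds, pvals, down_threshold = 0.3,
                           down_all_threshold = 0.5,
                           slight_range = c(0.4, 0.8), alpha = 0.05) {
  if (is.null(names(folds)) || !identical(sort(names(folds)),
                                          sort(names(pvals))))
    stop("folds and pvals must be named identically by rhizosphere")
  pvals <- pvals[names(folds)]
  down <- folds <= down_threshold & pvals <= alpha
  category <- if (any(down)) {
    if (all(folds <= down_all_threshold)) "DOWN_ALL" else "DOWN_SOME"
  } else if (all(folds >= slight_range[1] & folds <= slight_range[2])) {
    "SLIGHT_DOWN"
  } else {
    "NONE"
  }
  list(category = category, rhizospheres = names(folds)[down])
}

#' Map an elevated-rhizosphere set to its specificity category label
#'
#' For the default pea/alfalfa/sugar beet study the labels are `ALL`,
#' `PEA_ONLY`, `ALFALFA_ONLY`, `SUGARBEET_ONLY`, `LEGUME` (pea + alfalfa),
#' `ALFALFA_SUGARBEET`, `PEA_SUGARBEET` and `NONE`. For any other
#' condition set the label is the sorted upper-case members joined by
#' underscores (`ALL` when every condition is present).
#'
#' @param elevated character vector of rhizospheres (possibly empty).
#' @param rhizospheres all rhizospheres under study.
#' @return a single category label.
#' @export
category_label <- function(elevated, rhizospheres = RHIZOSPHERES) {
  if (length(elevated) == 0) return("NONE")
  if (setequal(elevated, rhizospheres)) return("ALL")
  if (setequal(rhizospheres, RHIZOSPHERES)) {
    key <- paste(sort(elevated), collapse = "+")
    lab <- c("pea" = "PEA_ONLY", "alfalfa" = "ALFALFA_ONLY",
             "sugarbeet" = "SUGARBEET_ONLY",
             "alfalfa+pea" = "LEGUME",
             "alfalfa+sugarbeet" = "ALFALFA_SUGARBEET",
             "pea+sugarbeet" = "PEA_SUGARBEET")[key]
    if (!is.na(lab)) return(unname(lab))
  }
  paste(toupper(sort(elevated)), collapse = "_")
}

#' Classify every gene's rhizosphere specificity
#'
#' Applies [call_elevated()] and [call_repressed()] to the per-rhizosphere
#' indirect contrast results of every gene and maps the outcomes to
#' category labels. If a gene satisfies both an elevation and a repression
#' rule (across different rhizospheres), the up-classification wins and a
#' conflict flag is set, so no gene carries both a non-`NONE` up and down
#' category.
#'
#' @param indirect named list of `contrast_result` objects, one per
#'   rhizosphere (names are the rhizosphere labels), each from the
#'   rhizosphere-versus-baseline contrast.
#' @param replicon_map optional data.frame (`gene_id`, `replicon`).
#' @inheritParams call_elevated
#' @inheritParams call_repressed
#' @return a `gene_calls` data.frame: `gene_id`, `replicon`, per-rhizosphere
#'   `fold_<r>` and `p_<r>` columns, `up_category`, `down_category`,
#'   `conflict`.
#' @export
classify_genes <- function(indirect, replicon_map = NULL,
                           primary_threshold = 3, secondary_threshold = 2,
                           alpha = 0.05, secondary_requires_p = TRUE,
                           down_threshold = 0.3, down_all_threshold = 0.5,
                           slight_range = c(0.4, 0.8)) {
  rs <- names(indirect)
  if (is.null(rs) || length(rs) < 2)
    stop("indirect must be a named list of contrast results per rhizosphere")
  genes <- indirect[[1]]$gene_id
  fold <- sapply(indirect, function(cr) {
    stopifnot(setequal(cr$gene_id, genes))
    cr$fold_change[match(genes, cr$gene_id)]
  })
  pv <- sapply(indirect, function(cr) cr$p_value[match(genes, cr$gene_id)])
  rownames(fold) <- rownames(pv) <- genes

  up <- character(length(genes))
  down <- character(length(genes))
  conflict <- logical(length(genes))
  for (i in seq_along(genes)) {
    f <- fold[i, ]; p <- pv[i, ]
    elev <- call_elevated(f, p, primary_threshold, secondary_threshold,
                          alpha, secondary_requires_p)
    rep_ <- call_repressed(f, p, down_threshold, down_all_threshold,
                           slight_range, alpha)
    up[i] <- category_label(elev, rs)
    down[i] <- rep_$category
    if (up[i] != "NONE" && down[i] != "NONE") {
      conflict[i] <- TRUE
      down[i] <- "NONE"
    }
  }
  calls <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  if (!is.null(replicon_map)) {
    calls$replicon <- replicon_map$replicon[
      match(genes, replicon_map$gene_id)]
  } else {
    calls$replicon <- NA_character_
  }
  for (r in rs) {
    calls[[paste0("fold_", r)]] <- fold[, r]
    calls[[paste0("p_", r)]] <- pv[, r]
  }
  calls$up_category <- up
  calls$down_category <- down
  calls$conflict <- conflict
  class(calls) <- c("gene_calls", "data.frame")
  calls
}

#' Intersect indirect specificity calls with direct contrasts
#'
#' Retains the genes whose indirect category is the focal rhizosphere's
#' singleton (e.g. `PEA_ONLY`) *and* whose direct rhizosphere-versus-
#' rhizosphere fold against each other rhizosphere is at least `threshold`
#' with p <= alpha -- the conservative intersection of the two
#' independent comparison methods.
#'
#' @param calls a `gene_calls` data.frame from [classify_genes()].
#' @param direct list of `contrast_result` objects covering, in either
#'   orientation, the focal rhizosphere against every other rhizosphere
#'   (folds in the reverse orientation are inverted).
#' @param focal the rhizosphere whose specific gene set is sought.
#' @param threshold direct-contrast fold cutoff.
#' @param alpha P-value cutoff.
#' @param rhizospheres all rhizospheres under study.
#' @return character vector of retained gene ids.
#' @export
reconcile_specific <- function(calls, direct, focal = "pea", threshold = 3,
                               alpha = 0.05, rhizospheres = RHIZOSPHERES) {
  singleton <- category_label(focal, rhizospheres)
  cand <- calls$gene_id[calls$up_category == singleton]
  others <- setdiff(rhizospheres, focal)
  for (other in others) {
    cr <- NULL
    invert <- FALSE
    for (d in direct) {
      if (identical(attr(d, "numerator"), focal) &&
          identical(attr(d, "denominator"), other)) {
        cr <- d; invert <- FALSE; break
      }
      if (identical(attr(d, "numerator"), other) &&
          identical(attr(d, "denominator"), focal)) {
        cr <- d; invert <- TRUE; break
      }
    }
    if (is.null(cr))
      stop("no direct contrast found for ", focal, " vs ", other)
    idx <- match(cand, cr$gene_id)
    if (anyNA(idx)) stop("direct contrast is missing candidate genes")
    f <- cr$fold_change[idx]
    if (invert) f <- 1 / f
    keep <- f >= threshold & cr$p_value[idx] <= alpha
    cand <- cand[keep]
  }
  cand
}

#' Count a category's genes on a replicon
#'
#' @param calls a `gene_calls` data.frame with a `replicon` column.
#' @param category a specificity category label (up categories match
#'   `up_category`; `DOWN_*`/`SLIGHT_DOWN` match `down_category`).
#' @param replicon replicon label (e.g. `"pRL8"`).
#' @param genes optional character vector restricting the calls considered
#'   (e.g. the reconciled set from [reconcile_specific()]).
#' @return list with `category`, `replicon`, `n_category`,
#'   `n_on_replicon` and `fraction` (`NA` with a message when the category
#'   is empty).
#' @export
replicon_report <- function(calls, category, replicon, genes = NULL) {
  if (!is.null(genes)) calls <- calls[calls$gene_id %in% genes, , drop = FALSE]
  col <- if (category %in% c("DOWN_ALL", "DOWN_SOME", "SLIGHT_DOWN"))
    "down_category" else "up_category"
  in_cat <- calls[[col]] == category
  n_cat <- sum(in_cat)
  n_repl <- sum(in_cat & !is.na(calls$replicon) & calls$replicon == replicon)
  frac <- if (n_cat == 0) {
    message("category ", category, " is empty; fraction undefined")
    NA_real_
  } else n_repl / n_cat
  list(category = category, replicon = replicon,
       n_category = n_cat, n_on_replicon = n_repl, fraction = frac)
}

#' Venn region counts for two or three gene sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return data.frame with one row per disjoint region: a `region` label
#'   (set names joined by `&`, exclusive of the other sets) and `count`.
#'   Region counts sum to the size of the union; per-set totals are
#'   attached as attribute `totals`.
#' @export
venn_regions <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) stop("venn_regions expects 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_len(k)]
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  region <- apply(patterns, 1, function(row)
    paste(names(sets)[as.logical(row)], collapse = "&"))
  count <- apply(patterns, 1, function(row) {
    if (length(universe) == 0) return(0L)
    sum(apply(member, 1, function(m) all(m == as.logical(row))))
  })
  out <- data.frame(region = region, count = as.integer(count),
                    stringsAsFactors = FALSE)
  attr(out, "totals") <- vapply(sets, function(s) length(unique(s)), 1L)
  out
}
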