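#' Subtract local background from spot intensities
#'
#' Each channel's foreground has its local background subtracted. Corrected
#' intensities are floored at `floor` (default 0.5) so downstream log
#' transforms stay defined; spots where foreground does not exceed
#' background in either channel are flagged rather than dropped.
#'
#' @param slide a `slide_table` data.frame (columns `gene_id`, `ch1_fg`,
#'   `ch1_bg`, `ch2_fg`, `ch2_bg`).
#' @param floor minimum corrected intensity.
#' @return the slide with corrected channels `ch1`, `ch2` and a logical
#'   `flag` column; slide attributes are preserved.
#' @export
background_correct <- function(slide, floor = 0.5) {
  req <- c("gene_id", "ch1_fg", "ch1_bg", "ch2_fg", "ch2_bg")
  if (!all(req %in% names(slide)))
    stop("slide must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(slide$gene_id))
    stop("gene_id must be unique within a slide")
  out <- data.frame(
    gene_id = slide$gene_id,
    ch1 = pmax(slide$ch1_fg - slide$ch1_bg, floor),
    ch2 = pmax(slide$ch2_fg - slide$ch2_bg, floor),
    flag = slide$ch1_fg <= slide$ch1_bg | slide$ch2_fg <= slide$ch2_bg,
    stringsAsFactors = FALSE
  )
  for (a in c("slide_id", "condition_ch1", "condition_ch2", "dye_swap"))
    attr(out, a) <- attr(slide, a)
  class(out) <- c("corrected_slide", "data.frame")
  out
}

#' Compute M (log-ratio) and A (mean log-intensity) for a slide
#'
#' @param slide a background-corrected slide from [background_correct()].
#' @return a `normalized_slide` data.frame with columns `gene_id`, `M`
#'   (log2 of channel 1 over channel 2), `A` and `flag`; attribute
#'   `normalized` is `FALSE` until [lowess_normalize()] is applied.
#' @export
compute_ma <- function(slide) {
  stopifnot(all(c("gene_id", "ch1", "ch2") %in% names(slide)))
  out <- data.frame(
    gene_id = slide$gene_id,
    M = log2(slide$ch1 / slide$ch2),
    A = (log2(slide$ch1) + log2(slide$ch2)) / 2,
    flag = if ("flag" %in% names(slide)) slide$flag else FALSE,
    stringsAsFactors = FALSE
  )
  for (a in c("slide_id", "condition_ch1", "condition_ch2", "dye_swap"))
    attr(out, a) <- attr(slide, a)
  attr(out, "normalized") <- FALSE
  class(out) <- c("normalized_slide", "data.frame")
  out
}

#' Loess-normalize a slide's log-ratios against intensity
#'
#' Removes intensity-dependent dye bias by subtracting a locally weighted
#' robust regression of M on A: a degree-2 loess with tricube weights and
#' iterated (Tukey biweight) robustification, so that differentially
#' expressed genes do not pull the fitted trend. Returns
#' `M' = M - fhat(A)`; A is unchanged.
#'
#' @param slide a `normalized_slide` from [compute_ma()].
#' @param span loess span (fraction of points in each local window).
#' @return the slide with `M` replaced by the normalized values and
#'   attribute `normalized = TRUE`.
#' @export
lowess_normalize <- function(slide, span = 0.3) {
  stopifnot(all(c("M", "A") %in% names(slide)))
  ok <- is.finite(slide$M) & is.finite(slide$A)
  if (sum(ok) < 20)
    stop("loess normalization needs at least 20 genes with finite (M, A)")
  fit <- stats::loess(M ~ A, data = slide[ok, ], span = span, degree = 2,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  fitted <- rep(NA_real_, nrow(slide))
  fitted[ok] <- stats::predict(fit, slide$A[ok])
  out <- slide
  out$M <- slide$M - fitted
  attr(out, "normalized") <- TRUE
  out
}

#' Background-correct, transform and normalize a batch of slides
#'
#' Convenience wrapper running [background_correct()], [compute_ma()] and
#' [lowess_normalize()] over a list of raw slide tables.
#'
#' @param slides list of `slide_table` data.frames.
#' @param floor background floor, see [background_correct()].
#' @param span loess span, see [lowess_normalize()].
#' @return named list of normalized slides.
#' @export
process_slides <- function(slides, floor = 0.5, span = 0.3) {
  lapply(slides, function(s)
    lowess_normalize(compute_ma(background_correct(s, floor = floor)),
                     span = span))
}

# Orientation-corrected replicate matrix (genes x slides) for one contrast.
# Dye-swapped slides (denominator in channel 1) have M negated.
replicate_matrix <- function(slides, numerator, denominator) {
  keep <- Filter(function(s) {
    conds <- c(attr(s, "condition_ch1"), attr(s, "condition_ch2"))
    setequal(conds, c(numerator, denominator))
  }, slides)
  if (length(keep) < 2)
    stop("need at least 2 replicate slides for contrast ",
         numerator, " vs ", denominator)
  genes <- keep[[1]]$gene_id
  M <- sapply(keep, function(s) {
    stopifnot(setequal(s$gene_id, genes))
    m <- s$M[match(genes, s$gene_id)]
    if (attr(s, "condition_ch1") == numerator) m else -m
  })
  flags <- sapply(keep, function(s) s$flag[match(genes, s$gene_id)])
  # a single-gene slide collapses sapply's result to a vector
  if (length(genes) == 1L) {
    M <- matrix(M, nrow = 1L)
    flags <- matrix(flags, nrow = 1L)
  }
  rownames(M) <- rownames(flags) <- genes
  list(M = M, flags = flags)
}

# One-sample t-test of each row against 0, closed form. Zero-variance
# rows follow the documented convention: p = 1 if the mean is 0, else 0
# (flagged as degenerate by the caller).
row_t_pvalue <- function(M) {
  n <- ncol(M)
  m <- rowMeans(M)
  s2 <- (rowSums(M^2) - n * m^2) / (n - 1)
  s2 <- pmax(s2, 0)
  p <- rep(NA_real_, nrow(M))
  zero <- s2 == 0
  p[zero] <- ifelse(m[zero] == 0, 1, 0)
  tt <- m[!zero] / sqrt(s2[!zero] / n)
  p[!zero] <- 2 * stats::pt(-abs(tt), df = n - 1)
  list(mean = m, p = p, zero_variance = zero)
}

#' Aggregate replicate slides into per-gene contrast statistics
#'
#' Reconciles dye-swap orientations (slides hybridized with the
#' denominator in channel 1 have their log-ratios negated), averages
#' replicate normalized log-ratios per gene, and computes a two-sided
#' one-sample t-test of the replicate log-ratios against 0. Genes flagged
#' (foreground below background) in every replicate are reported with
#' p = 1 and flagged; zero-variance replicate sets get p = 1 if the mean
#' is 0 and p = 0 otherwise, with a degeneracy flag.
#'
#' @param slides list of normalized slides (see [process_slides()]).
#' @param numerator,denominator condition labels of the contrast; the
#'   reported fold is numerator over denominator.
#' @param fdr if `TRUE`, add a Benjamini-Hochberg adjusted `p_adj` column
#'   (off by default; the classification rules filter on raw P).
#' @return a `contrast_result` data.frame with columns `gene_id`,
#'   `fold_change`, `mean_log2_ratio`, `p_value`, `n_replicates`,
#'   `n_flagged`, `flag`, `degenerate`; the orientation-corrected
#'   replicate matrix is attached as attribute `replicates`.
#' @export
aggregate_contrast <- function(slides, numerator, denominator, fdr = FALSE) {
  rm_ <- replicate_matrix(slides, numerator, denominator)
  M <- rm_$M
  n <- ncol(M)
  tt <- row_t_pvalue(M)
  all_flagged <- rowSums(rm_$flags) == n
  p <- tt$p
  p[all_flagged] <- 1
  res <- data.frame(
    gene_id = rownames(M),
    fold_change = 2^tt$mean,
    mean_log2_ratio = tt$mean,
    p_value = p,
    n_replicates = n,
    n_flagged = rowSums(rm_$flags),
    flag = all_flagged,
    degenerate = tt$zero_variance & !all_flagged,
    stringsAsFactors = FALSE
  )
  if (fdr) res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  attr(res, "replicates") <- M
  attr(res, "numerator") <- numerator
  attr(res, "denominator") <- denominator
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Derive a rhizosphere-versus-rhizosphere contrast via a common baseline
#'
#' Two contrasts sharing the same denominator (the free-living baseline)
#' are combined into an indirect comparison of their numerators: the
#' derived fold is the ratio of folds, the mean log-ratio the difference
#' of means, and the P-value a two-sided Welch two-sample t-test of the
#' two replicate sets.
#'
#' @param a,b `contrast_result` objects with identical denominators and
#'   gene sets.
#' @return a `contrast_result` for `numerator(a)` versus `numerator(b)`
#'   with `n_replicates = min(n_a, n_b)`.
#' @export
derive_indirect_ratio <- function(a, b) {
  if (!identical(attr(a, "denominator"), attr(b, "denominator")))
    stop("contrasts must share the same denominator condition")
  Ra <- attr(a, "replicates")
  Rb <- attr(b, "replicates")
  if (is.null(Ra) || is.null(Rb))
    stop("contrast results must carry replicate-level log-ratios")
  stopifnot(setequal(rownames(Ra), rownames(Rb)))
  Rb <- Rb[rownames(Ra), , drop = FALSE]
  na <- ncol(Ra); nb <- ncol(Rb)
  ma <- rowMeans(Ra); mb <- rowMeans(Rb)
  va <- pmax((rowSums(Ra^2) - na * ma^2) / (na - 1), 0)
  vb <- pmax((rowSums(Rb^2) - nb * mb^2) / (nb - 1), 0)
  d <- ma - mb
  se2 <- va / na + vb / nb
  p <- rep(NA_real_, length(d))
  zero <- se2 == 0
  p[zero] <- ifelse(d[zero] == 0, 1, 0)
  tt <- d[!zero] / sqrt(se2[!zero])
  df <- se2[!zero]^2 /
    ((va[!zero] / na)^2 / (na - 1) + (vb[!zero] / nb)^2 / (nb - 1))
  p[!zero] <- 2 * stats::pt(-abs(tt), df = df)
  res <- data.frame(
    gene_id = rownames(Ra),
    fold_change = 2^d,
    mean_log2_ratio = d,
    p_value = p,
    n_replicates = min(na, nb),
    n_flagged = 0L,
    flag = FALSE,
    degenerate = zero,
    stringsAsFactors = FALSE
  )
  attr(res, "numerator") <- attr(a, "numerator")
  attr(res, "denominator") <- attr(b, "numerator")
  class(res) <- c("contrast_result", "data.frame")
  res
}
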