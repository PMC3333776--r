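# Tab-separated readers and writers for every pipeline artifact. The
# dialect is plain TSV with a header row, the same accepted from real
# scanner exports.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write slide tables and their design file
#'
#' One TSV per slide (columns `gene_id`, `ch1_fg`, `ch1_bg`, `ch2_fg`,
#' `ch2_bg`) plus a companion design file (`slide_id`, `condition_ch1`,
#' `condition_ch2`, `replicate`, `dye_swap`).
#'
#' @param slides named list of `slide_table` data.frames.
#' @param design the design data.frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the design file path.
#' @export
write_slide_tables <- function(slides, design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in slides)
    write_tsv(as.data.frame(s),
              file.path(dir, paste0(attr(s, "slide_id"), ".tsv")))
  write_tsv(design, file.path(dir, "design.tsv"))
  invisible(file.path(dir, "design.tsv"))
}

#' Read a slide directory written by [write_slide_tables()]
#'
#' @param dir directory containing `design.tsv` and one TSV per slide.
#' @return list with `slides` (named list of `slide_table`s, attributes
#'   restored from the design) and `design`.
#' @export
read_slide_tables <- function(dir) {
  design <- read_tsv(file.path(dir, "design.tsv"))
  design$dye_swap <- as.logical(design$dye_swap)
  slides <- lapply(seq_len(nrow(design)), function(k) {
    s <- read_tsv(file.path(dir, paste0(design$slide_id[k], ".tsv")))
    attr(s, "slide_id") <- design$slide_id[k]
    attr(s, "condition_ch1") <- design$condition_ch1[k]
    attr(s, "condition_ch2") <- design$condition_ch2[k]
    attr(s, "dye_swap") <- design$dye_swap[k]
    class(s) <- c("slide_table", "data.frame")
    s
  })
  list(slides = stats::setNames(slides, design$slide_id), design = design)
}

#' Write a contrast result table
#'
#' Columns: `gene_id`, `contrast`, `fold_change`, `mean_log2_ratio`,
#' `p_value`, `n`, `flags`.
#'
#' @param result a `contrast_result`.
#' @param path output TSV path.
#' @export
write_contrast_table <- function(result, path) {
  out <- data.frame(
    gene_id = result$gene_id,
    contrast = paste0(attr(result, "numerator"), "_vs_",
                      attr(result, "denominator")),
    fold_change = result$fold_change,
    mean_log2_ratio = result$mean_log2_ratio,
    p_value = result$p_value,
    n = result$n_replicates,
    flags = ifelse(result$flag, "all_flagged",
                   ifelse(result$degenerate, "zero_variance", "")),
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}

#' Write the planted truth table
#' @param truth output of [generate_truth()].
#' @param path output TSV path.
#' @export
write_truth_table <- function(truth, path) write_tsv(as.data.frame(truth), path)

#' Write a CFU plate-count sheet
#' @param sheet long-format CFU sheet (see [rci_table()]).
#' @param path output TSV path.
#' @export
write_cfu_sheet <- function(sheet, path) write_tsv(sheet, path)

#' Read a CFU plate-count sheet
#' @param path TSV path.
#' @return data.frame as consumed by [rci_table()].
#' @export
read_cfu_sheet <- function(path) read_tsv(path)

#' Write a qPCR Ct table
#' @param ct Ct table (see [generate_ct_table()]).
#' @param path output TSV path.
#' @export
write_ct_table <- function(ct, path) write_tsv(ct, path)

#' Read a qPCR Ct table
#' @param path TSV path.
#' @return data.frame as consumed by [ddct_fold()].
#' @export
read_ct_table <- function(path) {
  ct <- read_tsv(path)
  if ("is_reference" %in% names(ct))
    ct$is_reference <- as.logical(ct$is_reference)
  ct
}
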