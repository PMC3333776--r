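# Shared fixture builders: everything is generated in code at test time.

rhizos <- c("pea", "alfalfa", "sugarbeet")

# Minimal normalized slide built directly (bypasses the raw-slide path) so
# aggregation can be tested against hand-computed numbers.
make_norm_slide <- function(M, numerator, denominator, swap = FALSE,
                            genes = sprintf("g%03d", seq_along(M)),
                            flag = FALSE) {
  s <- data.frame(gene_id = genes, M = M, A = rep(10, length(M)),
                  flag = flag, stringsAsFactors = FALSE)
  attr(s, "slide_id") <- paste0(numerator, "_", denominator,
                                sample(1e6, 1))
  attr(s, "condition_ch1") <- if (swap) denominator else numerator
  attr(s, "condition_ch2") <- if (swap) numerator else denominator
  attr(s, "dye_swap") <- swap
  attr(s, "normalized") <- TRUE
  class(s) <- c("normalized_slide", "data.frame")
  s
}

# Collapse up/down calls into the single planted-category vocabulary used
# by the truth table, for round-trip comparisons.
combined_category <- function(calls) {
  ifelse(calls$up_category != "NONE", calls$up_category,
         ifelse(calls$down_category == "DOWN_ALL", "DOWN_ALL", "NONE"))
}

# Run simulate -> process -> aggregate for the indirect contrasts only.
indirect_contrasts <- function(truth, cfg, span = 0.3) {
  design <- default_design(cfg, include_direct = FALSE)
  slides <- generate_slides(truth, design, cfg)
  norm <- process_slides(slides, span = span)
  stats::setNames(
    lapply(rhizos, function(r) aggregate_contrast(norm, r, "glucose")),
    rhizos)
}
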