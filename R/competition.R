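#' Per-plant wild-type recovery percentage
#'
#' The percentage of recovered colonies that are wild type,
#' `100 * wildtype / (wildtype + mutant)`, computed per plant replicate.
#' Plants with zero total count are excluded with a warning (returned as
#' `NA`).
#'
#' @param wildtype_cfu,mutant_cfu dilution-corrected colony counts.
#' @return numeric vector of percentages.
#' @export
#' @examples
#' recovery_percentage(97, 903)   # 9.7
#' recovery_percentage(717, 283)  # 71.7
recovery_percentage <- function(wildtype_cfu, mutant_cfu) {
  if (any(wildtype_cfu < 0, na.rm = TRUE) ||
      any(mutant_cfu < 0, na.rm = TRUE))
    stop("CFU counts must be non-negative")
  total <- wildtype_cfu + mutant_cfu
  if (any(total == 0, na.rm = TRUE))
    warning("plant record(s) with zero total CFU excluded (NA)")
  ifelse(total > 0, 100 * wildtype_cfu / total, NA_real_)
}

#' Expected minority-strain recovery under equal fitness
#'
#' When a mutant is inoculated at `inoculum_ratio_mutant_to_wt`-fold
#' excess over the wild type and both strains are equally fit, the
#' expected wild-type recovery is `100 / (1 + ratio)` percent -- 9.1% for
#' the standard 10:1 design.
#'
#' @param inoculum_ratio_mutant_to_wt mutant:wild-type inoculum ratio (> 0).
#' @return expected wild-type recovery, percent.
#' @export
#' @examples
#' expected_baseline(10)  # 9.0909...
expected_baseline <- function(inoculum_ratio_mutant_to_wt) {
  if (any(inoculum_ratio_mutant_to_wt <= 0))
    stop("inoculum ratio must be > 0")
  100 / (1 + inoculum_ratio_mutant_to_wt)
}

#' Rhizosphere Colonization Index
#'
#' Scores a mutant's competitiveness against the wild type:
#' `RCI = 1 / (mean recovery / baseline recovery)`, i.e.
#' `baseline_pct / mean_recovery_pct`, where the baseline is the wild-type
#' recovery in the wild-type-versus-wild-type control. An RCI of 1 means
#' equal competitiveness; lower values mean a less competitive mutant.
#' Per-plant recovery percentages are averaged (mean of percentages, with
#' the SEM over plants), not pooled across plants.
#'
#' @param recovery_pct per-plant wild-type recovery percentages; either
#'   given directly or computed from `wildtype_cfu`/`mutant_cfu`.
#' @param baseline_pct wild-type recovery in the control, percent.
#' @param wildtype_cfu,mutant_cfu optional per-plant counts used when
#'   `recovery_pct` is missing.
#' @param mutant_id label carried into the result.
#' @return an `rci_result` list: `mutant_id`, `mean_recovery_pct`,
#'   `sem_recovery_pct`, `rci`, `n_plants`.
#' @export
#' @examples
#' compute_rci(71.7, baseline_pct = 9.7)$rci  # 0.1353... -> 0.14
#' compute_rci(10.0, baseline_pct = 9.7)$rci  # 0.97
compute_rci <- function(recovery_pct = NULL, baseline_pct,
                        wildtype_cfu = NULL, mutant_cfu = NULL,
                        mutant_id = NA_character_) {
  if (baseline_pct <= 0 || baseline_pct >= 100)
    stop("baseline_pct must be strictly between 0 and 100")
  if (is.null(recovery_pct)) {
    if (is.null(wildtype_cfu) || is.null(mutant_cfu))
      stop("provide recovery_pct or both wildtype_cfu and mutant_cfu")
    recovery_pct <- recovery_percentage(wildtype_cfu, mutant_cfu)
  }
  recovery_pct <- recovery_pct[!is.na(recovery_pct)]
  if (length(recovery_pct) == 0)
    stop("no usable plant records (all excluded)")
  m <- mean(recovery_pct)
  if (m <= 0) stop("mean recovery percentage must be > 0")
  n <- length(recovery_pct)
  sem <- if (n >= 2) stats::sd(recovery_pct) / sqrt(n) else NA_real_
  structure(list(
    mutant_id = mutant_id,
    mean_recovery_pct = m,
    sem_recovery_pct = sem,
    rci = baseline_pct / m,
    n_plants = n
  ), class = "rci_result")
}

#' @export
print.rci_result <- function(x, ...) {
  cat(sprintf(
    "RCI %s: %.2f (wild-type recovery %.1f%% +/- %s, n = %d plants)\n",
    if (is.na(x$mutant_id)) "" else x$mutant_id,
    x$rci, x$mean_recovery_pct,
    if (is.na(x$sem_recovery_pct)) "NA"
    else sprintf("%.1f%%", x$sem_recovery_pct),
    x$n_plants))
  invisible(x)
}

#' RCI table from a CFU plate-count sheet
#'
#' The sheet is long-format with one row per (mutant, rhizosphere, plant,
#' strain): columns `mutant_id`, `rhizosphere`, `plant`, `strain`
#' (`"wildtype"` or `"mutant"`), `dilution_factor`, `colonies`. Counts are
#' dilution-corrected (`colonies * dilution_factor`) before percentages;
#' raw plate counts below 10 trigger a low-count warning. When
#' `baseline_pct` is not supplied, it is computed as the mean wild-type
#' recovery over the rows whose `mutant_id` equals `control_id`.
#'
#' @param sheet the CFU sheet data.frame.
#' @param baseline_pct control wild-type recovery, percent, or `NULL` to
#'   estimate it from the sheet's control block.
#' @param control_id `mutant_id` of the wild-type-versus-wild-type block.
#' @return data.frame with one row per (mutant_id, rhizosphere):
#'   `mean_recovery_pct`, `sem_recovery_pct`, `rci`, `n_plants`; the
#'   baseline used is attached as attribute `baseline_pct`.
#' @export
rci_table <- function(sheet, baseline_pct = NULL, control_id = "control") {
  req <- c("mutant_id", "rhizosphere", "plant", "strain",
           "dilution_factor", "colonies")
  if (!all(req %in% names(sheet)))
    stop("CFU sheet must have columns: ", paste(req, collapse = ", "))
  if (any(sheet$colonies < 10))
    warning("raw plate count(s) below 10 colonies; percentages may be noisy")
  sheet$count <- sheet$colonies * sheet$dilution_factor

  per_plant <- function(block) {
    plants <- unique(block$plant)
    vapply(plants, function(pl) {
      wt <- sum(block$count[block$plant == pl & block$strain == "wildtype"])
      mu <- sum(block$count[block$plant == pl & block$strain == "mutant"])
      recovery_percentage(wt, mu)
    }, numeric(1))
  }

  if (is.null(baseline_pct)) {
    ctrl <- sheet[sheet$mutant_id == control_id, , drop = FALSE]
    if (nrow(ctrl) == 0)
      stop("no control block '", control_id,
           "' in sheet; supply baseline_pct")
    baseline_pct <- mean(per_plant(ctrl), na.rm = TRUE)
  }

  keys <- unique(sheet[sheet$mutant_id != control_id,
                       c("mutant_id", "rhizosphere")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    block <- sheet[sheet$mutant_id == keys$mutant_id[i] &
                   sheet$rhizosphere == keys$rhizosphere[i], , drop = FALSE]
    r <- compute_rci(per_plant(block), baseline_pct = baseline_pct,
                     mutant_id = keys$mutant_id[i])
    data.frame(mutant_id = keys$mutant_id[i],
               rhizosphere = keys$rhizosphere[i],
               mean_recovery_pct = r$mean_recovery_pct,
               sem_recovery_pct = r$sem_recovery_pct,
               rci = r$rci, n_plants = r$n_plants,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_pct") <- baseline_pct
  out
}

#' Convert a simulated competition assay to a long CFU sheet
#'
#' @param assay a `competition_assay` from [generate_competition_counts()].
#' @param dilution_factor dilution factor recorded on every plate.
#' @return long-format CFU sheet as read by [rci_table()]; `colonies` are
#'   the counts divided by the dilution factor (rounded).
#' @export
as_cfu_sheet <- function(assay, dilution_factor = 1) {
  long <- rbind(
    data.frame(mutant_id = assay$mutant_id, rhizosphere = assay$rhizosphere,
               plant = assay$plant, strain = "wildtype",
               dilution_factor = dilution_factor,
               colonies = round(assay$wildtype_cfu / dilution_factor),
               stringsAsFactors = FALSE),
    data.frame(mutant_id = assay$mutant_id, rhizosphere = assay$rhizosphere,
               plant = assay$plant, strain = "mutant",
               dilution_factor = dilution_factor,
               colonies = round(assay$mutant_cfu / dilution_factor),
               stringsAsFactors = FALSE)
  )
  long[order(long$plant, long$strain), , drop = FALSE]
}
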