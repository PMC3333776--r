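p_ok <- c(pea = 0.01, alfalfa = 0.01, sugarbeet = 0.01)

test_that("elevation rule reproduces the published worked examples", {
  # multidrug exporter: 135-fold in pea, 3.5 / 2.8 in alfalfa / sugar beet
  expect_setequal(
    call_elevated(c(pea = 135, alfalfa = 3.5, sugarbeet = 2.8), p_ok),
    c("pea", "alfalfa", "sugarbeet"))

  # tartrate transporter: alfalfa 1.5-fold falls below the two-fold cutoff
  expect_equal(
    call_elevated(c(pea = 3.4, alfalfa = 1.5, sugarbeet = 1.0),
                  c(pea = 0.01, alfalfa = 0.01, sugarbeet = 0.5)),
    "pea")

  # no rhizosphere reaches the primary three-fold threshold
  expect_length(
    call_elevated(c(pea = 2.9, alfalfa = 2.9, sugarbeet = 2.9), p_ok), 0)

  # secondary membership needs p <= alpha by default, not with the flag off
  folds <- c(pea = 5, alfalfa = 2.5, sugarbeet = 1.0)
  pv <- c(pea = 0.01, alfalfa = 0.2, sugarbeet = 0.9)
  expect_equal(call_elevated(folds, pv), "pea")
  expect_setequal(call_elevated(folds, pv, secondary_requires_p = FALSE),
                  c("pea", "alfalfa"))

  expect_error(call_elevated(c(pea = 3), c(alfalfa = 0.01)), "named")
})

test_that("repression rule covers the down, slight-down and null bands", {
  expect_equal(
    call_repressed(c(pea = 0.25, alfalfa = 0.45, sugarbeet = 0.5),
                   c(pea = 0.01, alfalfa = 0.2, sugarbeet = 0.3))$category,
    "DOWN_ALL")
  expect_equal(
    call_repressed(c(pea = 0.6, alfalfa = 0.7, sugarbeet = 0.8),
                   p_ok)$category,
    "SLIGHT_DOWN")
  expect_equal(
    call_repressed(c(pea = 1.0, alfalfa = 1.0, sugarbeet = 1.0),
                   c(pea = 0.9, alfalfa = 0.9, sugarbeet = 0.9))$category,
    "NONE")
  # down somewhere but another rhizosphere above the 0.5 extension
  expect_equal(
    call_repressed(c(pea = 0.2, alfalfa = 0.9, sugarbeet = 1.0),
                   p_ok)$category,
    "DOWN_SOME")
})

test_that("elevated sets map to category labels", {
  expect_equal(category_label(c("pea", "alfalfa")), "LEGUME")
  expect_equal(category_label(c("pea", "alfalfa", "sugarbeet")), "ALL")
  expect_equal(category_label(character(0)), "NONE")
  expect_equal(category_label("sugarbeet"), "SUGARBEET_ONLY")
  expect_equal(category_label(c("alfalfa", "sugarbeet")),
               "ALFALFA_SUGARBEET")
  # generalizes to arbitrary condition sets
  expect_equal(category_label("maize", c("maize", "wheat")), "MAIZE")
  expect_equal(category_label(c("maize", "wheat"), c("maize", "wheat")),
               "ALL")
})

test_that("raising the primary threshold never grows an elevated set", {
  set.seed(42)
  for (i in 1:200) {
    folds <- setNames(2^runif(3, -2, 5), rhizos)
    pv <- setNames(runif(3), rhizos)
    lo <- call_elevated(folds, pv, primary_threshold = 3)
    hi <- call_elevated(folds, pv, primary_threshold = 4)
    expect_true(all(hi %in% lo))
  }
})

test_that("every gene gets exactly one up-category and no up/down overlap", {
  cfg <- sim_config(n_genes = 500, seed = 23)
  truth <- generate_truth(cfg)
  calls <- classify_genes(indirect_contrasts(truth, cfg),
                          truth[c("gene_id", "replicon")])
  expect_equal(nrow(calls), 500)
  expect_true(all(calls$up_category %in% c(
    "ALL", "PEA_ONLY", "ALFALFA_ONLY", "SUGARBEET_ONLY", "LEGUME",
    "ALFALFA_SUGARBEET", "PEA_SUGARBEET", "NONE")))
  both <- calls$up_category != "NONE" & calls$down_category != "NONE"
  expect_false(any(both))
  # category gene lists partition the input set
  expect_equal(sum(table(calls$up_category)), 500)
})

test_that("noise-free cohort recovers every planted category", {
  cfg <- sim_config(n_genes = 400, noise_sd_log2 = 0, seed = 24)
  truth <- generate_truth(cfg)
  calls <- classify_genes(indirect_contrasts(truth, cfg),
                          truth[c("gene_id", "replicon")])
  expect_equal(combined_category(calls), truth$category)
})

test_that("direct-contrast reconciliation filters as stated", {
  # hand-built calls and direct tables
  calls <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    up_category = c("PEA_ONLY", "PEA_ONLY", "ALL"),
    stringsAsFactors = FALSE
  )
  mk_direct <- function(num, den, folds, ps) {
    d <- data.frame(gene_id = c("g1", "g2", "g3"), fold_change = folds,
                    p_value = ps, stringsAsFactors = FALSE)
    attr(d, "numerator") <- num; attr(d, "denominator") <- den
    class(d) <- c("contrast_result", "data.frame")
    d
  }
  direct <- list(
    mk_direct("pea", "alfalfa", c(4.1, 1.2, 5), c(0.01, 0.01, 0.01)),
    # reverse orientation: fold is inverted before the filter
    mk_direct("sugarbeet", "pea", c(1 / 5.0, 1 / 6.0, 2), c(0.01, 0.01, 0.01))
  )
  kept <- reconcile_specific(calls, direct, focal = "pea")
  expect_equal(kept, "g1")  # g2 fails direct pea/alfalfa; g3 not PEA_ONLY
  expect_error(reconcile_specific(calls, direct[1], focal = "pea"),
               "no direct contrast")
})

test_that("noise-free reconciliation returns exactly the planted set", {
  cfg <- sim_config(n_genes = 400, noise_sd_log2 = 0, seed = 25)
  truth <- generate_truth(cfg)
  design <- default_design(cfg)
  norm <- process_slides(generate_slides(truth, design, cfg))
  ind <- setNames(lapply(rhizos, function(r)
    aggregate_contrast(norm, r, "glucose")), rhizos)
  pairs <- combn(rhizos, 2, simplify = FALSE)
  direct <- lapply(pairs, function(pr)
    aggregate_contrast(norm, pr[1], pr[2]))
  calls <- classify_genes(ind, truth[c("gene_id", "replicon")])
  kept <- reconcile_specific(calls, direct, focal = "pea")
  expect_setequal(kept, truth$gene_id[truth$category == "PEA_ONLY"])
})

test_that("replicon report counts and fractions are exact", {
  calls <- data.frame(
    gene_id = sprintf("g%02d", 1:40),
    up_category = rep(c("PEA_ONLY", "NONE"), c(30, 10)),
    down_category = "NONE",
    replicon = c(rep("pRL8", 11), rep("chromosome", 29)),
    stringsAsFactors = FALSE
  )
  rep_ <- replicon_report(calls, "PEA_ONLY", "pRL8")
  expect_equal(rep_$n_category, 30)
  expect_equal(rep_$n_on_replicon, 11)
  expect_equal(round(100 * rep_$fraction), 37)

  expect_equal(replicon_report(calls, "NONE", "pRL8")$fraction, 0)
  expect_message(
    empty <- replicon_report(calls, "LEGUME", "pRL8"),
    "empty")
  expect_true(is.na(empty$fraction))

  # planted synthetic assignment is recovered exactly
  cfg <- sim_config(n_genes = 400, noise_sd_log2 = 0, seed = 26)
  truth <- generate_truth(cfg)
  calls2 <- classify_genes(indirect_contrasts(truth, cfg),
                           truth[c("gene_id", "replicon")])
  rep2 <- replicon_report(calls2, "PEA_ONLY", "pRL8")
  planted <- truth[truth$category == "PEA_ONLY", ]
  expect_equal(rep2$n_category, nrow(planted))
  expect_equal(rep2$n_on_replicon, sum(planted$replicon == "pRL8"))
})

test_that("venn regions match brute-force enumeration", {
  expect_equal(
    venn_regions(list(A = c("1", "2"), B = c("2", "3")))$count,
    c(1L, 1L, 1L))  # A&B, A-only, B-only order per expand.grid

  ids <- venn_regions(list(A = c("1", "2"), B = c("2", "3")))
  expect_setequal(ids$region, c("A", "B", "A&B"))
  expect_equal(sum(ids$count), 3)

  # identical sets: everything in the full intersection
  same <- venn_regions(list(A = c("x", "y"), B = c("x", "y"),
                            C = c("x", "y")))
  expect_equal(same$count[same$region == "A&B&C"], 2L)
  expect_equal(sum(same$count), 2)

  # three random sets vs brute-force oracle over membership patterns
  set.seed(5)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j)
      as.character(sample(30, sample(0:20, 1))))
    names(sets) <- c("A", "B", "C")
    vr <- venn_regions(sets)
    universe <- unique(unlist(sets))
    oracle_counts <- sapply(vr$region, function(reg) {
      members <- strsplit(reg, "&", fixed = TRUE)[[1]]
      sum(vapply(universe, function(u) {
        inn <- vapply(names(sets), function(s) u %in% sets[[s]], TRUE)
        all(inn[members]) && !any(inn[setdiff(names(sets), members)])
      }, TRUE))
    })
    expect_equal(vr$count, unname(as.integer(oracle_counts)))
    expect_equal(sum(vr$count), length(universe))
  }
})
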