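test_that("background correction subtracts, floors and flags", {
  slide <- data.frame(
    gene_id = c("a", "b", "c"),
    ch1_fg = c(1000, 50, 200), ch1_bg = c(100, 100, 0),
    ch2_fg = c(500, 400, 300), ch2_bg = c(100, 100, 0)
  )
  out <- background_correct(slide)
  expect_equal(out$ch1, c(900, 0.5, 200))
  expect_equal(out$ch2, c(400, 300, 300))
  expect_equal(out$flag, c(FALSE, TRUE, FALSE))
  # all-zero backgrounds leave intensities unchanged
  expect_equal(out$ch1[3], slide$ch1_fg[3])
  expect_equal(out$ch2[3], slide$ch2_fg[3])
})

test_that("loess normalization absorbs constant and additive trends", {
  set.seed(31)
  n <- 500
  A <- runif(n, 6, 14)
  ns <- make_norm_slide(rep(0.7, n), "pea", "glucose")
  ns$A <- A
  out <- lowess_normalize(ns)
  expect_lt(max(abs(out$M)), 1e-6)

  # additive offset invariance: M + c gives the same normalized values
  ns2 <- make_norm_slide(rnorm(n, 0, 0.3), "pea", "glucose")
  ns2$A <- A
  ns3 <- ns2
  ns3$M <- ns2$M + 1.23
  expect_equal(lowess_normalize(ns2)$M, lowess_normalize(ns3)$M,
               tolerance = 1e-6)

  expect_error(lowess_normalize(make_norm_slide(rnorm(5), "x", "y")),
               "at least 20")
})

test_that("loess normalization removes a planted cubic dye bias", {
  cfg <- sim_config(n_genes = 2000, noise_sd_log2 = 0,
                    dye_bias_amplitude = 0.3, seed = 13)
  truth <- generate_truth(cfg)
  design <- default_design(cfg, include_direct = FALSE)[1, , drop = FALSE]
  slide <- generate_slides(truth, design, cfg)[[1]]
  ns <- lowess_normalize(compute_ma(background_correct(slide)))
  m_true <- log2(truth$fold_pea)
  qa <- quantile(ns$A, c(0.05, 0.95))
  interior <- ns$A >= qa[1] & ns$A <= qa[2]
  expect_lt(max(abs(ns$M - m_true)[interior]), 0.05)
})

test_that("normalization agrees with an independent local-regression fit", {
  # oracle: limma's loessFit, a different local-regression implementation
  cfg <- sim_config(n_genes = 1500, noise_sd_log2 = 0.2,
                    dye_bias_amplitude = 0.3,
                    category_proportions = c(NONE = 1), seed = 17)
  truth <- generate_truth(cfg)
  design <- default_design(cfg, include_direct = FALSE)[1, , drop = FALSE]
  slide <- generate_slides(truth, design, cfg)[[1]]
  ma <- compute_ma(background_correct(slide))
  ours <- lowess_normalize(ma)$M
  oracle <- ma$M - limma::loessFit(ma$M, ma$A, span = 0.3)$fitted
  expect_lt(mean(abs(ours - oracle)), 0.05)

  # bias-free slide: normalization barely perturbs M
  cfg0 <- sim_config(n_genes = 1500, noise_sd_log2 = 0.2,
                     dye_bias_amplitude = 0,
                     category_proportions = c(NONE = 1), seed = 18)
  truth0 <- generate_truth(cfg0)
  s0 <- generate_slides(truth0,
                        default_design(cfg0, include_direct = FALSE)[1, , drop = FALSE],
                        cfg0)[[1]]
  ma0 <- compute_ma(background_correct(s0))
  expect_lt(mean(abs(lowess_normalize(ma0)$M - ma0$M)), 0.02)
})

test_that("contrast aggregation matches a textbook t-test", {
  set.seed(7)
  m <- log2(3) + rnorm(4, 0, 0.05)
  slides <- lapply(1:4, function(i)
    make_norm_slide(c(m[i], 0.2 * i), "pea", "glucose",
                    genes = c("g1", "g2")))
  res <- aggregate_contrast(slides, "pea", "glucose")
  expect_equal(res$fold_change[res$gene_id == "g1"], 2^mean(m),
               tolerance = 1e-12)
  oracle <- t.test(m)$p.value
  expect_equal(res$p_value[res$gene_id == "g1"], oracle, tolerance = 1e-9)
  expect_lt(res$p_value[res$gene_id == "g1"], 0.05)
  # fold_change = 2^mean_log2_ratio invariant
  expect_equal(res$fold_change, 2^res$mean_log2_ratio, tolerance = 1e-9)
})

test_that("zero-variance replicates follow the documented convention", {
  slides <- lapply(1:4, function(i)
    make_norm_slide(c(0, 1), "pea", "glucose", genes = c("null", "up")))
  res <- aggregate_contrast(slides, "pea", "glucose")
  expect_equal(res$fold_change[res$gene_id == "null"], 1)
  expect_equal(res$p_value[res$gene_id == "null"], 1)
  expect_equal(res$p_value[res$gene_id == "up"], 0)
  expect_true(all(res$degenerate))
})

test_that("dye-swapped slides contribute with corrected orientation", {
  s_fwd <- make_norm_slide(1.0, "pea", "glucose", genes = "g1")
  s_swp <- make_norm_slide(-1.0, "pea", "glucose", swap = TRUE, genes = "g1")
  res <- aggregate_contrast(list(s_fwd, s_swp), "pea", "glucose")
  expect_equal(res$mean_log2_ratio, 1.0)

  # orientation inversion: fold(A/B) = 1/fold(B/A)
  set.seed(8)
  slides <- lapply(1:3, function(i)
    make_norm_slide(rnorm(5), "pea", "alfalfa",
                    genes = sprintf("g%d", 1:5)))
  ab <- aggregate_contrast(slides, "pea", "alfalfa")
  ba <- aggregate_contrast(slides, "alfalfa", "pea")
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-9)
})

test_that("genes flagged in all replicates are reported flagged with p = 1", {
  slides <- lapply(1:3, function(i)
    make_norm_slide(c(2, 2), "pea", "glucose", genes = c("bad", "good"),
                    flag = c(TRUE, FALSE)))
  res <- aggregate_contrast(slides, "pea", "glucose")
  expect_true(res$flag[res$gene_id == "bad"])
  expect_equal(res$p_value[res$gene_id == "bad"], 1)
  expect_false(res$flag[res$gene_id == "good"])
})

test_that("indirect ratios derive fold, P and cross-check the direct path", {
  set.seed(9)
  a <- aggregate_contrast(lapply(1:4, function(i)
    make_norm_slide(log2(6) + rnorm(1, 0, 0.1), "pea", "glucose",
                    genes = "g1")), "pea", "glucose")
  b <- aggregate_contrast(lapply(1:4, function(i)
    make_norm_slide(log2(2) + rnorm(1, 0, 0.1), "alfalfa", "glucose",
                    genes = "g1")), "alfalfa", "glucose")
  d <- derive_indirect_ratio(a, b)
  expect_equal(d$fold_change, a$fold_change / b$fold_change,
               tolerance = 1e-9)
  expect_equal(attr(d, "numerator"), "pea")
  expect_equal(attr(d, "denominator"), "alfalfa")
  # oracle: Welch two-sample t-test on the replicate sets
  oracle <- t.test(attr(a, "replicates")[1, ],
                   attr(b, "replicates")[1, ])$p.value
  expect_equal(d$p_value, oracle, tolerance = 1e-9)

  # identical replicate sets: fold 1, p = 1
  d0 <- derive_indirect_ratio(a, a)
  expect_equal(d0$fold_change, 1)
  expect_equal(d0$p_value, 1)

  # mismatched denominators are a design error
  expect_error(derive_indirect_ratio(a, d), "same denominator")
})

test_that("zero-noise derived ratios equal the direct-contrast folds", {
  cfg <- sim_config(n_genes = 300, noise_sd_log2 = 0,
                    dye_bias_amplitude = 0, seed = 21)
  truth <- generate_truth(cfg)
  design <- default_design(cfg)
  norm <- process_slides(generate_slides(truth, design, cfg))
  pea <- aggregate_contrast(norm, "pea", "glucose")
  alf <- aggregate_contrast(norm, "alfalfa", "glucose")
  derived <- derive_indirect_ratio(pea, alf)
  direct <- aggregate_contrast(norm, "pea", "alfalfa")
  expect_equal(
    derived$fold_change[match(direct$gene_id, derived$gene_id)],
    direct$fold_change, tolerance = 0.05)
  # and both equal the planted ratio
  planted <- truth$fold_pea / truth$fold_alfalfa
  expect_equal(direct$fold_change[match(truth$gene_id, direct$gene_id)],
               planted, tolerance = 0.05)
})
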