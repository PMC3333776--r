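---
title: "Methods: rhizosphere specificity classification, colonization index and qPCR confirmation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhizosphere specificity classification, colonization index and qPCR confirmation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoclass)
```

## The scientific problem

A soil bacterium such as *Rhizobium leguminosarum* bv. *viciae* remodels
its transcriptome when it colonizes the rhizosphere — the nutrient-rich
soil layer shaped by root exudates — and does so differently around
different host plants. The analysis this package implements compares the
bacterial transcriptome in the rhizospheres of pea, alfalfa and sugar
beet against free-living glucose-grown cultures, classifies each gene as
generally rhizosphere-induced or plant-specific, asks whether specific
genes cluster on particular replicons (plasmids), and validates the
biological importance of induced genes with competitive-colonization
assays and qPCR.

Because the raw hybridizations live in public archives and are not
needed to validate the *method*, the package ships a synthetic-data
generator that emulates every input with planted ground truth. All
statements below about recovery rates and error levels are the
quantities the package's own test suite computes.

## Two-color array processing

Each hybridization compares two samples labelled with different
fluorophores on one slide. Per spot we observe foreground and local
background intensities in both channels.

1. **Background subtraction.** Corrected intensity is
   `max(fg - bg, 0.5)`. The floor (default 0.5, flag recorded) keeps
   log-ratios defined for spots where background exceeds foreground;
   flagged genes are reported, never silently dropped. Genes flagged in
   every replicate of a contrast are assigned p = 1.
2. **MA transform.** `M = log2(ch1/ch2)`, `A = (log2 ch1 + log2 ch2)/2`.
3. **Loess normalization.** Two-color arrays show a smooth
   intensity-dependent dye bias. We subtract a locally weighted
   regression of M on A: degree-2 local polynomials, tricube weights,
   iterated Tukey-biweight robustification (`stats::loess`,
   `family = "symmetric"`), span 0.3. The robustness iterations matter:
   genuinely differential genes are large-residual points and must not
   pull the fitted trend. Degree 2 tracks curved bias shapes with little
   local bias; the suite verifies that a planted cubic bias of amplitude
   0.3 log2 units is removed to within 0.05 log2 units over the interior
   90% of the intensity range, and a degenerate slide with fewer than 20
   usable spots is an error.
4. **Replicate statistics.** Dye-swapped slides have M negated, then
   per gene: `mean_log2_ratio`, `fold_change = 2^mean`, and a two-sided
   one-sample t-test of the replicate log-ratios against 0. Zero-variance
   replicate sets get the documented deterministic convention p = 1 if
   the mean is 0, else p = 0 with a degeneracy flag (the t statistic is
   undefined there). No multiple-testing correction is applied by
   default because the classification rules filter on raw P ≤ 0.05; a
   Benjamini–Hochberg column is available via `fdr = TRUE`.
5. **Indirect ratios.** Two contrasts sharing the free-living baseline
   are combined: fold ratio, mean difference, Welch two-sample t-test
   across the two replicate sets.

## Specificity classification

The elevation rule, with defaults `primary = 3`, `secondary = 2`,
`alpha = 0.05`: a gene is elevated in a rhizosphere iff its fold there
is ≥ 3 with p ≤ 0.05, or ≥ 2 with p ≤ 0.05 while some other rhizosphere
passes the 3-fold test. The elevated set maps to a category label (ALL;
PEA_ONLY, ALFALFA_ONLY, SUGARBEET_ONLY; LEGUME = pea + alfalfa;
ALFALFA_SUGARBEET; PEA_SUGARBEET; NONE). Whether the published rule
demanded p ≤ 0.05 for the *secondary* (2-fold) members is not stated;
we require it by default for symmetry with the primary call and expose
`secondary_requires_p = FALSE` for the fold-only reading.

Down-regulation: a gene is down in a rhizosphere iff fold ≤ 0.3 with
p ≤ 0.05, extended to DOWN_ALL when every other rhizosphere is ≤ 0.5
(no P requirement on the extension, matching the stated rule);
SLIGHT_DOWN when all folds sit in 0.4–0.8 without a strict down call.
If a gene satisfies both an up and a down rule across rhizospheres the
up-classification wins and a conflict flag is set, so the up and down
categories never overlap.

Reconciliation of the two independent designs: a gene is accepted as
focal-rhizosphere-specific when its indirect category is the focal
singleton *and* its direct (rhizosphere-vs-rhizosphere) fold against
each other rhizosphere is ≥ 3 with p ≤ 0.05. The combination rule is not
printed in the source; intersection is the conservative choice and is
what `reconcile_specific()` documents and does. Replicon enrichment is a
plain count/fraction report; Venn region counts are exact enumerations.

## The synthetic-data generator

The generator is the test bed: it plants a known category per gene and
builds everything downstream from it.

* **Category mixture** (defaults): 80% unchanged (NONE), 5% DOWN_ALL,
  3% ALL, 3% PEA_ONLY, 2% each ALFALFA_ONLY / SUGARBEET_ONLY / LEGUME,
  1.5% each ALFALFA_SUGARBEET / PEA_SUGARBEET. Counts are apportioned by
  largest remainder (ties by category name order), so they are
  deterministic and conserve `n_genes`.
* **Planted folds.** One member rhizosphere of each category is primary
  with fold uniform in [3.5, 30]; other members are secondary in
  [2.2, 2.9]; excluded rhizospheres and NONE genes draw folds
  log2-uniform in [0.8, 1.25]; DOWN_ALL draws in [0.1, 0.3]. The margins
  (3.5 vs the 3-fold cutoff, 2.2 vs 2-fold) keep the truth unambiguous
  under the classifier. The unchanged bulk is symmetric about ratio 1 on
  the log scale by construction — this is deliberate: loess
  normalization estimates the dye trend from the bulk, and an
  asymmetric bulk would re-centre every slide and systematically push
  the 2.2-fold secondary genes below the 2-fold cutoff even without
  noise. `none_fold_range = c(1, 1)` gives an exact null cohort for
  size/type-I studies.
* **Slides.** Per spot, mean log2 intensity A is uniform on [6, 14]; the
  true log-ratio gets the dye bias `amplitude * (4x^3 - 3x)` (Chebyshev
  cubic on A rescaled to [-1, 1], same curve for all slides of a batch)
  plus i.i.d. Gaussian log2 noise per replicate; channels are
  `2^(A ± M/2)` plus an additive uniform background (30–70). Even
  replicates are dye-swapped. Replicate counts default to 4 per
  contrast (the direct-design replication; the source used 5/3/3 for
  the indirect hybridizations — a single knob keeps the simulated
  designs balanced).
* **Noise level.** The source does not report its arrays'
  replicate noise; the default `noise_sd_log2 = 0.25` is a typical
  two-color between-replicate spread and is exposed in the config.
* **Competition counts.** Inverting the colonization-index formula, the
  expected wild-type recovery is `baseline_pct / true_rci`; per-plant
  wild-type counts are binomial draws at that rate out of `cfu_scale`
  colonies. This reproduces the study's 10:1 mutant:wild-type design
  where equal fitness yields the theoretical 100/11 = 9.1% recovery.
* **qPCR.** The planted ratio enters as a −log2(ratio) cycle offset on
  the target gene in the treatment condition; the reference gene (mdh)
  is flat; wells get Gaussian cycle noise.
* **Replicons.** Genes are placed on a chromosome and six plasmids with
  genome-like weights; pea-specific genes land on pRL8 with probability
  0.37, emulating the plasmid-borne host-specificity signal the
  pipeline is designed to surface.
* **Determinism.** Every output draws from a sub-stream seed derived
  from the single config seed and a stage label, so identical configs
  give bit-identical outputs.

What the generator does *not* emulate: spatial slide artifacts,
print-tip groups, saturation, RNA-amplification bias, and correlated
(non-Gaussian) replicate noise. Passing tests therefore demonstrate the
correctness of the computational chain and its behaviour under the
stated noise model, not robustness to every artifact of real
hybridizations.

## Competition assays and the colonization index

Per plant, the wild-type recovery percentage is
`100 * wt / (wt + mutant)` after dilution correction; plants with zero
total count are excluded with a warning, and raw plate counts below 10
trigger a low-count warning. Per mutant, recoveries are averaged across
plants (mean of percentages with SEM — matching the source's
"mean ± SEM" reporting — rather than pooling counts) and

RCI = baseline% / mean recovery%,

where the baseline is the wild-type recovery in the
wild-type-versus-wild-type control. RCI 1 means equal competitiveness;
the index is scale-invariant in counts and strictly decreasing in
recovery. Values are kept at full precision with a 2-decimal display
convention.

## qPCR confirmation

`ddct_fold()` implements the comparative-CT method: ΔCt = mean target
Ct − mean reference Ct per condition, ΔΔCt = treatment − control, fold =
E^(−ΔΔCt) with efficiency E = 2 by default (an `efficiency` argument
covers calibrated assays). The fold is invariant to constant cycle
offsets and inverts under condition-label swap.

`permutation_ratio_test()` is a generic randomization test of ratio = 1
(in the spirit of randomization-based qPCR analysis tools, not a
re-implementation of any of them): condition labels are reallocated
independently within the target and the reference wells — both pools are
exchangeable under the null — and the two-sided p is the fraction of
reallocations with |ΔΔCt| at least the observed. All reallocations are
enumerated when their number fits in `n_permutations` (at triplicates:
C(6,3)² = 400, so the test is exact there); otherwise reallocations are
sampled with the +1 correction. Note the granularity at triplicates:
the most extreme target split has probability 2/20, so attainable
p-values near 0.05 are coarse and a large effect at n = 3 lands at
p ≈ 0.05–0.07; four replicates per condition resolve below 0.05.

## Numerical conventions and edge cases

* Log base 2 throughout; down-regulation reported as folds < 1.
* `fold_change = 2^mean_log2_ratio` holds to 1e-9 by construction.
* Background floor 0.5; loess span 0.3; both exposed as arguments.
* Zero-variance and all-flagged genes follow the deterministic
  conventions above rather than propagating NaN.
* Venn regions, category partitions and largest-remainder counts are
  exact integer computations.

## Problem sizes used by the test suite

The packaged checks run the full chain at 300–800 genes for exact
zero-noise round-trips, and at 5,000 genes × 4 replicates for the
statistical properties: category accuracy ≥ 0.95 at noise SD 0.25,
null-cohort type-I error 0.05 ± 0.01 at P ≤ 0.05, dye-bias removal
within 0.05 log2 units, colonization-index recovery within three
binomial standard errors, and exact ΔΔCt round-trips. These sizes give
stable Monte-Carlo estimates while keeping a full run around a minute.

## Known limitations

* The classifier's category vocabulary is tied to the three-plant
  design; other condition sets fall back to generic labels.
* The t-test convention stands in for the original commercial
  analysis software, whose exact P-value computation is undocumented;
  agreement is therefore by statistical convention, not reconstruction.
* The permutation qPCR test is coarse at triplicates (see above).
* Indirect-vs-direct reconciliation is the intersection rule only.
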