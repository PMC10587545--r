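---
title: "Window-based Poisson modelling of recurrent SCNA hotspots"
author: "scnaScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based Poisson modelling of recurrent SCNA hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnaScan)
```

## The model and its assumptions

Somatic copy number alterations (SCNAs) are contiguous gains or losses of
DNA, each delimited by double-strand-break repair events. Across a tumour
cohort, loci where segments recur unusually often are candidates for
functional relevance. scnaScan formalises recurrence per fixed-width
genomic window: for window $w$ and sample $s$, the count $x_{ws}$ of the
sample's segments overlapping the window is modelled as
$x_{ws} \sim \mathrm{Poisson}(\lambda_w)$, i.i.d. over samples. The
log-likelihood
$\ell(\lambda) = \sum_s \left[x_{ws}\log\lambda - \lambda - \log x_{ws}!\right]$
is maximised by the sample mean; `estimateLambdaMLE()` exposes both the
closed form and a numerical maximiser (`stats::optimize`, tolerance
$10^{-10}$) and the package requires them to agree to $10^{-6}$ relative —
a dual-route guard against silent likelihood bugs.

The assumptions worth keeping in mind:

* **Independence over samples.** Tumours from the same patient or shared
  germline artefacts would violate this; input is expected to be one
  record set per patient (sample barcodes are truncated to patient level
  on read, `harmonizeSampleIds()`).
* **Homogeneous rate within a window.** A 1 Mb window mixes loci; a sharp
  breakpoint cluster and a uniformly elevated megabase are not
  distinguished.
* **No overdispersion correction.** Real cohorts show more variance than
  Poisson; the estimator of the mean rate remains valid, but no
  significance is attached to individual $\hat\lambda$ values. Hotspot
  calling is a rank-based top-tail rule, not a test, precisely so the
  mis-specification affects only the interpretation of the tail fraction.
* **Every cohort sample counts.** Zero-segment samples enter the
  denominator; dropping them would bias $\hat\lambda$ upward.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| window size | 1,000,000 | bp | the published operating point; 2,897 windows on the hg19 autosomes |
| width threshold | 100,000 | bp | splits focal (Set2, ≤ 100 kb) from large-scale (Set1, > 100 kb) segments; boundary value goes to Set2 (strict `>` for Set1) |
| hotspot fraction | 0.05 | — | top tail of $\hat\lambda$; round-half-up(0.05 × 2,897) = 145 windows |
| enrichment alpha / top-k | 0.05 / 10 | — | BH-adjusted significance filter, then ratio-ranked top ten |
| burden segment set | all | — | whether burden counts all segments or one width class is configurable; pooled counts are the default because the width split is an analysis lens, not a biological partition of burden |

Chromosomes X and Y are excluded from the default analysis set (sex-mixed
cohorts confound copy number there); a custom `chrom.sizes` file widens
the set. Coordinates are handled as GRanges (1-based, closed) internally;
SEG input declares its dialect (`1based` TCGA convention by default) and
BED is converted on read. The published overlap rule — segment start
before window end and segment end after window start, on half-open
intervals — is exactly "the closed intervals share at least one base", so
`findOverlaps()` implements it verbatim; abutting intervals never count,
which the tests pin down at single-base resolution.

## Numerical and procedural choices

* **Hotspot count** is round-half-up(fraction × N). Ceiling gives the
  same 145 at the published operating point; round-half-up is declared to
  fix behaviour on all other inputs.
* **Ties at the hotspot cut** break by genome order (smaller window
  index). Determinism matters more than any claim about which tied window
  is "more" recurrent.
* **$\log_2\lambda$ summaries** drop $\lambda = 0$ windows with a message
  rather than pseudo-counting; a pseudo-count would silently invent a
  rate scale for empty windows.
* **Segment width** is the half-open difference (GRanges `width()`),
  self-consistent with the I/O conversion; the 100 kb comparison is
  `> threshold` for Set1.
* **Median split**: samples sorted by burden with sample-id tie-break;
  odd cohorts put the middle sample in Low. **Tertiles**: rank-based
  contiguous thirds, remainders assigned from Low upward (332 → 111/111/
  110). Rank-based cutting cannot produce empty groups under heavy ties,
  unlike value-quantile cuts.
* **Welch's t** is the default two-group test (Student's by flag):
  burden groups have no variance-equality guarantee. Degenerate groups
  are flagged `testable = FALSE` instead of raising, so gene sweeps
  survive constant rows.
* **Enrichment** is the upper-tail hypergeometric with BH adjustment.
  The web service the analysis would otherwise lean on applies a
  proprietary multiple-testing procedure; BH is transparent, standard and
  testable, so term-for-term agreement with that service is not a goal.
  The default universe is the annotation's gene set after family
  filtering — the natural frame when the query itself is family-filtered.
* **Family filter** patterns are anchored and case-sensitive:
  `OR<digit><letter...><digit>` (olfactory nomenclature — `ORC1`/`ORAI1`
  survive), `TAS1R`/`TAS2R`, `IGH*`, `IGK*`, `IGL*`, `HLA-*`, plus any
  user-supplied exact-symbol list.
* **Set1/Set2 are independent runs** of the same pipeline, and the pooled
  run is emitted alongside; no cross-set union of hotspots is taken,
  since per-set reporting is the only unambiguous reading.

## What the synthetic generator emulates

`simulateCohort()` draws, per (window, sample), a Poisson count at the
planted placement rate, then places that many segments uniformly within
the window with widths from a two-class log-uniform mixture (60 % in
1–100 kb, 40 % in 100 kb–1 Mb by default) truncated at the chromosome
end. Expression at designated genes gains an additive shift (default
0.5 units on an 8 ± 1 baseline) for the high-burden half of the cohort;
survival times are exponential with per-burden-tertile hazards (default
multipliers 1 / 0.75 / 0.5 of a 1/730-per-day baseline, i.e. hazard ratio
2 between Low and High, with independent exponential censoring at
1/1825 per day, roughly 30 % censoring). Four decoy genes named from the
hyper-polymorphic families are planted so the filter has real work in
integration runs. Each output stratum (segments, genes, expression,
survival) draws from its own RNG stream derived from the master seed, so
the draws of one never shift another's.

**Placed versus effective rates.** Because widths are independent of the
placement window, segments cross window boundaries — deliberately, to
exercise the multi-window counting semantics. Consequently the rate of
segments *overlapping* a window exceeds the rate *placed* in it: each
upstream window $u$ contributes $\lambda_u \cdot P(\text{a segment
starting uniformly in } u \text{ reaches this window})$, a probability
with a closed form under the log-uniform mixture.
`expectedWindowRates()` computes this exactly and `truthTable()` emits
both numbers per window; recovery is scored against the effective rate,
which is the correct expectation of the estimator under the generator
(the first window of each chromosome has no upstream source, so there the
two coincide — a property the tests use to check marginal Poissonness
without spillover). A Monte-Carlo run at 3,000 samples verifies the
closed form against observed means within a Bonferroni-adjusted 4-SE
band.

What the generator does **not** emulate: real STAD karyotypes, arm-level
and whole-genome-doubling structure, purity/ploidy and SNP6 probe noise,
overdispersion of counts, gene-length and GC biases, or correlated
expression networks. Passing tests therefore demonstrate correctness of
the estimator, the counting semantics and the downstream statistics under
the stated model — not that real cohorts satisfy that model.

## Problem sizes

The default simulated cohort is 300 samples on three 10 Mb chromosomes
(30 windows at 1 Mb) — large enough that $\mathrm{SE}(\hat\lambda) =
\sqrt{\lambda/n} \approx 0.08$ at the planted hotspot rate 2.0, so
recovery within 3 SE is a sharp check, and small enough that 200-replicate
recovery, calibration and power studies (the sizes used by both the test
suite and `scripts/acceptance.R`) complete in a couple of minutes. With
the planted 0.5-unit expression effect at $n = 150$ per median group, the
Welch test's theoretical power is ≈ 0.99; with hazard ratio 2 across
tertiles of 100, log-rank power is ≈ 0.95 — both comfortably above the
0.9 the calibration study asserts, while null rejection rates sit within
Monte-Carlo error of 0.05.

## Known limitations

* $\hat\lambda = 0$ windows carry no log-scale representation; cohorts
  much smaller than a few dozen samples will produce many of them.
* Hotspot calling is purely rank-based; no FDR or significance is
  attached to a hotspot, and the 5 % tail is a convention, not a test.
* The enrichment stage assumes symbol-keyed gene sets; no ontology
  traversal or redundancy pruning is performed.
* No Cox regression or covariate adjustment in the survival stage; the
  log-rank comparison is marginal.
* Segment-level significance of individual alterations (GISTIC-style
  scores), arm-level calls and overdispersion corrections are out of
  scope.
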