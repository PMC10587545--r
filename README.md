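# scnaScan

Recurrent somatic copy number alterations (SCNAs) mark genomic loci where
double-strand breaks are repeatedly resolved into gains and losses across a
tumour cohort. scnaScan finds those recurrence **hotspots** from ordinary
SEG-format segment tables: it models the number of SCNA segments of each
sample overlapping a fixed-width genomic window as Poisson, estimates the
per-window rate λ by maximum likelihood across the cohort, and calls the
top tail of λ genome-wide as hotspots. Around that core it provides the
standard downstream steps of a cohort SCNA study — gene annotation with
hyper-polymorphic-family filtering, local hypergeometric term enrichment,
SCNA-burden association tests, and Kaplan–Meier survival stratification —
plus a seeded synthetic-cohort generator so the whole pipeline is testable
without any data download. It is aimed at cancer-genomics analysts who have
segment calls (TCGA SNP6-style SEG, CCLE exports) and want a reproducible,
scripted hotspot analysis.

## The model

For window *w* and sample *s*, let *x<sub>ws</sub>* be the number of SCNA
segments of *s* overlapping *w* (a segment overlaps a window when its start
lies before the window end and its end after the window start; a segment
spanning *k* windows counts once in each). The counts in a window are
modelled as i.i.d. Poisson(λ<sub>w</sub>) over the cohort, and λ<sub>w</sub>
maximizes

ℓ(λ) = Σ<sub>s</sub> [ x<sub>ws</sub> log λ − λ − log(x<sub>ws</sub>!) ],

whose closed-form maximizer is the sample mean; a numerical maximizer is
exposed as a cross-check and agrees to < 1e−6 relative. Windows are 1 Mb
tiles of the hg19 autosomes (2,897 windows; chrX/chrY excluded), segments
are analysed both pooled and split at 100 kb width (Set1 > 100 kb,
Set2 ≤ 100 kb), and hotspots are the round-half-up top 5 % of λ values —
145 of 2,897 windows — with ties at the cut broken by genome order.

## Worked example

A synthetic 300-sample cohort on three 10 Mb chromosomes, with two planted
hotspots (rate 2.0 against background 0.2):

```r
library(scnaScan)

cfg <- simulationConfig(nSamples = 300, seed = 42)
co  <- simulateCohort(cfg)

windows <- tileWindows(cfg$chromSizes, cfg$windowSize)
wc <- countWindowOverlaps(co$segments, windows, samples = co$burden$sample_id)
wc <- estimateLambda(wc)
wc
#> WindowCounts: 30 windows x 300 samples (width class: all)
#>   total counted overlaps: 3298
#>   lambda estimated; max lambda_hat = 2.09

hs <- annotateGenes(callHotspots(wc, fraction = 0.05), co$genes)
hs
#> HotspotSet: 2 hotspots from 30 windows (top 5.0%)
#>   minimum hotspot lambda: 1.867
#>   annotated genes: 5 before / 4 after family filtering

subset(lambdaTable(hs), is_hotspot)[, c(1:4, 6, 9)]
#>    chrom   start     end window_index lambda_hat rank
#> 5   chr1 4000001 5000000            5   2.090000    1
#> 17  chr2 6000001 7000000           17   1.866667    2
```

Both planted hotspots (windows 5 and 17) are recovered; their λ̂ of 2.09
and 1.87 estimate the planted rate 2.0 plus a small, analytically known
spillover from segments that start upstream and cross the window boundary
(`expectedWindowRates(cfg)` gives the exact expectation, ≈ 2.03 here).
The minimum hotspot λ (1.867) is the threshold line a Manhattan plot of
`manhattanData(hs)` would draw.

Downstream, burden groups associate with the planted expression effect and
survival hazards:

```r
grp <- splitByMedian(co$burden)$median_group
e   <- co$expression["G001", co$burden$sample_id]
groupTTest(e[grp == "High"], e[grp == "Low"])
#>      mean1    mean2        t      p_value  n1  n2 testable
#> 1 8.475929 7.891767 5.502551 8.187263e-08 150 150     TRUE

tert <- tertileGroups(co$burden$burden, co$burden$sample_id)
km <- kmLogrank(co$clinical$time, co$clinical$event, tert)
#> log-rank chisq: 9.42, df: 2, p = 0.0090
```

The High-burden half is shifted by ≈ 0.58 expression units (planted effect
0.5), and the burden tertiles separate in survival (planted hazard ratio 2
between Low and High), both detected at p < 0.05.

File-based runs use `runConfig()`/`runPipeline()` (or the thin wrapper in
`inst/scripts/scna-pipeline.R`), which write every stage's TSV — per-window
λ tables, hotspot-gene lists, enrichment, burden, association, KM curves —
and a JSON manifest into the output directory.

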