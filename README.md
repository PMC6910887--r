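# SNPloidy

Triploidy cannot be seen by read-depth (CNV-seq) analysis of low-coverage
whole-genome sequencing — every chromosome is amplified equally — but it
leaves a clear fingerprint in allele fractions. At a heterozygous SNP the
*mutation ratio* (MR), the fraction of reads carrying the alternate
allele, concentrates near 1/2 in a diploid but near 1/3 (AAB) or 2/3
(ABB) in a triploid. SNPloidy classifies 2–3x WGS samples — typically
products-of-conception (miscarriage) tissue — as diploid or triploid from
that fingerprint, and reuses the same per-site heterozygosity to scan for
uniparental disomy (UPD). It is aimed at labs running LC-WGS miscarriage
or prenatal screening pipelines who already have called variants with
allelic depths.

## Method in brief

Candidate sites are common panel SNPs (population AF > 5%) with ≥ 10
reads; heterozygosity is observational (both alleles covered). Counts of
candidate MRs in the closed intervals [0.28, 0.38], [0.45, 0.55],
[0.62, 0.72], normalised to ordinates y₁, y₂, y₃ summing to 1, are
interpolated exactly by a parabola *y = ax² + bx + c*:

    a = 18 (y₁ − 2y₂ + y₃),   b = 3 (y₃ − y₁) − a,   c = y₂ − a/4 − b/2

A sample is triploid when the parabola opens upward (*a* > 0) with its
symmetry axis −*b*/2*a* in [0.45, 0.55]; diploid when it opens downward.
The side-to-centre ratio r = (n⅓ + n⅔)/n½ satisfies
a = 18 (r − 2)/(r + 1), so r = 2 is the exact decision boundary, and a
within-batch Z test on r serves as auxiliary evidence. The UPD scanner
tiles each chromosome into 1-Mb bins and calls runs of bins whose
heterozygous-SNP frequency is ≤ 5% (LOH consistent with isodisomy).
See the vignette (`vignettes/snp-based-ploidy-screening.Rmd`) for the
full model, parameter rationale, and limitations.

## Worked example

No external data is needed — the package ships a generative simulator
that emits exactly what the pipeline consumes (per-site allele depths at
panel positions, plus the panel itself):

```r
library(SNPloidy)

sim  <- simulateSample(simConfig(ploidy = "triploid", sex = "XXY",
                                 seed = 7))
call <- callPloidy(sim$sites, sim$panel, sampleId = "POC_01")
call
#> PloidyCall for POC_01
#>   verdict: triploid
#>   ratio (1/3+2/3)/(1/2): 2.3257
#>   parabola a = 1.7629, axis = 0.5033
#>   z = NA; candidate het sites = 10426
```

The ratio 2.33 is above the analytic cutoff of 2, equivalently *a* > 0,
and the axis sits in [0.45, 0.55]: a triploid call. A batch adds the
Z test and can be scored against the simulation truth:

```r
b   <- simulateBatch(5, 1, simConfig(nSitesPerChrom = 1500L), seed = 11)
res <- callPloidyBatch(b$samples, b$panel)
res$table[, c("sampleId", "ratio", "a", "axis", "z", "verdict")]
#>   sampleId ratio      a  axis       z  verdict
#> 1  DIP_001 0.798 -12.03 0.502 -0.0998  diploid
#> 2  DIP_002 0.814 -11.76 0.497  0.2458  diploid
#> 3  DIP_003 0.872 -10.84 0.500  1.4784  diploid
#> 4  DIP_004 0.786 -12.23 0.504 -0.3515  diploid
#> 5  DIP_005 0.743 -12.98 0.501 -1.2729  diploid
#> 6  TRI_006 2.402   2.13 0.506 34.1228 triploid

evaluateBatch(res$table, b$truth)$metrics
#> sensitivity specificity    accuracy
#>         100         100         100
```

Real data enter through `readVcfSites()` (VCF with per-sample AD) or
`readSiteTable()` (TSV), with the panel from `readPanel()`. The UPD scan
is `callUPD(binHSF(sites, panel))`; QC guards are `xFractionCheck()`
(maternal-contamination flag from the X read share) and
`depthTitration()` (how little coverage is enough). A thin command-line
front end with `call`, `batch`, `upd`, `simulate`, `titrate` and
`evaluate` subcommands is at `inst/scripts/snp-ploidy.R`.

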