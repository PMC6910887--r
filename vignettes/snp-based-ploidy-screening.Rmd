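---
title: "SNP-based triploidy and UPD screening from low-coverage WGS"
author: "SNPloidy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-based triploidy and UPD screening from low-coverage WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SNPloidy)
library(GenomicRanges)
```

## The problem

Triploidy (69,XXX / 69,XXY / 69,XYY) is among the most common chromosomal
abnormalities in early miscarriage. Read-depth (CNV-seq style) analysis of
low-coverage whole-genome sequencing cannot see it — every chromosome is
amplified equally — but allele fractions can. At a heterozygous SNP, a
diploid carries one copy of each allele, so the fraction of reads bearing
the alternate allele (the *mutation ratio*, MR — the low-coverage analogue
of the B-allele fraction) concentrates near 1/2. A triploid heterozygote is
AAB or ABB, so its MR concentrates near 1/3 or 2/3 instead. This package
turns that signal into a per-sample verdict, and reuses the same
per-site heterozygosity information to scan for uniparental disomy (UPD).

## The classifier

For each sample:

1. **Candidate selection.** Sites must match a common-SNP panel (standing in
   for dbSNP + 1000 Genomes) on position and alleles, have population
   alternate-allele frequency > 5% (`minPanelAF`), and carry at least 10
   reads (`minTotalDepth`). Heterozygosity is *observational* — both
   alleles supported by at least one read — because diploid-model genotype
   calls are unreliable in triploids. Sex chromosomes are excluded from
   the MR analysis by default (`excludeChroms`): X heterozygotes are
   diploid-like in XXY and absent in XY/XYY, so they only dilute the
   signal (see *Design choices*).
2. **Interval counts.** MRs of candidate heterozygous sites are counted in
   three closed intervals: the 1/3 interval [0.28, 0.38], the 1/2 interval
   [0.45, 0.55] and the 2/3 interval [0.62, 0.72]. The intervals are
   disjoint, so no site is counted twice; MRs outside all three count only
   toward the candidate total.
3. **Exact quadratic.** The three counts, normalised to sum to one
   ($y_i = n_i / \sum n$), define points $(1/3, y_1)$, $(1/2, y_2)$,
   $(2/3, y_3)$. The unique interpolating parabola $y = ax^2 + bx + c$ has
   closed-form coefficients (equally spaced abscissae, $h = 1/6$):
   $$a = 18\,(y_1 - 2y_2 + y_3),\qquad b = 3\,(y_3 - y_1) - a,\qquad
     c = y_2 - a/4 - b/2,$$
   with symmetry axis $-b/2a$. There is no iterative fitting and no
   tolerance knob; a three-point least squares would return exactly the
   same coefficients (a test asserts this against an independent
   Vandermonde solve).
4. **Verdict.** Triploid iff the parabola opens upward ($a > 0$) *and* the
   axis, rounded to 2 decimals, lies in [0.45, 0.55] (with a small
   configurable slack, below). Downward ($a < 0$) means diploid. $a = 0$
   exactly is degenerate and reported inconclusive, never diploid.
5. **Ratio statistic and Z test.** The side-to-centre ratio
   $r = (n_{1/3} + n_{2/3}) / n_{1/2}$ satisfies, under sum normalisation,
   $$a = 18\,\frac{r - 2}{r + 1},$$
   so $a > 0 \iff r > 2$: the ratio cutoff of 2 and the opening-direction
   rule are the *same* classifier. Within a batch, each sample's $r$ is
   standardised against a reference mean/SD as auxiliary evidence
   ($|z| \ge 3$ flags, never overrides). The robust default excludes
   samples with $r > 2$ from the reference so triploids cannot mask
   themselves.

### Parameters that matter

| parameter | default | why |
|---|---|---|
| `minPanelAF` | 0.05 | common SNPs only; rarer sites are mostly sequencing artefacts at 2–3x |
| `minTotalDepth` | 10 reads | MR of a 10-read site has SD ≈ 0.16; fewer reads cannot resolve 1/3 vs 1/2. Applied to depths as given in the input |
| MR intervals | [0.28,0.38], [0.45,0.55], [0.62,0.72] | ±0.05 around the expected modes; disjoint by construction |
| `axisLo`/`axisHi` | 0.45 / 0.55 | a genuine two-mode (1/3 + 2/3) pattern has its vertex near 0.5; a one-sided bump does not |
| `axisSlack` | 0.01 | confirmed triploids occur with a printed axis of 0.56; the slack keeps them positive while flagging `axis_out_of_range`. Strict mode: `axisSlack = 0` |
| `minSites` | 1000 | below this the interval counts are too noisy for a conclusive verdict; the sample fails safely as `inconclusive` |
| `zFlagThreshold` | 3 | auxiliary only; no published threshold exists |

The ratio statistic is undefined when $n_{1/2} = 0$ (sample flagged
inconclusive). Samples whose ratio falls within `intermediateBand`
(default ±0.1) of the boundary 2 get an `intermediate_counts` flag —
intermediate patterns are what mosaicism or heavy contamination produce,
and this method only flags them, it does not resolve them.

## The UPD scan

The same per-site data, binned: each chromosome is tiled with 1-Mb bins
and the heterozygous-SNP frequency (HSF) of a bin is the fraction of its
*informative* sites — covered panel sites passing the depth filter — that
look heterozygous. Covered sites (not all panel sites) form the
denominator, otherwise poorly covered bins would masquerade as LOH. Bins
are coloured green (HSF > 5%), pink (HSF ≤ 5%: LOH consistent with
isodisomy; an HSF of exactly 0 is included), yellow (fewer than
`minInformative = 20` informative sites: unreportable), or gap (≥ 50%
overlap with a declared assembly gap).

A chromosome whose informative bins are ≥ 90% pink yields a
whole-chromosome call; otherwise maximal runs of ≥ 5 consecutive pink bins
(one yellow/gap interruption tolerated; green always ends a run) are
reported as segmental calls. A whole-chromosome call additionally requires
at least `minRun` informative bins, so a nearly-unmappable contig cannot
produce a call from noise. Without parental genotypes isodisomy and
simple LOH are indistinguishable, and the report wording says
"consistent with UPD" accordingly.

Two scan-specific choices:

* **Heterozygote definition (`hetMinReads = 2`).** The classifier can
  afford the loose both-alleles-covered definition because its MR
  intervals ignore error-driven MRs near 0 or 1. The scan cannot: at mean
  depth 15 and error rate 0.002, a single-read heterozygote definition
  makes ~3% of truly homozygous sites look heterozygous, which pushes an
  isodisomic bin's HSF right at the 5% boundary. Requiring two supporting
  reads per allele drops the error-driven rate to ~4×10⁻⁴ while keeping
  >99.9% of true heterozygotes at that depth.
* **`minInformative = 20`** makes a truly heterozygous bin (HSF ≈ 30–50%)
  statistically separable from a pink bin (≤ 5%) at the binomial level.

## QC guards

**Maternal-cell contamination.** Admixed maternal (46,XX) cells pull
triploid MRs toward diploid values — the classifier's blind spot, risking
false negatives. The guard uses the X chromosome: it computes the
X:autosome per-site depth ratio (on panel-matched sites *without* the
analysis depth filter, which would censor the lower-depth X of a male and
bias the ratio toward 1), infers the apparent sex from the X
heterozygosity rate, and flags contamination when the observed ratio is
inconsistent — beyond a relative tolerance of 0.25 — with *both* the
pure-XX expectation (1.0) and the pure-XY expectation (0.5). A male fetus
with substantial female contamination sits between the two (e.g. 0.65 at
30% contamination) and is caught; a pure sample of either sex is not.
The flag is qualitative, as a screening guard should be; no maternal
fraction is estimated. The tolerance implies the guard reacts to
male-fetus contamination above roughly 25%; milder contamination shows up
earlier in the `intermediate_counts` flag.

**Depth titration.** `depthTitration()` simulates replicate diploid
samples across target depths and reports the mean, SD and coefficient of
variation of the ratio statistic per depth. Binomial read-sampling noise
shrinks with depth, so the CV of the ratio is non-increasing in depth and
the curve stabilises by roughly 3–5x — the basis of the recommendation
that ~3x coverage suffices. The CV, not the raw SD, is the dispersion
measure because the mean ratio itself shifts with depth: at very low
depth, few read-count fractions can land in the side intervals at all
(e.g. no fraction with denominator < 6 lies in [0.28, 0.38]), so the
titration uses its own depth filter (`minTotalDepth = 4`) and the mean
ratio climbs toward its asymptote as depth grows. The `z` column
standardises each depth's mean ratio against the replicate spread at the
deepest depth — a convention this package defines for itself, since the
published curve does not state its reference.

## The simulator

`simulateSample()` generates exactly what the method consumes: per-site
ref/alt read depths at panel positions.

* Synthetic genome: four 100-Mb autosomes + chrX, 5000 panel sites per
  chromosome. These sizes make a bin hold ~50 informative sites at depth
  15, comfortably above `minInformative`, while keeping simulation cheap.
* Panel AF ~ Uniform(0.05, 0.95). The lower bound is the panel frequency
  filter. The symmetric range matters: alternate-allele frequencies
  skewed low would make AAB heterozygotes far outnumber ABB
  ($3p(1-p)^2$ vs $3p^2(1-p)$ under Hardy–Weinberg), dragging the fitted
  axis far above 0.5 — whereas confirmed triploids show axes within a few
  hundredths of 0.5. A symmetric spectrum reproduces that behaviour;
  real common-SNP panels are approximately symmetric in ref/alt at these
  frequencies.
* Genotypes: Hardy–Weinberg at the site's AF for the sample's copy number
  (autosomes: ploidy; X: 2/1/3/2/1 for XX/XY/XXX/XXY/XYY). Depth:
  Poisson, mean 15 by default (the titration shows ≥3x suffices; 15
  represents a comfortable study-scale coverage after the panel depth
  filter). X depth scales with X copy number relative to autosomes.
* Reads: alternate reads are Binomial(depth, p) where p is the
  depth-weighted mixture of the fetal allele fraction, an independently
  drawn maternal diploid genotype (weight `maternalFraction`), and a
  mosaic subpopulation of the other ploidy (weight `mosaicFraction`,
  derived from the same zygote by dropping/duplicating one homologue);
  a symmetric error rate ε = 0.002 is applied last, so homozygous sites
  show MRs near ε.
* UPD regions force fetal homozygosity (isodisomy), with heterozygosity
  arising only through ε.

What it does **not** model — and hence what passing tests do not show
about real data: GC/mappability bias, mapping artefacts, strand bias,
genotype-calling error beyond the symmetric ε, linkage between maternal
and fetal genotypes (the mother is drawn independently of the fetus's
inherited allele), and real AF spectra. The simulator validates the
*statistical machinery*, not the upstream bioinformatics.

## Numerical choices and degenerate inputs

* The quadratic is interpolated in closed form; the only numerical
  subtlety is the sign of $a$ when the ratio is exactly 2, where floating
  arithmetic leaves $|a| \sim 10^{-16}$. Tests snap $|a| < 10^{-12}$ to
  zero; the classifier reports $a = 0$ exactly as inconclusive.
* Zero-depth sites are retained at parse time and rejected only by the
  explicit depth filter; `mutationRatio()` refuses zero-depth input
  loudly rather than returning NaN.
* All interval membership is closed on both ends; bins are 0-based
  half-open internally and in BED output, 1-based in VCF/site tables.
* Reports serialise deterministically (fixed key order, full-precision
  numbers), so identical input and configuration give byte-identical
  output.

## Problem sizes used in the test-suite experiments

The packaged experiments run at a reduced scale chosen to keep the full
suite fast while leaving each check statistically decisive: batches of
50 diploid + 8 triploid samples with ~4000–6000 candidate heterozygous
sites per sample (the published experiment used 213 + 8 samples at ~60 M
read pairs); 100 replicates for UPD recovery; 50 replicates per depth for
the titration; 10⁴ random count triples for the algebraic properties.

## Known limitations

* Near-triploid karyotypes (68,XX; 68,XXY,−21) are indistinguishable from
  triploidy by this statistic and are reported as triploid.
* Mosaicism produces intermediate interval counts; the method flags
  (`intermediate_counts`) but does not resolve them, and heavy mosaicism
  can be missed entirely.
* The UPD scan sees isodisomy only; heterodisomy requires parental
  genotypes. Segments are reported as coordinates, not cytobands.
* The contamination guard is insensitive below ~25% admixture for male
  fetuses and blind for female fetuses (XX contaminating XX leaves the X
  share unchanged).
* The X-share and X-heterozygosity logic assumes a single X-named
  chromosome (`qcConfig(xChrom=)`).
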