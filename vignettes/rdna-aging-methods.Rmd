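---
title: "Models and methods for age-dependent rDNA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for age-dependent rDNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rDNAge)
```

## The measurement problem

The ribosomal RNA gene in mouse is a tandem array of roughly 43 kb units —
the 45S pre-rRNA gene (processed into 18S, 5.8S and 28S) plus an intergenic
spacer — with hundreds to over a thousand copies per cell. Because the
locus is multicopy and recombinogenic, three things vary with age that a
single-copy locus would not show: the copy number itself (and its
cell-to-cell dispersion), the fraction of copies in particular chromatin or
methylation states, and the fraction of copies carrying a sequence variant
at a given position. Every readout in this package is therefore a
*population statistic over repeat copies*, and every estimator below is
shaped by that fact.

## Copy number

**ddPCR.** Distributing template copies over $N$ droplets at random gives a
per-droplet occupancy that is binomial, and Poisson in the practical limit.
From the positive fraction $q$, the mean copies per droplet is
$\lambda = -\ln(1-q)$; `ddpcr_lambda()` propagates the binomial standard
error of $q$ through the same transform for a 95% CI, and refuses a
saturated assay ($q = 1$), where $\lambda$ is undefined. Duplexing against
a single-copy reference gene at 2 copies per diploid cell converts
concentration to copies per cell without requiring an input-mass estimate:
$C = 2\,\lambda_t/\lambda_r$. The reference channel is the precision
bottleneck (its $\lambda$ is ~100-fold smaller), which is why the analysis
scripts average replicate assays.

**Single-cell qPCR.** The standard curve is ordinary least squares of Cq on
$\log_{10}(\text{copies})$; its slope $m$ implies the amplification
efficiency $E = 10^{-1/m}$ ($m \approx -3.32$ at perfect doubling).
Inversion is exact: `qpcr_copies_single_cell()` composed with the noise-free
simulator is the identity to floating-point precision, which the tests
assert at $10^{-9}$ relative error. A zero-copy well produces no
amplification; we signal that as `NA` Cq and report 0 copies with a flag,
never a finite cycle. Per-mouse summaries use the sample SD ($n-1$) in
CV = SD/mean; a one-cell mouse gets `NA` dispersion, not zero.

**WGS read fraction.** If a cell has $C$ copies of a $u$ bp unit in a
genome with $G$ bp outside the array, the expected rDNA read fraction is
$f = Cu/(G + Cu)$ — the array inflates its own denominator. The default
("self-consistent") estimator inverts this exactly,
$C = fG/((1-f)u)$; a "simple" mode $C = f \cdot G_\text{total}/u$ is also
exposed because published estimates rarely state which convention was
used, and both constants ($G$, $u$) are arguments rather than constants
baked in.

## Mutation rates and age-differential sites

The per-position *mutation rate* here is a variant-copy frequency across
the repeat array: non-reference bases plus insertions plus deletions over
depth. Three filters make it usable on a multicopy locus:

* **Fixed differences** (rate > 0.9) are sites where the amplified copies
  simply differ from the reference assembly; they carry no age signal and
  are excluded everywhere.
* **The artifact threshold** is learned, not assumed: the maximum
  per-position rate observed on a single-copy control gene (ATP5b) bounds
  what PCR and sequencing error can produce, and only |group-mean
  difference| above that bound counts.
* **Group separation**: a site additionally passes only if the lowest rate
  in the higher group exceeds the highest rate in the lower group. The
  published criterion is stated only as a threshold screen; we add
  separation because with two samples per group a single outlier mouse can
  otherwise clear the threshold alone. The flag is switchable
  (`require_separation = FALSE`) for sensitivity analyses.

Differences are signed (old mean − young mean) and screened by absolute
value — young-high sites are real calls (position 3094 in the default
variant table is one). 28S positions conserved in yeast are annotated from
a fixed two-entry lookup (28S 4614 → 25S 3295, 3291 → 2131); the map
is deliberately static data, not an alignment.

**Reporting rounding.** Group means are printed half-up at 3 decimals
(0.4185 prints as 0.419), while the printed difference applies the
statistical round-half-even convention to the full-precision difference
(0.0345 prints as 0.034). The mixed rule is deliberate: means of two
3-decimal rates land on exact halves, and resolving those halves upward
while keeping differences at the R default is the only combination we
found that reproduces the conventional presentation of such tables
consistently across signs. Full-precision values are always retained in
the unformatted call objects; rounding happens only at report time.

**Hot spots.** Window sums use non-overlapping 20 bp windows anchored at
position 1 (the alternative — sliding windows — is not what "summed every
20 bp" describes most plainly, and tiling keeps sums additive across
samples). Only above-threshold, non-fixed rates contribute; a final
partial window is kept and flagged rather than dropped.

## The digest model

A restriction site at position $p$ cuts between $p-1$ and $p$ on the
linear unit, so fragments are maximal runs between cuts and always tile the
unit — a conservation property the tests assert on random site sets. The
default geometry places BamHI-1, NdeI, and an optional internal BamHI-2 so
the probe-detected BamHI–NdeI fragment is 4,000 bp without BamHI-2 and
2,400 bp with it, with one methylation-sensitive SacII site inside the
probe fragment.

Band intensity is modeled as proportional to the number of
probe-hybridizing copies, *not* fragment length: the probe is short, so
each fragment binds one probe regardless of its size. Copies partition
over per-copy states (BamHI-2 yes/no × methylated yes/no, treated as
independent), the loading control SWI5 contributes 2 copies per cell, and
a single exposure constant scales a lane. Three statistics follow:

* relative copy number: band/SWI5 per lane, scaled so the young-group mean
  is exactly 1;
* methylation ratio: (band/SWI5 with SacII) ÷ (band/SWI5 without SacII),
  which is 1 for a fully methylated population (SacII blocked everywhere)
  and 0 for a fully unmethylated one, and is monotone in the methylated
  fraction in between;
* active/inactive ratio from psoralen cross-linking: with per-copy active
  fraction $a$, the expected ratio is $a/(1-a)$.

The model carries a single representative SacII site; real units have
several, but one blocked/unblocked site already reproduces the band-level
arithmetic the ratio statistics need, and the site count cancels in the
ratio.

## The synthetic cohort generator

The generator's defaults are the study conditions, chosen once:

| parameter | default | why |
|---|---|---|
| young mean copies | 471 (BALB/cA-like), 1,025 (C57BL/6-like) | the two strains' young-group means |
| old/young mean ratio | 1.2 | a modest (<2-fold) age gain |
| CV young / old | 0.35 / 0.20 | dispersion falls with age |
| mice per group / cells per mouse | 4 / 50 | single-cell assay scale |
| methylated fraction young / old | 0.10 / 0.25 | methylation rises with age |
| active fraction young / old | 0.50 / 0.40 | about half of copies inactive; less in old |
| BamHI-2 fraction young / old | 0.50 / 0.35 | relative loss of BamHI-2 with age |
| error floor | 5×10⁻⁴ per base | amplicon PCR+sequencing artifact scale |
| depth | 10⁴ reads/position | deep-sequencing amplicon scale |
| droplets per assay | 20,000 | typical droplet-generator scale |

Per-cell copy numbers are log-normal, moment-matched to the mean and CV
and rounded half-up to integers: strictly positive, right-skewed, and
fully determined by the two parameters we actually control. The published
data give per-mouse dot plots, not a distributional family, so the family
is a modeling choice and the dispersion parameters stay config-exposed.
Per-cell state fractions scatter around their group means as Beta
variables with concentration 80 (SD ≈ 0.03–0.06 across the default means)
— enough cell-to-cell heterogeneity to be non-degenerate without drowning
the age contrast; degenerate means 0 and 1 stay exact.

Sequencing error is additive on reference copies: with planted variant
frequency $f$ and error floor $e$, the expected non-reference rate is
$f + (1-f)e$ — a read is non-reference if it carries the variant or an
error on a reference copy. Errors are substitutions spread uniformly over
the three non-reference bases; the generator plants no indels (the rate
estimator still counts them, and hand-built pileups with indels are
tested), and no read-level FASTQ is simulated — pileups are generated
directly, with SAM ingestion reserved for real data.

All randomness flows from one root seed through `substream_seed(root,
label)`, a deterministic label hash, so any stage can be re-run in
isolation and reproduce its slice of a pipeline run; every generator is
bit-reproducible for a fixed seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: mapping and alignment artifacts (reads are never
simulated), PCR amplification bias along the amplicon, batch effects
between mice, correlation between copy number and per-copy states within a
cell, position-dependent error profiles, and hybridization-efficiency
artifacts of real Southern blots. Tests against the generator validate the
estimators' arithmetic and statistical behavior under the stated model,
not the wet-lab steps upstream.

## Numerical choices and degenerate inputs

* Copy numbers are real-valued internally and rounded only at report time
  (half-up).
* `cohort_stats` with one cell reports `NA` SD/CV; `mutation_rate_track`
  masks zero-depth positions as `NA` rather than zero; both distinctions
  are load-bearing downstream (masked positions exclude a site from
  calling; they never count as rate 0).
* The t test is the classical equal-variance Student test by default
  (Welch behind a flag); two identical zero-variance groups return
  t = 0, p = 1 instead of erroring, since "no difference" is the correct
  answer there.
* Saturated ddPCR assays, zero reference signal, rDNA read fraction 1,
  SacII-minus lanes with a missing band, and missing day-3 CFU anchors are
  all hard errors naming the condition — these are cases where a number
  would be a lie.

## Problem sizes

The test suite and acceptance script size their simulations for
single-CPU runs: moment-recovery checks use 1,000 cells; the ddPCR
unbiasedness check uses 200 assays of 10⁴ droplets per occupancy level;
the planted-variant recovery study uses 100 seeded cohorts (plus 100
variant-free cohorts for the false-call rate) at depth 10⁴ over the full
5,100-position 28S coordinate; the full pipeline runs two strains at 4
mice × 50 cells per group. These sizes keep every Monte-Carlo tolerance at
3 standard errors or better.

## Known limitations

Variants cannot be phased onto individual repeat copies — a rate of 0.4 at
two positions does not say whether the same copies carry both. The WGS
estimator's constants (genome length, diploidy handling) are conventions,
and published WGS-derived copy numbers depend on the convention chosen.
The digest model abstracts densitometry entirely; its intensities are
exact expectations, so it validates ratio arithmetic, not gel
quantification. The age-differential screen with two samples per group has
no within-group variance estimate beyond separation; it is a screen, not a
hypothesis test.
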