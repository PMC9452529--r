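---
title: "Genotyping single-cell transcriptomes from allelic imbalance: model and methods"
author: "allelicCall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping single-cell transcriptomes from allelic imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelicCall)
```

## The problem

Separating cancer from non-cancer cells is the first step of any tumour
single-cell mRNA analysis, and doing it from expression alone is fallible:
transcriptional similarity between cancer cells and their cell of origin,
or between stromal populations and presumed malignant ones, can mislead
both marker genes and expression-based copy-number inference. A cancer
cell, however, physically carries the somatic copy-number genotype. Within
a region where the tumour has gained or lost one parental haplotype, the
two alleles of every heterozygous SNP are no longer represented equally,
so the allele fractions observed in the reads of a single transcriptome
shift away from 0.5 in a direction that is knowable in advance — provided
the SNPs have been phased against the tumour's DNA. allelicCall implements
this genotyping: it consumes copy-number segments and SNPs derived from
bulk tumour/normal DNA, phases the SNPs, and scores each cell's allele
counts under the cancer and normal genotype hypotheses.

The workflow has four steps:

1. call usable heterozygous SNPs from normal DNA (`callHetSNPs`);
2. phase them within copy-number-altered segments using tumour-DNA
   B-allele frequencies (`phaseSNPs`);
3. annotate, filter and orient the per-cell allele counts to the
   major/minor haplotype (`annotateSNPs`, `filterSNPs`, `orientCounts`,
   `aggregateBySegment`);
4. calibrate the error/ASE/overdispersion model and compute the posterior
   probability that each cell carries the cancer genotype (`fitASE`,
   `fitOverdispersion`, `cancerPosterior`).

`runPipeline()` chains the four steps.

## The statistical model

For a SNP $s$ in a segment whose major haplotype carries a fraction $f$ of
the copies ($f = 0.5$ diploid, $2/3$ one-copy gain, $1$ LoH), the expected
fraction of reads from the major allele is

$$r_s(f) = \frac{f\rho_s}{f\rho_s + (1-f)(1-\rho_s)}\,(1 - 2\epsilon_s)
  + \epsilon_s,$$

where $\rho_s$ is the gene's allele-specific expression (ASE) ratio (0.5
for no ASE) and $\epsilon_s$ a site-class error rate. Errors squeeze $r$
into $[\epsilon, 1-\epsilon]$; ASE tilts the pre-error ratio by the gene's
transcriptional allele bias. Counts of major/minor reads $(m_s, n_s)$ are
modelled beta-binomially with mean $r_s(f)$ and overdispersion $\phi$
(concentration $\theta = (1-\phi)/\phi$), capturing the extra-binomial
variability created by transcriptional bursting:

$$P_R(\mathrm{data} \mid f) = \prod_{s \in R} \binom{m_s + n_s}{m_s}
  \frac{B\!\left(m_s + r_s\theta,\; n_s + (1 - r_s)\theta\right)}
       {B\!\left(r_s\theta,\; (1 - r_s)\theta\right)}.$$

The cancer hypothesis sets $f$ in each copy-number-changed region to the
fraction implied by the DNA copy number; the normal hypothesis sets
$f = 0.5$ everywhere. With a flat prior the posterior is

$$P(\mathrm{cancer} \mid \mathrm{data}) =
  \frac{P(\mathrm{data} \mid \mathrm{cancer})}
       {P(\mathrm{data} \mid \mathrm{cancer}) +
        P(\mathrm{data} \mid \mathrm{normal})},$$

and cells are labelled cancer above 0.99, normal below 0.01, unassigned
otherwise. Cells with no informative reads sit at exactly 0.5. Only SNPs
inside copy-number-changed segments inform the call; balanced segments
(including 2+2 gains) carry no allelic signal and are excluded from
hypotheses, as are homozygous deletions, where $r$ is undefined.

All likelihoods are evaluated in log space via log-gamma, and the
posterior through `plogis` of the log-likelihood difference, so the
computation cannot underflow even at thousands of informative reads.
The likelihood is evaluated per SNP, not on segment totals, so that the
site-specific $\epsilon_s$ and gene-specific $\rho_s$ enter exactly;
segment totals (`aggregateBySegment`) serve reporting and binning.

## Parameters, defaults, and how they are calibrated

* **Error rates $\epsilon$** (per site class): defaults 0.01 exonic, 0.05
  intronic — typical non-reference read fractions at homozygous-reference
  sites in droplet data, where intronic alignments are noisier.
  `calibrateError()` re-estimates them by pooling non-reference reads at
  known hom-ref sites; classes without data keep the defaults.
* **ASE ratios $\rho$** (per gene): `fitASE()` aggregates major/minor
  counts over known normal cells and applies the conjugate update of a
  $\mathrm{Beta}(c/2, c/2)$ prior (mean 0.5, spread $c$, default 10); the
  point estimate is the posterior mean. With `spread = "fit"` the
  concentration is set to its maximum-likelihood value on the observed
  allele fractions of genes with more than 400 counts — high-count genes,
  where sampling noise no longer dominates the gene-to-gene spread.
  Without normal cells every $\rho$ stays 0.5 (both alleles equally
  likely). The posterior mean (not the mode) is used; an option to
  marginalise the overdispersion fit over the ASE posterior exists
  (`marginalizeASE`) but is off by default, since a plug-in posterior
  mean gives an indistinguishable fit at realistic depths.
* **Overdispersion $\phi$**: one global value, fitted by bounded
  maximum likelihood (`optimize` on $[10^{-6}, 1-10^{-6}]$) over all
  normal-cell SNP observations at $f = 0.5$. A single global $\phi$
  mirrors the likelihood above, which uses one concentration for all
  sites. Without normal cells $\phi$ is set manually (default 0.05) or
  can be fitted across all cells — which inflates it and makes calls more
  conservative, the safer direction. Data sets consisting solely of
  single-read observations leave the likelihood flat in $\phi$; the fit
  detects this and keeps the configured value with a warning.
* **Thresholds**: posterior 0.99/0.01 for cancer/normal labels; BAF
  window [0.2, 0.8] and exact binomial test at 5% FDR for het calling;
  5% FDR for phasing; 400 counts for high-expression genes; 500 counts
  per adaptive bin; 5 Mb evaluation windows. These are the standard
  operating constants of the method and are all surfaced as arguments.

## SNP filtering and phasing conventions

Sites are kept only when inside a gene (exonic or intronic — intergenic
alignments in 3' droplet data are unreliable), not imprinted, not in genes
with known complex ASE (all `HLA-` genes by prefix plus the hemoglobin
genes), and covered by at least one read across the data set ("zero
coverage" is judged per data set, not per cell subset). Where genes
overlap, exonic wins over intronic and the first gene in sorted order
provides the symbol.

Both the heterozygosity test and the phasing test are two-sided exact
binomial tests against 0.5 in the "minlike" convention (the sum of all
outcome probabilities not exceeding that of the observed outcome — the
convention of `stats::binom.test`), with Benjamini–Hochberg correction.
The two corrections are separate families: one across all candidate het
sites, one across all sites in all uneven segments being phased. Ties in
the BH ordering are resolved by stable sort on position. A segment with
equal major and minor copy numbers cannot be phased — its tumour BAF
carries no haplotype signal — and `phaseSegment` refuses it; the joint
driver `phaseSNPs` skips such segments with a warning.

## Coordinates and containers

Internally everything lives in Bioconductor containers: segments and SNPs
are `GRanges` (1-based, closed intervals, the Bioconductor convention),
chromosome registries are `Seqinfo`, and per-cell counts are a sparse
`AlleleExperiment` (a `RangedSummarizedExperiment` with `ref`/`alt` and,
after orientation, `major`/`minor` assays). On-disk conventions are
handled at the I/O boundary: segment TSVs are 1-based inclusive, VCF is
1-based, and chromosome names are normalized by stripping any `chr`
prefix on input. Sex chromosomes are not treated specially by the code;
hypotheses on them are the caller's responsibility (the het-SNP model
assumes two alleles).

## Segment post-processing

`cleanSegments` applies the standard artifact rules to copy-number caller
output: segments shorter than 1 Mb or than 10% of their chromosome are
removed; sub-megabase gaps between same-state neighbours are bridged; a
chromosome is collapsed to one state when that state covers at least 90%
of the chromosome's segment-covered length. The 10% rule uses the full
registry chromosome length while the 90% rule uses covered length — the
former guards against small artifacts relative to the chromosome, the
latter asks whether the *called* portion is effectively homogeneous; both
denominators are configurable since either choice is defensible. The
operation is idempotent. `flagSubclonal` partitions states by tumour-cell
fraction: at least 0.5 is clonal; [0.10, 0.5) is subclonal only when the
segment exceeds 20 Mb (smaller minority states are more likely fit
artifacts); the rest are dropped.

## Subclones

`assignSubclones` compares two clone hypotheses restricted to the
segments on which they differ (a segment absent from one hypothesis is
balanced there). The same 0.99/0.01 posterior bands label cells
subclone / major-clone / ambiguous; cells with no reads on the
distinguishing segments are necessarily ambiguous.

## The minimum detectable LoH

At an informative-read density of $d$ reads/Mb (about 0.5 for a typical
droplet experiment: 1522 SNP-covering reads per cell over a ~3,100 Mb
genome), a region of $L$ Mb yields $n = Ld$ reads, and the question "how
small an LoH is detectable at 99% accuracy under a binomial read model?"
admits several formalizations. `minDetectableLoH` exposes them rather
than guessing a single intent:

* **balanced** (default): binomial reads with major-allele probability
  $1-\epsilon$ (cancer) versus 0.5 (normal), classified at the
  maximum-likelihood threshold; require the mean of the two per-class
  error probabilities to be at most 1%. With the default exonic
  $\epsilon = 0.01$ the smallest whole read count is $n = 10$, i.e.
  **20 Mb** at 0.5 reads/Mb.
* **posterior**: a cell whose $n$ reads all support the major allele must
  reach posterior 0.99; with $\epsilon = 0$ this solves $2^n > 99$,
  giving $n = 7$ and **14 Mb** — a closed-form lower bound for any other
  interpretation.
* **betabinomial**: the balanced construction with beta-binomial reads,
  for sensitivity analysis; overdispersion lengthens the requirement
  (42 Mb at $\phi = 0.05$) and at large $\phi$ a 99% single-cell accuracy
  may be unreachable at any length, which the function reports as an
  error rather than a number.

Published statements of this quantity for droplet data are around
19.7 Mb; the balanced binomial mode is the interpretation that matches a
binomial assumption at 99% accuracy and reproduces that figure to within
the granularity of a whole read (20 Mb at exactly 0.5 reads/Mb). The
read requirement is integer by default; `integerReads = FALSE`
interpolates the error curve continuously.

```{r detect}
minDetectableLoH()                                # balanced, eps = 0.01
minDetectableLoH(mode = "posterior", epsilon = 0) # lower bound
informativeReadDensity(1522)                      # reads/Mb over GRCh37
```

## What the simulator emulates — and what it does not

`simConfig`/`simulateReference`/`simulateBulkDNA`/`simulateCells`
generate a complete input bundle under one seed: a toy genome (default
3 × 100 Mb), a gene model with exon blocks, het SNPs placed uniformly
within gene bodies, bulk DNA counts (binomial around 0.5 in normal;
around the purity- and cell-fraction-adjusted major fraction in tumour),
and per-cell counts drawn from the classifier's own generative model:
negative-binomial per-cell totals (mean 1522, the typical droplet depth),
multinomial scatter over SNPs proportional to log-normal per-gene
expression weights, and beta-binomial allele splits with per-gene
$\rho \sim \mathrm{Beta}$ (mean 0.5, concentration 30, i.e. moderate ASE
with s.d. ≈ 0.09), site-class errors, and $\phi = 0.05$. The default
cancer genotype is a 30 Mb cnLOH plus a 50 Mb one-copy arm gain.

Because cells are drawn from the same family of distributions the model
fits, passing tests demonstrate internal consistency — correct equations,
calibration, and decision rules — not robustness to everything real data
contains. Not emulated: doublets, ambient RNA, UMI duplication,
alignment/mapping bias toward the reference allele, clustered SNP
coverage within transcripts (reads here land on SNPs independently),
mis-specified copy-number segments, and expression differences between
cell types. The simulated read density per altered megabase is about
ten-fold the genome-wide droplet average, because the toy genome is
ten-fold smaller than the human genome at the same per-cell read count;
conclusions about borderline detectability therefore come from
`minDetectableLoH`, not from the simulation.

## Numerical choices and degenerate inputs

* Beta functions via `lbeta`/`lgamma`; the $\phi \to 0$ binomial limit is
  numerically exact to $10^{-4}$ at $\phi = 10^{-8}$.
* Zero-coverage observations contribute zero log-likelihood (empty
  product), so uncovered cells fall out at posterior 0.5.
* $r$ is kept strictly inside $(0,1)$: an error rate of exactly 0 with
  $f = 1$ would put $r = 1$, so fully error-free hypotheses should use a
  tiny $\epsilon$ instead.
* Fitted $\rho$ values are clamped to $(10^{-9}, 1-10^{-9})$; the
  spread fit uses shrunken fractions $(M + 0.5)/(T + 1)$ to keep fully
  imbalanced genes finite.
* `optimize` tolerances: $10^{-7}$ for $\phi$; the ASE concentration is
  searched on a log scale over $[0.01, 10^5]$.
* ROC construction delegates to pROC (all-thresholds sweep, trapezoidal
  area); windows with no reads are excluded, and a window counts as
  altered when at least half of it overlaps a changed segment.

## Problem sizes in the test-suite

The packaged checks run at study scale where that matters and small scale
elsewhere: classification calibration and window-score AUC use 600 cells
at mean depth 1522 on the default genotype; parameter recovery uses 500
normal cells; subclone recovery uses 1,000 cancer cells with a 100 Mb
cnLOH subclone in 30%; FDR control uses 2,000 null sites at depth ~40.
All are seed-pinned and complete in a few minutes.

## Known limitations

The method needs somatic copy-number changes (and knowledge of them): a
copy-number-quiet tumour, or one whose only changes are balanced, is
invisible to allelic imbalance. Phasing power depends on tumour purity
and DNA depth; heavily contaminated tumour DNA leaves sites unphased and
cells unassigned rather than mislabelled. Point-mutation-based calling is
out of scope (too few covering reads per cell at realistic burdens), as
is de-novo copy-number discovery from the single-cell data itself.
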