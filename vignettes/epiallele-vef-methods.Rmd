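---
title: "Epiallele-resolved detection of mosaic promoter methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epiallele-resolved detection of mosaic promoter methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivef)
```

## The problem epivef addresses

Constitutional epimutations are promoter methylation events that arise very
early in development — plausibly as a single-cell event followed by clonal
expansion — and therefore persist as a *mosaic* in normal adult tissue: only
a small fraction of cells carry the methylated promoter, typically on one
allele. In white blood cells (WBC) the affected-cell fraction can be as low
as 10^-4^ to 10^-1^, far below what array- or pool-level methylation
averages can distinguish from background noise.

Ultradeep bisulfite amplicon sequencing resolves this by reading each DNA
fragment individually. After bisulfite conversion, unmethylated cytosines
read as T and methylated cytosines as C, so each sequenced fragment carries
the full ordered methylation pattern of the CpGs it covers — an
**epiallele**, one molecular observation from one cell. Because a clonal
epimutation methylates essentially all CpGs of the promoter in affected
cells, a carrier's fragment population is strongly bimodal: near-fully
methylated molecules from the mutant clone against near-fully unmethylated
background. Counting fragments rather than averaging bases is what makes a
1-in-10,000 clone detectable at ~30,000x coverage.

## The measurement model

For each fragment the **beta value** is the fraction of methylated CpGs
among its observed CpGs. A fragment is a **hypermethylated epiallele** when
beta >= 0.5 (`beta_threshold`). The per-amplicon **hypermethylated variant
epiallele frequency (VEF)** is the fraction of hypermethylated epialleles,
and the sample-level measure is the arithmetic mean of the VEFs of the two
central amplicons (CpG14-31 and CpG17-34 in the default panel), which
together cover the biologically relevant CpG14-34 window. A sample is
methylation **positive** when its combined VEF strictly exceeds a
tissue-specific cutoff:

* WBC: 6.96 x 10^-4^ — mosaic, low-level methylation in blood;
* tumor: 4.71 x 10^-2^ — clonal expansion implies a large methylated
  fraction in tumors arising from a methylated cell.

These calibrated cutoffs are the package defaults and the boundary is
deliberately strict (a VEF exactly at the cutoff is negative): the cutoff
is the highest value still consistent with background, so only values
above it constitute evidence. `estimate_cutoff()` additionally offers a
data-driven procedure (the smallest background value exceeding the
empirical 1 - alpha background quantile, alpha = 0.01) for assays without
calibrated cutoffs; it never silently replaces the defaults.

### Allele-specific methylation

One amplicon (CpG33-49) contains a biallelic SNP. Because the SNP base is
read *within the same fragment* as the CpG calls, every SNP-informative
epiallele is physically phased to an allele — no statistical phasing is
involved. For heterozygous samples the VEF is computed separately for ref-
and alt-tagged epialleles, and the **fold enrichment** is the ratio of the
larger to the smaller per-allele VEF, with direction naming the
preferentially methylated allele. Two conventions matter:

* no pseudocounts — exclusive methylation of one allele (the other
  allele's VEF exactly 0) is reported as an infinite fold with an explicit
  flag, rather than a capped value; at VEFs of order 10^-3^ any pseudocount
  would dominate the ratio;
* "balanced" requires exact equality of the two per-allele VEFs. Near-ties
  are handled downstream: a concordance verdict requires at least
  `min_informative` (default 500) SNP-tagged epialleles per sample, which
  keeps zero-count infinite calls meaningful, and the magnitude is always
  reported so callers can apply their own tie band.

Matched pairs (blood/tumor within a patient, child/parent within a family)
are **concordant** when methylation is enriched on the same allele in
both. Under a null of random allele assignment the probability that *n*
informative pairs all agree is 0.5^n^ (`concordance_null_prob()`); four
all-concordant pairs correspond to 6.25%, i.e. below the 7% chance level.

### Exact cohort statistics

Cohort frequencies are reported with exact Clopper–Pearson intervals
(binomial tail inversion, computed via the beta-quantile form), and group
differences in positivity use the two-sided Fisher exact test with the
"no more probable than observed" convention. Both are delegated to the
standard R implementations (`qbeta`, `fisher.test`) and are verified in
the test suite against independent oracles: bisection on binomial tail
probabilities for every (x, n) with n <= 200, and full hypergeometric
enumeration for every 2x2 table with total <= 60. The choice of the exact
interval family was validated by back-matching published example
intervals (e.g. 9/200 gives 2.1–8.4% exactly, where a normal
approximation would give 1.6–7.4%). VEF-distribution comparisons
(`group_vef_comparison()`) wrap two-way ANOVA, Wilcoxon rank-sum and
paired t tests; no multiple-testing adjustment is applied, and the report
says so.

## The synthetic-data generator

The simulator exists so that every downstream stage is testable against
known truth without any external data. It emulates:

* the four-amplicon promoter panel: 50 CpGs (CpG00–CpG49) with coordinates
  decreasing along the index (a minus-strand promoter), amplicons scoring
  CpGs 0–13, 14–31, 17–34 and 33–49, and a bisulfite-safe A/G SNP inside
  the CpG33-49 amplicon;
* mosaic monoallelic hypermethylation: each fragment is drawn from a
  fully methylated clone with the clone fraction of its allele, otherwise
  from the fully unmethylated background — the bimodality observed in real
  carrier samples is thus built into the generative model;
* assay scale: 30,000 fragments per amplicon, paired 2 x 226 bp mates
  (which overlap across the ~370–400 bp amplicons and are emitted as
  concordant SAM mate pairs);
* noise, applied per CpG: failed bisulfite conversion (unmethylated read
  as methylated, default 0.005), methylation miscalls (methylated read as
  unmethylated, default 0.005), and sequencing substitutions (default
  0.001 per base, flipping a CpG call with probability 1/3 and destroying
  it with probability 2/3, since substitutions to non-C/T bases are
  uninformative). The biology-level rates are not published quantities;
  they were fixed once at values typical of modern bisulfite amplicon
  assays, chosen so that background VEF stays well below the WBC cutoff,
  and are configurable.

Only the top (bisulfite-converted) strand is simulated and scored:
amplicon assays are strand-specific by primer design. The default SNP
uses A/G alleles so both survive C-to-T conversion; a SNP declared
`bisulfite_safe = FALSE` is refused by every allele-specific operation.

Reproducibility contract: each sample's random stream derives from
`(master seed, sample_id)` via `sample_seed()`, so cohorts are
reproducible sample-by-sample and identical configurations give
bit-identical fragment sets and pipeline outputs.

For cohort-scale work, `simulate_cohort(observe = TRUE)` skips fragment
materialisation and draws the observed VEF directly from the exact
fragment-level law (`hyper_call_prob()` collapses the per-CpG noise model
into retention and hyper-call probabilities, and the observed counts are
binomial draws from those). This is distributionally identical to
simulating and calling fragments — a property checked in the tests — and
makes 1000-sample cohorts cheap. Carrier true VEFs default to log-uniform
on [10^-3^, 10^-1^], a blood-like mosaic range; the clone sits on one
randomly chosen allele of a heterozygous genotype.

### What the generator does not emulate

No PCR amplification bias, chimeric reads, indels, or per-base quality
modelling; conversion failure is independent per CpG, whereas real
conversion failures cluster within molecules; allele sampling is exactly
binomial, with no extraction or amplification bottleneck. Passing
recovery tests on this design therefore demonstrates that the *callers*
are correct and unbiased under the stated noise model — not that the
assay itself is free of molecular artefacts. Conclusions about real
libraries still require the calibrated cutoffs and lab-side conversion
controls.

## Numerical and design choices

* **Completeness**: a fragment must cover *all* scored CpGs of its
  amplicon (`min_cpg_completeness = 1`) to count as an epiallele. Full
  coverage is the norm in amplicon sequencing, and partial fragments bias
  beta; fragments with any destroyed CpG call are simply discarded, which
  the collapsed observation law accounts for exactly.
* **Mate conflicts**: when overlapping mates disagree at a CpG (C vs T)
  the call is missing, not majority-voted — conservative and symmetric.
  The same rule applies to the SNP base.
* **Depth guards**: `min_fragments = 1000` per amplicon before a VEF is
  reported (estimates at the 10^-4^ scale need thousands of molecules);
  genotyping requires `min_depth = 100` ref+alt reads and calls
  heterozygosity inside an alt-fraction band of [0.2, 0.8] — conventional
  amplicon-genotyping defaults, configurable.
* **Smoothing**: per-CpG profiles are smoothed with a fixed-bandwidth
  normal-kernel mean over genomic coordinate (bandwidth 40 bp, about twice
  the median CpG spacing of the central window); raw values are always
  returned alongside.
* **Ranked beta curves** sort epialleles by beta and centre the rank axis
  at the first epiallele reaching 0.5, retaining at most 2500 ranks per
  side; an all-hypo sample's curve ends just below rank 0.
* **Degenerate inputs**: empty fragment sets yield empty epiallele tables;
  an all-zero background in `estimate_cutoff()` returns the configured
  floor with a warning; an empty profile partition is flagged rather than
  fabricated; a methylation-free denominator in `tumor_blood_fold()`
  yields a flagged infinite fold.

## Validation design and problem sizes

The test suite validates the pipeline at the following scales, chosen to
exercise the assay's operating point while keeping a full run in minutes:
VEF recovery at clone fractions 10^-3^, 10^-2^, 10^-1^ with 20 seeds each
at 30,000x (unbiasedness within 3 Monte-Carlo standard errors);
positivity classification on 100 carriers drawn from the blood-like VEF
range plus 100 non-carriers, fully fragment-level (sensitivity and
specificity both required >= 99%); allele-of-origin recovery on 100
heterozygous carriers (direction correct with fold magnitude > 2 required
in >= 95%); and bimodality on carrier samples at 10,000x (< 5% of
epialleles with beta in (0.2, 0.8)). The sensitivity population is the
carrier distribution the cohort generator defines (log-uniform over
[10^-3^, 10^-1^]) because that is the population the WBC cutoff is meant
to detect; a design pinned entirely at the cutoff-adjacent extreme would
instead measure the binomial boundary behaviour at a single point.

## Known limitations

* The package targets amplicon panels with an indexed CpG map; it is not
  a general whole-genome bisulfite caller and has no CHH/CHG support.
* Exactly one phasing SNP per region; no multi-SNP haplotyping and no
  parent-of-origin inference beyond direction concordance.
* The data-driven cutoff estimator is a documented stand-in for
  assay-specific computational calibration; calibrated cutoffs should be
  preferred whenever available.
* Real rs799905-style allele/strand resolution in bisulfite space is
  assay-dependent; the SNP is kept abstract and configurable, and unsafe
  SNPs are refused rather than guessed.
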