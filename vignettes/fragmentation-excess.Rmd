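---
title: "Detecting RNA decay-intermediate accumulation from 5' profiles"
author: "fragexcess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA decay-intermediate accumulation from 5' profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragexcess)
```

## The biological question

The bacterial RNA degradosome couples an endonuclease (RNase E) with a
DEAD-box RNA helicase and exonucleases. When the helicase is missing,
structured decay intermediates — fragments produced by endonucleolytic
cleavage but not yet fully degraded — are expected to linger. Each such
intermediate carries a new 5' end, and in a stranded RNA-seq library that
5' end becomes a read-start position that the wild type does not show.

`fragexcess` asks a genome-wide question: *does the mutant accumulate
read-start positions of its own, beyond what random fragmentation produces
in both strains?* The package also provides the companion rifampicin-chase
half-life machinery used to characterize decay kinetics directly.

## The fragmentation-excess statistic

For each strain, uniquely aligned reads are reduced to the 5' ends of their
sequenced fragments (in a paired-end stranded protocol only read 2 starts
at the fragment 5' end, so paired libraries are filtered to read-2 records;
single-end libraries are used as is). Accumulating those ends per
(reference, strand, position) gives the strain's **5' profile**. Replicate
profiles are merged by position-wise summation.

Because the statistic below is built from zero/non-zero contrasts, unequal
sequencing depth translates directly into spurious exclusive positions.
Depth is therefore equalized *before* profiling: every library is reduced,
by uniform sampling without replacement, to 90% of the unique-read count of
the smallest library (`undersample()`, `fraction = 0.9`).

For every position `i` covered in at least one strain,

\[ P_i = \frac{\mathrm{mutant}_i}{\mathrm{mutant}_i + \mathrm{wt}_i} . \]

`P = 1` positions are seen only in the mutant, `P = 0` only in the wild
type, `P = 0.5` equally in both. The histogram of `P` keeps `P = 0` and
`P = 1` as exact singleton classes (they arise only from integer zeros, so
no tolerance is involved) and distributes the interior over 99 equal-width
bins spanning (0, 1).

The decision is an equal-prior two-class Gaussian one. The counts of the
two extreme classes, `n0` and `n1`, are modelled as draws from Gaussians
with a common standard deviation `sigma` estimated from the background: the
sample SD of the 99 interior bin counts, zero bins included. The Bayes rule
misclassification probability — the **Bayesian error rate** — is

\[ \mathrm{BER} = \Phi\!\left( -\frac{|n_1 - n_0|}{2\sigma} \right), \]

and `BER < 0.01` is declared significant. `BER = 0.5` means the two counts
are indistinguishable against the background noise. The headline effect
size is the percent excess `100 (n_1/n_0 - 1)`.

### Numerical choices

* **Interior binning** is done in integer arithmetic (`99 m` against
  `m + w`), so bin membership is exact. Proportions landing exactly on a
  bin edge (`P = 1/3` does, with 99 bins) are assigned toward the center
  bin. This tie rule is what makes the histogram exactly mirror-symmetric
  under a strain swap: exchanging the strains maps `P` to `1 - P`, swaps
  `n0` with `n1`, reverses the interior bin vector, and leaves `sigma` and
  the BER bit-identical. A plain left-closed rule breaks that symmetry for
  edge values; off the edges the two rules agree.
* **`sigma`** is computed after sorting the bin counts, so the
  floating-point sum is permutation-invariant and the swap symmetry holds
  exactly, not just approximately.
* **Strandedness**: `P` is computed per (strand, position) because the
  libraries are stranded; `collapse_strands = TRUE` gives the unstranded
  reading.
* **Degenerate cases**: `sigma = 0` yields BER 0 (distinct counts) or 0.5
  (equal counts); `n0 = 0` reports infinite excess rather than a ratio.
* **Reproducibility**: one pipeline seed; each library's subsample is drawn
  from a child stream derived by hashing the library name, so adding a
  library never perturbs the others. Reruns are byte-identical.

### Decisions taken where the design was open

* Library sizes for the 90% rule are computed after the uniqueness filter
  but before the read-2 filter (the filter then runs on the subsample);
  `size_after_r2 = TRUE` exposes the alternative.
* Read-2 records whose mates did not align are treated exactly like paired
  read-2 records.
* The fragment 5' end is taken from the aligned span, so soft-clipped bases
  never shift it.

## What the synthetic generator emulates

`fragmentation_scenario()` plants a known structure: `n_shared_sites`
cleavage positions present in both strains, each drawing an independent
Poisson(`lambda_shared`) 5'-start count per replicate per strain, plus
`n_exclusive_sites` mutant-only positions (the planted decay intermediates)
drawing Poisson(`lambda_exclusive`) in mutant replicates. Poisson zeros at
shared sites are the *only* source of background strain-exclusive
positions, which is the property the null calibration exploits.

The default conditions are a 2 Mb genome (a typical bacterial chromosome)
with 20,000 shared sites, `lambda_shared = 0.3` and 3 replicates per
strain: a merged per-strain site rate of 0.9, at which roughly a quarter of
the sites end up exclusive to one strain by sampling alone — a deliberately
exclusive-rich, low-coverage regime in which the extreme classes are well
populated. Detection runs scale the same conditions to 115,000 shared
sites, which puts each strain above 10^5 informative reads. The planted
excess is not set by hand: `calibrate_excess_scenario(target_ratio = 1.78)`
solves the expectation equation

\[ n_\mathrm{excl} = (r - 1)\, n_\mathrm{shared}\,
   \frac{e^{-\Lambda}(1 - e^{-\Lambda})}{1 - e^{-R\lambda_e}},
   \qquad \Lambda = R\,\lambda_s , \]

for the number of exclusive sites that makes the expected `n1/n0` equal the
target ratio `r` — the 78%-excess regime.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data:

* Real coverage is highly heterogeneous (operons, rRNA leftovers); a single
  `lambda_shared` produces a much more homogeneous interior histogram.
* The planted exclusive reads can be a sizable fraction of the mutant
  library's mass. In that regime the 90% undersampling thins the mutant's
  shared coverage asymmetrically and attenuates the planted ratio — an
  artifact of the synthetic model, since real strain libraries carry
  comparable total mass. Record-level tests therefore pad libraries to a
  common size at one shared position before undersampling, restoring the
  equal-mass regime the method assumes.
* No sequence content, alignment error, or positional clustering of decay
  intermediates: exclusive sites are uniform over unoccupied
  (strand, position) slots, because no positional model is available.

## Decay kinetics

After rifampicin blocks transcription initiation, abundances are sampled at
0, 1, 3 and 9 minutes. Per gene, counts are converted to RPKM and
`fit_exponential_decay()` performs ordinary least squares of `log(level)`
on time with a free intercept; the rate is minus the slope and the
half-life `log(2)/k`. The RPKM denominator should be the *total* mapped
reads per time point: normalizing by the mRNA pool itself (the fallback
when totals are not supplied) deflates apparent decay, because that pool
shrinks during the chase.

With this sampling grid, half-lives below ~1 min or above ~15 min are not
measurable; estimates strictly outside the configurable (1, 15) min window
are flagged `too_fast` / `too_stable` (a tiny relative guard keeps
estimates computed exactly at a bound from being pushed over it by
floating-point rounding). Non-positive levels are dropped with a warning
and three usable points are required. The bulk half-life fits the fraction
of mRNA reads among total reads over time; strain comparisons use Welch's
unequal-variance two-tailed t-test with Benjamini-Hochberg adjustment
across genes, and qPCR series are quantified by `2^-ddCt` against an
internal reference gene and the time-zero sample.

The free intercept is a deliberate choice (anchoring the fit at the
observed t = 0 level correlates all residuals with that single noisy
measurement and is strictly less precise). Its cost is visible in the
noise sensitivity: with multiplicative log-normal noise of CV 0.1 at four
time points, the slope's relative standard error is
\(\sigma / (|k| \sqrt{S_{tt}}) \approx 6.2\%\) for a 3-min half-life, so
roughly one noisy series in ten misses the truth by more than 10%.
Replicates, not a different estimator, are the remedy: this is the
minimum-variance fit for the model.

A dedicated `decay_scenario()` / `generate_decay_series()` pair plants
known half-lives with log-normal noise of a stated CV so the whole chain is
verifiable, including the calculability flags.

## Problem sizes used in the self-tests

The calibration properties run 100 seeded scenarios each: the null at the
default 20,000-site conditions, detection at the 115,000-site depth. The
bit-exact round trip (alignments → filter → profile) and the undersampling
stability check run at a few-thousand-site scale. The BER and
hypergeometric implementations are compared against numerical integration
of the normal density and exhaustive probability-mass summation (all
universes up to 30) rather than against fixed constants.

## Known limitations

* The Gaussian/BER reading — `Phi(-|n1-n0|/(2 sigma))` with equal priors
  and the background pooled from interior *bin counts* — fixes the numeric
  scale of all results; other readings of "variance pooled from all P"
  (e.g. the variance of the P values themselves) would give different
  sigmas and BERs.
* The single-rate Poisson background cannot reproduce both a realistic
  interior histogram and a realistic exclusive-position mass at once; see
  the generator section.
* Per-gene half-lives assume first-order decay throughout the chase; no
  correction for residual transcription or delayed rifampicin action is
  applied.
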