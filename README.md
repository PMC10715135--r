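# fragexcess

Genome-wide detection of RNA decay-intermediate accumulation from 5'-end
read-start profiles, plus rifampicin-chase mRNA half-life estimation.

## The problem

In bacteria the RNA degradosome (RNase E scaffold, exonucleases, and a
DEAD-box RNA helicase) turns endonucleolytic cleavage products over to
completion. When the helicase is absent, structured decay intermediates
persist. Every such intermediate exposes a new 5' end, and in stranded
RNA-seq each of those ends becomes a read-start position found in the
mutant but not in the wild type. `fragexcess` quantifies that signal for
people analyzing two-strain comparisons of bacterial RNA-seq: does the
mutant carry an *excess* of strain-exclusive read-start positions over the
background that random fragmentation creates in both strains?

## The statistic

After equalizing sequencing depth (every library is randomly subsampled,
without replacement, to 90% of the smallest library's unique-read count)
and reducing reads to fragment 5' ends (read 2 in paired-end stranded
protocols), per-strain replicate-merged **5' profiles** count read starts
per (reference, strand, position). For each covered position *i*,

    P_i = mutant_i / (mutant_i + wt_i)

so `P = 1` marks mutant-exclusive positions (candidate decay
intermediates) and `P = 0` wild-type-exclusive ones (background). With
`n1` and `n0` the counts of those two classes and `σ` the sample SD of the
99 interior histogram bin counts (the pooled background noise), the
equal-prior two-class Gaussian **Bayesian error rate**

    BER = Φ( −|n1 − n0| / (2σ) )

is declared significant below 0.01. The effect size is the percent excess
`100·(n1/n0 − 1)`.

The decay module fits log-linear exponential decays to rifampicin-chase
RPKM series (half-life = ln 2 / k, calculable only within ~1–15 min on a
0/1/3/9-min grid), bulk mRNA-fraction half-lives, Welch unequal-variance
t-tests with Benjamini-Hochberg adjustment, and `2^-ΔΔCt` qPCR ratios.

A synthetic-data module plants known shared cleavage sites, mutant-only
decay-intermediate sites and exponential decay series, so the whole
pipeline is verifiable offline; `generate_alignments()` round-trips
bit-exactly through the SAM/profile machinery.

## Worked example

Plant a 78%-excess regime (the number of mutant-exclusive sites is solved
from the target ratio, not set by hand) and test it:

```r
library(fragexcess)

sc <- calibrate_excess_scenario(
  fragmentation_scenario(n_shared_sites = 115000, seed = 42),
  target_ratio = 1.78)
prof <- generate_profiles(sc)
fragmentation_excess(merge_replicates(prof$mutant),
                     merge_replicates(prof$wt))
#> Fragmentation-excess test (5' profile proportion statistic)
#>   P = 0 (wt-exclusive) positions:     n0 = 27430
#>   P = 1 (mutant-exclusive) positions: n1 = 49401
#>   excess: 80.1%  background sigma: 2160.40
#>   BER = 1.84e-07  ->  SIGNIFICANT excess (alpha = 0.01)
```

Read it as: 27,430 positions have read starts only in the wild type
(random-fragmentation background) against 49,401 only in the mutant — an
80% excess whose separation is ~10 background standard deviations, hence a
BER of 1.8e-7, far below the 0.01 significance threshold. On alignment
files the same analysis is one call:

```r
run_fragexcess(list("mut_rep1.bam", "mut_rep2.bam"),
               list("wt_rep1.bam", "wt_rep2.bam"),
               layout = "paired", fraction = 0.9, seed = 1,
               output_dir = "out")   # BEDGraphs, histogram.tsv, result.json
```

A noisy decay series and its recovered half-life:

```r
ds <- generate_decay_series(
  decay_scenario(true_half_life = 4, noise_cv = 0.1, seed = 7))
fit_exponential_decay(ds)
#> synthetic: half-life 3.7 min (k = 0.1875 /min, R2 = 0.965, status ok)
```

A thin CLI over the same functions lives at
`inst/scripts/fragexcess-cli.R` (subcommands `fragexcess`, `decay`,
`simulate`).

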