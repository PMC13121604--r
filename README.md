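# rtswitch

Detection of replication-timing (RT) switches from E/L Repli-seq and their
integration with nascent transcription, for allele-resolved (hybrid-genome)
designs.

## The problem

During cell-fate transitions, sub-megabase replication domains change the
time in S phase at which they replicate. E/L Repli-seq measures this as the
log2 ratio of read coverage between FACS-sorted early- and late-S fractions,

```
RT(bin) = log2( E_rpm(bin) + eps ) − log2( L_rpm(bin) + eps )
```

computed per fixed-width genomic window (50 kb for statistics, 5 kb for
display tracks). In hybrid cell lines the two parental alleles are
distinguishable, so RT can be profiled per allele, and engineered
cis-element insertions can be tested for their ability to advance the RT of
one allele relative to the untouched one. Nascent transcription (Bru-seq)
over the same regions asks whether RT changes travel with transcription
changes.

`rtswitch` implements the downstream analysis as a reusable, tested R
package:

* **Profiles** — binning of bedGraph fraction coverage, log2(E/L) with a
  coverage floor and symmetric pseudocount, quantile normalization to a
  reference sample, affine dynamic-range scaling for display (about ±7 →
  ±3), and masked moving-average smoothing (300 kb). Statistics always run
  on unscaled values.
* **Switch calling** — per-window RT change between two conditions, either
  a Monte-Carlo empirical-null test (null drawn from the genome-wide pool
  of within-condition replicate differences, rescaled to the sampling
  variance of the between-condition mean difference) or a paired/Welch
  t-test; Benjamini–Hochberg q-values; windows at q ≤ 0.001 stitched into
  direction-pure switching regions allowing a 300 kb gap (bedtools
  `merge -d` semantics).
* **Allelic advance** — per-bin
  `(mut_allele1 − mut_allele2) − (wt_allele1 − wt_allele2)`, the mutant's
  allelic RT difference normalized for the wild-type baseline asynchrony.
* **Transcription integration** — region/domain RPKM from nascent coverage,
  paired t-tests for transcription change, a transcriptional noise
  threshold derived by shuffling RT-advancing regions into intergenic
  space, and joint RT × transcription classification.
* **Barcode counting** — exact 16-mer barcode matching in FASTQ reads,
  reported as reads per million (RPM), for reporter-insertion expression.
* **Synthetic data** — a seeded generator that plants domains, TTR ramps,
  RT switches, allelic offsets and expression states, then draws Poisson
  Early/Late counts whose expected log2 ratio equals the planted RT
  (`pE = 2^s / (1 + 2^s)`), so every statistical guarantee is testable
  against known truth.

## Worked example

Simulate a 40 Mb two-condition dataset with three planted RT switches
(two advances with induced transcription, one delay with induced
transcription) and one silent no-change region, then run the full
pipeline:

```r
library(rtswitch)

cfg <- demo_config(seed = 2,
                   classes = c(advance_up = 2, delay_up = 1,
                               nochange_silent = 1),
                   chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
                   constitutive_genes = 10)
make_demo("demo_data", seed = 2, config = cfg)
res <- run_pipeline("demo_data", "demo_out", n_mc = 5e4,
                    n_shuffles = 30, seed = 2)
res$regions[, c("chrom", "start", "end", "direction",
                "mean_delta_rt", "min_q", "n_windows")]
#>   chrom    start      end direction mean_delta_rt        min_q n_windows
#> 1  chr1  3000000  3550000   advance      2.012611 0.0006666533        11
#> 2  chr1  5100000  5350000   advance      1.924073 0.0006666533         5
#> 3  chr2 15000000 15400000     delay     -2.052787 0.0006666533         8

res$noise
#> noise_threshold: 0.01206 RPKM (q = 0.99 over 30 shuffles, 60 placements)

res$classification
#> RT x transcription classification of 3 regions
#>            tx
#> rt          sig_up sig_down ns_expressed ns_silent
#>   advance        2        0            0         0
#>   delay          1        0            0         0
#>   no-change      0        0            0         0
```

The three planted switching regions are recovered at their exact planted
boundaries with the planted ΔRT of ±2 log2 units; the noise threshold
(0.99 quantile of RPKM at shuffled intergenic placements) sits just above
the planted 0.01 RPKM background; and all three regions with induced genes
classify as significantly up-regulated. Outputs are also written as
TSV/BED/JSON under `demo_out/`, with every threshold and seed recorded in
`demo_out/pipeline.log`.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/rtswitch.R", package="rtswitch"))')" demo --out demo --seed 2
```

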