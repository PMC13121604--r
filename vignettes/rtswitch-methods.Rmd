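---
title: "Replication-timing switch detection and transcription integration: methods"
author: "rtswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication-timing switch detection and transcription integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `rtswitch`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

# The measurement model

E/L Repli-seq sorts S-phase cells into an early and a late fraction and
sequences nascent (BrdU-labelled) DNA from each. For a genomic bin $b$ the
replication-timing signal is

$$\mathrm{RT}(b) = \log_2\frac{E_{\mathrm{rpm}}(b) + \varepsilon}
                              {L_{\mathrm{rpm}}(b) + \varepsilon},$$

where each fraction is first scaled to reads per million of its own
library and $\varepsilon$ is a symmetric pseudocount (default 0.5 RPM).
The symmetric pseudocount keeps the profile antisymmetric under swapping
the fractions, and avoids infinities at empty bins. Bins with raw
$E + L$ below a coverage floor (default 20 per 50 kb bin; the floor is a
package choice, configurable and recorded in the pipeline log) are masked
and excluded from every downstream computation.

Two grids are used, as is conventional: 50 kb bins for statistics and 5 kb
bins for display profiles. In hybrid lines, reads are assumed already
parsed by allele upstream (e.g. by strain-specific variants), so each
allele simply contributes its own pair of fraction tracks.

## Normalization, scaling, smoothing

* **Quantile normalization** maps each sample's unmasked values onto the
  quantiles of a reference sample at matching ranks (ties receive the mean
  of the tied reference quantiles; unequal sample sizes interpolate the
  reference order statistics). When unmasked counts match, the sorted
  output equals the sorted reference exactly, and the operation is
  idempotent. Normalization is genome-wide by default; a per-chromosome
  variant would only be preferable with strong chromosome-scale coverage
  artefacts, which the generator does not produce.
* **Scaling** is an affine map sending the 0.5% and 99.5% genome-wide
  quantiles to −3 and +3, compressing the raw dynamic range (about ±7) to
  a display range (about ±3); values outside the anchors are mapped
  linearly, not clipped, unless requested. Scaling exists for plotting
  only: all statistics consume unscaled values, and the pipeline wiring
  enforces this. The exact historical scaling implementation used for the
  original display tracks is not reproduced; only its documented
  dynamic-range behaviour is.
* **Smoothing** is a centred moving average over
  $n = \mathrm{round}(W / w)$ bins ($W$ = 300 kb window, $w$ = bin size;
  for an even $n$ the extra bin falls on the right), computed over
  unmasked bins only, per chromosome, with windows shrinking at chromosome
  ends. A moving average was chosen over loess because it is linear,
  deterministic, exactly testable (a unit spike spreads to $1/n$ over $n$
  bins), and mass-conserving away from chromosome ends. With truncated
  end windows no constant-preserving linear smoother can conserve the mean
  exactly at the boundary; the package preserves constants (row-stochastic
  weights) and accepts the boundary-mean effect.

# Calling RT switches

Given replicate RT profiles for two conditions on a shared 50 kb grid, the
per-window statistic is $|\bar B(w) - \bar A(w)|$, the absolute difference
of unmasked replicate means. Two testing modes exist.

## Monte-Carlo empirical null

The null distribution is built from the data themselves: for every
replicate pair within a condition, the per-window value differences are
pooled across all genome windows. A pair difference has variance
$2\sigma_w^2$ while the observed statistic has variance
$(1/n_A + 1/n_B)\,\sigma_w^2$, so pool draws are rescaled by
$\sqrt{(1/n_A + 1/n_B)/2}$ before comparison; without this the test would
be severely conservative for designs with more than one replicate per
side. Because the pool is the empirical marginal across windows, the
type-I rate is nominal on average even when measurement noise varies with
RT level (the variance of a log ratio of Poisson counts grows toward the
extremes of the RT range). The empirical p-value uses the add-one
estimator $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{mc})$ and is
never zero.

`n_mc` (default $10^5$) is a resolution parameter, not a study condition:
the smallest attainable p is $1/(n_{mc}+1)$, and with $m$ windows tested
and $k$ truly-changed windows, Benjamini–Hochberg requires
$m \cdot p_{\min} / k \le q_{\text{cut}}$; at $q_{\text{cut}} = 10^{-3}$,
2,000 windows and a hundred-odd signal windows, $n_{mc} = 10^4$ cannot
clear the threshold while $10^5$ comfortably does. A single null sample is
shared across windows (valid because the null is one pooled
distribution), which makes the test $O(n_{mc}\log n_{mc} + m)$.

## Paired / Welch t-test

For designs with enough replicates (the genome-wide eight-replicate
comparison), a vectorized two-sided paired t-test per window (replicates
paired by position; Welch as the unpaired alternative) is exact under
normality and much cheaper. Zero-variance windows are handled explicitly:
p = 1 when the difference is exactly zero, and a missing-value sentinel
(excluded from BH, flagged) when a nonzero difference has zero variance.

## Multiple testing and stitching

Benjamini–Hochberg q-values (via `stats::p.adjust`) control FDR across
tested windows. Windows at $q \le 10^{-3}$ are partitioned by direction
(advance = positive shift in condition 2, delay = negative) and stitched
per direction allowing a 300 kb gap, with bedtools `merge -d` semantics
(separation $\le$ gap merges). Direction purity is required because a
region-level $\Delta$RT and the downstream classification need a sign;
windows of opposite sign are never merged even when interleaved.

## Allelic RT advance

For an engineered clone, the advance of one allele over the other,
corrected for baseline allelic asynchrony, is per 50 kb bin

$$d(b) = \left[\mathrm{RT}_{\mathrm{mut}}^{a_1}(b) -
               \mathrm{RT}_{\mathrm{mut}}^{a_2}(b)\right] -
         \left[\mathrm{RT}_{\mathrm{wt}}^{a_1}(b) -
               \mathrm{RT}_{\mathrm{wt}}^{a_2}(b)\right],$$

reported as the mean over unmasked region bins together with the per-bin
values. Windows whose RT differs from wild type are flagged at
Monte-Carlo p < 0.01 (the rule used to shade track figures).

# Transcription integration

Region transcription is strand-agnostic nascent coverage in RPKM:
$\mathrm{reads} / (\mathrm{kb} \times \mathrm{millions})$, per replicate
and condition; domain-level analysis applies the same computation to a
fixed domain list plus a paired t-test on per-replicate domain RT means.
Transcription change per region is a paired t-test on replicate RPKM with
$\log_2$ fold change $\log_2\!\big((\bar x_2 + c)/(\bar x_1 + c)\big)$,
pseudocount $c = 0.01$ RPKM so induction from silence has a finite fold
change. Region-level significance is uncorrected p < 0.01 (a BH option
exists); this matches treating each stitched region as one pre-selected
test.

## The noise threshold

Whether a "transcribed" region is distinguishable from background is
decided against an empirical null: the RT-advancing regions are placed
uniformly at random within intergenic space (placements independent per
region, lengths preserved, fully contained in the gene-free complement),
the RPKM of every placement is computed, and the threshold is the 0.99
quantile of the pooled shuffled RPKMs. The quantile rule is this package's
declared substitute for reading the threshold off a plot; the quantile and
shuffle count are exposed, and the pooled sample is returned for the
diagnostic plot. Shuffling is genome-wide within intergenic space by
default (a same-chromosome option exists); nothing in the generator makes
chromosomes differ systematically, so the constraint would only matter
with real chromosome-scale effects.

## Classification

Each region with an RT label (advance / delay / no-change, inherited from
called switching regions by majority overlap) is placed in exactly one
transcription category: significantly up / down (p < 0.01, split by fold
change sign), or non-significant and above / below the noise threshold in
the second condition. The cross-tabulation is exhaustive and exclusive by
construction.

# The synthetic-data generator

The generator emulates, per chromosome: a baseline RT field of
constant-level domains (levels from $\{-3, -1.5, 0, 1.5, 3\}$ log2 units,
lengths uniform on 0.6–1.6 Mb — the sub-megabase domain scale) joined by
linear TTR ramps with slope 4 log2/Mb; planted RT switches added to the
second condition (optionally one allele); baseline allelic offsets added
to one allele in both conditions. Fraction counts per bin are
$E \sim \mathrm{Pois}(2\lambda p_E)$,
$L \sim \mathrm{Pois}(2\lambda(1 - p_E))$ with the base-2 logistic
$p_E = 2^s/(1+2^s)$, so the expected measured log2 ratio equals the
planted $s$ and parameter recovery is well-posed. $\lambda$ defaults to
100 reads per bin per fraction, a realistic 50 kb depth for a
30M-read library. Poisson is the default noise model — the real noise
model of fraction counts is unknown, so the simplest null that exercises
the statistics is used — with an optional gamma overdispersion multiplier
to stress type-I behaviour.

Nascent transcription is generated hierarchically: each gene draws a
Poisson total matching its target RPKM at the nominal library size
(default $10^7$ reads/replicate; RPKM is defined against this nominal
size, which the dataset manifest records), spread multinomially over the
gene body by bin overlap, plus per-bin Poisson intergenic background
(default 0.01 RPKM) over the gene-free fraction of each bin. Totals are
conserved exactly.

The demo configuration plants joint RT × transcription classes at random
positions with two constraints that mirror the biology and keep recovery
well-posed: regions are bin-aligned inside the flat interior of a single
domain (so the planted $|\Delta \mathrm{RT}|$ is exact at every
constituent bin and boundary recovery is unambiguous), and advances are
planted in late-or-mid domains, delays in early-or-mid domains — a domain
cannot advance beyond the earliest part of the dynamic range, and without
this constraint quantile normalization would rightly compress impossible
out-of-range values. The allele-specific demo fixes the baseline field
deterministically (alternating ±1.5 domains) with the engineered advance
mid-domain in a late domain, because the variance of $\log_2(E/L)$ grows
steeply at extreme RT and a random placement would make the fixture's
precision depend on the draw.

What the generator does **not** emulate: read-level artefacts (mappability,
GC, duplicates), fragment-level structure, SNP-level allele assignment
errors, correlated biological replicate structure, or chromosome-scale
coverage biases. Passing tests therefore demonstrate the correctness and
calibration of the statistics under a clean, known noise model — not
robustness to every artefact of real libraries.

# Numerical and design choices

* Coordinates are 0-based half-open in every file format (bedGraph, BED,
  truth tables); in memory the package uses Bioconductor `GRanges`
  (1-based closed), with `rtracklayer` converting at the file boundary.
* Merging uses separation $\le$ gap (bedtools `-d`), implemented as
  `GenomicRanges::reduce(min.gapwidth = gap + 1)`.
* Shuffled placements sample an allowed interval with probability
  proportional to its count of eligible start positions, then a start
  uniformly within it — exactly uniform over all eligible placements.
* All Monte-Carlo and shuffle paths require seeds; the pipeline logs every
  threshold, seed and excluded chromosome actually applied, and identical
  configuration yields byte-identical outputs.
* Problem sizes in the shipped tests and acceptance script — a 100 Mb
  genome (2,000 windows of 50 kb) with 4v4 replicates for recovery, 20,000
  windows for the type-I simulation, 100 intergenic shuffles for the noise
  threshold — were chosen as the smallest sizes at which the quantities of
  interest (sensitivity, type-I rate, threshold stability) are estimated
  with comfortable margins.
* Chromosome exclusion (e.g. a chromosome that is homozygous in one clone
  and hence not allele-resolvable) is a plain filter applied before any
  statistics.

# Known limitations

* The Monte-Carlo null treats windows as exchangeable; spatial
  autocorrelation of RT noise is not modelled (nor is it generated), and
  an HMM-style segmentation is out of scope.
* Quantile normalization assumes the compared samples share a marginal RT
  distribution; when a large fraction of the genome genuinely changes, it
  attenuates the largest shifts. With the planted fractions used here
  (<10% of bins) the attenuation is mild.
* The paired t-test's exactness relies on approximate normality of
  replicate means; at very low coverage (heavily masked bins) the MC mode
  is preferable.
* Barcode counting is exact substring matching only — no mismatch
  tolerance — matching its intended use of counting engineered 16-mers.
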