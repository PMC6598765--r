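---
title: "Carry-over calibration and QC for CUT&RUN: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carry-over calibration and QC for CUT&RUN: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrycal)
```

## The problem

CUT&RUN tethers micrococcal nuclease to antibody-bound chromatin in intact
permeabilized cells and releases only the targeted fragments, so background is
far lower than in ChIP-seq. That is a blessing for signal-to-noise and a curse
for normalization: there is no genome-wide background to scale by, so samples
in a series (antibody titrations, cell-number titrations, digestion time
courses) need an external calibrant. The usual answer is a heterologous
spike-in added at the stop step. The alternative this package is built
around: the fusion protein is purified from *E. coli*, and residual *E. coli*
DNA binds the concanavalin-A beads along with everything else. Because the
bead amount is held constant across a series, the carried-over DNA is present
in constant amount per sample — it behaves exactly like a deliberately added
spike-in, and it is present in every CUT&RUN library ever made, so series can
be recalibrated after the fact.

## Calibration model

Let $C_i$ be the number of fragments of sample $i$ mapping to the calibration
genome (spike-in or carry-over, per `calibration_config(mode)`). The scale
factor is

$$ s_i = \frac{m}{C_i}, \qquad m = 10{,}000 \text{ by default}, $$

and calibrated signal is raw signal times $s_i$. The multiplier $m$ is a pure
display constant: all ratios between samples are independent of it. A zero
$C_i$ is an error, not a silent 0 or Inf — it is precisely the situation of a
sample whose spike-in was omitted, which is recoverable by switching to
carry-over mode.

Why this works: if sample $i$ contains primary material $M_i$ (proportional
to cells times per-cell occupancy) and constant calibrant material $K$, and
the library of sample $i$ is recovered/sequenced with efficiency $e_i$, then
counts are $X_i \approx e_i M_i$ and $C_i \approx e_i K$, so $X_i\, m / C_i
\approx m M_i / K$: the nuisance $e_i$ cancels and calibrated counts compare
material across samples on a common scale.

The concordance diagnostic `spike_carryover_correlation()` is the Pearson
correlation between spike-in and carry-over counts across the samples of a
group, computed on raw counts. Raw-count correlation is deliberate: the
packaged batch table (`h3k27me3_batch_counts()`) reproduces its four printed
group correlations (0.92, 0.99, 0.94, 0.90) only on raw counts, and the test
suite pins this with an independent covariance-formula oracle. Correlations
are rounded to two decimals for display only.

## (TA)n masking

Some sequencing libraries carry (TA)n low-complexity contamination of
undetermined origin that cross-maps into genomic (TA)n tracts.
`scan_ta_repeats()` finds all maximal runs of strictly alternating T/A —
either phase, starting with either base, case-insensitive, `N` or any other
base breaking the run — of length at least `min_run_length` (default 25 bp,
the length of a (TA)$_{12}$T query). This is an exact scanner, not a
heuristic aligner: an alignment search with the same query admits imperfect
matches, so region counts on a real genome will differ from an
alignment-derived mask. We accept that deviation for determinism and zero
dependencies, and therefore make no claim of reproducing any particular
genome-wide region count. Filtering is binary and conservative:
`exclude_fragments()` removes every fragment with ≥ 1 bp overlap with any
mask region, per half-open BED semantics.

## Coverage normalization

`fractional_count_track()` implements scaled fractional counts: with per-bp
depth $d(x)$ over a genome of size $G$,

$$ v(x) = d(x)\, \frac{G}{\sum_y d(y)}. $$

The defining property — if counts were distributed uniformly, the value would
be 1 at every bp — forces the denominator to be total base-pair coverage
$\sum_y d(y)$ (the sum of fragment lengths), not the fragment count; for
finite-length fragments only this normalization makes a tiling of unit-depth
fragments map to exactly 1. Two consequences the tests assert: the
bp-weighted mean of every track is exactly 1 (to 1e-9), and the track is
invariant to duplicating the fragment set. No mappability or GC correction is
attempted. bedGraph output prints 5 significant digits, drops trailing `.0`
on integers, and omits zero runs.

## Peak scoring and QC

* **Summit windows.** Scores are means over `[summit − flank, summit +
  flank]` *inclusive* — 301 bp at the default `flank = 150` — truncated at
  chromosome ends (a truncated window averages over its actual width).
  Bases without coverage count as zero, the bedGraph reading of absent
  intervals; treating them as missing would bias sparse samples upward.
* **IgG filter.** A peak is removed when its IgG-control score is *strictly
  greater* than the `igg_percentile` (default 99) percentile of all IgG
  scores, with the percentile computed by linear interpolation between order
  statistics (the convention of mainstream statistical software; on scores
  1..100 the 99th percentile is 99.01, so exactly the top scorer is removed).
  Ties at the threshold are retained.
* **Correlation matrices.** Peak rows with any missing entry are dropped
  before *all* pairwise correlations (complete-observation policy), so every
  entry of the matrix is computed on the same peak set; R² is the square of
  Pearson r. R² is invariant to positive affine rescaling of columns, which
  is what makes the matrix insensitive to calibration scaling — asserted as a
  property test.
* **FRiP.** Fragments (pairs), not reads, overlapping ≥ 1 bp of ≥ 1 peak.
  `frip_series()` draws an *independent* seeded subsample at each depth of a
  halving series; nested subsets are available behind a flag but
  independence is the default because nothing in the down-sampling design
  requires coupling.

## The synthetic generator

`sim_config()` specifies toy genomes (defaults: 1 Mb primary, 100 kb
spike-in, 100 kb carry-over), per-sample expected primary fragment counts
(default 20 samples log-spaced over 1e3–1e5, a 100-fold input titration),
constant expected spike-in (1,000) and carry-over (5,000) fragments per
sample — Poisson-distributed so concordance statistics are non-degenerate —
and peak structure: 50 evenly spaced 1 kb sites with enrichment folds on a
geometric ladder from 4 to 64, plus a 10% uniform background, fragment
lengths truncated-normal 150 ± 30 bp (nucleosomal scale).

Two modeling choices deserve explanation:

* **Shared recovery factor.** Each sample draws a lognormal factor
  (mean 1, CV 0.5 by default) multiplying the expected counts of *all three*
  genomes. Physically this is per-sample variation in material recovery and
  library representation, which is what moves spike-in and carry-over counts
  up and down together in real series; the batch table shows exactly this
  (antibody-first samples recover several-fold more of both calibrant
  genomes). Statistically it is load-bearing: with independent Poisson counts
  at constant rates, spike-in and carry-over would be uncorrelated and no
  concordance could be demonstrated. Because the factor multiplies primary
  and calibrant counts alike, carry-over calibration cancels it — which is
  the property the recovery tests measure (calibrated occupancy per unit
  input constant across a 100-fold titration within 3 SE, versus ~50%
  apparent variation uncalibrated).
* **Contamination as redirection.** Premature release of the nuclease-bound
  complex under standard digestion lets it cleave accessible DNA,
  adding diffuse background. The generator first draws every primary
  fragment as signal (peak or background), then redirects an independent
  `contamination_rate` fraction to uniform positions. Drawing the release
  indicator independently of all signal draws means two series simulated from
  the same seed at different contamination rates are matched fragment for
  fragment, so protocol contrasts are paired comparisons rather than
  comparisons of unrelated random datasets. Marginal class proportions are
  the usual mixture ones.

What the generator does *not* emulate: sequence-level reads (no FASTQ, no
alignment errors, no duplicates), mappability structure, cross-mapping
between genomes, antibody or digestion kinetics (time-course yields are free
multipliers, not a kinetic model), and peak calling (true peak locations are
used as the peak list, since peak calling is outside the package). Passing
simulation-based tests therefore demonstrates the correctness and statistical
behavior of the computations, not performance on any particular real
dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale, chosen
so each check exercises the relevant statistics with comfortable margins:
oracle-equivalence checks use 1,000 randomized instances per operation on
~150–500 bp toy chromosomes; conservation checks use 100 random fragment sets
on a 4 kb genome (tolerance 1e-9 on a quantity that is exact up to float
summation); the titration scenario uses 20 samples on a 1 Mb genome; the
protocol contrast uses 50 replicate pairs of 5-timepoint courses (yields
spanning 100-fold, ~2 × 10^4 expected fragments at unit yield) on a 400 kb
genome with 40 peaks. Correlation oracles agree to 1e-12; bedGraph round
trips agree to the 5-significant-digit formatting precision.

Degenerate inputs are errors, not silent values: empty fragment sets cannot
produce FRiP or fractional tracks, zero calibration counts cannot produce
factors, zero-variance vectors yield `NA` correlations with a warning, and
summits off the genome name the offending peak.

## Seeding

Every stochastic operation takes an explicit seed; none touches the global
RNG state (seeds are applied and the caller's state restored). Per-sample
simulation seeds derive deterministically from `(master seed, sample index)`,
so any sample can be regenerated in isolation, and the CLI's manifest files
record everything needed to reproduce a run byte for byte.

## Known limitations

The calibration is relative, not absolute: it compares material across
samples and says nothing about per-cell occupancy without an external anchor.
Carry-over calibration inherits the constant-bead assumption; series with
varying bead amounts need the explicit spike-in mode. The (TA)n scanner is
exact-match by design and will not find degenerate or interrupted repeats.
The package consumes aligned, genome-assigned fragments; alignment, peak
calling and cross-mapping correction are upstream concerns.
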