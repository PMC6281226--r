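---
title: "Quantifying index switching from antigen-receptor cross patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying index switching from antigen-receptor cross patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbleed)
```

## The measurement problem

Dual-indexed plate libraries identify each well by a (row index, column
index) pair. When all index combinations are used exhaustively — the normal
situation in plate-based single-cell RNA-seq — a read whose row or column
index has been exchanged during ExAmp cluster generation demultiplexes to a
*different, valid* well, and nothing in the read reveals the error. The one
systematic trace it leaves is geometric: a single-index switch can only move
reads to wells sharing one index with the source, so spurious signal from a
well-specific transcript forms a cross pattern in the plate layout. Row
indices are plate-specific while column indices are shared by all plates
pooled on a lane, so the column arm of the cross spans plates and the row
arm does not.

Recombined antigen receptors are near-ideal well-specific transcripts: each
T or plasma cell carries an effectively unique `V_junction_J` sequence,
expressed at thousands of TPM in its own well. Observing that marker at low
level in other wells of the cross, and essentially nowhere else, both
demonstrates index switching and measures it.

## Model and estimator

Let a marker have source well $s$ with expression $e_s$ (TPM), and let
$r_w = e_w/e_s$ be its relative expression in well $w$. The per-marker
misassigned fraction is

$$\hat S = \sum_{w\,\in\,\mathrm{row\ arm}(s)} r_w
         + \sum_{w\,\in\,\mathrm{col\ arm}(s)} r_w,$$

the summed recipient relative expression over the cross. Under a per-read
channel in which the row index switches with probability $s_{row}$ (target
uniform over the other row indices of the lane) and the column index
independently with $s_{col}$, the source retains a fraction
$(1-s_{row})(1-s_{col})$ of its reads and each arm sums to an expected
$s/(1-s)$, giving

$$E[\hat S] \approx \frac{s_{col}}{1-s_{col}} + \frac{s_{row}}{1-s_{row}},$$

i.e. for small rates, the total single-index switching probability. This
expectation assumes equal library sizes across wells (the TPM denominator
cancels) and no contamination; `expected_spread()` exposes it as the
analytic oracle used in the test suite. Two conventions for reporting are
available: the sum $\hat S$ itself (default) and $\hat S/(1+\hat S)$, the
share of the marker's total signal that left the source. At
$\hat S \approx 0.04$ they differ by under 0.2 percentage points; the
default follows the summed-relative-expression definition of the estimator.

Double switches ($s_{row} s_{col}$, order $10^{-4}$ per read) and physical
contamination land outside the cross. Outside-cross signal is therefore
*never* added to $\hat S$; it is reported as a separate diagnostic column
and drives the marker filters below.

## Marker curation

An estimate is only as good as the claim that one cell generated the
signal. The procedure is:

1. **Origin wells.** For each marker detected in at least three non-control
   wells of a batch, the well with maximal TPM is the origin. Markers below
   three detections carry too little spreading evidence and are reported in
   a low-evidence table but never estimated.
2. **Source criteria.** A well is a source if (i) the marker is detected
   elsewhere on its row or column (cross centre); (ii) its expression is at
   least five-fold the maximum over all other wells on both arms; (iii) the
   well's annotated cell type matches the marker family (T cell for TR,
   plasma cell for IG); (iv) the marker is the well's top marker among the
   same family and chain — alpha and beta rank separately, so one cell can
   source one alpha and one beta marker.
3. **Rejection filters.** A marker is excluded if detected in fewer than
   three wells, in more than three outside-cross wells, or with more than
   two sources; a marker passing all three but with no well meeting the
   four criteria is excluded as source-less (its rate cannot be anchored).
4. **Marker level.** V-gene segments are preferred (more readily detected
   than full-length receptors), unless a V gene is detected in more than
   one outside-cross well or has more than two sources — the signatures of
   a V gene shared by several receptors — in which case the full-length
   receptors using it substitute.
5. **Dual sources.** A marker with two accepted sources (a clone present
   twice) has the signal on wells lying in both crosses allocated in
   proportion to the source expressions; the second share is computed as
   the complement of the first so per-well conservation is exact in
   floating point. Relative expression is then taken against each source's
   own level.
6. **Exclusions.** The A1 well of every plate is a multi-cell positive
   control and is excluded from every set (cross, outside, detection
   counts, estimates). IG (BCR) markers are profiled but excluded from rate
   estimation by default: plasma cells devote the majority of their
   transcriptome to immunoglobulin, and assemblers reconstructing receptors
   from index-switched reads produce spurious low-expression BCR markers;
   `include_bcr = TRUE` re-enables them.

Recipient wells with relative expression at or above 0.1 are flagged as
possible in vivo clonal expansion rather than switching; the threshold sits
in the empirical gap between switching artefacts (almost all below 0.05)
and true duplications (0.1–0.99), and is configurable.

## Per-index propensities and the two tests

For each column index $c$, the wells reachable from a source by a *single*
column switch into $c$ are exactly the wells with the source's row index
and column $c$. The propensity of $c$ accumulates the relative expression
of those wells over all curated markers whose source does not use $c$, and
divides by the number of such markers (the index's exposures). Row indices
are handled symmetrically. Under uniform switching all propensities share
one expectation; an index consistently favoured as a switch target stands
out. The division by exposures is our reading of the published per-index
adjustment ("dividing by the frequency the index was not used as source");
it is the only normalisation that makes propensities comparable across
indices with different exposure counts, and it is applied nowhere else.

Two hypothesis tests are attached. The contamination test exploits the
two-plate geometry: the column arm crosses the plate boundary, and index
switching is blind to it while physical contamination is plate-local. Per
marker, the mean relative expression in same-plate and other-plate
column-arm wells forms a pair; a one-sided paired t-test (source plate
higher) detects contamination. Zero-variance differences return a flagged
degenerate result rather than an error. The platform comparison is a
two-sided equal-variance (Student's) two-sample t-test on the misassigned
fractions grouped by platform, with group medians reported. Both reuse
`stats::t.test`; the acceptance suite checks the paired statistic against
an independently hand-computed closed form.

## The simulator

`generate_batch()` emulates the study conditions so that every stage can be
verified against ground truth. Each occupied well hosts one cell with a
unique randomly generated `V_junction_J` marker (TR for T cells, IG for
plasma cells); clonal pairs share a marker. The cell emits
$N \sim \mathrm{Lognormal}(\mu, \sigma)$ marker reads, and each read
independently lands according to the product channel: row kept with
$1-s_{row}$ or switched to a (by default uniformly) random other row of
the lane, column likewise, with an optional plate-local contamination
channel that re-routes a read to a uniformly random other well of the
source plate. Landed reads are converted to TPM against a constant
background library, and an optional detection floor zeroes TPM below it.
Read counts are conserved exactly, and a fixed seed reproduces the batch
bit for bit.

Defaults are the study conditions, chosen once: a two-plate batch (16 × 12
index pairs, A1 controls), 90 T and 90 plasma cells, $s_{row} = s_{col} =
0.02$ (total 4.08%, the neighbourhood of rates reported for ExAmp
platforms), contamination 0, dropout 0, clone probability 0.02, background
$10^6$ reads per well, and marker depth $\mu = \log 7700$, $\sigma = 1.04$
— calibrated so marker TPM has median ≈ 7658 and quartile ratio ≈ 4,
matching the descriptive statistics of curated receptor markers in real
plates. Switch-target weight vectors are exposed to simulate index
proneness for power studies; uniformity is the default because no
consistent proneness is observed empirically.

What the generator deliberately does not emulate: assembler behaviour
(misassembled receptors from switched reads — the reason BCRs are excluded
— arise upstream of this package's inputs), index-sequence errors
converting one index into another (negligible with well-separated index
sets), per-well variation in background library size, ambient RNA, and
dual-index-switch rate estimation (not identifiable from cross geometry).
Passing tests therefore demonstrate that the estimator recovers the rates
of this channel model, not that real libraries obey it; on real data the
filters absorb — but cannot fully rule out — contamination and misassembly.

## Numerical and design choices

* Detection floor: TPM > 0 by default (no floor is stated for the original
  analysis); exposed for sensitivity analysis, as is the five-fold factor.
* The five-fold dominance comparison is non-strict (≥), and criterion (iv)
  tolerates ties at the top; exact TPM ties are unlikely after
  quantification but must not crash.
* Origin ties resolve to the lexicographically smallest well label, with a
  warning.
* "Detected in more than two wells" (origin rule) and "fewer than three
  wells" (filter) are treated as the same ≥3 threshold.
* Quantiles use linear interpolation (`stats::quantile` type 7), stated in
  the report metadata because a median and IQR alone cannot pin the
  convention.
* Summaries are reported per marker and per source well (markers of one
  well averaged first), since one cell can source several markers and the
  two groupings differ.
* Internal coordinates are plate/row-letter/column; displays use the
  star-suffix dialect for the second plate of a batch ("D\*5"), accepted on
  input and normalised on output.
* Expression TSVs are written with 6 significant digits, making write–read
  round trips exact at that precision.

## Scope of the test suite

The suite verifies the worked normalization example (320/1104 within-cross
vs 13/6820 outside-cross detections → 99.35% of spread within the cross),
the partition and conservation identities exactly, parameter recovery at
total switching rates 0.02–0.08 (two batches of 100 T-cell markers per
condition, median within ±25% of the closed form, monotone across matched
seeds), oracle equivalence of per-recipient means over 200 markers within
three standard errors (markers as the sampling unit, deep background so
libraries are equal as the oracle assumes), closed-form checks of the
paired t statistic, and uniformity of the platform-test p-value under the
null over 200 simulated batch pairs (Kolmogorov–Smirnov at α = 0.01).
These problem sizes keep the full suite around a minute on one core while
leaving Monte-Carlo bands well inside the tolerances tested.

## Known limitations

* At high switching rates the outside-cross filter preferentially rejects
  deep libraries (their double switches become visible), so the accepted
  set thins; the median remains calibrated but its sampling error grows.
* Relative expression is a ratio estimator; its small positive bias
  ($\mathcal{O}(1/N)$ in the source read depth, plus the marker's own
  contribution to the TPM denominator) is negligible at realistic depths
  but measurable in very deep simulations.
* Contamination inflates both the estimate and the outside-cross rejection
  rate; the paired test detects plate-local contamination but cannot
  separate a lane-wide contaminant from switching.
* Layouts beyond the shared-column two-plate design (e.g. partially
  overlapping index sets) are out of scope.
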