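# crossbleed

Quantify index switching ("index hopping") in dual-indexed, plate-based
single-cell RNA-seq using cell-unique antigen-receptor markers.

## The problem

On patterned-flow-cell Illumina platforms (HiSeq 3000/4000/X, ExAmp cluster
generation), free adaptors can prime library molecules and exchange one of
the two sample indices, so a fraction of reads demultiplexes to the wrong
well. In plate-based experiments each well is identified by a (row index,
column index) pair; a single-index switch therefore moves reads to a well
sharing one index with the source — the spurious signal traces a **cross
pattern** centred on the source well, with the column arm spanning all
plates pooled on the lane and the row arm confined to the source plate.

T and B cells provide natural tracers: V(D)J recombination makes each cell's
receptor (`V_junction_J`, e.g. `TRBV11-3_CTTAGTAGGGAACATGAAC_TRBJ1-1`) a
near-unique, highly expressed marker of exactly one well. crossbleed turns
this observation into an estimator of the per-well read-misassignment rate,
for anyone running Smart-seq2-style plate experiments with TraCeR/BraCeR
receptor reconstruction and Kallisto quantification.

## The estimator

For a marker with source well $s$, let $e_w$ be its expression (TPM) in well
$w$ and $r_w = e_w / e_s$ the relative expression. The misassigned fraction
of the marker is the summed recipient relative expression over the cross:

$$\hat{S} \;=\; \sum_{w \in \text{row arm}} r_w \;+\; \sum_{w \in \text{col arm}} r_w .$$

Under per-read single-index switching at rates $s_{row}$ and $s_{col}$,
$E[\hat S] = s_{col}/(1-s_{col}) + s_{row}/(1-s_{row})$, so $\hat S$
estimates the total switching rate. Markers qualify through the published
procedure: an origin well (batch maximum, ≥3 detections), four source-well
criteria (cross centre, ≥5× dominance over both arms, matching cell type,
top same-chain marker in the well), three rejection filters (<3 wells, >3
outside-cross wells, >2 sources), V-gene markers preferred over full-length
receptors unless the V gene smears outside its cross, dual (clonal) sources
allocated proportionally, BCR markers excluded from estimation, and the A1
multi-cell control wells excluded throughout. Per-index switching
propensities, a one-sided paired t-test for plate-local contamination, and a
Student's t platform comparison complete the analysis.

A stochastic plate simulator (`generate_batch`) with known ground truth and
a closed-form spread oracle (`expected_spread`) make every stage testable.

## Worked example

Simulate a two-plate batch (16 row × 12 column indices, 90 T + 90 plasma
cells) with 2% per-read switching per index, and fit:

```r
library(crossbleed)
batch <- generate_batch(sim_params(seed = 42))
fit <- fit_switching(batch$table, batch$space)
summary(fit)
#> Index-switching fit for batch 'Batch3' (HiSeq4000)
#>   markers profiled: 180 (0 low-evidence)
#>   accepted for estimation: 50 markers, 50 source wells
#>   misassigned fraction: median 4.0% (IQR 3.6%-4.2%)
#>   rejections: bcr_excluded=45, too_many_outside=85
#>   contamination (source plate > other plate): t = -0.209, df = 49, one-sided p = 0.5823
#>   groups: same_plate = 0.001342, other_plate = 0.001352
#>   index propensities: 0.0011-0.002 (row+column)
```

The median misassigned fraction of 4.0% recovers the simulated truth
($2 \times 0.02/0.98 = 4.08\%$). BCR markers pass through profiling but are
excluded from the rate estimate (`bcr_excluded`); markers whose signal
leaks into more than three outside-cross wells — here the deepest libraries,
whose rare double switches become visible — are dropped as unreliable
(`too_many_outside`). The contamination test finds no source-plate excess,
as it should with the contamination channel off. Per-marker estimates:

```r
round(head(coef(fit), 3), 4)
#>     TRBV16-2_ATGGCATGGGTAATG_TRBJ1-5|Plate4:E2
#>                                         0.0444
#>     TRAV28-1_CGTGGAGTCTCTGTGA_TRAJ34|Plate4:G3
#>                                         0.0444
#> TRBV23-2_ATGGCCCCGCTTAACGGGT_TRBJ2-2|Plate5:C4
#>                                         0.0367
```

`plot(fit, marker)` draws the plate-map of any marker with its source well
outlined — the visual cross-pattern check. Real data enter through
`read_layout()` + `read_expression_matrix()` (markers × wells TSV) or
`read_kallisto_abundance()` (per-well `abundance.tsv` files), and
`run_pipeline()` drives simulate → analyze → report with file artifacts.

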