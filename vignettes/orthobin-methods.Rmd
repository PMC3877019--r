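---
title: "orthobin: methods, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthobin: methods, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthobin)
```

## The model

orthobin compares bulk transcriptomes of two species measured on
platform-specific whole-genome arrays. Because the two platforms' probes
target different sequences, absolute intensities are confounded with probe
affinity, and only *within-dataset ranks* are treated as comparable across
datasets. The unit of comparison is the percentile rank of a gene's
replicate-averaged, probe-collapsed log2 intensity:

$$P(g) = 100 \cdot \frac{\#\{h : \bar{x}_h < \bar{x}_g\}}{N} \in [0, 100)$$

discretized into four bins: `H` ($P \ge 90$), `M` ($50 \le P < 90$),
`L` ($10 \le P < 50$), `VL` ($P < 10$). The central cross-species statistic
is the extreme-bin intersection: an ortholog pair (matched by case-folded
gene symbol) that is `H` in one species and `VL` in the other is a
species-specific expression call, provided the gene carries a curated
RefSeq (`NM_`) transcript accession in both species and its duplicate
probes hybridized consistently in both. Requiring the two most extreme
deciles makes the call robust to affinity differences: no plausible
affinity shift moves a gene from the bottom decile of one platform to the
top decile of the other.

Assumptions worth stating explicitly:

* Arrays within a dataset are biological/technical replicates of one
  condition; between-array variation is a monotone (approximately affine)
  distortion plus noise, which quantile normalization removes.
* Gene symbols identify orthologs one-to-one. This is the standard
  symbol-annotation rule; paralog families sharing a symbol prefix are not
  disambiguated, and genes named differently in the two species are
  silently unmatched (they can only reduce sensitivity, not create false
  calls).
* Expression supports a total order; ties are measure-zero on continuous
  data but are handled deterministically (below) because rounded public
  deposits do tie.

## Pipeline stages and their parameters

| Stage | Function | Parameters (default) |
|---|---|---|
| Between-array normalization | `quantile_normalize()` | none |
| Replicate averaging | `average_replicates()` | none (arithmetic mean over non-missing samples) |
| Probe → gene collapsing | `collapse_probes()` | consistency rule: provisional bin span ≤ 1 adjacent category |
| Ranking and binning | `percentile_rank()`, `assign_bins()` | cut-offs `c(10, 50, 90)` percentiles |
| Specific-gene calling | `call_specific_genes()` | bins (`H`, `VL`); curated filter `NM_` |
| Concordance | `concordance()` | denominator = query's `H` set; `round()` to integer percent |
| Gene-set profiles | `gene_set_profile()` | flag threshold: bin distance ≥ 2 under `VL < L < M < H` |

The cut-offs are deliberately configurable (`cutoffs =` everywhere, and
`--cutoffs` on the CLI): the 10/50/90 split is a convention, not an
estimate, and sensitivity analysis should be cheap. All analysis stages
are deterministic and seed-free; the only randomness in the package lives
in the synthetic generator.

### Numerical conventions

* **Percentiles** use strict-lower counts, so values lie in $[0, 100)$ and
  ties share a percentile. This is deterministic and permutation-invariant,
  and it honors "top 10%": with $N$ tie-free values, exactly $N/10$ genes
  have $P \ge 90$.
* **Bin boundaries** are half-open, closed at the lower edge
  (`H = [90, 100)`, `M = [50, 90)`, `L = [10, 50)`, `VL = [0, 10)`). The
  verbal interval labels "50–90th" and "10–50th" overlap at their
  endpoints; a deterministic partition requires choosing a side, and
  closing at the lower edge keeps a gene exactly at the 90th percentile in
  the top decile.
* **Quantile normalization** maps each sample onto the mean of the
  samples' empirical quantile functions. On complete matrices this is the
  classical sorted-column-mean algorithm (it agrees with
  `limma::normalizeQuantiles`, which the test suite uses as an independent
  oracle); with missing entries, samples are aligned by linear
  interpolation of their quantile functions at mid-rank grid points, and
  missing entries stay missing. Tied input values receive the mean of
  their target quantile values. The upstream two-color "aquantile"
  (A-value) flavour is implemented as plain quantile normalization of the
  provided log2 matrix: downstream only within-dataset ranks survive, and
  a monotone within-sample transformation leaves those unchanged. Output
  tables record this substitution in their provenance headers.
* **Ranking happens once, on replicate-averaged, gene-collapsed means** —
  not per-array with rank averaging. This is order-free and reproducible;
  per-array ranking followed by averaging gives near-identical bins on
  replicate-consistent data but depends on tie-breaking order.
* **"Inconsistent hybridization"** has no published numeric rule, so it is
  operationalized on the rank scale: a gene is dropped when its duplicate
  probes' provisional bins span more than one adjacent category (e.g.
  `H` with `L`). The rule is scale-free, testable and symmetric in probe
  order. Genes dropped this way are excluded from ortholog matching in
  either species.
* **Curated-accession rule**: a gene passes the `NM_` filter when at least
  one of its probes carries an `NM_` accession; whether *all* duplicates
  must be curated is not specified anywhere, and the any-probe rule keeps
  genes whose extra probes are merely predicted models. The flag is
  carried per dataset, and the specificity call requires it in both
  species. The filter applies at the comparison stage only — bin counts
  are reported before it.
* **Concordance** percentages divide by the *query* dataset's high-bin
  size and round to the nearest integer; this is the reading consistent
  with published overlap tables of this kind (787/1106 → 71%, 1072/1277 →
  84%, etc.), which the acceptance tests verify arithmetically.
* **Degenerate inputs**: a sample with no observed values is an error; a
  probe with no observed values is dropped with a warning (not imputed);
  an empty gene table round-trips as a header-only file; ranking below
  100 genes warns that percentiles are coarse (the math still follows the
  definition down to N = 1).

## The synthetic-data generator

`generate_synthetic()` emulates the study design the pipeline targets —
two species profiled on separate platforms with a shared ortholog set —
as a *stated world*, not a tuning knob:

* 7 replicate arrays for species A ("human") and 3 for species B
  ("mouse"), the sample sizes of the motivating design;
* baseline log2 gene means drawn once from $\mathcal{N}(8, 2^2)$ and
  shared between species (orthologs). Only ranks matter downstream, so
  the distributional choice is inert; 8 ± 2 log2 units is a realistic
  dynamic range for array intensities;
* 3 planted B-specific genes and 0 A-specific genes by default, mirroring
  the asymmetric outcome the pipeline is meant to detect. Planted means
  sit `specific_margin_bins = 2` local bin widths beyond the 90th/10th
  percentile values of the background (a "local bin width" is the value
  distance between the 80th and 90th, or 10th and 20th, background
  percentiles), so zero-noise recovery is exact by construction and
  moderate noise rarely flips a call;
* planted bin-shifted genes at exactly `shift_distance` bins (placed at
  bin mid-percentiles), decoys for the two filters
  (`n_decoy_noncurated`: specific-like but `XR_`-annotated;
  `n_decoy_inconsistent`: specific-like with a duplicate probe two bins
  away), duplicate probes with small jitter (10% of genes, 5% of those
  inconsistent), 10% non-curated background genes, and a few control
  probes;
* per-array affine distortion (scale in [0.8, 1.2], offset in [−1, 1]
  log2) that quantile normalization must undo, plus i.i.d.
  $\mathcal{N}(0, \texttt{noise\_sd}^2)$ noise per probe × sample
  (default 0.25 log2 units, a typical replicate-array residual). The
  distortion draws are consumed from the RNG stream whether or not the
  flag is on, so toggling distortion with a fixed seed changes nothing
  else — this is what makes the distortion-invariance test exact.

What the generator does **not** emulate: probe-sequence affinity biases
(the very thing the rank transform is designed to absorb — synthetic
probes for the two species measure the same mean), background
fluorescence, spatial artifacts, dye effects, correlated gene modules,
and platform-specific gene coverage (both synthetic platforms cover all
genes; real cross-platform comparisons lose genes to coverage, which is
why `gene_set_profile()` has an explicit "-" absent state). A green
planted-truth test therefore establishes that the *pipeline logic* is
correct, not that any particular biological dataset would reproduce a
published call set; reproducing published numbers additionally depends on
the deposited raw data, feature-extraction software versions and
annotation vintages, which no desk-scale test can fix.

## Design choices where the design was open

* **Probe-level vs gene-level high counts.** Published gene counts of
  this kind are ambiguous between probes and unique symbols (the two can
  differ by 20% or more on 44k arrays). `bin_dataset()` therefore records
  both in its `stats` element, and `run_bin()` logs them side by side.
* **Pooled vs per-array ranking** for the smaller replicate group: pooled
  (rank the replicate-averaged means), for determinism; see above.
* **Configs are JSON** (not YAML): the R dependency footprint stays at
  `jsonlite`, which the pipeline already needs for truth files and
  reports.
* **Linear vs log2 deposits**: series-matrix values are taken as log2
  unless the dataset entry sets `log2_transform`, in which case
  non-positive entries become missing before transformation and the
  choice is recorded on the object (`log2_transformed_on_read`).

## Known limitations

* Symbol-identity ortholog matching misses renamed orthologs and
  many-to-many families; a homology-table hook would change the matching
  module only, but is intentionally out of scope.
* The consistency filter needs duplicate probes to act; single-probe
  genes are never checked for hybridization quality.
* Concordance compares `H` bins only; it says nothing about agreement in
  the other three bins (the cross-bin matrix from `run_compare()` does).
* The percentile definition makes bins depend on the gene universe after
  collapsing; comparing datasets filtered to very different universes
  shifts what "top decile" means. This is inherent to rank methods, not
  fixable locally.
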