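---
title: "Models and methods behind scqpcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scqpcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the numerical conventions,
and the design choices made where the design was genuinely open. It states
no empirical result that the package's tests or `scripts/acceptance.R` do
not themselves compute.

## The data and its scale

A single-cell qRT-PCR experiment measures, for each cell and each gene on a
fixed panel, a cycle threshold Ct: the PCR cycle at which amplification
crosses detection. Ct is inversely related to input transcript abundance
(one cycle ≈ one doubling), and a reaction that has not crossed by the final
cycle — the limit of detection, LOD, in cycles — yields no measurement
(dropout). Plate exports additionally carry per-chamber Pass/Fail quality
calls and use a `999` sentinel for failed reactions; all of `999`, blank
cells, declared missing tokens and `Fail` calls are treated identically as
*not detected*. This convention is the parser's, not the instrument
vendor's: the export dialects are not formally specified anywhere, so the
defaults (`biomark_dialect()`) are documented assumptions with override
hooks for every column name, the delimiter, the fail token and the sentinel.

Index sorting deposits one cell per well and records the cell's
surface-marker and scatter intensities at sort time. The well ID is the only
shared key between the expression file and the index table, so every reader
canonicalises well labels (`"a1"` → `"A01"`); cell IDs are plate-qualified
(`"P2:A01"`) because well IDs alone collide across runs. Join mismatches
are warnings, not errors — sorters legitimately record wells whose
amplification later fails — and intensities may be negative after sorter
compensation, so no clamping is applied.

Multi-plate concatenation requires identical gene panels and identical LOD.
A silent panel intersection would hide chip mix-ups, which is why a mismatch
is a hard error listing the differing genes.

## QC and the stage machine

Filtering uses per-gene rules on **raw Ct** (`Ct ≤ max_ct`, optionally
requiring detection), combined with `all` (default) or `any`. The default
combinator is `all` because a positive control failing in any channel marks
a failed cell. A not-detected entry passes a rule with
`require_detected = FALSE` vacuously — there is no Ct to compare. Whether
thresholds should apply per control gene or to a combined statistic is not
settled by practice; per-gene rules plus a combinator is the chosen
generalisation. QC summaries use `hist()` binning pooled over cells plus a
per-plate Gaussian kernel density with Silverman's rule-of-thumb bandwidth
(`bw.nrd0`), so the summaries are exactly reproducible.

Transformations compose in a fixed order enforced by a stage machine
(`raw_ct → inverted → hk_normalised → z_transformed`, with housekeeping
optional and also permitted on raw Ct). Violating the order raises an error
naming the expected stage. Two orderings the original ecosystem leaves
ambiguous — housekeeping before vs after inversion, and z per gene vs per
cell — are parameters rather than guesses; the defaults are inversion first
and `per_gene`.

- **Inversion**: detected entries become `LOD − Ct`, clamped at 0 for
  supra-LOD Ct; dropouts become 0, equivalent to imputing Ct = LOD — no
  detection by the final cycle means expression at or below the floor. The
  double-inversion identity is exact up to one ulp of the floating-point
  subtraction, which is the tolerance the tests assert (`< 1e-12`).
- **Housekeeping-median scaling**: per cell, the median `m_c` of the
  detected housekeeping values is shifted to the grand median `M` of the
  `m_c` by adding `M − m_c` to every value in the cell. "Scaling to a
  median" is implemented additively because ΔCt arithmetic is additive on
  the cycle scale (multiplicative in linear expression space); the grand
  median is used as reference because any fixed target would be arbitrary.
  Afterwards each cell's housekeeping median equals `M` *exactly* and
  within-cell gene differences are unchanged — both are tested
  postconditions. Cells with no detected housekeeping gene are left
  unshifted and flagged; housekeeping normalisation is unreliable at the
  single-cell level and therefore strictly optional.
- **z-transform**: subtract mean, divide by sd (sample denominator by
  default, population available). Zero-variance vectors map to all-zeros
  with a warning rather than an error: an all-dropout gene should remain
  visible downstream, not abort the analysis.

## Embedding and clustering

Correlation distance is `d_ij = 1 − r(x_i, x_j)` with Pearson `r` by default
(Spearman selectable); the original description does not name the estimator
and Pearson is the field's default companion. Zero-variance rows make `r`
undefined and are reported as an error listing the offending cells — they
should have been filtered.

Hierarchical clustering wraps `stats::hclust` (single/complete/average, and
`ward.D2` for "ward"); the default linkage is **complete**, the classical
companion of correlation distance in this ecosystem. Ward assumes
(squared-)Euclidean geometry, so requesting it on a non-Euclidean metric
warns rather than errors — the agglomeration rule is deliberately a free
user choice. k-means uses `stats::kmeans` with a fixed default seed (0) and
10 restarts, run under a saved-and-restored RNG state so calls are
deterministic and do not disturb the caller's stream.

PCA is `stats::prcomp` on the column-centred matrix (no scaling — the input
is normally already z-scored). Isomap delegates to `vegan::isomap` on a
k-nearest-neighbour graph; a disconnected graph is rethrown as an error
advising a larger neighbourhood. "Local loop embedding (LLE)" has no
standard definition; it is read as standard *locally linear* embedding
(Roweis–Saul) and implemented directly (regularised local Gram weights,
bottom non-constant eigenvectors of `(I−W)ᵀ(I−W)`), since no pre-installed
R package provides it. Embeddings and clustering run on the current stage
matrix (normally z-scores) or, on request, on the index-marker matrix with
incomplete rows excluded and reported.

The adjusted Rand index used throughout testing is the standard
chance-corrected contingency form, implemented in-package.

## Grouping semantics

Groupings are ordered, coloured partitions of the current cells; every
operation returns a valid partition (pairwise disjoint, union = cells,
unique colours from a 12-colour colour-blind-safe palette, darkened on each
cycle past 12). Conventions that a GUI leaves implicit are fixed
deterministically here: 1-D cut-offs form half-open bins with boundary
values going to the upper bin (standard histogram convention); 2-D gates
are inclusive rectangles, first gate wins on overlap, and ungated cells form
an automatic `rest` group, mirroring cytometry gating while keeping the
result a partition. 1-D binning operates on the current stage matrix and the
stage is recorded in the log. Merging keeps the earliest merged member's
position; reordering carries colours with their groups.

## Figures, scrapbook, sessions

Every figure returns a machine-readable sidecar (violin summary table,
heatmap layout, scatter point table) so tests assert on data, not pixels;
PNG + SVG files are optional outputs. The expression heatmap's layout (cell
order, per-cell colour bar) is the single source of order for the index
heatmap, which is what keeps the paired views column-aligned. Gene ordering
in heatmaps is clustered by default (the fixed-order alternative is a
parameter). Heatmap colour scales are diverging and centred at 0 for
z-stage data, sequential otherwise. Interactive/rotatable 3-D views are out
of scope; the 3-D scatter is a fixed-angle orthographic projection of
components 1–3.

Session archives are ZIP files containing the manifest, matrices as TSV
printed at 17 significant digits (`%.17g` round-trips IEEE doubles
exactly), the grouping, the JSON step log, and the scrapbook. The archive
writer is a small pure-R STORE-method ZIP implementation (with CRC-32) —
the target environment has no `zip` binary — and reading uses R's internal
`unzip`. Timestamps inside the archive are fixed, so *save → load → save*
reproduces the archive byte-for-byte; this is the tested persistence fixed
point. Instead of exporting R scripts for reproducibility, the archive
stores a machine-readable config snapshot and log; `replay()` re-runs the
snapshot against the raw inputs and reproduces the matrices bit-exactly,
because all randomness flows through the registered seed.

## The synthetic generator: what it emulates, and what it does not

`simulate_experiment()` states a world and keeps it fixed:

- True Ct for gene g in a cell of group k is `Normal(μ_gk, σ)` with
  `μ_gk = baseline_mu` (default 26) reduced by `effect_size` (default 6
  cycles, i.e. ~64-fold) for the group's marker genes (8 per group by
  default on a 96-gene panel), and by 10 cycles for control genes.
  Defaults mirror a 5-population, 60-cells-per-group design.
- Dropout is Bernoulli with `P(miss) = logistic((ct − midpoint)·slope)`
  (midpoint 33, slope 1): weakly expressed transcripts fail more often,
  which is the empirically dominant feature of this assay. Controls have
  near-zero dropout; a 5% fraction of cells get failed controls to exercise
  QC.
- Index intensities are log-normal (sorter fluorescence is approximately
  log-normal) with a one-decade shift for each group's marker, minus a
  compensation offset so some values are negative.
- Cells are interleaved across 96-well plates; the first plate is written
  in the long "table" dialect and the rest in the grid "heatmap" dialect,
  so generated data exercises both parsers end to end.

It does **not** attempt biological realism: no gene–gene correlation beyond
group structure, no amplification-efficiency noise, no plate batch effects,
no doublets. A green recovery test therefore establishes that the pipeline
recovers planted, well-separated structure — not that it would resolve
subtle biology. Baseline σ (1.5 cycles) and the dropout parameters were
chosen once as typical of this assay class and are not tuned against test
outcomes.

`worked_micro_fixture()` complements the generator with a 4-cell × 3-gene
fixture whose expected matrices after filtering, inversion and z-transform
are frozen literals (the z-scores were computed once by an independent
one-off calculation and embedded to 10 decimals).

## Known limitations

- Only rectangular 2-D gates (no polygons/ellipses), matching the scope of
  the original design.
- Only the housekeeping-median normalisation option is provided besides
  "none"; other normalisation schemes alluded to in the original ecosystem
  are unnamed there and thus out of scope.
- No automatic choice of k, and no automatic outlier-chip detection: both
  are deliberate user decisions supported by the QC summaries.
- LLE quality degrades on noisy, high-dimensional expression data (as
  standard LLE does); it is provided for parity, with Isomap and PCA as the
  robust defaults.
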