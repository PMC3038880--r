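---
title: "Quantitative methylation analysis at imprinted DMRs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative methylation analysis at imprinted DMRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintpsq)
```

## The measurement model

Imprinted loci carry differentially methylated regions (DMRs) methylated on
exactly one parental allele. In a normal diploid sample every cell
contributes one methylated and one unmethylated copy, so a quantitative
bisulfite-pyrosequencing (PSQ) assay over a DMR should read close to 50%
regardless of tissue. That single fact drives everything in this package:
deviation from the bi-allelic 50% expectation is the signal, whether the
question is assay validity, tissue stability, population outliers or
response to a demethylating drug.

A PSQ assay reads 3-9 CpGs inside an amplicon and reports a percent
methylation per CpG. The package's central container
(`methylation_dataset()`) is therefore a long table of
(assay, sample, CpG index) percentages in [0, 100] with per-sample
metadata; individual CpG readings may be missing (failed dispensations) and
are excluded pairwise everywhere.

## The DMR window

"Differentially methylated" is made operational by `derive_dmr_window()`:
given readings of 50%-methylated standards across known DMR assays, the
window is

    lower = center - k * spread,   upper = center + k * spread

with `center` the mean, `spread` the sample standard deviation and
`k = 1.5` by default. With the reference standards (center 50.38%, spread
9.7667%) this yields the 35.73%-65.03% operating window used throughout.
Bounds are treated as a closed interval — a value exactly on a bound is
still consistent with differential methylation — and are kept at full
precision internally, rounded to two decimals only for reporting.
`classify_value()` maps any percent to
hypomethylated / differential / hypermethylated; the three categories are
exhaustive and mutually exclusive by construction.

`classify_dataset()` averages each individual's CpGs first, then averages
individuals within a tissue (individuals are the replication unit;
averaging is deliberately unweighted by CpG count), and classifies each
assay x tissue cell. An assay is "ever differential" when at least one
tissue falls inside the window.

## Assay design conventions

The in-silico designer (`design_assay()`) works on the bisulfite-converted
top strand; reverse primers are designed against its reverse complement.
The genome does not dictate a strand — one convention is chosen and
documented. Other deliberate choices:

* **Tm rule.** The target is a 56 °C melting temperature. The constraint is
  a design window, not a physical prediction, so the simplest reproducible
  convention is used: the Wallace rule, Tm = 2(A+T) + 4(G+C), with a
  +/- 2 °C tolerance by default.
* **Methylation-insensitive primers.** Primer footprints must contain no
  CpG (configurable via `max_cpg_in_primer`), because a CpG under a primer
  makes annealing depend on methylation state. A CpG split across the 3'
  edge of the footprint counts.
* **SNP avoidance.** Footprints overlapping annotated SNP positions are
  rejected by default.
* **Determinism.** The search is exhaustive over the flank windows; among
  feasible pairs the shortest amplicon wins, ties break leftmost. Identical
  inputs always return the identical design, and every returned design is
  re-checkable by an independent constraint scan (the test suite does
  exactly that).
* **Unstated bounds.** Primer lengths (18-30 nt) and the amplicon cap
  (350 bp) are conventional defaults, configurable and not derived from any
  reference protocol.

The universal biotinylated second-round tag (`PSQ_UNIVERSAL_TAG`) is
prepended verbatim by `tag_second_round_primer()`; biotin is metadata.

## Validation statistics

* **Linearity** (`assess_linearity()`): OLS of observed on the expected
  0/25/50/75/100 mixture ladder; r² is the squared Pearson correlation.
* **Replicate agreement** (`replicate_agreement()`): classic Bland-Altman —
  bias is the mean of (rep1 - rep2) and limits of agreement are
  bias +/- 1.96 x sample SD of the differences — plus the OLS r² of rep2 on
  rep1. Both per-CpG and per-assay-mean applications are meaningful; feed
  whichever pairing you intend.
* **Titration sensitivity** (`titration_sensitivity()`): per template mass,
  the mean 50%-standard reading must fall inside the window; a replicate
  whose mean lands 20 or more percentage points outside either bound is
  called an allelic dropout (mono-allelic amplification drags a 50% locus
  toward a rail). The 20-point margin is a package convention — no numeric
  criterion exists in the source literature — and is configurable.

## Feature associations and hypothesis tests

`feature_association()` relates average somatic methylation across the
catalog to CTCF occupancy (Welch t-test, with variable + constitutive
pooled as "binding"; the three-level means are attached), CpG-island status
(Welch t-test), genomic location (one-way ANOVA; groups with n < 2 are
dropped with a warning) and CpG density (OLS r²). CpG density is counted on
the top strand over a 500 bp window centred on the amplicon midpoint and
reported per 100 bp (count / 5), which is why every catalog density is a
multiple of 0.2.

Matched-pair t-tests drive the stability analyses: testis versus the
somatic mean per assay (`tissue_deviation_test()`) and maternal versus
paternal intra-CpG dispersion per sample
(`compare_parental_variability()`). Degenerate inputs (zero-variance
differences) return statistic 0 / p = 1 for a zero shift and p = 0
otherwise, rather than erroring as `stats::t.test()` would.

No multiple-testing correction is applied anywhere: raw p-values are
reported, mirroring single-platform exploratory practice; treat them
accordingly.

Note on reproducibility: recomputing the density association over the
packaged catalog minus the five never-differential assays gives r² = 0.029,
not the 0.090 reported alongside the original catalog. The printed
denominators there (38/44 islands, 11/43 CTCF) are inconsistent with the
printed 49-row table minus those five names, so the original DMR set and
per-assay densities were evidently not exactly the printed ones. The
package computes the association from its inputs and does not patch the
fixture to force agreement.

## Population outliers and treatment response

"95% and 99% CI" outlier screening is implemented as a **normal reference
range** — mean +/- z x SD of the cohort, truncated to [0, 100] — because
individuals, not means, are being flagged; a percentile-based band is
available (`method = "percentile"`). Intervals include the tested
individual by default (the simplest reading; leave-one-out is an option).
Flag sets are nested across levels by construction.

`individual_burden()` asks whether any individual is aberrant across DMRs:
a two-way ANOVA without replication on per-assay z-scores (individual +
assay), reporting the individual-effect p-value. `cis_cluster_correlation()`
computes pairwise r² of per-individual means for assays sharing a
`cluster_id`. `treatment_reduction()` scores demethylation as
100 x (control - treated)/control per assay and dose; gains are negative
reductions and a zero control leaves the value undefined (never 0).

## The synthetic world

Every analysis is testable offline because `generate_tissue_panel()`,
`generate_blood_cohort()`, `generate_standards()` and
`generate_design_region()` emit data with the statistical structure the
analysis assumes, alongside machine-readable ground truth. The defaults
are a stated world, chosen once:

* Eight adult tissues, three pooled individuals (the tissue-panel shape);
  50 individuals for blood cohorts; a 23-assay blood panel
  (`blood_panel_assays()`: 15 maternal, 8 paternal).
* Germ-line DMRs at a true 50% in every somatic tissue. In testis, sperm
  erase maternal imprints (true value 5%) and carry paternal ones (95%).
  Maternal somatic DMRs are tissue-specific (50% in one or two tissues,
  20% or 80% elsewhere); paternal somatic DMRs sit at 50% everywhere.
* Technical noise is truncated-Gaussian on the percent scale, SD 2% — the
  order of magnitude implied by a replicate bias of 1.60%; no quantitative
  noise levels are published, so these are documented defaults, not
  reference values. A per-(assay, CpG) offset drawn once (maternal SD 2%,
  paternal 5%) models systematic dispensation bias, which is what makes
  intra-CpG SD a stable per-assay property and separates the parental
  classes.
* Allelic dropout is whole-allele loss: the reading is replaced by a draw
  near 0 or 100 with equal probability, with default probability 0.1 at
  <= 1 ng template and 0 above.
* Design-region fixtures embed a CpG island of exactly the requested CpG
  count between CpG-free flanks each carrying a verified Wallace-56 °C
  primer site.

What the generator does **not** emulate: read-level bisulfite data,
PCR thermodynamic bias, bisulfite conversion failure, batch structure, or
genuine biological inter-individual variance beyond Gaussian spread. A
green test therefore establishes that the statistics recover a stated
Gaussian world — not that they are robust to every artefact of real PSQ
runs.

Determinism: all generators are integer-seeded with no time-based entropy;
the same seed reproduces the same dataset byte for byte.

## Numerical conventions and degenerate inputs

* Percentages are clipped to [0, 100] at emission; statistics never clip.
* Sample (n-1) standard deviations throughout.
* Catalog positions are 1-based as printed; all interval arithmetic is
  0-based half-open (BED), with explicit converters
  (`position_to_interval()`); BED records are never reordered.
* Report CSVs round percentages to 2 decimals; the JSON summary keeps full
  precision.
* Constant observed values in a linearity fit give r² = 0 with a warning;
  a constant predictor is an error.

## Known limitations

* The packaged catalog is a transcription: 49 rows, while its source
  abstract speaks of 50 assays; the missing row is unresolved and shipped
  as-is (see `inst/extdata/README.md`). Cluster assignments are
  package-supplied annotation.
* The density-association r² reproducibility gap described above.
* The ANOVA burden test assumes a near-complete individual x assay matrix
  (> 80% cells present).
* No thermodynamic primer checks (nearest-neighbour Tm, dimers, secondary
  structure) — the designer enforces the documented constraint set only.
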