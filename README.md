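# imprintpsq

Quantitative analysis of DNA methylation at human imprinted differentially
methylated regions (DMRs) measured by bisulfite pyrosequencing (PSQ).

Imprinted genes are expressed from one parental allele, and each imprinted
locus carries at least one DMR methylated on exactly one allele. A normal
diploid sample therefore reads close to 50% aggregate methylation at a DMR,
in every tissue, independent of expression — which makes imprinted DMRs
sensitive reporters of epigenetic stability in clinical material. This
package is for epigenomics researchers who quantify imprinted methylation
with targeted PSQ assays: it covers in-silico assay design on
bisulfite-converted templates, standards-based assay validation, DMR
calling and classification, stability and genomic-feature statistics,
population outlier screening, demethylation-treatment scoring, and a
ground-truth synthetic data generator so the whole pipeline is testable
without any external data. It ships a transcribed catalog of 49 PSQ assays
covering the known human imprinted loci
(`inst/extdata/table1_assays.csv`).

## The core model

The operating definition of "differentially methylated" comes from
50%-methylated standards read across known DMR assays. With center x̄ (mean
reading), spread s (sample SD) and multiplier k (default 1.5), the DMR
window is

    [x̄ − k·s, x̄ + k·s]

With the reference standards (x̄ = 50.38, s = 9.7667) this is the
**35.73%–65.03%** window. A per-assay, per-tissue mean below the window is
hypomethylated, above it hypermethylated, inside it (bounds inclusive)
consistent with differential methylation. Around this sit the supporting
statistics: mixture-series linearity (OLS), Bland–Altman replicate
agreement (bias ± 1.96·SD of differences), input-titration sensitivity with
allelic-dropout detection, matched-pair t-tests for tissue deviation and
parental-class variability, normal reference ranges (mean ± z·SD) for
cohort outliers, and 100·(control − treated)/control for demethylation
response.

## Worked example

```r
library(imprintpsq)

catalog <- load_assay_catalog(packaged_catalog_path())
summarize_catalog(catalog,
                  exclude = c("UBE3A", "BLCAP", "CDKN1C", "TCEB3C", "RTL"))
#> Assay catalog summary (44 assays)
#>   timing: germline=17, germline_qualified=2, somatic=11, none=1, unknown=13
#>   parental_mark: maternal=21, paternal=9, none=1, unknown=13
#>   ctcf_class: none=24, constitutive=8, variable=12
#>   cpg_island: FALSE=7, TRUE=37
```

Seventeen unqualified germ-line DMRs; after removing the five assays that
never report differential methylation, 12 variable-CTCF and 8
constitutive-CTCF regions remain.

```r
spread <- (65.03 - 50.38) / 1.5
window <- derive_dmr_window(50.38 + spread * c(-1, 0, 1), k = 1.5)
window
#> DMR window: 35.73%-65.03% (center 50.38%, spread 9.7667, k = 1.5)

classify_value(c(45.23, 12.07, 88.27), window)   # H19, CDKN1C, RTL averages
#> [1] differential    hypomethylated  hypermethylated
```

The H19 DMR average (45.23%) is consistent with differential methylation;
CDKN1C (12.07%) and RTL (88.27%) are constitutively hypo- and
hypermethylated — they are imprinted genes without promoter DMRs.

```r
panel <- generate_tissue_panel(synthetic_config(seed = 1))
cls <- classify_dataset(panel$dataset, window)
head(cls, 8)
#>   assay   tissue      mean       category
#> 1   mg1    brain 50.747632   differential
#> 2   mg1   breast 50.084906   differential
#> 3   mg1    colon 50.375619   differential
#> 4   mg1    heart 50.634150   differential
#> 5   mg1   kidney 50.184847   differential
#> 6   mg1    liver 49.405088   differential
#> 7   mg1 placenta 49.560155   differential
#> 8   mg1   testis  5.942263 hypomethylated
```

A simulated maternal germ-line DMR holds ~50% in all somatic tissues and
collapses in testis, where sperm have erased the maternal imprint.

```r
feature_association(catalog, "density",
                    exclude = c("UBE3A", "BLCAP", "CDKN1C", "TCEB3C", "RTL"))
#> CpG density association: r^2 0.029 (slope -1.062 %/CpG-per-100bp, n = 44)
```

CpG density does not predict average somatic methylation across the DMR
set (see the methods vignette for a note on this statistic's
reproducibility from the printed catalog).

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end from scratch:
it simulates standards, a tissue panel and a 50-individual blood cohort at
the documented defaults, validates the standards (linearity, titration),
runs the full pipeline (catalog summary, DMR window, classification,
feature associations, outlier screening) against the packaged catalog, and
computes the cohort statistics (parental variability, cis-cluster
correlation), writing its JSON output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

The exported functions are the primary interface. A thin wrapper for the
end-to-end flows is included:

```sh
Rscript inst/scripts/run-analysis.R --config config.json --seed 1 --out report/
```

See the methods vignette (`vignettes/imprinted-dmr-analysis.Rmd`) for the
models, assumptions, defaults and design decisions.
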