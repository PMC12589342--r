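# tmeatlas

Compositional analysis of the tumor microenvironment (TME) from single-cell
RNA-seq, for cohorts stratified by an immunohistochemical (IHC) marker.

The package is written for the common study design in which tumor and
adjacent-normal samples are grouped by a protein readout — here the RUNX3
transcription factor in non-small-cell lung cancer, with groups `NOR`
(normal lung), `RUNX3_Neg` and `RUNX3_Pos` — and the question is how the
cellular composition and the myeloid compartment of the TME differ between
groups. It provides, as testable R functions with a thin command-line
wrapper:

* **Composite IHC scoring** — percent-positive points (0–2) plus staining-
  intensity points (0–2), composite 0–4; composites ≤ 2 define the negative
  group, ≥ 3 the positive group.
* **Hierarchical marker-based annotation** — normalize → cluster (PCA +
  Louvain on a kNN graph) → score clusters against marker references →
  argmax assignment, at three levels: 13 major lung-TME cell types, 5
  mononuclear-phagocyte (MP) subtypes, and a six-gene macrophage
  classification (AZU1 / CXCL10 / FABP4 / SELENOP / SPP1 / STMN1 states).
* **Ro/e tissue preference** — for observed counts `O(i,j)` of type *i* in
  tissue group *j*, the chi-squared expectation
  `E(i,j) = row_i × col_j / N` and the ratio `Ro/e = O/E`; a ratio strictly
  above 1 calls a preference, below 1 a depletion.
* **M1/M2 polarization scores** — per-cell module scores (set mean minus
  expression-bin-matched control mean) with t-test / one-way ANOVA group
  comparisons and significance stars.
* **Differential expression and enrichment** — Wilcoxon rank-sum DE with
  Benjamini–Hochberg control and volcano classification; hypergeometric
  over-representation against GMT collections.
* **Ligand–receptor interactions** — CellPhoneDB-style mean-expression
  products with min-over-complex, tested against a label-permutation null.
* **A synthetic-cohort generator** — negative-binomial counts with planted
  hierarchical cell types and group-specific composition shifts, so the
  entire pipeline runs and is tested without any external data.

## Worked example

Score an IHC specimen table and run the full synthetic cohort:

```r
library(tmeatlas)

score_and_group(example_ihc_specimens())
#>   specimen_id percent_positive intensity percent_points intensity_points
#> 1          P1                5      none              0                0
#> 2          P2               30  moderate              1                1
#> 3          P3               15      weak              1                0
#> 4          P4               60    strong              2                2
#> ...
#>   overall_score     group
#> 1             0 RUNX3_Neg
#> 2             2 RUNX3_Neg
#> 3             1 RUNX3_Neg
#> 4             4 RUNX3_Pos
```

Seven specimens split 3 negative / 4 positive. Now simulate a cohort
(10 samples, 5,000 cells), annotate it, and ask which cell types prefer
which tissue:

```r
d <- simulate_cohort(n_cells_per_sample = 500, n_genes = 1200, seed = 1)
ann <- annotate_hierarchy(d$counts, d$truth[, c("cell_id", "sample_id", "group")],
                          seed = 1)
roe_from_annotation(ann)
#> roe_table: 13 types x 3 groups, N = 5000 cells
#>                 NOR RUNX3_Neg RUNX3_Pos
#> AT2           1.812     0.519     0.752
#> ...
#> Fibroblasts   0.101     1.174     1.544
#> MPs           1.584     0.540     0.907
#> TCells        1.631     0.604     0.824
#> global chi-squared p = 9.63e-166
```

Reading the ratios: fibroblasts show by far the strongest preference for
RUNX3-positive cancer tissue (Ro/e 1.54), while MPs and T cells sit below
expectation in both cancer groups — the planted structure, recovered through
clustering and marker assignment rather than read off the truth labels. The
myeloid subtable shows the macrophage/monocyte split between the two cancer
groups:

```r
roe_from_annotation(ann, type_field = "mp_subtype")
#> roe_table: 5 types x 3 groups, N = 728 cells
#>               NOR RUNX3_Neg RUNX3_Pos
#> cDC1        1.412     0.781     0.558
#> cDC2        0.482     1.635     1.395
#> Macrophages 1.157     0.523     1.007
#> MatureDCs   0.399     1.808     1.426
#> Monocytes   0.866     1.866     0.788
```

Macrophages are depleted (0.52) and monocytes enriched (1.87) in the
RUNX3-negative cancer tissue, with the opposite tendency in the positive
group. `run_all(run_config(...))` chains every stage — simulation, IHC
scoring, annotation, Ro/e at all three levels, M1/M2 scoring, DE,
enrichment, ligand–receptor testing — into one output directory with a
hash-stamped `manifest.json`; a fixed seed reproduces every table byte for
byte. The same stages are available as subcommands of
`inst/cli/tmeatlas-cli.R`.

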