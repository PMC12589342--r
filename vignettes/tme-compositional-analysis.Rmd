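---
title: "Compositional analysis of the tumor microenvironment with tmeatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of the tumor microenvironment with tmeatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmeatlas)
```

## The analysis this package implements

`tmeatlas` packages the comparative workflow used to ask how the cellular
composition of the non-small-cell lung cancer (NSCLC) tumor microenvironment
(TME) differs between patient strata defined by an immunohistochemical (IHC)
marker — here the RUNX3 transcription factor. Tissue samples fall into three
groups: adjacent normal lung (`NOR`), cancers with low composite RUNX3
staining (`RUNX3_Neg`), and cancers with high staining (`RUNX3_Pos`). From
per-cell transcriptomes the pipeline:

1. scores the IHC readout into the composite 0–4 scale and the Neg/Pos
   grouping;
2. annotates cells hierarchically from marker genes — 13 major lung-TME
   types, then 5 mononuclear-phagocyte (MP) subtypes within the MPs, then a
   six-gene classification of macrophage states (anchored on AZU1, CXCL10,
   FABP4, SELENOP, SPP1, STMN1);
3. quantifies tissue preference of every type with the
   observed-over-expected ratio Ro/e;
4. scores M1/M2 macrophage polarization programs per cell and compares them
   across groups and macrophage states;
5. tests differential expression between groups in the MP compartment,
   summarizes hits by over-representation against gene-set collections, and
   scores ligand–receptor interactions between tumor cells and MPs with a
   permutation null.

Because no public accession accompanies the motivating cohort, the package
ships a synthetic-data generator whose planted structure mirrors the
qualitative findings the pipeline is meant to detect. Every stage is
exercised end to end on generated data; nothing requires a download.

## The Ro/e statistic

For an observed cell-count table $O_{ij}$ (cell type $i$ in tissue group
$j$), the expected count under compositional homogeneity is the chi-squared
contingency expectation

$$E_{ij} = \frac{(\sum_j O_{ij})(\sum_i O_{ij})}{N}, \qquad
R_{o/e}(i,j) = O_{ij} / E_{ij}.$$

$R_{o/e} > 1$ (strictly) is read as preference of type $i$ for tissue $j$;
$< 1$ as depletion. A ratio of exactly 1 is *not* a preference. Entries with
zero row or column totals have an undefined ratio and are reported as
missing, never as zero — silently reporting 0 would fake a depletion call.
No multiplicity correction is applied to preference calls (the convention of
the originating analysis); the global chi-squared p-value is attached to
each table for context. Group tables pool cells across a group's samples;
`roe_from_annotation(per_sample = TRUE)` instead averages per-sample ratios,
since it is ambiguous which of the two a given published figure used.

Useful invariants, both tested against an independent implementation of the
expectation: $\sum_j E_{ij} = \sum_j O_{ij}$ per type, and
$\sum_j R_{ij} E_{ij}$ recovers the row totals.

## Composite IHC score

Two components, each 0–2 points, are summed to 0–4: percent positive cells
(< 10% → 0; 10–50% → 1, both endpoints included; > 50% → 2) and staining
intensity (none/weak → 0; moderate → 1; strong → 2). Composites 0–2 define
`RUNX3_Neg`, 3–4 `RUNX3_Pos`. Reader adjudication is out of computational
scope; the module takes one consensus record per specimen. The distinction
between "no staining" and "weak" does not matter for the score (both are 0
points), so both labels are accepted.

## Hierarchical marker-based annotation

Annotation is cluster-then-label:

* **Normalization** — per-cell scaling to a fixed target sum (default
  10,000) followed by natural log1p; the most common convention, and
  parameterized because upstream protocols vary. All-zero cells cannot be
  scaled and are dropped with a warning.
* **Clustering** — highly variable genes are selected by mean-binned
  normalized dispersion (variance/mean z-scored within 20 mean-expression
  bins; default 200 genes retained). Plain variance ranking is biased toward
  highly expressed genes and demotes bimodal markers, which measurably
  degrades recovery. The selected genes are z-scaled (capped at 10),
  reduced to 20 principal components, connected in an exact k=15
  nearest-neighbour graph, and partitioned by Louvain community detection
  (default resolution 1.5 for annotation). A k-means fallback is available.
  Cells are processed in a canonical internal order so the partition does
  not depend on input order, and all randomness flows from one seed. The
  raw cluster counts of any particular dataset (the motivating study
  reports 37 and 17) are data- and resolution-dependent and are not a
  quantity this package tries to reproduce.
* **Scoring and assignment** — each cluster × type score is the mean over
  the type's present markers of the z-scored (across cells) mean expression
  in the cluster; zero-variance genes get z = 0 by convention. Clusters take
  their argmax type; exact ties break lexicographically and are flagged.
  Multiple clusters may map to one type, so over-clustering is harmless
  while under-clustering is the failure mode to watch.
* **Hierarchy** — the major level runs on all cells; the MP reference then
  re-clusters the MPs subset; the six-gene reference re-clusters the
  macrophage subset. Subtype fields are non-missing only along this path.
  A dataset that consists entirely of one ancestor type (e.g. a sorted MP
  subset) carries no between-cluster variance in that ancestor's markers,
  so such data must enter the hierarchy at its own level via
  `start_level = "mp"` or `"macro"`.

The packaged marker references use canonical lung-TME panels of 6–8 genes
per type (e.g. AT2 → SFTPC/SFTPB/SFTPA1..., fibroblasts → COL1A1/COL1A2/
DCN..., MPs → LYZ/AIF1/TYROBP...; the macrophage level is anchored by the
six classification genes plus small program extensions). Panels of this
size are what practitioners actually curate, and they matter statistically:
with 3-gene panels, count-level dropout leaves a visible fraction of cells
without usable signal and recovery degrades.

## Module scores and group comparisons

The M1/M2 polarization score of a cell is the mean expression of the set
genes minus the mean of control genes drawn from matching average-expression
bins (25 bins, 50 controls per set gene by default) — the dominant
"module score" convention in single-cell work, seed-reproducible here. The
control matching makes scores robust to global location shifts. One known
degeneracy is worth stating: if the background is perfectly flat, a gene
set's members occupy an expression bin of their own and become their own
controls, nulling the score; with realistically heterogeneous baselines the
score recovers a planted shift to within a few percent.

Group summaries report mean, SD, n, and the z-score of group means across
the entities being compared (tissue groups or macrophage states; zero
variance gives z = 0). Two groups are compared by t-test (Welch by default;
`var_equal = TRUE` gives the classical Student test), three or more by
one-way ANOVA. Stars follow the usual thresholds — `*` p < 0.05, `**`
p < 0.01, `***` p < 0.001, `ns` otherwise, with boundary values falling to
the weaker label. The packaged M1/M2 sets are canonical programs
(M1: CXCL9/CXCL10/CXCL11/GBP1/IL1B/TNF/...; M2: MRC1/MSR1/FABP4/CD163/...)
and are overridable by GMT file, since the motivating analysis does not
enumerate its sets.

## Differential expression, over-representation, ligand–receptor scoring

Per-gene DE between two cell groups uses the two-sided Wilcoxon rank-sum
test (the scRNA-seq convention; exact for small untied samples, normal
approximation with tie correction otherwise) with Benjamini–Hochberg
control. Fold changes are computed from group means on the normalized
expression scale (the log transform is inverted first) with a pseudocount
of 1; means of log-transformed values would systematically compress true
fold changes. Volcano classification defaults to |log2FC| ≥ 1 and q < 0.05,
both parameters.

Over-representation uses the upper-tail hypergeometric test within a
universe defaulting to all detected genes; never-observed genes would
otherwise inflate enrichment. The packaged ~30-set collection is an
explicitly synthetic stand-in for live GO/KEGG queries, which this package
does not perform.

Ligand–receptor interaction scores follow the mean-product convention with
min-over-complex (the CellPhoneDB family): sender-side ligand mean times
receiver-side receptor mean, a multi-gene complex contributing its weakest
member. Significance comes from jointly permuting sender/receiver labels;
p = (1 + #{permuted ≥ observed}) / (n_perm + 1), bounded below by
1/(n_perm+1). The packaged pair database covers EFNA1–EPHA2, SAA1–FPR2,
APP–FPR2, CXCL14–CXCR4, APP–TREM2 and HLA-F–VSIR; prostaglandin signalling
(PGE2 → PTGER receptors) has no ligand transcript and is represented by the
synthase proxy pair PTGES–PTGER4, which measures the pathway's
transcriptional footprint rather than the metabolite.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` draws 10 samples (3 normal, 3 RUNX3_Neg, 4 RUNX3_Pos;
500 cells each by default) with a three-level planted hierarchy. Counts are
negative binomial with a shared over-dispersion (phi = 0.5; variance
mu + phi·mu²), gene baselines log-normal (meanlog 0, sdlog 1), a per-cell
log-normal library factor (sdlog 0.2), and marker genes of a cell's type
path multiplied by a fold change (default 8) that is additive down the
hierarchy. Group proportions encode, directionally, the findings the
pipeline should recover: fibroblasts the only type preferred in RUNX3_Pos
cancer tissue; club/ciliated/plasma/B/neutrophil/mast/pDC enrichment in
RUNX3_Neg; MPs and T cells depleted in both cancer groups; at the MP level,
macrophages depleted and monocytes enriched in RUNX3_Neg with the opposite
tendency in RUNX3_Pos; and the six macrophage states shifting as the
six-gene classification describes (FABP4-state dominant in normal lung and
depleted in cancer, AZU1-state moving oppositely in the two cancer groups).
Magnitudes are free design parameters — the source cohort publishes no
proportions usable for calibration — chosen so every planted ratio is
separated from 1 by at least ~9% (≥ 11% for the headline directions), i.e.
several sampling standard errors at the tested depths.

The generator deliberately omits doublets, ambient RNA, batch effects, UMI
saturation, and transcriptome-wide co-expression beyond the planted
markers. Passing tests therefore demonstrate that the statistical machinery
recovers known structure under clean, well-separated conditions; they do
not certify performance on real tissue, where marker panels overlap,
populations form continua, and batch structure competes with biology.

## Numerical choices and degenerate inputs

* All stochastic steps take explicit integer seeds; a fixed configuration
  reproduces byte-identical output tables (hashes recorded in the run
  manifest).
* Z-scores of zero-variance quantities are defined as 0 throughout.
* Argmax ties in type assignment break lexicographically and carry a flag.
* Ro/e entries with zero marginals are NA, and tables with N = 0 are
  errors.
* `bh_adjust` validates p ∈ (0, 1] and delegates to the standard step-up;
  the test suite checks it against a longhand implementation.
* Exact-allocation mode (`exact_proportions`) uses largest-remainder
  rounding, giving deterministic integer compositions for worked examples.
* Default problem sizes: unit tests exercise scenarios at 400–1,000 cells;
  the recovery checks run the bundled scenarios at 5,000 cells (and 5,000
  cells per group for composition recovery), the depths at which the
  planted separations correspond to several standard errors.

## A short worked run

```{r worked, eval = FALSE}
library(tmeatlas)

out <- file.path(tempdir(), "tme-run")
man <- run_all(run_config(out_dir = out, scenario = "cohort", seed = 1,
                          n_cells_per_sample = 250, n_genes = 800))
read.delim(file.path(out, "roe_long_major.tsv"))[1:5, ]
```

The output directory contains the scored IHC table, the hierarchical
annotation, wide and long Ro/e tables per level, the M1/M2 report, the DE
and enrichment tables for the MP compartment, ligand–receptor results, and
`manifest.json` hashing every file.

## Known limitations

* Marker-based argmax assignment cannot express "unknown" — a cluster of a
  type missing from the reference is forced into the nearest available
  label.
* Pooled Ro/e treats cells as exchangeable within a group; per-sample
  random effects and compositional alternatives (CLR, Dirichlet-
  multinomial) are out of scope.
* The LR permutation null shuffles cell labels within the sender/receiver
  union and so tests label association, not transcriptome-wide network
  structure.
* Preference calls carry no multiplicity control by design; consult the
  attached global chi-squared p-value when many types are scanned.
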