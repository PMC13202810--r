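---
title: "Quantifying cardiac intercellular communication from snRNA-seq"
author: "cardioCrosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac intercellular communication from snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioCrosstalk)
```

# Overview

Single-nucleus RNA-seq of diseased hearts yields a gene-by-cell count matrix
in which every cell carries a sample, condition and cell-type label. Beyond
per-cell-type transcriptional changes, disease remodels how cell types talk
to each other: a ligand secreted by cardiac fibroblasts (CF) is read by a
receptor on cardiomyocytes (CM), endothelial cells (EC) signal to CM, and so
on. `cardioCrosstalk` quantifies this intercellular communication from
annotated counts, compares each disease condition against a healthy control,
and summarizes the result at the level of individual ligand–receptor pairs,
functional pathway categories, and whole sender–receiver networks.

The pipeline has six stages, each usable on its own:

1. per-cell quality control and filtering (`computeQCMetrics`,
   `filterCells`);
2. log-normalization and highly-variable-gene ranking
   (`logNormalizeCounts`, `selectHVG`);
3. Wilcoxon rank-sum differential expression per cell type
   (`wilcoxonDE`, `summarizeDEGs`, `topDEGs`, `heatmapMatrix`);
4. cell-type composition testing (`cellTypeProportions`,
   `compositionTest`);
5. ligand–receptor crosstalk statistics with condition-versus-control
   fold changes and category summaries (`computeCrosstalk`,
   `foldChangeVsControl`, `categorySummary`, `topInteractions`);
6. directed weighted communication networks and topology metrics
   (`buildCommNetwork`, `networkMetrics`, `exportNetwork`).

`runPipeline` chains them with one configuration object and writes a
deterministic CSV/JSON bundle plus a manifest.

# The crosstalk statistics

For a directed sender–receiver cell-type pair $(S, R)$ and a
ligand–receptor gene pair $(\ell, r)$ within one condition, two statistics
are computed from the log-normalized expression matrix $x$:

$$\text{Crosstalk Potential} \;=\;
  \overline{x_{\ell}}^{\,S} \times \overline{x_{r}}^{\,R},$$

the product of the mean ligand expression over sender cells and the mean
receptor expression over receiver cells, and

$$\text{Crosstalk Score} \;=\;
  \sqrt{p_{\ell}^{\,S} \times p_{r}^{\,R}},$$

the geometric mean of the expressing-cell percentages (0–100 scale; a cell
"expresses" a gene when its normalized value is strictly positive, i.e. its
raw count is nonzero). The score therefore lies in $[0, 100]$, reaches 100
only when every sender expresses the ligand and every receiver the
receptor, and is 0 exactly when either side is silent. For a homophilic
pair such as PTPRM–PTPRM the same gene is evaluated as ligand in the
senders and as receptor in the receivers.

Statistics are only reported when both the sender and the receiver cell
type have at least `min_cells = 10` cells in the condition; undersized
groups yield records flagged invalid with missing statistics, and every
downstream comparison involving an invalid record propagates as a missing
value rather than a zero — treating an unobservable group as "no
communication" would fabricate suppression.

Disease-versus-control remodelling is expressed as
$\log_2\!\big((P_{\text{cond}} + \varepsilon)/(P_{\text{ctrl}} +
\varepsilon)\big)$ with $\varepsilon = 10^{-6}$ guarding zero potentials.
Category summaries aggregate in two complementary ways: the unweighted mean
of pair-level log2 fold changes within a category (across all directions),
and the total category potential as a percentage of the control baseline
(the control's own value is exactly 100%). Pair ranking
(`topInteractions`) orders pairs by the unweighted mean of their valid
potentials across all conditions and directions, ties broken
alphabetically by pair id; the choice of an unweighted mean (rather than a
sum) makes the ranking insensitive to how many conditions pass the
minimum-cell rule for a pair.

Two interpretation choices deserve emphasis. First, "normalized
expression" means the log-normalized values by default; means of de-logged
values (`expm1`) are available via
`computeCrosstalk(..., expression_scale = "linear")` as a sensitivity
analysis, because means on the log scale compress strong effects. Second,
no per-pair significance test is attached to individual interactions: a
defensible null for a product-of-means statistic requires a permutation
scheme whose design (what to permute, within which strata) would dominate
the result, so the package reports effect sizes and leaves inference to
the differential-expression stage.

# The ligand–receptor catalogue

The bundled table (`cardiacLRPairs()`) holds 15 single-gene cardiac pairs:
the homophilic adhesion molecules PTPRM, NEGR1, NCAM1 and CD99
(`adhesion_junction`); IGF2→IGF1R and IGF2→IGF2R (`growth_factor`);
COL4A2→SDC4 and FN1→SDC4 (`ecm_structural`); COL4A1/COL4A2→CD44 and
COL6A2/THBS3→SDC4 (`ecm_adhesive`); THBS1→CD36 (`metabolic`, CD36 being
the fatty-acid translocase); and JAG2/DLL1→NOTCH2 (`notch`). Category
labels are open strings, so user-supplied tables may introduce further
categories (e.g. `morphogen`). Multi-subunit complexes are deliberately
rejected rather than silently aggregated: every bundled pair is
single-gene, and any aggregation rule (minimum, mean, product over
subunits) would be an undeclared modelling decision. Gene matching against
the count matrix is case-sensitive exact match — HGNC symbols are
uppercase, and silent case-folding hides data errors — with an explicit
`ignore_case = TRUE` fallback in `restrictToUniverse`.

# Upstream stages and their parameters

**Quality control.** Per cell: detected genes (count > 0), total counts,
and mitochondrial/ribosomal percentages, with `MT-`-prefixed genes as
mitochondrial and `^RP[SL]` as ribosomal. Percentages use total counts
over *all* genes as denominator. Cells are excluded when the mitochondrial
percentage exceeds 20% or the detected-gene count falls below 200 or above
6,000; exclusion is by strict inequality, so boundary cells (exactly 20%,
200 or 6,000) are kept — the filter predicate is applied literally rather
than reinterpreted as "at least"/"at most". Ribosomal content is reported
but not filtered on, since only the mitochondrial and feature-count rules
are part of the filter definition. The filter is idempotent.

**Normalization.** `logNormalizeCounts` computes
$\ln(1 + c_{gj}\,s/ t_j)$ with scale factor $s = 10{,}000$ and $t_j$ the
cell's total counts — the natural logarithm, which matters when comparing
mean expression values across tools. Zeros are preserved exactly and the
transform is invariant to per-cell count scaling.

**Highly variable genes.** The variance-stabilizing ranking: fit a
mean–variance trend by local polynomial regression (degree 2, span 0.3) of
$\log_{10}$ variance on $\log_{10}$ mean of raw counts, standardize each
gene with its trend-predicted standard deviation, clip standardized values
at $\sqrt{N}$ ($N$ cells), and rank genes by the variance of the clipped
values (default top 2,000; ties broken by gene symbol so the ranking is
deterministic; constant genes get standardized variance 0 and rank last).
On panels with fewer than 30 positive-variance genes a local fit is
ill-defined, and the trend falls back to a global quadratic — the limit
the local regression approaches in that regime. Embeddings (PCA/UMAP) are
deliberately out of scope: cell-type labels are inputs here, not the
product of clustering.

**Differential expression.** Within one cell type, each condition is
compared against the control by the two-sided Wilcoxon rank-sum test with
normal approximation, tie correction and continuity correction (group
sizes in this setting are in the hundreds; when all values are tied the
statistic sits at its null center and $p = 1$). A gene is tested when its
expressing fraction reaches `min_pct = 0.1` in *either* group — the
more sensitive reading of the threshold, and the convention of marker
tests, since requiring both groups would blind the test to genes switched
off in one condition. Benjamini–Hochberg adjustment is applied across the
genes tested within one (cell type, condition) comparison; that is the
natural testing family here, and pooling families across cell types would
let a heavily remodelled cell type distort the threshold of a quiet one.
Fold changes are computed on the expression scale,
$\log_2\!\big((\overline{e^{x}-1}_1 + 10^{-9}) /
(\overline{e^{x}-1}_2 + 10^{-9})\big)$, so that a reported doubling means
a doubling of (shifted) expression, not of log-expression. Top-$k$ gene
selection orders by adjusted $p$, then $|\log_2\text{FC}|$ descending,
then symbol. Heatmap matrices z-score each gene across group means
(constant rows become zero rows) and order rows by complete-linkage
hierarchical clustering on Euclidean distances, with a deterministic leaf
order: at every merge, the subtree containing the smaller original row
index comes first.

**Composition.** Cell-type proportions per condition, and per (cell type,
condition) a two-sided Fisher's exact test of the 2×2 table
(in type vs other types) × (condition vs control), BH-corrected across
cell types within each condition (mirroring the one-column-per-condition
display such results feed). Cells are pooled across samples within a
condition — a per-sample mixed model is out of scope, and the pooled test
answers the descriptive question the proportions themselves pose. The
proportion fold change uses a pseudo-proportion of $10^{-6}$ and is capped
at $\pm 3$ log2 units; with that cap the result is insensitive to the
pseudo-proportion anywhere below $10^{-4}$.

**Networks.** Per condition, each configured direction with at least one
valid record becomes one directed edge weighted by the mean potential over
that direction's valid ligand–receptor records. The default directions are
CF→CM, CM→EC, EC→CM and CM→CF; additional populations (for instance a
combined epicardial group) are analysed by simply listing extra
directions. Two scalar indices operationalize qualitative topology
descriptions, and both are this package's own constructions, chosen for
simplicity: *centralization*, $(\max_e w_e - \overline{w})/\sum_e w_e$,
which is 0 when all edge weights are equal and grows as weight concentrates
on one edge; and *fragmentation*, the fraction of configured directions
lacking a valid edge.

# The synthetic-data generator

Because the patient-level data behind such analyses is controlled-access
at the cell level, every stage must be testable on synthetic data with
known ground truth. `simulateCounts` draws counts gene-wise from a
negative binomial (gamma–Poisson) with a single shared dispersion — the
standard count model for this data type, and sufficient for rank- and
mean-based downstream statistics. The reference configuration
(`simConfig()` defaults) mirrors the structure the analysis expects: the
four communicating cell types (CM, CF, EC, ENDOC) across six diagnostic
conditions with `"Donor"` first as control, 100 cells per cell type per
condition, and a 1,000-gene panel containing all bundled ligand–receptor
genes plus `MT-*` and `RPL*`/`RPS*` genes so the QC stage is exercised.

Numerical choices:

* **Baseline means.** Background genes have NB mean 0.5 and dispersion
  (size) 2, giving the zero-inflation and per-cell detected-gene counts
  typical of nuclei. Ligand/receptor genes default to mean 2: curated
  signalling genes are expressed in heart tissue, and a dropout-dominated
  pair is not the regime a mean-product statistic addresses.
* **Library-size heterogeneity.** Per-cell size factors are log-normal
  with $\sigma = 0.3$ and $\mu = -\sigma^2/2$, i.e. mean-preserving, so a
  gene's configured NB mean is also its expected count — without the
  $-\sigma^2/2$ shift every mean would be biased upward by
  $e^{\sigma^2/2}-1 \approx 4.6\%$. This heterogeneity is exactly what the
  normalization stage's scale invariance must absorb.
* **Planted effects.** Multipliers act on the NB mean of *raw* counts in
  one (condition, cell type) block, addressed either by pair (ligand side,
  receptor side or both) or directly by gene. On the log-normalized scale
  the realized effect is attenuated relative to the nominal multiplier, so
  recovery checks compare against an oracle computed from the realized
  normalized means, never against the nominal multiplier itself.
* **QC violators.** Configured counts of outlier cells are appended with
  ground-truth flags: high-mitochondrial cells (mitochondrial fraction
  forced above 50%), low-complexity cells (all but 150 genes zeroed), and
  all-genes-detected cells (which violate the 6,000-gene ceiling only when
  the panel itself exceeds 6,000 genes; fixtures for that rule are built
  directly as matrices).
* **Determinism.** The configuration seed fully determines the output;
  identical configurations are bit-identical.
* **Barcodes** follow `<celltype>_<condition>_<index>`, keeping fixtures
  human-readable.

The generator deliberately omits gene–gene correlation, batch effects,
doublets and trajectory structure. Passing tests on it therefore
demonstrate that the implementation computes its statistics correctly
under the stated count model and recovers planted signal of realistic
size; they do not certify behaviour under batch confounding or ambient
contamination, which upstream tools address before this pipeline begins.

# Verification strategy and problem sizes

The test suite checks every formula against an independent oracle:
crosstalk statistics against naive per-cell accumulation (tolerance
1e-10), Wilcoxon p-values against exhaustive permutation enumeration at
6-vs-6 group sizes (within 0.02, the accuracy of the continuity-corrected
normal approximation at that size), Fisher p-values against direct
hypergeometric enumeration over all 2×2 tables with total up to 12 plus
random tables with margins up to 30 (tolerance 1e-9), and heatmap row
orders against a cubic-time agglomeration oracle. Calibration and
recovery use the generator: null simulations with 300 cells per group and
2,000 genes over five seeds (raw $p < 0.05$ fraction expected in
[0.03, 0.07]), 50 planted up-genes in a 120-gene panel at multiplier 6
(recall and precision at FDR 0.05), a planted ligand multiplier of 4 with
500 cells per group for crosstalk recovery, and no-effect runs with 1,000
cells per group for category-level calibration. These sizes were chosen so
the whole suite runs on a laptop-class machine while keeping Monte-Carlo
noise well inside the asserted bounds. `scripts/acceptance.R` recomputes
the same quantities from scratch on the reference study for any seed.

# Known limitations

* Communication is inferred from transcript co-expression; protein
  abundance, secretion, ligand diffusion and receptor activation are not
  modelled.
* A single shared NB dispersion and independent genes make the simulator a
  calibration instrument, not a portrait of real heart data.
* The composition test pools cells within conditions, so its p-values
  overstate certainty relative to a donor-level analysis when few donors
  are available.
* Individual ligand–receptor interactions carry no significance test (see
  above); category summaries are descriptive effect sizes.
* Multi-subunit ligand or receptor complexes are unsupported by design.
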