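---
title: "Methods: CITE-seq analysis of CML stem and progenitor cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CITE-seq analysis of CML stem and progenitor cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cmlcite` analyzes CITE-seq data from chronic myeloid leukemia (CML) bone
marrow: simultaneous RNA, surface-protein (ADT) and sample-hashtag (HTO)
counts per cell. This vignette is the package's account of the methods: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

# The analysis chain

## Quality filtering and demultiplexing

A cell is retained iff its detected-gene count lies in
`[min_genes, max_genes]` (defaults 1000/9000) **and** its mitochondrial UMI
fraction is at most `max_mito_fraction` (default 0.11 for patient samples;
0.06 is the normal-bone-marrow reference setting). Both bounds are
inclusive; mitochondrial genes are identified by the `MT-` name prefix
unless an explicit set is supplied.

Hashtag demultiplexing thresholds each HTO independently by Otsu's method:
counts are `log1p`-transformed, binned into a 256-bin histogram, and the
bin boundary maximizing the between-class variance
$\sigma_B^2 = w_0 w_1 (\mu_0 - \mu_1)^2$ is found by exhaustive search over
the 256 candidate cuts. The cut is then relaxed downward by
`background_buffer` (0.1) times the transformed range and floored at
`override` (0.5) times the transformed maximum. The buffer/override
semantics are an interpretation — the tool this mirrors does not document
them — and both are exposed as parameters so alternative semantics can be
swapped in. A constant vector has no threshold; the caller treats all cells
as background for that hashtag. A cell is assigned a hashtag iff its count
*strictly* exceeds that hashtag's cut and no other; two or more exceedances
make a multiplet, none leaves the cell unassigned (ties at the cut are
background).

Residual doublets are flagged by partitioning cells into 2 groups in HTO
space — Ward-style agglomerative community detection
(`igraph::cluster_fast_greedy` cut at 2) on a KNN graph of CLR-normalized
HTO counts — and flagging every (RNA cluster r, HTO group h) intersection
whose overlap exceeds 0.7 *in both directions* (|r∩h|/|r| and |r∩h|/|h|).
Only the intersection is removed, a conservative reading of the rule.

## Normalization, HVGs, graph, clustering

Counts are scaled per cell to the median library size and
`log1p`-transformed. Highly variable genes must be detected in at least
`min_cells` cells (default 50; 1000-gene/30-cell dialect available for
shallower samples); eligible genes are ranked by the dispersion
(variance/mean) of their normalized values, z-scored within mean-expression
bins (median/MAD, bins floored at 20 genes so the bin statistics are
stable). Absolute residuals against the bin median would systematically
favor low-abundance genes, whose dispersions fluctuate on a larger scale —
the within-bin z makes genes compete against peers of comparable abundance.

The selected genes are z-scaled and projected onto at most `n_pcs` (20)
principal components. Components below a **parallel-analysis noise edge**
are discarded: the edge is 1.05 times the top eigenvalue of the matrix with
every gene independently permuted across cells, which preserves the
(selection-biased) marginal distributions while destroying all gene–gene
structure. At least 2 components are always kept. This denoising step (in
the spirit of scran's `denoisePCA`) matters particularly for low-rank data:
Euclidean distances accumulate variance from every retained component, and
components that carry no structure only dilute the neighborhoods the KNN
graph is built from. When `fit_cells` is given (e.g. "PCA fitted to the
primitive CML cells only"), scaling statistics and loadings come from that
subset and all cells are projected with them.

The KNN graph (k = 11) is clustered with Leiden (modularity objective;
resolution 1 for patient samples, 0.76 for the reference, 0.1 for the
coarse primitive merge) on **smooth-KNN fuzzy edge weights**
$w = \exp(-(d - \rho)/\sigma)$ with $\rho$ the distance to the nearest
neighbor and $\sigma$ the mean excess distance, symmetrized by fuzzy union
— the graph construction used by the UMAP family of tools. UMAP runs on
the same PC coordinates (min_dist 1, spread 2, 2000 epochs; 500 in the
primitive-merge dialect) and is deterministic under a fixed seed with
single-threaded SGD.

Marker specificity ranks each gene within each cell (average ranks for
ties; higher expression = higher rank — the source does not state tie
handling, averaging is the conventional choice), averages ranks per
cluster, and normalizes each gene's mean ranks to sum to 1 across clusters.
The top 10 genes per cluster are the annotation report.

## Reference projection and label transfer

A reference model stores the HVG list, per-gene normalization statistics,
PCA loadings, reference PC coordinates and labels. Query cells are
normalized *with the reference's* library target and statistics; reference
HVGs missing from the query are zero-filled (warned; rejected below 90 %
coverage) and extra query genes ignored, preventing silent feature
misalignment. Each query cell's 5 nearest reference cells vote with
normalized inverse-distance weights $w_j = (1/(d_j+\varepsilon)) /
\sum_l 1/(d_l+\varepsilon)$, $\varepsilon = 10^{-9}$ (the weight function
is a design choice — the mirrored tool does not publish one — and the
simplest monotone option). The top cluster is assigned only if its summed
weight strictly exceeds 0.5; otherwise the cell abstains. Abstention is
monotone in the threshold by construction. Mapping scores are
$s_r = c_r \, n_{ref} / (k\, n_{query})$ where $c_r$ counts how often
reference cell r appears among query neighbors; mean 1 is this package's
normalization convention.

## BCR::ABL1 status of primitive cells

Primitive cells from all patients are merged with a control; provenance
(patient, original cell id) is kept so statuses can be linked back by cell
id. The merge dialect fits 500 HVGs (min_cells 30, configurable
sex-chromosome exclusion list) and the PCA on the CML cells only, then
clusters coarsely (Leiden 0.1). Signature scoring library-size-normalizes
(full-matrix cell totals), `log1p`-transforms, z-scores each signature gene
across cells and averages over the *variable* genes — constant genes are
dropped rather than zero-scored, so padding a signature with constant genes
cannot dilute it, and an all-constant signature scores 0. Up- and
down-gene lists (selected in the source comparison at log2FC > 1 and < 0
respectively) are scored as independent LSC and HSC signatures, not
subtracted.

The published procedure assigns status by visual enrichment; this package
formalizes it so the call is deterministic and testable: the cluster
holding the majority of control cells is `control`; every other cluster is
`pos` iff its mean LSC score exceeds its mean HSC score **and** its LSC
scores exceed the control cluster's by a one-sided Wilcoxon rank-sum test
at α = 0.05 (α exposed in the API); otherwise `neg`. Without control
cells the comparison is between CML clusters, with a warning.

## Differential expression

RNA: each group's cells are randomly partitioned into 3 near-equal
pseudobulk replicates (seeded; counts conserved by construction).
Mitochondrial/ribosomal genes (configurable `MT-`/`RPL`/`RPS` prefixes —
the source gives no list) and genes with total count < 10 are excluded,
then DESeq2 (negative-binomial Wald test, median-of-ratios size factors,
Benjamini–Hochberg) compares the groups; independent filtering is disabled
so every tested gene appears in the table. Significance requires adjusted
p < 0.01 and |log2FC| > 1. Cluster-unique sets are the significant up (or
down) genes not significant in *any* other cluster's comparison; the
pan-CML set is the intersection of significant up (down) genes across all
clusters. A 25-cell minimum per group is the recommended floor for the
primitive-cell comparisons.

ADT: CLR per cell ($\mathrm{CLR}_i = \log(x_i+1) - \frac1m \sum_j
\log(x_j+1)$, natural log; the pseudocount handles zeros), log2 fold change
of group means on the antilog ×1000 scale, two-sided Mann–Whitney U on the
per-cell CLR values, Bonferroni over the tested antibodies, significance at
adjusted p < 0.05 and |log2FC| > 1. The exact p is computed by full
enumeration of labelings when the smaller group has ≤ 8 observations *and*
the total is ≤ 24 (enumeration is correct under ties; beyond 24 the
combinatorics are infeasible and the normal approximation with tie
correction takes over). The two-sided exact convention is
$P(|U - \mu_U| \ge |u_{obs} - \mu_U|)$.

## Gating and capture fractions

Scaled ADT values are `exp(CLR) × 1000` (a cytometry-style export scale; a
CLR of 0 maps to 1000). Gates are conjunctions of per-antibody terms: `+`
terms require strict exceedance, `−` terms the complement, so the four
sign combinations over two markers partition any cell set exactly — the
property behind reporting CD26/CD35 quadrant fractions. Gate positions are
user-supplied (mirroring manual cytometry gating; the source's numeric
positions are unrecoverable), with `otsu_threshold` available as an
automatic mid-gap option on bimodal scaled values. Capture fraction is
|gate ∩ population| / |population| (undefined, not zero, for an empty
population); the LSC/HSC ratio reports CD26⁺CD35⁻ : CD26⁻CD35⁺ counts
within a compartment, missing when the denominator is 0.

## Bulk deconvolution

The signature matrix holds per-cluster mean library-size-normalized
expression over the union of each cluster's top 50 marker genes by
specificity (clusters under 10 cells are excluded). Each bulk sample is
solved by non-negative least squares $\min_f \|b - Sf\|_2,\ f \ge 0$ — a
deliberate, solver-agnostic stand-in for the ν-SVR engine used in the
original workflow, with the identical input/output contract (fractions
normalized to sum to 1). Signature and bulk columns are first scaled to a
common total and the solution converted back to the original column units,
which makes the contract exact: scaling a bulk sample by any positive
constant cannot change its fractions, and exact linear mixtures are
recovered to numerical precision. Joint quantile normalization (limma) is
available and on by default for cross-platform use (microarray bulk
against a count-derived signature); it deliberately distorts exact linear
mixtures, so for same-platform data — including all synthetic recovery
checks in this package — `quantile_scale = FALSE` is the correct setting.
Group comparison uses Welch's t-test ("Student t-test" in the source is
ambiguous about variance pooling; unequal variance is the safer default)
at p < 0.05.

# The synthetic-data generator

The generator emulates the study's structure so that every stage has ground
truth: an 11-cluster stem/progenitor hierarchy (Primitive, MPP-I, MPP-II,
LMPP, CMP, GMP, MEP, MkP, EryP, CLP, ProB), each cluster a shared baseline
of per-gene expected counts with 15 disjoint marker genes boosted 8-fold
and 2–3 marker ADTs boosted 20-fold over a background of 5 expected
counts. RNA counts are negative binomial with mean m and dispersion φ
(variance $m + \varphi m^2$; default φ = 0.3, a typical droplet-level
overdispersion; φ = 0 gives the Poisson limit), with a per-cell log-normal
library factor (sd 0.3) so normalization stages are non-trivial. Baselines
are sized for ~10,000 UMIs/cell over 2000 genes — realistic droplet depth —
and the universe contains `MT-` and `RPL`/`RPS` names so QC filters
engage.

A patient adds two layers. (1) A **pan-CML program**: 71 well-expressed
genes shifted log2FC 2 in every patient cell, with per-cell log2-normal
intensity variation (sd 0.5) modeling cell-to-cell variability in leukemic
program activity. This emulates the leukemia-wide signature that separates
patient cells from normal bone marrow; its size mirrors the 50-up/21-down
pan-cluster set scale, and the severalfold shift reflects a
fusion-oncogene-driven program. The per-cell variability is what makes
these genes dispersed — hence selectable as HVGs — within a patient; with
the study's merge dialect (HVGs and PCA fitted on CML cells only) the
control-offset direction is representable only insofar as patient cells
themselves vary along it. (2) The **primitive sub-states**: each Primitive
cell is leukemic with probability `bcr_abl1_fraction`; leukemic cells scale
the signature's up-genes by $2^{+effect}$ and its down-genes (the HSC
program lost in leukemic cells) by $2^{-effect}$, and carry boosted CD26
and CD25 ADTs; non-leukemic primitive cells carry boosted CD35. Signature
and pan gene sets are drawn from well-expressed free genes (baseline at or
above the free-gene median): DE-derived signatures consist of robustly
detected genes, and near-undetectable genes would carry no usable signal.

Hashtags: each cell receives one hashtag uniformly; counts are Poisson
background (mean 2) plus Poisson signal (mean 100) on the assigned
hashtag(s); a `doublet_rate` fraction of cells carries a second, distinct
hashtag signal and is flagged in truth. Doublets exist in HTO space only —
the doublet rule this exercises operates on HTO/RNA cluster overlap, so
RNA doublet profiles are unnecessary. Bulk samples are fraction-weighted
sums of cluster mean profiles with multiplicative log-normal noise.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: transcriptome-wide co-expression structure
(genes are conditionally independent given cluster, sub-state and library
factor), ambient RNA, batch or patient effects beyond library-size
variation, RNA doublet profiles, and empty droplets. Real data violate all
of these; the tests demonstrate that the implementations are correct and
that recovery works under the stated generative model, not that the
pipeline is robust to artifacts it never sees.

# Numerical choices and degenerate inputs

- All randomness flows from explicit integer seeds; generators derive
  per-stream children below 2³¹ and are bit-reproducible.
- Zero-count cells get scale factor 0 (not NaN) in normalization; constant
  genes z-scale to all-zero rows rather than NaN.
- `prcomp` rank reduction and the parallel-analysis trim never go below 2
  components; the permutation uses a private RNG stream, restoring the
  caller's seed state.
- Weighted-vote ties and the 0.5 threshold: strict inequality, so a
  perfect 50/50 split abstains.
- Wilcoxon tie handling: average ranks; exact enumeration subtracts 1e-9
  before comparing |U − μ| so floating-point equality counts as "at least
  as extreme".
- Fractions from NNLS with an all-zero solution are returned as zeros (not
  renormalized); all-zero bulk samples are rejected.
- `assign_status` with identical score vectors labels every non-control
  cluster `neg` (the rank-sum test cannot reject).
- Problem sizes in the test-suite: unit tests run on a 300-gene, ~200-cell
  universe; end-to-end checks use the full default generator (2000 genes,
  1000–2000 cells), chosen to exercise the study-scale dialects while
  keeping the whole suite in single-digit minutes on one CPU.

# Known limitations

- The NNLS deconvolution shares the input/output contract of the original
  ν-SVR engine but not its internals (no support-vector gene weighting, no
  batch-mode expression imputation).
- Otsu "background buffer" and "override" semantics are an interpretation
  of an undocumented tool internal, as is the realization of the 2-way HTO
  partition by agglomerative graph clustering.
- Exact Mann–Whitney enumeration is capped at 24 total observations.
- The coarse three-cluster structure of a primitive merge depends on the
  strength of the pan-CML and signature programs relative to the NB noise;
  with weak programs the control and BCR::ABL1⁻ populations are genuinely
  inseparable under this generative model (no batch effects), and the
  coarse clustering will merge them.
- Direct detection of BCR::ABL1 fusion transcripts from reads is out of
  scope; status is inferred from expression programs only.
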