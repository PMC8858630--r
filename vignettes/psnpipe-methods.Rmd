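---
title: "Methods: models, parameters and design choices in psnpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in psnpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

psnpipe implements, as one tested pipeline, the bespoke computational
procedures used in single-cell transcriptomic comparisons of pulmonary
part-solid nodules: cohorts where each patient contributes a ground-glass
(GG) and a solid tumour component sample, with normal lung (nLung) for a
subset of patients. This vignette explains each stage's model and
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic cohort generator does and does not emulate, and the
design choices made where the procedures are conventionally left
under-specified.

## Quality control and normalization

Cells are retained when they have between 200 and 6000 detected genes
(inclusive bounds: the removal rules are "fewer than" / "more than", so
boundary cells stay), at most 15% of UMIs from mitochondrial genes
(symbols with case-insensitive prefix `MT-`, the community convention), and
at most 60,000 total UMIs. Genes are kept when detected in at least 5
cells. Filters are applied per sample, cells before genes; both filters are
idempotent, and the order matters only through the gene-in-5-cells rule.

Normalization is `ln(count / cell_total x 10000 + 1)`. Zero counts map to
zero, so sparsity is preserved, and for every cell with a positive total
`sum(exp(value) - 1)` equals the scale factor exactly — the invariant the
test suite checks to 1e-6 relative.

Variable genes (default 2000) are ranked by standardized variance: a
mean-variance trend is fit on the log10 scale and each gene's counts are
z-scored with the trend-predicted standard deviation, clipped at
`sqrt(n_cells)`. The trend is a ridge-regularized quadratic in log10 mean
rather than a local regression: it is deterministic, dependency-free, and
an adequate approximation of the named "vst" procedure at the panel sizes
this package targets. With very few genes anchoring a mean range the trend
follows individual outliers, as any local fit would; the tests anchor
trends deliberately when they plant outliers.

Doublets are flagged by marker co-expression: a cell expressing canonical
markers of two or more cell types. The quantitative reading — a marker set
counts as expressed when more than half its genes have nonzero normalized
value — is a package choice; the field states this rule only
qualitatively.

## CNV inference and malignant-cell calling

The copy-number signal is a deliberately minimal moving-average estimator,
standing in for heavier HMM-based tools while preserving the signal
structure the downstream classifier needs. Per gene, the reference-cell
mean is subtracted from log-normalized expression; residuals are clipped at
±3; a centered moving average of width 101 genes is taken along genome
order within each chromosome (shrinking at chromosome edges); each cell's
median smoothed value is subtracted; and the reference cells' mean smoothed
profile is subtracted gene-wise. Reference populations follow the
convention for tumour CNV baselines: T cells, endothelial cells, fibroblasts, and normal-lung epithelial
cells, pooled per patient. The mitochondrial contig is excluded: it
carries no copy-number information, and its expression tracks per-cell
mitochondrial content, which would otherwise dominate the per-cell
correlations.

The per-cell CNV score is the mean square of the re-standardized signal.
Within each patient (GG and solid epithelial cells pooled), the cells with
scores in the top 5% (ceiling, minimum 1) are averaged gene-wise — as
signed signals, not squared scores, since a correlation against a squared
vector would discard the amplification/deletion sign — into a reference
vector, and a cell is called malignant when the Pearson correlation of its
signal with that vector strictly exceeds 0.3. Cells with zero-variance
signal have undefined correlation and are conservatively called
non-malignant with a flag.

A resolution caveat documented here because it shapes the evaluation: the
null distribution of the classifier correlation is governed by the number
of effectively independent smoothing windows, roughly genes/window. On a
2000-gene panel that is ~20 windows (null sd ~0.22), leaving an irreducible
~5% false-positive rate at the 0.3 threshold no matter the implementation;
at 6000 genes the null sd drops to ~0.13 and specificity is comfortably
above 95%. The malignant-calling evaluation therefore uses a 6000-gene
panel (6 patients x 300 cells), matching the genome-scale gene density the
101-gene window presumes; other stages use 2000-gene panels.

## NMF expression programs and meta-programs

Per sample, malignant-cell expression is z-scored per gene, negatives set
to zero, and factorized by NMF at each rank k in the configured range
(default range 6–9; the recovery evaluation uses 4–6 at its smaller
sample sizes). The solver is Frobenius-loss multiplicative updates from a
non-negative double-SVD initialization with small-constant zero-fill —
deterministic, run to a 1e-4 relative-error tolerance or 500 iterations.
Each factor yields a program: its top 50 genes by loading, ties broken
lexicographically.

A program is *robust* when a program of the same sample at a different rank
shares at least 35 of its 50 genes. Robust programs are pooled per group
(GG and solid clustered separately), with pairwise distance 50 minus the
shared-gene count, average-linkage hierarchical clustering, and a fixed cut
at height 15 (= 50 − 35) replacing manual dendrogram inspection — a
deterministic rule, deliberately commensurate with the robustness
criterion. Clusters spanning at least two samples become meta-programs. A
core gene must appear in at least 25% of a meta-program's member programs
*and* in programs from at least two samples; the 25%-of-member-programs
reading (rather than 25% of samples, or gene-wise overlap against foreign
programs) is one of several defensible readings of the criterion as it is
usually stated, and both the fraction and the cross-sample requirement are configurable.
Functional annotation of meta-programs is a user-supplied label mapping;
ontology enrichment is out of scope.

## Signature scoring

A gene set's score in a cell is the mean normalized expression of the set
minus the mean of a pooled background: for each foreground gene, 100 genes
drawn uniformly from its expression bin (25 equal-count bins on mean
expression across all cells), excluding foreground genes — exclusion
prevents self-matching bias — with replacement when a bin is smaller than
100. Scores are invariant to adding a constant to a cell (foreground and
background shift together). Each set draws from a random stream derived
from `(seed, set name)`, so adding or reordering sets never changes
another set's scores. Set genes missing from the matrix are dropped with a
warning.

## Group statistics

Composition tables are per-sample fractions over a stated denominator
(e.g. immune cells only). Group comparisons use the two-sided Wilcoxon
rank-sum (unpaired) or signed-rank (paired, e.g. GG vs solid within
patient) test. Exact enumeration is used for the unpaired test up to a
combined n of 12 without ties and for the paired test up to 15 nonzero
differences without ties, otherwise the normal approximation with tie and
continuity correction — switch points that are conventionally
left to the statistics environment, fixed here and documented. Benjamini–Hochberg adjustment is
applied within one family per cell type across its group comparisons.
(The BH transform is not idempotent — re-adjusting adjusted values changes
them — so the tests assert its real properties: adjusted ≥ raw, capped at
1, monotone in sorted order.)

Signature scores are compared between clinical groups with the
random-intercept model `score ~ group + (1 | patient)`, fit by REML. The
implementation profiles the likelihood over the single variance ratio
(bounded one-dimensional optimization, tolerance 1e-8, the zero boundary
checked explicitly), and computes Satterthwaite degrees of freedom for each
contrast from the gradient of the contrast variance in the variance
components and the observed REML information (central finite differences).
Treatment coding uses nLung as reference when present, else GG. Pairwise
group comparisons are separate two-group fits, matching per-panel
significance reporting; a joint three-level fit returns one contrast per
non-reference level. The implementation is cross-checked in the tests
against lme4/lmerTest on general fits (agreement ~1e-7) and against the
pooled two-sample t-test in the zero-patient-variance limit, where the
boundary fit collapses to OLS with df = N − 2 exactly.

## Ligand–receptor communication

The communication score is a declared simplification of mass-action
models: per cell, a multi-subunit ligand or receptor is summarized by the
geometric mean of its subunits (zero if any subunit is silent); L and R are
the sender/receiver group means; the probability is `L*R / (0.5 + L*R)` —
zero exactly when either side is silent, monotone, saturating at 1.
Significance is a one-sided permutation test: group labels are shuffled
globally, all probabilities recomputed, and `p = (1 + #{perm >= obs}) /
(1 + n_perm)` with one shared permutation stream across pairs per seed;
zero observed probability reports p = 1 with a flag. Defaults: 999
permutations, groups under 10 cells skipped, BH within each
sender–receiver family. The permutation count and null construction vary
between tools; these defaults are declared, not inferred. Calibration measured over 3000 null replicates: rejection rate
0.052 ± 0.004 at nominal 0.05.

## The synthetic cohort generator

The generator exists so every stage is testable against planted truth. Its
defaults mirror the target study design: 12 patients with paired GG and
solid samples, nLung for the first 5; six cell types (normal epithelial,
malignant, T, myeloid, fibroblast, endothelial) whose group-level abundance
weights encode the planted composition shifts (e.g. malignant fraction 0 /
0.20 / 0.35 and T fraction 0.30 / 0.30 / 0.20 across nLung / GG / solid);
three chromosome-scale CNV segments in malignant cells (chromosomes 1 and
3 at fold 2.0, chromosome 5 at fold 0.5 — the fold-about-2 amplitude
typical of arm-level events); three 50-gene expression programs active in
~30% of malignant cells with log-amplitude ~2, interleaved along
non-CNV chromosomes; and one 40-gene signature set shifted by +0.25 (GG)
and +0.5 (solid) log units.

Counts are negative binomial (shared dispersion 2) with mean
`libsize x p`, where `libsize` is log-normal (median 2500, sdlog 0.3) and
`p` allocates a Beta-distributed mitochondrial fraction (mean 5%) to `MT-`
genes and the softmax of the type's log-baseline plus planted log-fold
terms to the rest. Marker genes are near-exclusive per type (silenced
elsewhere), and markers and program genes are scattered along their
chromosomes — as real marker and program genes are — so that no planted
gene block mimics a CNV segment after smoothing. QC violators are planted
by construction (e.g. low-gene cells restricted to 150 genes; high-mito
cells given a mitochondrial top-up beyond 25%), and clean cells receive
deterministic minimal corrections guaranteeing they pass every rule, so
planted class labels match QC outcomes exactly. All randomness flows from
the single config seed; identical config and seed reproduce the cohort
byte-identically.

What the generator does *not* emulate: transcriptome-wide co-expression
structure, ambient RNA, empirical library-size/detection relationships,
batch effects, doublets (beyond test-constructed marker co-expression),
sub-clonal CNV heterogeneity, or realistic gene-length/GC effects.
Passing tests therefore demonstrate algorithmic correctness and
recoverability of planted structure at realistic noise levels — not
performance on real tissue.

## Problem sizes used in the checks

The test suite and acceptance script size their cohorts to exercise each
property well: QC exactness on 1000 cells (8000-gene panel, every
violation class planted); malignant calling on 6 patients x 300 cells
(6000 genes); meta-program recovery on 6 patients x 300 cells (2000
genes, 1000 variable genes, k 4–6, roughly 45–115 malignant cells per
tumour sample); mixed-model calibration on 500 null fits and 200 recovery
replicates (10 patients x 100 cells); communication calibration on 200
null datasets at 99 permutations. These sizes were chosen once as adequate
for the properties tested and are stated here so results are interpreted
at the scale they were computed.

## Known limitations

The CNV estimator is a moving-average proxy, not a segmentation model: it
reports relative, smoothed signal, and its specificity depends on panel
gene density as described above. The NMF solver is single-start
(deterministic initialization) rather than consensus-over-restarts. The
core-gene rule implements one reading of an ambiguous convention.
The communication score is a simplified model, not a full mass-action
framework, and its
absolute probabilities are not comparable across datasets with different
normalization depths.
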