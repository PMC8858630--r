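# psnpipe

Single-cell analysis pipeline for pulmonary part-solid nodules (PSNs):
lung lesions with a ground-glass (GG) and a solid CT component. Cohorts of
this kind profile, per patient, a GG sample and a paired solid sample by
droplet scRNA-seq, with normal lung (nLung) for a subset of patients, and
ask how malignant cells and the surrounding microenvironment differ along
the nLung → GG → solid axis. psnpipe packages the bespoke computational
steps such studies rely on as tested, reusable R functions, together with
a synthetic cohort generator with planted ground truth so that every stage
can be validated without access to patient data.

## What it implements

- **QC and normalization** — retain cells with 200 ≤ detected genes ≤
  6000, mitochondrial UMI fraction ≤ 15%, total UMIs ≤ 60,000; drop genes
  seen in < 5 cells; normalize as ln(UMI-per-10,000 + 1); rank 2000
  variable genes by trend-standardized variance; flag doublets by
  canonical-marker co-expression.
- **CNV-based malignant-cell calling** — smoothed CNV signal from
  genome-ordered expression (reference-mean subtraction, ±3 clipping,
  101-gene moving average, median recentering, re-standardization);
  per-cell score = mean square of the signal; per patient, a reference
  vector averages the top-5% scoring cells; a cell is malignant when the
  Pearson correlation of its signal with the reference vector exceeds
  r = 0.3.
- **NMF meta-programs** — per-sample NMF of malignant cells (z-scored,
  negatives zeroed) across ranks k = 6…9; programs = top 50 genes per
  factor; robust iff ≥ 35/50 genes shared with a program at another rank;
  average-linkage clustering of robust programs (distance = 50 − overlap,
  cut at 15) into meta-programs spanning ≥ 2 samples; core genes appear in
  ≥ 25% of member programs across ≥ 2 samples.
- **Signature scoring** — per-cell mean expression of a gene set minus the
  mean of 100 background genes per set gene drawn from matching expression
  bins (25 equal-count bins).
- **Group statistics** — per-sample composition tables; two-sided
  unpaired/paired Wilcoxon tests with Benjamini–Hochberg adjustment; and
  the random-intercept mixed model `score ~ clinical_group + (1|patient)`
  fit by REML with Satterthwaite degrees of freedom for the fixed-effect
  tests.
- **Ligand–receptor communication** — a Hill-form score
  L·R/(0.5 + L·R) from sender-ligand and receiver-receptor group means
  (geometric mean over subunits per cell), with a one-sided
  label-permutation test.
- **Synthetic cohorts** — multi-patient fixtures with planted CNV
  segments, shared expression programs, signature shifts, composition
  differences and QC violators, written/read as 10x-style MatrixMarket
  triplets.

## Worked example

```r
library(psnpipe)

# simulate a small cohort: 3 patients, paired GG/solid (+ nLung for two)
cfg <- cohort_config(n_patients = 3, nlung_patients = 2,
                     n_cells_per_sample = 200, seed = 42)
cohort <- simulate_cohort(cfg)
length(cohort$samples)
#> [1] 8

# QC + log-normalization across samples
nm <- qc_normalize_cohort(cohort$samples)
nm
#> norm_matrix: 1818 genes x 1520 cells | 8 sample(s)

# per-patient CNV-based malignant calling
calls <- call_malignant_cells(nm)
table(calls$group, calls$malignant)
#>         FALSE TRUE
#>   GG       84  115
#>   solid    48  221

# signature scoring + mixed-model group comparison
sets <- list(gene_set("stress_response", cfg$signature_shift_spec[[1]]$genes))
scores <- score_named_sets(nm, sets, seed = 1)
fit <- fit_lmm(scores$stress_response, nm$cells$group, nm$cells$patient_id)
fit
#>              contrast   estimate          se       df         t            p
#> 1    groupGG_vs_nLung 0.07034089 0.009639413 343.8547  7.297217 2.048598e-12
#> 2 groupsolid_vs_nLung 0.18031568 0.009639413 343.8547 18.706085 2.345090e-54
```

Reading the output: of the epithelial-compartment cells in the tumour
samples, 115/199 (GG) and 221/269 (solid) are called malignant — the
generator plants a higher malignant fraction in solid samples. The mixed
model recovers the planted upward shifts of the signature in GG (+0.07)
and solid (+0.18) relative to normal lung, with patient as a random
intercept and Satterthwaite degrees of freedom; both fixed effects are
strongly significant, solid more than GG, matching the planted ordering.

The full pipeline (`run_pipeline()`) chains QC → labels → CNV/malignant
calling → meta-programs → signature scores → composition and mixed-model
tests → communication tests, logs per-stage dimensions, and writes TSV
outputs; see the methods vignette (`vignettes/psnpipe-methods.Rmd`) for
the models, parameter defaults and design choices.

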