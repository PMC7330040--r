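# tmenet

Weighted co-expression module analysis of tumor-microenvironment programs
in colorectal-cancer (CRC) liver metastasis.

## The problem

Metastatic dissemination of CRC is driven less by new driver mutations than
by transcriptional programs of the tumor microenvironment (TME): EMT,
angiogenesis, immune suppression and cancer-associated fibroblasts.
Matched-trio designs — adjacent normal (AN), primary tumors without
metastasis (CNM), primaries with metastasis (CWM) and the paired liver
metastases (CLM) — let these programs be separated from somatic genetics,
which is largely concordant between a primary tumor and its metastasis.
`tmenet` implements the full analysis chain for such a design, for
computational biologists who want every stage reproducible and testable:

1. **Network construction** — count filter, quantile normalization,
   soft-thresholded Pearson adjacency `a_ij = |cor(x_i,x_j)|^β` (β = 6),
   topological overlap
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 − a_ij)`,
   average-linkage module detection with eigengene merging at
   dissimilarity 0.10.
2. **Eigengene statistics** — module eigengenes (first principal component
   of standardized member expression), Pearson module–trait correlation
   with t-based p-values and BH FDR, Welch/paired group tests, eigengene
   clustering.
3. **Module annotation** — one-way ANOVA against purified cell-type
   reference profiles, size-corrected signature overlap
   `100·|S∩M|/|M|` with a seeded random-signature null, hypergeometric
   over-representation, ranked minimum-hypergeometric scores, hub genes by
   intramodular connectivity `kIM(g) = Σ_{h∈M(g)} TOM_gh`.
4. **Genomic alterations** — gene-level absolute copy-number categories
   (deletion < 1.0 ≤ loss < 1.85 ≤ diploid ≤ 2.15 < gain ≤ 4.0 <
   amplification, most-deviant-from-2 rule, deletion precedence), a
   two-stage somatic SNV filter cascade with per-rule audit, mutation
   severity ranking, Fisher group tests, primary/metastasis concordance,
   Jaccard mutation-profile clustering.
5. **Outcome** — Welch-t differential expression (DEG ⇔ FDR < 0.05 and
   |FC| ≥ 2), mean-split dichotomization, Kaplan–Meier/log-rank,
   responder-style score comparisons.

A seeded synthetic matched-trio cohort generator with planted module
structure, trait effects, cell-type references, copy-number segments,
concordance-controlled variant tables and module-dependent survival gives
every stage known ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole chain on the standard
synthetic cohort (2,000 genes, five planted modules, 64 samples):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_build_network.R
Rscript analysis/03_eigengene_traits.R
Rscript analysis/04_module_annotation.R
Rscript analysis/05_genomic_alterations.R
Rscript analysis/06_outcome.R
```

Stage 2 reports, for the default seed:

```
genes after count filter: 2000; network genes (signal > 5 in 80%): 2000
scale-free fit at beta 6: signed R^2 = 0.853, slope = -1.23
detected modules: GM1=500, GM2=250, GM3=204, GM4=150, GM5=101
ARI vs planted truth (non-background genes): 0.997
```

All five planted modules are recovered (adjusted Rand index 0.997 against
the planted labels; GM1 additionally absorbs some background genes at the
static cut). Stage 3 then finds exactly the planted biology:

```
module-metastasis correlations (top 3):
  GM1: r = +0.650, p = 6.17e-09, FDR = 3.08e-08
  GM4: r = +0.124, p = 3.29e-01, FDR = 8.22e-01
  GM2: r = -0.057, p = 6.53e-01, FDR = 8.38e-01
```

GM1 — the module whose latent factor was shifted in the metastatic groups —
is the only metastasis-correlated module; stage 4 maps GM1/GM2/GM3 to the
CAF/myeloid/lymphoid reference profiles they were planted in, and stage 5
recovers the configured 90 % primary/metastasis variant concordance
(`mean concordance before filtering: 90.0%`). Stage 6 dichotomizes patients
by mean split on GM1 and reports the survival contrast
(`median survival: High 20.1 vs Low 58.3 months`, log-rank p = 0.059 at
n = 32), the direction planted through the positive module-1 hazard
coefficient.

Programmatic use mirrors the scripts:

```r
library(tmenet)
coh  <- generate_cohort(cohort_config(seed = 1))
par  <- network_params()                    # beta 6, merge 0.10
tom  <- topological_overlap(adjacency(coh$expression, par))
mods <- merge_close_modules(detect_modules(tom, par), coh$expression, par)
eig  <- module_eigengenes(coh$expression, mods)
module_trait_correlation(eig, data.frame(metastasis = coh$samples$metastasis))
```

## Layout

```
R/                   package code (all computation lives here)
analysis/01..06_*.R  numbered workflow drivers writing results/
scripts/acceptance.R headline-quantity reproduction script
tests/testthat/      unit, property and acceptance tests with oracles
vignettes/           methods vignette (model, parameters, limitations)
```
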