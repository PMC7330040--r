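---
title: "Methods: co-expression modules, eigengene statistics and genomic alterations in tmenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, eigengene statistics and genomic alterations in tmenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmenet)
```

## What the pipeline computes

`tmenet` implements an integrative analysis that links tumor-microenvironment
(TME) transcriptional programs — EMT, angiogenesis, immune suppression,
cancer-associated fibroblasts — to colorectal-cancer liver metastasis in a
matched-trio design: adjacent normal tissue (AN), primary tumors without
metastasis (CNM), primary tumors with metastasis (CWM) and the matched liver
metastases (CLM). The chain is

1. count filtering and quantile normalization;
2. weighted co-expression network construction and module detection;
3. module eigengenes and their relation to clinical traits and groups;
4. module annotation against purified cell-type references and curated
   signatures;
5. gene-level copy-number classification and a somatic-variant filter
   cascade with concordance and mutation-profile clustering;
6. outcome analysis: differential expression, mean-split Kaplan–Meier /
   log-rank, and two-group score comparisons.

Because the patient data behind such studies are generally not depositable,
the package ships a fully seeded synthetic cohort generator with planted
ground truth; every stage is validated by recovering what was planted or by
exact oracles.

## The network model

Expression is analyzed on the log2 scale. For genes $i, j$ the unsigned
weighted adjacency is

$$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta, \qquad a_{ii} = 0,$$

with soft threshold $\beta = 6$ by default. An even power makes the sign of
the correlation irrelevant, so the unsigned form is the natural reading of
"correlation raised to the sixth power"; a signed variant
($((1+r)/2)^\beta$) is available behind the `signed` flag but is off by
default. The zero diagonal makes whole-network connectivity a plain row sum,
$k_i = \sum_j a_{ij}$.

The adjacency is transformed into the topological overlap measure

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad \mathrm{TOM}_{ii} = 1,$$

which credits a gene pair both for its direct adjacency and for the
neighborhood it shares. Modules are detected by average-linkage hierarchical
clustering on the dissimilarity $1 - \mathrm{TOM}$ with a **static** cut:

* `cut_height` default 0.99 — clusters are read off the tree at a fixed
  height;
* `min_module_size` default 30 — smaller clusters become `"unassigned"`,
  the grey-module convention;
* modules whose eigengenes satisfy $1 - \mathrm{cor}(ME_a, ME_b) < 0.10$
  are merged iteratively (`merge_threshold` default 0.10), recomputing
  eigengenes after every merge.

The static cut is the main deliberate simplification in the network stage:
dynamic tree cutting has many interacting parameters and is hard to make
bit-reproducible, while the static cut has one parameter, is deterministic,
and — combined with the 0.10 eigengene merge, which is the step the design
pins down precisely — recovers planted modules essentially perfectly
(adjusted Rand index $\ge 0.997$ on the standard synthetic cohort through
the full counts → normalization → network path). The cost is that the
detected module count on real data will not match a dynamic-cut analysis
module for module; this is documented rather than patched.

Scale-free fit is reported as the regression of $\log_{10}$ bin frequency on
$\log_{10}$ mean bin connectivity over equal-width connectivity bins,
together with the signed index $-\mathrm{sign}(\mathrm{slope}) \cdot R^2$.
Two details matter. Binning is equal-width on the raw connectivity scale:
under any power transform of the degrees, log-width bins would leave the
histogram shape — and hence $R^2$ — unchanged, which would make soft
thresholding invisible to the diagnostic. And the signed index is the
quantity to compare across $\beta$: a connectivity distribution can be
perfectly log-linear with a *positive* slope, which is a good regression and
a bad power law.

## Eigengenes and trait statistics

A module eigengene is the first principal component of the member genes'
standardized expression, scaled to mean 0 / sd 1 over samples and oriented
so its mean correlation with the members is non-negative. The sd-1 scaling
(rather than unit norm) makes group tests scale-free; it affects no
correlation or test statistic. PC-1 optimality — the eigengene explains at
least as much member variance as any alternative linear combination — is
verified by Monte-Carlo probe in the tests.

Module–trait association is the Pearson correlation of eigengene and trait
with the two-sided asymptotic $t$ p-value on $n-2$ df and
Benjamini–Hochberg FDR across modules per trait; group contrasts are Welch
$t$ (unpaired, e.g. CWM vs CNM) or paired $t$ (CLM vs CWM, matched by
patient). Asymptotic rather than permutation p-values match conventional
usage at these sample sizes; all four test families (trait correlation,
group tests, cell-type ANOVA, overlap chi-square) are verified to produce
uniform p-values under the null generator (Kolmogorov–Smirnov at 500
replicates).

External scoring recomputes eigengenes from whichever member genes an
external matrix contains, dropping missing genes (never imputing) and
reporting the member-coverage fraction so transferability can be judged.

## Module annotation

* **Cell-type enrichment**: the module score in reference profiles is the
  *mean* standardized member expression, not a re-fit PC-1 — reference
  panels have few profiles (the purified-cell settings this emulates have
  on the order of a dozen), where PC-1 is unstable. Scores are compared
  across cell types by one-way ANOVA with BH FDR.
* **Signature overlap**: the size-corrected statistic
  $100 \cdot |S \cap M| / |M|$ with a null from 1,000 random same-size
  signatures drawn from the universe (seeded), reported as null mean/sd for
  hollow-bar display. The p-value is a chi-square test on the 2×2
  membership table with the continuity correction off; Fisher's exact test
  is exposed as a flag. Both tests appear in this literature; chi-square is
  the default for the overlap display and the two agree in rank order,
  which the tests assert.
* **ORA**: upper-tail hypergeometric probability, BH FDR, enrichment score
  $-\log_{10} p$; checked against brute-force enumeration to $10^{-10}$.
* **Ranked mHG**: for each prefix of a ranked gene list the upper-tail
  hypergeometric p of the member count in the prefix; the score is the
  minimum over prefixes. Significance comes from seeded rank permutations
  with the add-one correction — assumption-free and reproducible, at the
  cost of a resolution floor of $1/(n_{\mathrm{perm}}+1)$.
* **Hubs**: intramodular connectivity $kIM(g) = \sum_{h \in M(g)}
  \mathrm{TOM}_{gh}$, rank 1 = strongest hub, ties broken by gene id;
  neighborhoods of a focal gene return the top-TOM members per module.
* The universe for overlap and ORA defaults to all network genes,
  overridable.

## Copy number and somatic variants

Gene-level absolute copy number uses five categories: deletion
($\mathrm{CN} < 1.0$), loss ($1.0 \le \mathrm{CN} < 1.85$), diploid
($1.85 \le \mathrm{CN} \le 2.15$), gain ($2.15 < \mathrm{CN} \le 4.0$),
amplification ($\mathrm{CN} > 4.0$). When a gene overlaps several segments
the copy number most deviating from 2 is selected, **except** that any
overlapping segment below 1.0 forces the deletion category. A tie at equal
deviation on both sides of 2 resolves to the lower copy number
(conservative toward loss; configurable in principle, logged always). All
coordinates are 1-based fully-closed intervals, stated once and enforced
everywhere; any-base overlap counts. Category boundaries are tested on both
sides at $\pm 10^{-9}$.

The somatic SNV filter is a two-stage cascade with inclusive bounds:
supporting reads in tumor $\ge 8$; supporting reads in normal $\ge 6$ (a
deliberately generic `n_supporting` field — callers differ on whether this
counts reference-supporting reads or total coverage, so either semantics
can be supplied); tumor VAF $\ge 0.1$; normal VAF $\le 0.1$; caller p
$\le 0.05$; then Fisher exact p $\le 0.05$, distance of the variant base
from either read end $\ge 5$, and three artifact screens (base quality,
mapping quality, strand bias) that pass when their p-value *exceeds*
$\alpha = 0.05$, i.e. no significant artifact signal. The three screens
require read-level data this package does not model; they are consumed as
precomputed per-site p-values — a documented limitation, not a hidden one.
The audit attributes each rejected variant to the first rule it fails, and
records with missing stringent-stage statistics are flagged not-evaluable
rather than silently passed or dropped; audit counts always sum to
input − passed − not-evaluable.

Mutation severity is ordinal: missense (1) < inframe indel (2) <
splice-site (3) < frameshift indel = nonsense (4); consequence types
outside the ordering rank 0. Concordance between a patient's primary tumor
and metastasis is shared/(shared + private) over site keys
(chrom, pos, ref, alt). Mutation-profile clustering uses Jaccard distances
on binary sample × site matrices with average linkage.

## Outcome analysis

The differential-expression engine is a Welch/paired $t$ on log2 expression
with the DEG rule FDR < 0.05 **and** |fold change| ≥ 2 (i.e.
$|\log_2 \mathrm{FC}| \ge 1$) — both conditions, so a significant gene
below the fold-change bar is never a DEG. This is explicitly a moment-based
stand-in, not a negative-binomial count model; DEG counts from count-model
analyses are therefore not comparable targets.

Survival uses mean-split dichotomization (High ⇔ score strictly above the
cohort mean; ties at the mean are Low), product-limit curves and the
standard two-group log-rank test (hypergeometric variance at each event
time, simultaneous-event tie convention, 1 df). With no censoring the KM
curve equals the empirical survival function exactly, which the tests
assert; power at hazard ratio 3 with $n = 50/50$ and ~20% censoring
exceeds 0.8.

## The synthetic cohort: what it emulates and what it does not

Member genes of module $m$ follow a single-factor model
$x_g = \mu_g + \lambda_g f_m + \varepsilon$, with per-sample factor
$f_m \sim N(0,1)$ plus group-specific shifts, loadings
$\lambda_g \sim U(0.65, 0.95)$ and noise sd $\sigma = 0.6$. This puts the
within-module correlation $\lambda^2 / (\lambda^2 + \sigma^2)$ around
0.5–0.7 — the coherence of a well-defined co-expression module — and the
tests verify the closed form to 0.02. Defaults are the standard cohort:
2,000 genes, five modules of 300/250/200/150/100 members, 1,000 background
genes, and 16 samples per group (64 total), a desk-scale rendering of a
trio design with a few dozen patients. The planted metastasis effect is a
+1.5 shift of module 1's factor in CWM and CLM; survival hazard is
$h_i = h_0 \exp(0.8 \cdot ME_1(i))$ with $h_0 = 0.02$/month and ~20%
independent censoring; matched CWM/CLM variant sets share 90% of each
patient's site union, mirroring the high primary/metastasis concordance
such cohorts show. Counts are Poisson draws around $2^{x}$ rescaled to
lognormal library sizes near $2 \times 10^6$, giving the count-filter
stage real work.

What the generator does **not** emulate: read-level sequencing error,
isoforms, realistic mutational signatures, copy-number effects on
expression, batch structure, or correlated modules (factors are
independent; module–module eigengene correlation on real tissue is often
substantial). Passing tests therefore demonstrate that the machinery is
correct and calibrated — not that real tissue satisfies the factor model.

## Numerical and design choices

* Determinism everywhere: the cohort is a pure function of its
  configuration; sub-generators use fixed offsets from the configured seed
  so they are independently callable; module labels are canonical
  (decreasing size, ties by smallest member gene id); all tie-breaks are
  lexicographic and stated.
* Quantile normalization maps every sample to the mean empirical
  distribution by sort-based assignment (ties broken by order), so two
  samples that are permutations of each other become identical — the
  defining property, asserted in the tests.
* Zero-variance genes cannot be correlated and are dropped with a warning
  naming them, never silently.
* The normalization target is log2 quantile-normalized values; that is the
  assumed substrate for all downstream stages.
* Chi-square calibration of the overlap test is checked on tables large
  enough (universe 20,000, signature 4,000, module 2,000) for the discrete
  overlap distribution to be effectively continuous; at small counts the
  exact Fisher flag is the better choice.
* Problem sizes in the test suite (tiny 60-gene cohorts for calibration
  loops, the 2,000-gene standard cohort for recovery, 500-replicate nulls)
  were chosen so that each statistical claim is tested at the scale where
  its approximation is valid while the full suite stays comfortably
  interactive.

## Known limitations

* Static tree cut: module counts on real data are not comparable to
  dynamic-cut analyses (the merge step, not the cut, is the precisely
  specified part of the procedure).
* The DE stand-in is not a count model.
* The three read-level artifact screens are consumed, not computed.
* No covariate adjustment, mixed effects, or Cox regression — the design
  this mirrors used none.
* The mHG p-value is permutation-based with a resolution floor, not the
  exact dynamic-programming bound.
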