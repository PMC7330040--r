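#!/usr/bin/env Rscript
# Stage 6 — differential expression and outcome.
#
# Runs the Welch-t differential-expression stand-in (DEG rule: FDR < 0.05
# and |fold change| >= 2) for CWM vs CNM, dichotomizes patients by mean
# split on the top metastasis module's eigengene, compares survival by
# Kaplan-Meier/log-rank, and contrasts module scores between MSI and MSS
# tumors as the responder-style two-group comparison.

suppressPackageStartupMessages(library(tmenet))

expr <- read_matrix_tsv(file.path("results", "cohort", "expression.tsv"))
samples <- utils::read.delim(file.path("results", "cohort", "phenotype.tsv"))
survival_df <- utils::read.delim(file.path("results", "cohort",
                                           "survival.tsv"))
eig <- read_matrix_tsv(file.path("results", "traits", "eigengenes.tsv"))
mt <- utils::read.delim(file.path("results", "traits", "module_trait.tsv"))

de <- differential_expression(expr, samples, c("CWM", "CNM"))
message(sprintf("DEGs CWM vs CNM: %d up, %d down (FDR < 0.05, |FC| >= 2)",
                sum(de$is_deg & de$log2_fc > 0),
                sum(de$is_deg & de$log2_fc < 0)))

top_mod <- mt$module[which.max(abs(mt$r))]
scores <- eig[top_mod, survival_df$sample]
labels <- mean_split(scores)
km <- kaplan_meier_logrank(survival_df, labels)
message(sprintf(
  "log-rank for %s High vs Low (n = %d/%d): chi2 = %.2f, p = %.3g",
  top_mod, km$n[["High"]], km$n[["Low"]], km$chi2, km$p))
med <- vapply(c("High", "Low"), function(g) {
  cur <- km$curves[km$curves$group == g, ]
  cur$time[match(TRUE, cur$survival <= 0.5)]
}, numeric(1))
message(sprintf("median survival: High %.1f vs Low %.1f months",
                med[["High"]], med[["Low"]]))

tumors <- samples$sample[samples$group %in% c("CNM", "CWM", "CLM")]
msi <- stats::setNames(ifelse(samples$msi[match(tumors, samples$sample)] == 1,
                              "MSI", "MSS"), tumors)
rc <- responder_comparison(eig[top_mod, tumors], msi)
message(sprintf("%s score MSI vs MSS: t = %.2f, p = %.3g",
                top_mod, rc$statistic, rc$p))

dir.create(file.path("results", "outcome"), showWarnings = FALSE)
utils::write.table(de, file.path("results", "outcome", "de_cwm_vs_cnm.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(km$curves, file.path("results", "outcome",
                                        "km_curves.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(top_module = top_mod, logrank_chi2 = km$chi2, logrank_p = km$p,
       msi_t = rc$statistic, msi_p = rc$p,
       n_deg_up = sum(de$is_deg & de$log2_fc > 0),
       n_deg_down = sum(de$is_deg & de$log2_fc < 0)),
  file.path("results", "outcome", "summary.json"), auto_unbox = TRUE)
message("outcome outputs written to results/outcome")
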