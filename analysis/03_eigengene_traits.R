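#!/usr/bin/env Rscript
# Stage 3 — module eigengenes and their clinical-trait relationships.
#
# Summarizes every detected module by its eigengene (first principal
# component of the standardized member expression), correlates eigengenes
# with the binary metastasis trait, compares groups (Welch t for CWM vs
# CNM, paired t for CLM vs CWM), and clusters eigengenes together with the
# trait.

suppressPackageStartupMessages(library(tmenet))

expr <- read_matrix_tsv(file.path("results", "cohort", "expression.tsv"))
partition <- read_partition_tsv(file.path("results", "network",
                                          "modules.tsv"))
samples <- utils::read.delim(file.path("results", "cohort",
                                       "phenotype.tsv"))

eig <- module_eigengenes(expr[names(partition), ], partition)
mt <- module_trait_correlation(eig, data.frame(metastasis =
                                                 samples$metastasis))
mt <- mt[order(-abs(mt$r)), ]
message("module-metastasis correlations (top 3):")
for (i in 1:min(3, nrow(mt)))
  message(sprintf("  %s: r = %+.3f, p = %.2e, FDR = %.2e",
                  mt$module[i], mt$r[i], mt$p[i], mt$fdr[i]))

welch <- module_group_tests(eig, samples, c("CWM", "CNM"))
paired <- module_group_tests(eig, samples, c("CLM", "CWM"), paired = TRUE)
message(sum(welch$fdr <= 0.05), " module(s) shifted in CWM vs CNM ",
        "(Welch, FDR <= 0.05); ",
        sum(paired$fdr <= 0.05), " in CLM vs CWM (paired t)")

hc <- cluster_eigengenes(eig, trait = samples$metastasis,
                         trait_name = "Metastasis")

dir.create(file.path("results", "traits"), showWarnings = FALSE)
write_matrix_tsv(round(eig, 6), file.path("results", "traits",
                                          "eigengenes.tsv"),
                 id_col = "module")
utils::write.table(mt, file.path("results", "traits", "module_trait.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cbind(comparison = "CWM_vs_CNM_welch", welch),
                   file.path("results", "traits", "group_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cbind(comparison = "CLM_vs_CWM_paired", paired),
                   file.path("results", "traits", "group_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   append = TRUE, col.names = FALSE)
write_newick(hc, file.path("results", "traits", "eigengene_dendrogram.nwk"))
message("trait outputs written to results/traits")
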