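#!/usr/bin/env Rscript
# Stage 4 — what the modules are made of.
#
# Annotates detected modules by (i) one-way ANOVA of module scores across
# purified cell-type reference profiles, (ii) size-corrected overlap with
# the signature collection against a 1,000-draw random-signature null,
# (iii) hypergeometric over-representation of the metastasis-module genes
# in the signatures, with a ranked minimum-hypergeometric check, and
# (iv) hub genes by intramodular connectivity plus the top hub's
# cross-module neighborhood.

suppressPackageStartupMessages(library(tmenet))

expr <- read_matrix_tsv(file.path("results", "cohort", "expression.tsv"))
partition <- read_partition_tsv(file.path("results", "network",
                                          "modules.tsv"))
refs_expr <- read_matrix_tsv(file.path("results", "cohort",
                                       "references.tsv"))
ct_map <- utils::read.delim(file.path("results", "cohort", "celltypes.tsv"))
refs <- list(expression = refs_expr,
             celltype = ct_map$celltype[match(colnames(refs_expr),
                                              ct_map$profile)])
signatures <- read_gmt(file.path("results", "cohort", "signatures.gmt"))
tom <- readRDS(file.path("results", "network", "tom.rds"))
mt <- utils::read.delim(file.path("results", "traits", "module_trait.tsv"))

ct <- celltype_enrichment_anova(refs, partition)
message("cell-type enrichment (FDR <= 0.05): ",
        paste(sprintf("%s->%s", ct$module, ct$top_celltype)[ct$fdr <= 0.05],
              collapse = ", "))

ov <- signature_overlap(partition, signatures,
                        universe = rownames(expr), n_null = 1000L,
                        seed = 11L)
strong <- ov[ov$overlap_pct > ov$null_mean_pct + 3 * ov$null_sd_pct &
               ov$p < 0.01, ]
message(nrow(strong), " module-signature pairs exceed the random null by ",
        "3 sd at p < 0.01")

top_mod <- mt$module[which.max(abs(mt$r))]
hits <- names(partition)[partition == top_mod]
ora <- ora_hypergeometric(hits, signatures, rownames(expr))
message("ORA of the top metastasis module (", top_mod, "): best set ",
        ora$set[which.min(ora$p)],
        sprintf(" (p = %.2e)", min(ora$p)))

# ranked check: genes ordered by |correlation with the module eigengene|
eig <- read_matrix_tsv(file.path("results", "traits", "eigengenes.tsv"))
ranked <- rownames(expr)[order(-abs(cor(t(expr), eig[top_mod, ])))]
best_set <- ora$set[which.min(ora$p)]
mhg <- ranked_min_hypergeometric(ranked, signatures[[best_set]],
                                 n_perm = 500L, seed = 12L)
message(sprintf("mHG of %s on the %s-ranked list: score %.2e, perm p %.3g",
                best_set, top_mod, mhg$mhg_score, mhg$p))

kim <- intramodular_connectivity(tom, partition)
hubs <- do.call(rbind, lapply(module_labels(partition), function(m)
  kim[kim$module == m & kim$rank <= 5, ]))
top_hub <- kim$gene[kim$module == top_mod & kim$rank == 1]
nb <- hub_neighborhood(top_hub, tom, partition, n_per_module = 10)

dir.create(file.path("results", "annotation"), showWarnings = FALSE)
utils::write.table(ct, file.path("results", "annotation", "celltype_anova.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ov, file.path("results", "annotation",
                                 "signature_overlap.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ora, file.path("results", "annotation", "ora.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(hubs, file.path("results", "annotation", "hub_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(nb, file.path("results", "annotation",
                                 "top_hub_neighborhood.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("annotation outputs written to results/annotation")
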