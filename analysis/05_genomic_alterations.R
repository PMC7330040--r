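#!/usr/bin/env Rscript
# Stage 5 — copy-number classification and the somatic variant cascade.
#
# Classifies every gene per tumor sample into the five absolute
# copy-number categories (with the most-deviant-from-2 rule and Deletion
# precedence), filters the variant table through the two-stage cascade
# with a per-rule audit, tests per-gene alteration frequencies between CNM
# and CWM (Fisher exact), measures primary/metastasis concordance per
# patient, and clusters binary mutation profiles.

suppressPackageStartupMessages(library(tmenet))

segments <- utils::read.delim(file.path("results", "cohort", "segments.tsv"))
gene_models <- utils::read.delim(file.path("results", "cohort",
                                           "gene_models.tsv"))
variants <- utils::read.delim(file.path("results", "cohort", "variants.tsv"))
samples <- utils::read.delim(file.path("results", "cohort", "phenotype.tsv"))

calls <- classify_gene_copy_number(segments, gene_models)
message("gene CN calls: ",
        paste(names(table(calls$category)), table(calls$category),
              sep = "=", collapse = ", "))

flt <- filter_somatic_snvs(variants)
message(sprintf("variant filter: %d of %d pass (%d not evaluable)",
                nrow(flt$passed), nrow(variants), nrow(flt$not_evaluable)))
message("first-failing-rule audit: ",
        paste(names(flt$audit), flt$audit, sep = "=", collapse = ", "))

freq <- alteration_frequencies(flt$passed, calls, samples,
                               c("CNM", "CWM"))
message("most group-skewed gene: ", freq$gene[1],
        sprintf(" (Fisher p = %.3g)", freq$p[1]))

conc <- pairwise_concordance(flt$passed, samples)
message(sprintf("mean primary/metastasis concordance (passed variants): %.1f%%",
                100 * mean(conc$concordance)))
conc_raw <- pairwise_concordance(variants, samples)
message(sprintf("mean concordance before filtering: %.1f%%",
                100 * mean(conc_raw$concordance)))

tumor <- samples$sample[samples$group %in% c("CWM", "CLM")]
hc <- cluster_mutation_profiles(flt$passed, samples,
                                include_samples = tumor)

dir.create(file.path("results", "alterations"), showWarnings = FALSE)
utils::write.table(calls, file.path("results", "alterations",
                                    "gene_cn_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(as.list(flt$audit),
                     file.path("results", "alterations", "filter_audit.json"),
                     auto_unbox = TRUE)
utils::write.table(freq, file.path("results", "alterations",
                                   "alteration_frequencies.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(conc, file.path("results", "alterations",
                                   "concordance.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_newick(hc, file.path("results", "alterations",
                           "mutation_profile_dendrogram.nwk"))
message("alteration outputs written to results/alterations")
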