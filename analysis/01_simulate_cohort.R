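#!/usr/bin/env Rscript
# Stage 1 — simulate the matched-trio cohort.
#
# Generates the standard synthetic cohort (2,000 genes, five planted
# co-expression modules of 300/250/200/150/100 genes, 1,000 background
# genes, 16 samples in each of AN/CNM/CWM/CLM) with a planted metastasis
# effect on module 1, cell-type reference profiles, signatures, copy-number
# segments, matched variant tables at 90 percent concordance, and survival
# tied to module-1 activity. Writes the full plain-text bundle that the
# later stages consume.

suppressPackageStartupMessages(library(tmenet))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

cfg <- cohort_config(seed = seed)
coh <- generate_cohort(cfg)
out <- file.path("results", "cohort")
write_cohort(coh, out)

message("cohort written to ", out)
message("genes: ", nrow(coh$expression), "  samples: ", ncol(coh$expression))
message("planted modules: ",
        paste(names(table(coh$truth_partition)[module_labels(coh$truth_partition)]),
              table(coh$truth_partition)[module_labels(coh$truth_partition)],
              sep = "=", collapse = ", "))
message("variant records: ", nrow(coh$variants),
        "  CN segments: ", nrow(coh$segments))
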