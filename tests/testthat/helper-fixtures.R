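# 12-case copy-number fixture: category boundaries (+-1e-9), the
# most-deviant-from-2 rule, Deletion precedence, and the equal-deviation
# tie rule. One sample, one gene per chromosome; segments tiled so each
# case is independent.
cn_fixture <- function() {
  eps <- 1e-9
  cases <- list(
    #          segments cn            expected category   expected cn
    list(cn = 0.5,                  cat = "deletion",      sel = 0.5),
    list(cn = 1.0 - eps,            cat = "deletion",      sel = 1.0 - eps),
    list(cn = 1.0,                  cat = "loss",          sel = 1.0),
    list(cn = 1.85 - eps,           cat = "loss",          sel = 1.85 - eps),
    list(cn = 1.85,                 cat = "diploid",       sel = 1.85),
    list(cn = 2.15,                 cat = "diploid",       sel = 2.15),
    list(cn = 2.15 + eps,           cat = "gain",          sel = 2.15 + eps),
    list(cn = 4.0,                  cat = "gain",          sel = 4.0),
    list(cn = 4.0 + eps,            cat = "amplification", sel = 4.0 + eps),
    # multi-segment rules:
    list(cn = c(2.0, 3.1),          cat = "gain",          sel = 3.1),
    list(cn = c(0.8, 5.0),          cat = "deletion",      sel = 0.8),
    list(cn = c(1.5, 2.5),          cat = "loss",          sel = 1.5))
  genes <- data.frame(gene = sprintf("gene%02d", seq_along(cases)),
                      chrom = sprintf("chr%02d", seq_along(cases)),
                      start = 1000, end = 1999)
  seg <- do.call(rbind, lapply(seq_along(cases), function(i) {
    cn <- cases[[i]]$cn
    n <- length(cn)
    # split the gene span into n consecutive segments
    bounds <- round(seq(500, 2500, length.out = n + 1))
    data.frame(sample = "S1", chrom = sprintf("chr%02d", i),
               start = bounds[-(n + 1)] + c(0, rep(1, n - 1)),
               end = bounds[-1], cn = cn)
  }))
  list(segments = seg, genes = genes,
       expected_cat = vapply(cases, `[[`, character(1), "cat"),
       expected_sel = vapply(cases, `[[`, numeric(1), "sel"))
}

# 30-record filter fixture: records 1-3 pass (boundary-inclusive values),
# records 4-13 each violate exactly one rule in cascade order, records
# 14-15 violate two rules (attributed to the first), record 16 has a
# missing screen p (not evaluable), records 17-30 pass comfortably.
filter_fixture <- function() {
  passing <- data.frame(
    sample = "T1", patient = "P1", gene = "G", chrom = "chr1", pos = 1,
    ref = "A", alt = "T", mutation_type = "missense",
    t_alt_reads = 20L, n_supporting = 20L, vaf_tumor = 0.3,
    vaf_normal = 0.01, p_somatic = 0.001, p_fisher = 0.001,
    dist_read_end = 30L, p_base_quality = 0.5, p_mapping_quality = 0.5,
    p_strand_bias = 0.5)
  v <- passing[rep(1, 30), ]
  v$pos <- 1:30
  rownames(v) <- NULL
  # boundary-inclusive passes
  v$t_alt_reads[1] <- 8L; v$n_supporting[1] <- 6L
  v$vaf_tumor[2] <- 0.1; v$vaf_normal[2] <- 0.1
  v$p_somatic[3] <- 0.05; v$p_fisher[3] <- 0.05; v$dist_read_end[3] <- 5L
  # one violation per rule, cascade order
  v$t_alt_reads[4] <- 7L
  v$n_supporting[5] <- 5L
  v$vaf_tumor[6] <- 0.08
  v$vaf_normal[7] <- 0.12
  v$p_somatic[8] <- 0.06
  v$p_fisher[9] <- 0.051
  v$dist_read_end[10] <- 3L
  v$p_base_quality[11] <- 0.04
  v$p_mapping_quality[12] <- 0.01
  v$p_strand_bias[13] <- 0.05   # boundary: screens need p > alpha
  # double violations attributed to the first failing rule
  v$t_alt_reads[14] <- 0L; v$p_fisher[14] <- 0.9
  v$vaf_tumor[15] <- 0.0; v$dist_read_end[15] <- 1L
  # not evaluable
  v$p_strand_bias[16] <- NA
  v
}
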