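#' Gene-level absolute copy-number classification
#'
#' Assigns each (sample, gene) pair a copy-number category from the
#' overlapping segments (any-base overlap; 1-based closed coordinates on
#' both sides). Categories: deletion (CN < 1.0), loss (1.0 <= CN < 1.85),
#' diploid (1.85 <= CN <= 2.15), gain (2.15 < CN <= 4.0), amplification
#' (CN > 4.0). When a gene overlaps several segments, the copy number most
#' deviating from 2 is selected — except that any overlapping segment with
#' CN < 1.0 forces the deletion category regardless of the others. A tie at
#' equal |CN - 2| on both sides of 2 resolves to the lower copy number
#' (conservative toward loss). Genes with no overlapping segment emit no
#' call; they are returned in the `"uncovered"` attribute.
#'
#' @param segments data frame with `sample`, `chrom`, `start`, `end`, `cn`
#'   (absolute copy number >= 0). Segments of one sample must not overlap.
#' @param genes data frame with `gene`, `chrom`, `start`, `end`.
#' @return data frame with `sample`, `gene`, `selected_cn`, `category`;
#'   attribute `"uncovered"` lists (sample, gene) pairs without coverage.
#' @export
classify_gene_copy_number <- function(segments, genes) {
  stopifnot(all(c("sample", "chrom", "start", "end", "cn") %in%
                  names(segments)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (any(segments$start > segments$end) || any(genes$start > genes$end))
    stop("start must be <= end (1-based closed intervals)")
  if (any(segments$cn < 0)) stop("copy number must be >= 0")
  rows <- list(); uncovered <- list()
  for (s in unique(segments$sample)) {
    seg <- segments[segments$sample == s, ]
    for (ch in unique(genes$chrom)) {
      segc <- seg[seg$chrom == ch, ]
      gc <- genes[genes$chrom == ch, ]
      if (nrow(gc) == 0L) next
      if (nrow(segc) > 1L) {
        o <- order(segc$start)
        if (any(segc$start[o][-1] <= segc$end[o][-nrow(segc)]))
          stop("data error: overlapping segments for sample ", s,
               " on ", ch)
      }
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(gc$start, gc$end),
        IRanges::IRanges(segc$start, segc$end))
      byg <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
      covered <- as.integer(names(byg))
      for (j in seq_along(byg)) {
        cn <- segc$cn[byg[[j]]]
        if (any(cn < 1.0)) {
          sel <- min(cn)          # report the deleted segment's CN
          cat <- "deletion"
        } else {
          dev <- abs(cn - 2)
          cand <- cn[dev == max(dev)]
          sel <- min(cand)        # tie at equal deviation -> loss side
          cat <- cn_category(sel)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = gc$gene[covered[j]], selected_cn = sel,
          category = cat, stringsAsFactors = FALSE)
      }
      miss <- setdiff(seq_len(nrow(gc)), covered)
      if (length(miss))
        uncovered[[length(uncovered) + 1L]] <- data.frame(
          sample = s, gene = gc$gene[miss], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "uncovered") <- if (length(uncovered))
    do.call(rbind, uncovered) else
    data.frame(sample = character(), gene = character())
  res
}

#' Absolute copy number to category
#' @param cn absolute copy number (vectorized).
#' @return character vector of categories.
#' @export
cn_category <- function(cn) {
  ifelse(cn < 1.0, "deletion",
    ifelse(cn < 1.85, "loss",
      ifelse(cn <= 2.15, "diploid",
        ifelse(cn <= 4.0, "gain", "amplification"))))
}

#' Somatic SNV filter thresholds
#'
#' Defaults follow the two-stage somatic filter: preliminary rules
#' (supporting reads in tumor >= 8, supporting reads in normal >= 6 — the
#' normal-side read requirement is deliberately a named, generic
#' `n_supporting` field since callers differ on whether it counts
#' reference-supporting or total coverage —, tumor VAF >= 0.1, normal VAF
#' <= 0.1, caller p <= 0.05) followed by the stringent stage (Fisher exact
#' p <= 0.05, SNV base at least 5 bp from either read end, and three
#' artifact screens for base quality, mapping quality and strand bias,
#' which pass when their p-value exceeds `screen_alpha`, i.e. no
#' significant artifact signal).
#'
#' @param min_t_alt_reads,min_n_supporting,min_vaf_tumor,max_vaf_normal,max_p_somatic
#'   preliminary-stage thresholds.
#' @param max_p_fisher,min_dist_read_end,screen_alpha stringent-stage
#'   thresholds.
#' @return named list of thresholds.
#' @export
snv_filter_config <- function(min_t_alt_reads = 8, min_n_supporting = 6,
                              min_vaf_tumor = 0.1, max_vaf_normal = 0.1,
                              max_p_somatic = 0.05, max_p_fisher = 0.05,
                              min_dist_read_end = 5, screen_alpha = 0.05) {
  as.list(environment())
}

snv_rule_order <- c("t_alt_reads", "n_supporting", "vaf_tumor", "vaf_normal",
                    "p_somatic", "p_fisher", "dist_read_end",
                    "base_quality", "mapping_quality", "strand_bias")

#' Somatic SNV filter cascade
#'
#' Applies the rules of [snv_filter_config()] in cascade order; a variant
#' passes only if every rule holds (all bounds are inclusive). The audit
#' attributes each rejected variant to the first rule it fails. Records
#' with missing (NA) stringent-stage statistics are flagged not-evaluable
#' rather than passed or rejected.
#'
#' @param variants variant data frame (see [generate_segments_and_variants()]
#'   for the field layout).
#' @param thresholds a [snv_filter_config()] list.
#' @return list with `passed` (data frame), `not_evaluable` (data frame)
#'   and `audit` (named integer vector of first-failing-rule counts, in
#'   cascade order).
#' @export
filter_somatic_snvs <- function(variants, thresholds = snv_filter_config()) {
  need <- c("t_alt_reads", "n_supporting", "vaf_tumor", "vaf_normal",
            "p_somatic", "p_fisher", "dist_read_end", "p_base_quality",
            "p_mapping_quality", "p_strand_bias")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols))
    stop("malformed variant table, missing fields: ",
         paste(missing_cols, collapse = ", "))
  bad_vaf <- with(variants, vaf_tumor < 0 | vaf_tumor > 1 |
                    vaf_normal < 0 | vaf_normal > 1)
  if (any(bad_vaf, na.rm = TRUE)) stop("malformed record: VAF outside [0,1]")
  th <- thresholds
  checks <- list(
    t_alt_reads = variants$t_alt_reads >= th$min_t_alt_reads,
    n_supporting = variants$n_supporting >= th$min_n_supporting,
    vaf_tumor = variants$vaf_tumor >= th$min_vaf_tumor,
    vaf_normal = variants$vaf_normal <= th$max_vaf_normal,
    p_somatic = variants$p_somatic <= th$max_p_somatic,
    p_fisher = variants$p_fisher <= th$max_p_fisher,
    dist_read_end = variants$dist_read_end >= th$min_dist_read_end,
    base_quality = variants$p_base_quality > th$screen_alpha,
    mapping_quality = variants$p_mapping_quality > th$screen_alpha,
    strand_bias = variants$p_strand_bias > th$screen_alpha)
  cmat <- do.call(cbind, checks[snv_rule_order])
  not_eval <- apply(cmat, 1, anyNA)
  first_fail <- apply(cmat, 1, function(r)
    if (anyNA(r)) NA_integer_ else which(!r)[1])
  passed <- vapply(seq_len(nrow(cmat)), function(i)
    !anyNA(cmat[i, ]) && all(cmat[i, ]), logical(1))
  audit <- vapply(seq_along(snv_rule_order), function(j)
    sum(first_fail == j, na.rm = TRUE), integer(1))
  names(audit) <- snv_rule_order
  list(passed = variants[passed, , drop = FALSE],
       not_evaluable = variants[not_eval, , drop = FALSE],
       audit = audit)
}

#' Mutation-severity ordinal rank
#'
#' Ordinal severity of coding consequences: missense (1) < inframe indel
#' (2) < splice-site (3) < frameshift indel = nonsense (4). Types outside
#' the ordering (e.g. synonymous, other) get rank 0; unknown types get
#' rank 0 with a warning.
#'
#' @param mutation_type character vector of consequence labels.
#' @return integer ranks.
#' @export
severity_rank <- function(mutation_type) {
  ranks <- c(missense = 1L, inframe_indel = 2L, splice = 3L,
             frameshift_indel = 4L, nonsense = 4L,
             synonymous = 0L, other = 0L)
  unknown <- setdiff(unique(mutation_type), names(ranks))
  if (length(unknown))
    warning("unknown mutation types ranked 0: ",
            paste(unknown, collapse = ", "))
  out <- unname(ranks[mutation_type])
  out[is.na(out)] <- 0L
  out
}

#' Per-gene, per-sample maximum severity
#'
#' @param variants passed variant data frame.
#' @return data frame with `sample`, `gene`, `max_severity`.
#' @export
gene_sample_severity <- function(variants) {
  sev <- severity_rank(variants$mutation_type)
  agg <- stats::aggregate(sev,
                          by = list(sample = variants$sample,
                                    gene = variants$gene), FUN = max)
  names(agg)[3] <- "max_severity"
  agg
}

#' Per-gene alteration frequencies and group Fisher tests
#'
#' A sample counts as altered in a gene if it carries a passing
#' non-synonymous mutation there (severity rank >= 1) or, when
#' `include_cn` is `TRUE`, an amplification or deletion call. Frequencies
#' are compared between two groups with a two-sided Fisher exact test and
#' BH FDR across genes.
#'
#' @param variants passed variant data frame.
#' @param cn_calls gene copy-number calls (or `NULL`).
#' @param samples sample annotation with `sample` and `group`.
#' @param groups length-2 character vector of group labels.
#' @param include_cn include amplification/deletion calls as alterations.
#' @return data frame with `gene`, per-group altered counts and
#'   frequencies, `p`, `fdr`.
#' @export
alteration_frequencies <- function(variants, cn_calls = NULL, samples,
                                   groups, include_cn = TRUE) {
  stopifnot(length(groups) == 2L)
  sa <- samples[samples$group %in% groups, c("sample", "group")]
  if (!all(groups %in% sa$group)) stop("both groups must be nonempty")
  mut <- variants[severity_rank(variants$mutation_type) >= 1L &
                    variants$sample %in% sa$sample,
                  c("sample", "gene")]
  alt <- mut
  if (include_cn && !is.null(cn_calls)) {
    cna <- cn_calls[cn_calls$category %in% c("amplification", "deletion") &
                      cn_calls$sample %in% sa$sample, c("sample", "gene")]
    alt <- rbind(alt, cna)
  }
  alt <- unique(alt)
  if (nrow(alt) == 0L) stop("no altered gene in the selected samples")
  n1 <- sum(sa$group == groups[1]); n2 <- sum(sa$group == groups[2])
  res <- do.call(rbind, lapply(unique(alt$gene), function(g) {
    carriers <- alt$sample[alt$gene == g]
    a1 <- sum(sa$group[match(carriers, sa$sample)] == groups[1])
    a2 <- length(carriers) - a1
    p <- stats::fisher.test(matrix(c(a1, n1 - a1, a2, n2 - a2), 2))$p.value
    data.frame(gene = g, altered_1 = a1, n_1 = n1, freq_1 = a1 / n1,
               altered_2 = a2, n_2 = n2, freq_2 = a2 / n2, p = p,
               stringsAsFactors = FALSE)
  }))
  names(res) <- sub("_1$", paste0("_", groups[1]), names(res))
  names(res) <- sub("_2$", paste0("_", groups[2]), names(res))
  res$fdr <- stats::p.adjust(res$p, "BH")
  res[order(res$p), ]
}

#' Primary / metastasis variant concordance per patient
#'
#' Variant identity is the site key (chrom, pos, ref, alt). For each
#' patient with one sample in each group, concordance =
#' shared / (shared + a_only + b_only). Patients missing a side are
#' excluded with a message.
#'
#' @param variants passed variant data frame.
#' @param samples sample annotation with `sample`, `patient`, `group`.
#' @param group_a,group_b the two group labels (e.g. `"CWM"`, `"CLM"`).
#' @return data frame with `patient`, `shared`, `a_only`, `b_only`,
#'   `concordance`.
#' @export
pairwise_concordance <- function(variants, samples, group_a = "CWM",
                                 group_b = "CLM") {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  sa <- samples[samples$group == group_a, ]
  sb <- samples[samples$group == group_b, ]
  patients <- intersect(sa$patient, sb$patient)
  dropped <- setdiff(union(sa$patient, sb$patient), patients)
  if (length(dropped))
    message("patients without both sides excluded: ",
            paste(sort(dropped), collapse = ", "))
  if (length(patients) == 0L) stop("no patient has samples in both groups")
  res <- do.call(rbind, lapply(sort(patients), function(p) {
    va <- variants[variants$sample %in% sa$sample[sa$patient == p], ]
    vb <- variants[variants$sample %in% sb$sample[sb$patient == p], ]
    ka <- unique(key(va)); kb <- unique(key(vb))
    sh <- length(intersect(ka, kb))
    ao <- length(setdiff(ka, kb)); bo <- length(setdiff(kb, ka))
    conc <- if (sh + ao + bo == 0L) NA_real_ else sh / (sh + ao + bo)
    data.frame(patient = p, shared = sh, a_only = ao, b_only = bo,
               concordance = conc, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Hierarchical clustering of binary mutation profiles
#'
#' Samples are encoded as binary vectors over all observed variant sites;
#' pairwise Jaccard distances feed average-linkage clustering. A sample
#' with zero variants is at distance 1 from every other sample (logged).
#'
#' @param variants passed variant data frame.
#' @param samples sample annotation; all listed tumor samples are included
#'   even if they carry no passing variant.
#' @param include_samples samples to cluster; defaults to those present in
#'   `variants`.
#' @return an `hclust` object.
#' @export
cluster_mutation_profiles <- function(variants, samples,
                                      include_samples =
                                        sort(unique(variants$sample))) {
  if (length(include_samples) < 2L) stop("need at least 2 samples")
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  sites <- sort(unique(key))
  m <- matrix(0L, nrow = length(include_samples), ncol = length(sites),
              dimnames = list(include_samples, sites))
  keep <- variants$sample %in% include_samples
  m[cbind(variants$sample[keep], key[keep])] <- 1L
  empty <- rownames(m)[rowSums(m) == 0L]
  if (length(empty))
    message("samples with zero passing variants (distance 1 to all): ",
            paste(empty, collapse = ", "))
  d <- as.matrix(stats::dist(m, method = "binary"))
  d[is.na(d)] <- 1  # two empty profiles share no site
  diag(d) <- 0
  stats::hclust(stats::as.dist(d), method = "average")
}
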