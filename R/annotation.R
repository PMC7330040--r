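#' Cell-type enrichment of modules in purified reference profiles
#'
#' For each module, a per-profile module score is computed as the mean of
#' the member genes' standardized expression across the reference profiles
#' (the mean is used instead of a re-fit first principal component because
#' reference panels typically contain few profiles, where PC-1 is
#' unstable). Scores are compared across cell types by one-way ANOVA; BH
#' FDR is applied across modules, and the cell type with maximal mean score
#' is reported.
#'
#' @param references list with `expression` (genes x profiles) and
#'   `celltype` (label per profile), as from
#'   [generate_reference_profiles()].
#' @param partition module partition.
#' @return data frame with `module`, `statistic` (ANOVA F), `p`, `fdr`,
#'   `score` (`-log10(p)`) and `top_celltype`.
#' @export
celltype_enrichment_anova <- function(references, partition) {
  prof <- references$expression
  ct <- factor(references$celltype)
  if (nlevels(ct) < 2L) stop("need at least 2 cell types")
  z <- standardize_rows(prof)
  labs <- module_labels(partition)
  rows <- list()
  for (m in labs) {
    mem <- intersect(names(partition)[partition == m], rownames(prof))
    if (length(mem) < 2L) {
      warning("module ", m, " has < 2 members in the references; skipped")
      next
    }
    score <- colMeans(z[mem, , drop = FALSE])
    fit <- stats::anova(stats::lm(score ~ ct))
    rows[[m]] <- data.frame(
      module = m, statistic = fit$`F value`[1], p = fit$`Pr(>F)`[1],
      top_celltype = levels(ct)[which.max(tapply(score, ct, mean))],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no module overlaps the reference genes")
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, "BH")
  res$score <- -log10(res$p)
  rownames(res) <- NULL
  res[, c("module", "statistic", "p", "fdr", "score", "top_celltype")]
}

#' Module / signature overlap with a random-signature null
#'
#' The overlap statistic is the size-corrected percentage
#' `100 * |signature intersect module| / |module|`. Its null distribution is
#' estimated from `n_null` random signatures of identical size drawn
#' uniformly from the gene universe (the hollow-bar control). The p-value
#' comes from a chi-square test (continuity correction off) on the 2x2
#' membership table of module x signature over the universe; Fisher's exact
#' test is available via `test = "fisher"`.
#'
#' @param partition module partition.
#' @param signatures named list of gene-id vectors.
#' @param universe gene universe; defaults to all partitioned genes
#'   (assigned or not).
#' @param n_null number of random signatures per (module, signature) size.
#' @param seed integer seed for the null draws.
#' @param test `"chisq"` (default) or `"fisher"`.
#' @return data frame with `module`, `signature`, `overlap_count`,
#'   `module_size`, `overlap_pct`, `null_mean_pct`, `null_sd_pct`, `p`.
#' @export
signature_overlap <- function(partition, signatures,
                              universe = names(partition), n_null = 1000L,
                              seed = 1L, test = c("chisq", "fisher")) {
  test <- match.arg(test)
  set.seed(seed)
  labs <- module_labels(partition)
  rows <- list()
  for (sig_name in names(signatures)) {
    sig <- intersect(signatures[[sig_name]], universe)
    if (length(signatures[[sig_name]]) > length(universe))
      stop("signature ", sig_name, " larger than the universe")
    # Null: the same-size random signature overlap, shared across modules
    # for this signature.
    nulls <- replicate(n_null, sample(universe, length(sig)),
                       simplify = FALSE)
    for (m in labs) {
      mem <- intersect(names(partition)[partition == m], universe)
      ov <- length(intersect(mem, sig))
      null_pct <- vapply(nulls, function(s)
        100 * length(intersect(mem, s)) / length(mem), numeric(1))
      tab <- matrix(c(ov, length(mem) - ov, length(sig) - ov,
                      length(universe) - length(mem) - length(sig) + ov),
                    nrow = 2)
      p <- if (test == "chisq")
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      else stats::fisher.test(tab)$p.value
      rows[[paste(m, sig_name)]] <- data.frame(
        module = m, signature = sig_name, overlap_count = ov,
        module_size = length(mem), overlap_pct = 100 * ov / length(mem),
        null_mean_pct = mean(null_pct), null_sd_pct = stats::sd(null_pct),
        p = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric probability of observing at least the
#' attained overlap between the hit list and each gene set, BH FDR across
#' sets, and the enrichment score `-log10(p)`.
#'
#' @param hits character vector of hit genes (subset of `universe`).
#' @param sets named list of gene sets.
#' @param universe gene universe.
#' @return data frame with `set`, `overlap`, `set_size`, `n_hits`, `p`,
#'   `fdr`, `score`.
#' @export
ora_hypergeometric <- function(hits, sets, universe) {
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  hits <- unique(hits)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(hits, s))
    p <- if (length(hits) == 0L) 1 else
      stats::phyper(ov - 1, length(s), length(universe) - length(s),
                    length(hits), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(s),
               n_hits = length(hits), p = p, stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, "BH")
  res$score <- -log10(res$p)
  res
}

#' Ranked minimum-hypergeometric enrichment
#'
#' For every prefix of the ranked universe, computes the upper-tail
#' hypergeometric probability of the number of gene-set members in that
#' prefix; the mHG score is the minimum over prefixes 1..N-1. Significance
#' is estimated by `n_perm` random permutations of the ranking with the
#' add-one correction, so the smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param ranked_universe character vector of genes, best rank first. Ties
#'   are implicit: the input order is taken as the ranking.
#' @param gene_set character vector (nonempty subset of the universe).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `mhg_score`, `p`, and `argmin_prefix` (the prefix
#'   length attaining the minimum).
#' @export
ranked_min_hypergeometric <- function(ranked_universe, gene_set,
                                      n_perm = 1000L, seed = 1L) {
  if (length(gene_set) == 0L) stop("gene_set is empty")
  if (!all(gene_set %in% ranked_universe))
    stop("gene_set must be a subset of the ranked universe")
  n <- length(ranked_universe)
  b_tot <- length(unique(gene_set))
  mhg <- function(is_hit) {
    b <- cumsum(is_hit)[-n]
    min(stats::phyper(b - 1, b_tot, n - b_tot, seq_len(n - 1L),
                      lower.tail = FALSE))
  }
  obs_hit <- ranked_universe %in% gene_set
  obs <- mhg(obs_hit)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) mhg(sample(obs_hit)),
                 numeric(1))
  b <- cumsum(obs_hit)[-n]
  hgt <- stats::phyper(b - 1, b_tot, n - b_tot, seq_len(n - 1L),
                       lower.tail = FALSE)
  list(mhg_score = obs, p = (1 + sum(perm <= obs)) / (n_perm + 1),
       argmin_prefix = which.min(hgt))
}

#' Intramodular connectivity and hub ranking
#'
#' `kIM(g)` is the sum of the topological overlaps of gene `g` with all
#' other genes of its module; rank 1 is the module's strongest hub. Ties
#' are broken deterministically by gene id. Unassigned genes get `NA`.
#'
#' @param tom TOM matrix.
#' @param partition module partition aligned with the TOM genes.
#' @return data frame with `gene`, `module`, `kIM`, `rank`.
#' @export
intramodular_connectivity <- function(tom, partition) {
  check_symmetric(tom, what = "TOM")
  genes <- rownames(tom)
  partition <- partition[genes]
  out <- data.frame(gene = genes, module = unname(partition),
                    kIM = NA_real_, rank = NA_integer_,
                    stringsAsFactors = FALSE)
  for (m in module_labels(partition)) {
    mem <- genes[partition == m]
    sub <- tom[mem, mem, drop = FALSE]
    kim <- rowSums(sub) - diag(sub)
    idx <- match(mem, out$gene)
    out$kIM[idx] <- kim
    ord <- order(-kim, mem)  # tie-break by gene id
    out$rank[idx[ord]] <- seq_along(ord)
  }
  out
}

#' Top-TOM neighborhood of a focal (hub) gene
#'
#' For each requested module, returns the `n_per_module` genes of that
#' module with the highest topological overlap to the focal gene (ties
#' broken lexicographically), as an edge list suitable for network viewers.
#'
#' @param gene focal gene id.
#' @param tom TOM matrix.
#' @param partition module partition.
#' @param n_per_module neighbors per module.
#' @param modules modules to search; defaults to all.
#' @return data frame with `source`, `target`, `module`, `weight`.
#' @export
hub_neighborhood <- function(gene, tom, partition, n_per_module = 10L,
                             modules = module_labels(partition)) {
  if (!gene %in% rownames(tom)) stop("unknown gene: ", gene)
  rows <- list()
  for (m in modules) {
    mem <- setdiff(names(partition)[partition == m], gene)
    mem <- intersect(mem, colnames(tom))
    if (length(mem) == 0L) next
    w <- tom[gene, mem]
    ord <- order(-w, mem)[seq_len(min(n_per_module, length(mem)))]
    rows[[m]] <- data.frame(source = gene, target = mem[ord], module = m,
                            weight = unname(w[ord]), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Global strongest-edge export
#'
#' All gene pairs whose TOM exceeds the given quantile of the off-diagonal
#' TOM distribution, capped at `max_edges` strongest edges — the whole-
#' network view consumed by graph-rendering tools.
#'
#' @param tom TOM matrix.
#' @param quantile_threshold off-diagonal TOM quantile (default 0.99).
#' @param max_edges cap on the number of edges returned.
#' @return data frame with `source`, `target`, `weight`, strongest first.
#' @export
export_network_edges <- function(tom, quantile_threshold = 0.99,
                                 max_edges = 10000L) {
  check_symmetric(tom, what = "TOM")
  ut <- upper.tri(tom)
  thr <- stats::quantile(tom[ut], quantile_threshold)
  idx <- which(ut & tom >= thr, arr.ind = TRUE)
  w <- tom[cbind(idx[, 1], idx[, 2])]
  ord <- order(-w)[seq_len(min(max_edges, length(w)))]
  data.frame(source = rownames(tom)[idx[ord, 1]],
             target = colnames(tom)[idx[ord, 2]],
             weight = w[ord], stringsAsFactors = FALSE)
}
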