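#' Module eigengene
#'
#' The eigengene summarizes a module as one score per sample: member genes
#' are standardized (mean 0, sd 1 per gene), the first principal component
#' over samples is extracted, standardized to mean 0 / sd 1, and
#' sign-oriented so its mean correlation with the member genes is
#' non-negative (the sign of a principal component is otherwise arbitrary).
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param members character vector of member gene ids.
#' @return numeric eigengene vector named by sample.
#' @export
module_eigengene <- function(expr, members) {
  check_matrix(expr, "expr")
  present <- intersect(members, rownames(expr))
  if (length(present) == 0L) stop("no member genes present in expr")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  x <- expr[present, , drop = FALSE]
  if (length(present) == 1L) {
    warning("single-member module: eigengene is the standardized gene")
    return(stats::setNames(standardize_vec(as.numeric(x)), colnames(expr)))
  }
  z <- standardize_rows(x)
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  e <- standardize_vec(e)
  if (mean(stats::cor(t(z), e)) < 0) e <- -e
  stats::setNames(e, colnames(expr))
}

#' Eigengene matrix for all modules of a partition
#'
#' @param expr log2 expression matrix.
#' @param partition named character vector gene -> module label;
#'   `"unassigned"` genes are skipped.
#' @return modules x samples matrix of eigengene scores.
#' @export
module_eigengenes <- function(expr, partition) {
  labs <- module_labels(partition)
  if (length(labs) == 0L) stop("partition contains no modules")
  out <- t(vapply(labs, function(l)
    module_eigengene(expr, names(partition)[partition == l]),
    numeric(ncol(expr))))
  rownames(out) <- labs
  out
}

#' Module eigengene vs clinical trait correlations
#'
#' Pearson correlation of each eigengene with each (binary or numeric)
#' trait, with two-sided asymptotic p-values from the t distribution on
#' n - 2 degrees of freedom and Benjamini-Hochberg FDR across modules,
#' separately per trait.
#'
#' @param eigengenes modules x samples matrix.
#' @param traits data frame of numeric traits (rows = samples in eigengene
#'   column order), or a single numeric vector.
#' @return data frame with `module`, `trait`, `r`, `p`, `fdr`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  if (is.atomic(traits)) traits <- data.frame(trait = traits)
  n <- ncol(eigengenes)
  if (nrow(traits) != n) stop("traits must have one row per sample")
  out <- list()
  for (tr in colnames(traits)) {
    tv <- traits[[tr]]
    if (stats::sd(tv) == 0)
      stop("undefined correlation: trait '", tr, "' is constant")
    r <- as.numeric(stats::cor(t(eigengenes), tv))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    out[[tr]] <- data.frame(module = rownames(eigengenes), trait = tr,
                            r = r, p = p, fdr = stats::p.adjust(p, "BH"),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-module group comparison of eigengene scores
#'
#' Welch two-sample t-test (unpaired) or paired t-test of eigengene values
#' between two sample groups, with BH FDR across modules. For the paired
#' test, samples are matched by `patient`; patients lacking a sample on
#' either side abort with a message listing the orphans.
#'
#' @param eigengenes modules x samples matrix.
#' @param samples sample annotation data frame with columns `sample`,
#'   `group` and (for paired tests) `patient`.
#' @param groups length-2 character vector, compared as `groups[1]` minus
#'   `groups[2]`.
#' @param paired logical.
#' @return data frame with `module`, `statistic`, `p`, `fdr`.
#' @export
module_group_tests <- function(eigengenes, samples, groups, paired = FALSE) {
  stopifnot(length(groups) == 2L)
  sa <- samples[samples$sample %in% colnames(eigengenes), ]
  a <- sa$sample[sa$group == groups[1]]
  b <- sa$sample[sa$group == groups[2]]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be present among the scored samples")
  if (paired) {
    pa <- sa$patient[match(a, sa$sample)]
    pb <- sa$patient[match(b, sa$sample)]
    orphans <- c(setdiff(pa, pb), setdiff(pb, pa))
    if (length(orphans))
      stop("unmatched patients for paired test: ",
           paste(sort(unique(orphans)), collapse = ", "))
    a <- a[order(pa)]
    b <- b[order(pb)]
  }
  res <- do.call(rbind, lapply(rownames(eigengenes), function(m) {
    tt <- stats::t.test(eigengenes[m, a], eigengenes[m, b], paired = paired)
    data.frame(module = m, statistic = unname(tt$statistic),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, "BH")
  res
}

#' Hierarchical clustering of eigengenes together with a trait
#'
#' Appends the (standardized) trait as a pseudo-eigengene and clusters all
#' rows by average linkage on the dissimilarity `1 - cor`. The returned
#' `hclust` object has a deterministic leaf order for fixed input.
#'
#' @param eigengenes modules x samples matrix (>= 2 modules).
#' @param trait optional numeric trait vector in sample column order; its
#'   leaf is labeled by `trait_name`.
#' @param trait_name label for the trait leaf.
#' @return an object of class `hclust`.
#' @export
cluster_eigengenes <- function(eigengenes, trait = NULL,
                               trait_name = "Metastasis") {
  if (nrow(eigengenes) < 2L) stop("need at least 2 modules")
  m <- eigengenes
  if (!is.null(trait)) {
    if (length(trait) != ncol(eigengenes))
      stop("trait must have one value per sample")
    m <- rbind(m, standardize_vec(trait))
    rownames(m)[nrow(m)] <- trait_name
  }
  stats::hclust(stats::as.dist(1 - stats::cor(t(m))), method = "average")
}

#' Score discovery modules in an external expression matrix
#'
#' Recomputes each module's eigengene from the member genes present in the
#' external matrix. Modules with fewer than two surviving members are
#' skipped with a warning; per-module member coverage is reported so
#' transferability can be judged.
#'
#' @param expr_ext external log2 expression matrix.
#' @param partition discovery module partition.
#' @return list with `eigengenes` (modules x external samples) and
#'   `coverage` (data frame of member counts and coverage fraction).
#' @export
score_modules_external <- function(expr_ext, partition) {
  check_matrix(expr_ext, "expr_ext")
  labs <- module_labels(partition)
  cov <- data.frame(module = labs,
                    n_members = NA_integer_, n_present = NA_integer_,
                    coverage = NA_real_, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_along(labs)) {
    mem <- names(partition)[partition == labs[i]]
    present <- intersect(mem, rownames(expr_ext))
    cov$n_members[i] <- length(mem)
    cov$n_present[i] <- length(present)
    cov$coverage[i] <- length(present) / length(mem)
    if (length(present) < 2L) {
      warning("module ", labs[i],
              " has < 2 members in the external matrix; skipped")
      next
    }
    rows[[labs[i]]] <- module_eigengene(expr_ext, present)
  }
  if (length(rows) == 0L) stop("no module could be scored")
  list(eigengenes = do.call(rbind, rows), coverage = cov)
}
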