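#' Network construction parameters
#'
#' @param beta positive integer soft-threshold power applied to the absolute
#'   Pearson correlation (default 6, the conventional choice meeting the
#'   approximate scale-free topology criterion).
#' @param merge_threshold eigengene dissimilarity `1 - cor(ME_a, ME_b)`
#'   below which two modules are merged (default 0.10).
#' @param cut_height static tree-cut height on the 1 - TOM average-linkage
#'   dendrogram, in (0, 1).
#' @param min_module_size smallest cluster kept as a module; smaller
#'   clusters are labeled `"unassigned"`.
#' @param signed if `FALSE` (default) the adjacency is unsigned,
#'   `|cor|^beta`; if `TRUE`, `((1 + cor) / 2)^beta`.
#' @return list of class `"network_params"`.
#' @export
network_params <- function(beta = 6L, merge_threshold = 0.10,
                           cut_height = 0.99, min_module_size = 30L,
                           signed = FALSE) {
  if (beta < 1) stop("beta must be >= 1")
  if (merge_threshold <= 0 || merge_threshold >= 1)
    stop("merge_threshold must be in (0, 1)")
  if (cut_height <= 0 || cut_height >= 1)
    stop("cut_height must be in (0, 1)")
  if (min_module_size < 3L) stop("min_module_size must be >= 3")
  structure(list(beta = as.integer(beta), merge_threshold = merge_threshold,
                 cut_height = cut_height,
                 min_module_size = as.integer(min_module_size),
                 signed = signed),
            class = "network_params")
}

#' Count filtering and quantile normalization
#'
#' Removes genes with fewer than `count_min` counts in at least
#' `sample_frac` of samples, log2-transforms (`log2(x + 1)`) and quantile
#' normalizes the remaining matrix to the mean empirical distribution.
#' A second mask retains genes whose normalized signal exceeds `signal_min`
#' units in at least `sample_frac` of samples; those gene ids are attached
#' as the `"network_genes"` attribute and are the intended substrate for
#' network construction.
#'
#' @param counts non-negative integer genes x samples matrix.
#' @param count_min,sample_frac,signal_min filter thresholds (defaults 5,
#'   0.8 and 5 log2 units).
#' @return normalized log2 expression matrix with attribute
#'   `"network_genes"`.
#' @export
filter_and_normalize <- function(counts, count_min = 5, sample_frac = 0.8,
                                 signal_min = 5) {
  check_matrix(counts, "counts")
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  low <- rowMeans(counts < count_min) >= sample_frac
  kept <- counts[!low, , drop = FALSE]
  if (nrow(kept) == 0L) stop("data error: no genes left after count filter")
  # sort-based assignment (ties broken by order) so every sample ends up
  # with exactly the mean empirical distribution
  expr <- limma::normalizeQuantiles(log2(kept + 1), ties = FALSE)
  expr <- as.matrix(expr)
  dimnames(expr) <- dimnames(kept)
  network <- rowMeans(expr > signal_min) >= sample_frac
  attr(expr, "network_genes") <- rownames(expr)[network]
  expr
}

#' Convenience accessor for the network-gene mask
#' @param expr output of [filter_and_normalize()].
#' @return character vector of gene ids retained for network construction.
#' @export
network_genes <- function(expr) attr(expr, "network_genes")

#' Soft-thresholded weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` (unsigned, the default) for all gene pairs,
#' with a zero diagonal by convention so connectivity is a plain row sum.
#' Genes with zero variance cannot be correlated and are dropped with a
#' warning naming them.
#'
#' @param expr log2 expression matrix (genes x samples, >= 3 samples).
#' @param params a [network_params()] object.
#' @return symmetric adjacency matrix over the retained genes, entries in
#'   \[0, 1\], zero diagonal.
#' @export
adjacency <- function(expr, params = network_params()) {
  check_matrix(expr, "expr")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance genes: ",
            paste(rownames(expr)[v == 0], collapse = ", "))
    expr <- expr[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(expr))
  a <- if (params$signed) ((1 + r) / 2)^params$beta else abs(r)^params$beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit of the connectivity distribution
#'
#' Bins whole-network connectivity `k_i = sum_j a_ij` into `n_bins`
#' equal-width bins and regresses `log10(frequency)` on `log10(mean k)`
#' over the occupied bins. A high R-squared with a negative slope indicates
#' approximate scale-free topology. Linear-width binning is deliberate:
#' under a power transform of the degrees, log-width bins would leave the
#' histogram shape unchanged, whereas soft thresholding is supposed to be
#' *visible* here as an improved fit over beta = 1.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @param n_bins number of connectivity bins.
#' @return list with `r_squared`, `slope`, `signed_r_squared`
#'   (`-sign(slope) * r_squared`, the index soft-threshold selection
#'   maximizes: a good fit with a positive slope is not scale-free), and
#'   the bin table.
#' @export
scale_free_fit <- function(adj, n_bins = 10L) {
  check_symmetric(adj, what = "adjacency")
  k <- rowSums(adj)
  k <- k[k > 0]
  if (length(unique(k)) < 2L)
    stop("undefined fit: all connectivities equal")
  if (length(unique(k)) < n_bins)
    stop("need at least n_bins distinct connectivity values")
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  br[1] <- br[1] - 1e-9; br[n_bins + 1L] <- br[n_bins + 1L] + 1e-9
  bin <- cut(k, br, labels = FALSE)
  tab <- data.frame(mean_k = as.numeric(tapply(k, bin, mean)),
                    freq = as.numeric(tapply(k, bin, length)) / length(k))
  fit <- stats::lm(log10(freq) ~ log10(mean_k), data = tab)
  y <- log10(tab$freq)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  slope <- unname(stats::coef(fit)[2])
  list(r_squared = r2, slope = slope,
       signed_r_squared = -sign(slope) * r2, bins = tab)
}

#' Topological overlap matrix
#'
#' Unsigned topological overlap: with `l_ij = sum_u a_iu a_uj` (shared
#' neighborhood weight) and connectivity `k_i = sum_u a_iu`,
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j` and
#' `TOM_ii = 1`. The measure credits two genes both for their direct
#' adjacency and for the adjacencies they share with third genes.
#'
#' @param adj symmetric adjacency with zero diagonal.
#' @return symmetric TOM with unit diagonal, entries in \[0, 1\].
#' @export
topological_overlap <- function(adj) {
  check_symmetric(adj, what = "adjacency")
  l <- adj %*% adj  # diag(adj) = 0, so u = i, j terms vanish
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2  # shave float asymmetry from the matrix product
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect modules by static cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at `params$cut_height`; clusters smaller than
#' `params$min_module_size` are labeled `"unassigned"`. Labels are
#' deterministic: `GM1, GM2, ...` by decreasing size, ties broken by the
#' lexicographically smallest member gene.
#'
#' @param tom TOM from [topological_overlap()].
#' @param params a [network_params()] object.
#' @return named character vector gene -> module label.
#' @export
detect_modules <- function(tom, params = network_params()) {
  check_symmetric(tom, what = "TOM")
  if (nrow(tom) < params$min_module_size)
    stop("fewer genes than min_module_size")
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = params$cut_height)
  partition <- stats::setNames(rep("unassigned", nrow(tom)), rownames(tom))
  sizes <- table(cl)
  valid <- names(sizes)[sizes >= params$min_module_size]
  if (length(valid) == 0L) {
    warning("no cluster reaches min_module_size; all genes unassigned")
    return(partition)
  }
  keep <- cl %in% as.integer(valid)
  partition[keep] <- paste0("C", cl[keep])
  canonical_labels(partition)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the pair of modules whose eigengene dissimilarity
#' `1 - cor(ME_a, ME_b)` is smallest, while that dissimilarity is below
#' `params$merge_threshold` (default 0.10). Eigengenes are recomputed after
#' every merge; the loop terminates because the module count strictly
#' decreases. Final labels are re-canonicalized by size.
#'
#' @param partition module partition from [detect_modules()].
#' @param expr the expression matrix the partition was derived from.
#' @param params a [network_params()] object.
#' @return merged partition (named character vector).
#' @export
merge_close_modules <- function(partition, expr, params = network_params()) {
  check_matrix(expr, "expr")
  repeat {
    labs <- module_labels(partition)
    if (length(labs) < 2L) break
    eig <- module_eigengenes(expr, partition)
    d <- 1 - stats::cor(t(eig))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[ij[1], ij[2]] >= params$merge_threshold) break
    a <- rownames(d)[ij[1]]; b <- rownames(d)[ij[2]]
    partition[partition == b] <- a
  }
  canonical_labels(partition)
}
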