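# Internal helpers shared across pipeline stages.

# Row-standardize a genes x samples matrix (mean 0, sd 1 per gene).
# Zero-variance rows are returned as all-zero rather than NaN; callers that
# must exclude them do so explicitly.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  out <- sweep(x, 1, mu, "-")
  ok <- sdv > 0
  out[ok, ] <- sweep(out[ok, , drop = FALSE], 1, sdv[ok], "/")
  out[!ok, ] <- 0
  out
}

standardize_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop(what, " must have unique rownames")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop(what, " must have unique colnames")
  invisible(x)
}

check_symmetric <- function(x, tol = 1e-8, what = "matrix") {
  if (nrow(x) != ncol(x) || max(abs(x - t(x))) > tol)
    stop(what, " must be symmetric")
  invisible(x)
}

#' Module labels of a partition
#'
#' Labels present in a partition, excluding the reserved background label
#' `"unassigned"`, ordered `GM1, GM2, ...` by numeric suffix when present.
#'
#' @param partition named character vector gene -> module label.
#' @return character vector of module labels.
#' @export
module_labels <- function(partition) {
  labs <- setdiff(unique(partition), "unassigned")
  num <- suppressWarnings(as.integer(sub("^GM", "", labs)))
  if (!anyNA(num)) labs <- labs[order(num)] else labs <- sort(labs)
  labs
}

# Relabel a partition as GM1..GMk ordered by decreasing size, ties broken by
# the lexicographically smallest member gene. Background stays "unassigned".
canonical_labels <- function(partition) {
  labs <- setdiff(unique(partition), "unassigned")
  if (length(labs) == 0L) return(partition)
  size <- vapply(labs, function(l) sum(partition == l), integer(1))
  first <- vapply(labs, function(l) min(names(partition)[partition == l]),
                  character(1))
  ord <- labs[order(-size, first)]
  map <- stats::setNames(paste0("GM", seq_along(ord)), ord)
  out <- partition
  keep <- partition != "unassigned"
  out[keep] <- map[partition[keep]]
  out
}
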