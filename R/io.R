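# Readers and writers for the pipeline's plain-text exchange formats:
# genes-x-samples TSV matrices, GMT gene sets, SEG-like segment tables,
# MAF-like variant tables and Newick dendrograms.

#' Write a genes x samples matrix as TSV
#' @param x matrix with row and column names.
#' @param path output file.
#' @param id_col name of the first (row-id) column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples TSV matrix
#' @param path input file; first column holds row ids.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write gene sets in GMT format
#' @param sets named list of gene-id vectors.
#' @param path output file.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file (name, description, then member genes per line).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' Write a module partition as a two-column TSV
#' @param partition named character vector gene -> module.
#' @param path output file.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(data.frame(gene = names(partition),
                                module = unname(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module partition from TSV
#' @param path two-column TSV (gene, module).
#' @return named character vector.
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$module, df$gene)
}

#' Write an hclust dendrogram as Newick text
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write every table of a synthetic cohort to a directory
#'
#' Emits `expression.tsv`, `counts.tsv`, `phenotype.tsv`,
#' `truth_partition.tsv`, `signatures.gmt`, `references.tsv` +
#' `celltypes.tsv`, `segments.tsv` (SEG-like), `variants.tsv` (MAF-like),
#' `gene_models.tsv` and `survival.tsv`. All output is plain text and a
#' deterministic function of the cohort.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(round(cohort$expression, 6), p("expression.tsv"))
  write_matrix_tsv(cohort$counts, p("counts.tsv"))
  utils::write.table(cohort$samples, p("phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_partition_tsv(cohort$truth_partition, p("truth_partition.tsv"))
  write_gmt(cohort$signatures, p("signatures.gmt"))
  write_matrix_tsv(round(cohort$references$expression, 6),
                   p("references.tsv"))
  utils::write.table(data.frame(profile = colnames(cohort$references$expression),
                                celltype = cohort$references$celltype),
                     p("celltypes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seg <- cohort$segments
  seg$cn <- round(seg$cn, 6)
  utils::write.table(seg, p("segments.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  var <- cohort$variants
  num <- vapply(var, is.double, logical(1))
  var[num] <- lapply(var[num], round, 6)
  utils::write.table(var, p("variants.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$gene_models, p("gene_models.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  surv <- cohort$survival
  surv$time <- round(surv$time, 6)
  utils::write.table(surv, p("survival.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
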