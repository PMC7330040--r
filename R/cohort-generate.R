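#' Generate a synthetic matched-trio multi-omics cohort
#'
#' Draws a complete cohort with known ground truth: a log2 expression matrix
#' with planted co-expression modules (member genes load on a per-module
#' latent factor; group-specific factor shifts encode the metastasis
#' association), a Poisson count matrix at realistic library sizes,
#' purified cell-type reference profiles, gene signatures overlapping the
#' planted modules, absolute copy-number segments over a toy genome,
#' matched primary/metastasis somatic variant tables with controlled
#' concordance, and survival times whose hazard depends on module activity.
#'
#' The cohort is a deterministic function of the configuration (including
#' its seed): the same `config` always yields a bit-identical cohort.
#'
#' @param config a [cohort_config()] object.
#' @return A list of class `"synthetic_cohort"` with elements `counts`,
#'   `expression` (genes x samples, log2 scale), `truth_partition` (named
#'   character vector, background genes labeled `"unassigned"`), `samples`
#'   (sample annotation data frame), `references`, `signatures` (named list
#'   of gene-id vectors), `segments`, `gene_models`, `variants`, `survival`
#'   and the `config` itself.
#' @examples
#' cfg <- cohort_config(n_genes = 60, module_sizes = c(20L, 15L),
#'                      n_background_genes = 25L,
#'                      samples_per_group = c(AN = 4L, CNM = 4L,
#'                                            CWM = 4L, CLM = 4L),
#'                      seed = 7L)
#' coh <- generate_cohort(cfg)
#' table(coh$truth_partition)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  genes <- cohort_gene_ids(config)
  truth <- cohort_truth_partition(config)
  samples <- cohort_sample_sheet(config)
  n_s <- nrow(samples)
  k <- length(config$module_sizes)

  set.seed(config$seed)
  # Latent module factors: standard normal per sample plus planted
  # group-wise mean shifts.
  factors <- matrix(stats::rnorm(k * n_s), nrow = k,
                    dimnames = list(paste0("GM", seq_len(k)), samples$sample))
  for (m in names(config$trait_effects)) {
    eff <- config$trait_effects[[m]]
    for (g in names(eff)) {
      idx <- samples$group == g
      factors[as.integer(m), idx] <- factors[as.integer(m), idx] + eff[[g]]
    }
  }

  baseline <- stats::runif(config$n_genes, config$baseline_range[1],
                           config$baseline_range[2])
  expr <- matrix(stats::rnorm(config$n_genes * n_s, sd = config$noise_sd),
                 nrow = config$n_genes,
                 dimnames = list(genes, samples$sample))
  loadings <- stats::setNames(rep(NA_real_, config$n_genes), genes)
  for (m in seq_len(k)) {
    mem <- names(truth)[truth == paste0("GM", m)]
    lam <- stats::runif(length(mem), config$loading_range[1],
                        config$loading_range[2])
    loadings[mem] <- lam
    expr[mem, ] <- expr[mem, ] + lam %o% factors[m, ]
  }
  expr <- expr + baseline

  # Counts: exponentiate, rescale each sample to a lognormal-perturbed
  # target depth, add Poisson sampling noise.
  lam <- 2^expr
  depth <- config$library_size * exp(stats::rnorm(n_s, sd = 0.2))
  lam <- sweep(lam, 2, depth / colSums(lam), "*")
  counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                   dimnames = dimnames(lam))

  # MSI is a patient-level flag, so trio members agree.
  pat <- unique(samples$patient)
  msi_pat <- stats::setNames(stats::runif(length(pat)) < config$msi_rate, pat)
  samples$msi <- as.integer(msi_pat[samples$patient])

  # Signatures emulating curated TME gene lists: for each planted module,
  # half its members diluted with random universe genes; plus two pure-noise
  # signatures as negative controls.
  signatures <- list()
  for (m in seq_len(k)) {
    mem <- names(truth)[truth == paste0("GM", m)]
    sz <- length(mem)
    half <- sample(mem, ceiling(sz / 2))
    rest <- sample(setdiff(genes, half), sz - length(half))
    signatures[[paste0("SIG_GM", m)]] <- sort(c(half, rest))
  }
  for (j in 1:2)
    signatures[[paste0("SIG_RANDOM", j)]] <-
      sort(sample(genes, ceiling(stats::median(config$module_sizes))))

  references <- generate_reference_profiles(config, truth)
  sv <- generate_segments_and_variants(config)

  eig <- module_eigengenes(expr, truth)
  survival <- generate_survival(config, eig, samples)

  out <- list(counts = counts, expression = expr, truth_partition = truth,
              truth_loadings = loadings, truth_factors = factors,
              samples = samples, references = references,
              signatures = signatures, segments = sv$segments,
              gene_models = sv$gene_models, variants = sv$variants,
              survival = survival, config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' Generate purified cell-type reference profiles
#'
#' Emulates FACS-purified expression references: every cell type gets
#' replicate profiles of baseline noise; member genes of the modules mapped
#' to that cell type are elevated by `config$reference_shift` log2 units.
#'
#' @param config a [cohort_config()] object.
#' @param truth a module partition (named character vector) identifying the
#'   member genes of each planted module.
#' @return list with `expression` (genes x profiles matrix) and `celltype`
#'   (label per profile column).
#' @export
generate_reference_profiles <- function(config, truth) {
  validate_cohort_config(config)
  k <- length(config$module_sizes)
  idx <- unlist(config$celltype_module_map, use.names = FALSE)
  if (length(idx) && any(idx < 1L | idx > k))
    stop("config error: celltype_module_map references unknown module index")
  genes <- names(truth)
  set.seed(config$seed + 1L)
  baseline <- stats::runif(length(genes), config$baseline_range[1],
                           config$baseline_range[2])
  cols <- unlist(lapply(config$celltypes, function(ct)
    sprintf("%s_%d", ct, seq_len(config$profiles_per_celltype))))
  celltype <- rep(config$celltypes, each = config$profiles_per_celltype)
  prof <- matrix(stats::rnorm(length(genes) * length(cols),
                              sd = config$reference_noise_sd),
                 nrow = length(genes), dimnames = list(genes, cols))
  prof <- prof + baseline
  for (ct in names(config$celltype_module_map)) {
    mods <- config$celltype_module_map[[ct]]
    mem <- genes[truth %in% paste0("GM", mods)]
    prof[mem, celltype == ct] <- prof[mem, celltype == ct] +
      config$reference_shift
  }
  list(expression = prof, celltype = celltype)
}

#' Generate copy-number segments, gene models and somatic variant tables
#'
#' Segments tile each chromosome of a toy genome per tumor sample, with
#' absolute copy number drawn per the configured category probabilities;
#' gene models are laid out at fixed spacing so a fraction of genes span
#' segment boundaries. Matched primary/metastasis (CWM/CLM) variant sets
#' share a controlled fraction of their site union (the concordance);
#' filter fields are drawn so a configurable fraction of records violates
#' each filter rule. All coordinates are 1-based, fully closed.
#'
#' @param config a [cohort_config()] object.
#' @return list with `segments`, `gene_models` and `variants` data frames.
#' @export
generate_segments_and_variants <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed + 2L)
  genes <- cohort_gene_ids(config)
  samples <- cohort_sample_sheet(config)

  per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  chrom <- paste0("chr", rep(seq_len(config$n_chromosomes),
                             each = per_chrom)[seq_len(config$n_genes)])
  within <- (seq_len(config$n_genes) - 1L) %% per_chrom
  start <- within * config$gene_spacing + 1
  gene_models <- data.frame(gene = genes, chrom = chrom, start = start,
                            end = start + config$gene_length - 1,
                            stringsAsFactors = FALSE)
  chrom_len <- per_chrom * config$gene_spacing + config$gene_length

  tumor <- samples$sample[samples$group != "AN"]
  mean_len <- config$segment_params$mean_segment_length
  probs <- config$segment_params$category_probs
  cn_draw <- function(cat) switch(cat,
    deletion = stats::runif(1, 0.2, 0.95),
    loss = stats::runif(1, 1.0, 1.80),
    diploid = stats::runif(1, 1.87, 2.13),
    gain = stats::runif(1, 2.20, 4.0),
    amplification = stats::runif(1, 4.05, 8.0))
  seg_list <- list()
  for (s in tumor) {
    for (ch in unique(gene_models$chrom)) {
      pos <- 1
      while (pos <= chrom_len) {
        len <- max(round(stats::rexp(1, 1 / mean_len)), 5 * config$gene_length)
        end <- min(pos + len - 1, chrom_len)
        cat <- sample(names(probs), 1, prob = probs)
        seg_list[[length(seg_list) + 1L]] <-
          data.frame(sample = s, chrom = ch, start = pos, end = end,
                     cn = cn_draw(cat), stringsAsFactors = FALSE)
        pos <- end + 1
      }
    }
  }
  segments <- do.call(rbind, seg_list)

  variants <- generate_variant_tables(config, samples, gene_models)
  list(segments = segments, gene_models = gene_models, variants = variants)
}

# Filter fields for n variant records; each rule independently violated
# with probability fail_frac, otherwise drawn comfortably inside its bound.
draw_variant_fields <- function(n, fail_frac) {
  f <- matrix(stats::runif(10 * n) < fail_frac, ncol = 10)
  pick <- function(j, bad, good) ifelse(f[, j], bad, good)
  data.frame(
    t_alt_reads = as.integer(pick(1, sample(0:7, n, replace = TRUE),
                                  8L + stats::rpois(n, 30))),
    n_supporting = as.integer(pick(2, sample(0:5, n, replace = TRUE),
                                   6L + stats::rpois(n, 30))),
    vaf_tumor = pick(3, stats::runif(n, 0, 0.09),
                     stats::runif(n, 0.15, 0.60)),
    vaf_normal = pick(4, stats::runif(n, 0.12, 0.40),
                      stats::runif(n, 0, 0.05)),
    p_somatic = pick(5, stats::runif(n, 0.06, 1),
                     stats::runif(n, 0, 0.049)),
    p_fisher = pick(6, stats::runif(n, 0.06, 1),
                    stats::runif(n, 0, 0.049)),
    dist_read_end = as.integer(pick(7, sample(0:4, n, replace = TRUE),
                                    5L + stats::rpois(n, 40))),
    p_base_quality = pick(8, stats::runif(n, 0, 0.04),
                          stats::runif(n, 0.1, 1)),
    p_mapping_quality = pick(9, stats::runif(n, 0, 0.04),
                             stats::runif(n, 0.1, 1)),
    p_strand_bias = pick(10, stats::runif(n, 0, 0.04),
                         stats::runif(n, 0.1, 1)))
}

mutation_type_probs <- c(missense = 0.62, synonymous = 0.15, nonsense = 0.06,
                         frameshift_indel = 0.07, inframe_indel = 0.04,
                         splice = 0.03, other = 0.03)

generate_variant_tables <- function(config, samples, gene_models) {
  vp <- config$variant_params
  bases <- c("A", "C", "G", "T")
  draw_sites <- function(n) {
    gi <- sample(nrow(gene_models), n, replace = TRUE)
    pos <- round(stats::runif(n, gene_models$start[gi], gene_models$end[gi]))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    data.frame(gene = gene_models$gene[gi], chrom = gene_models$chrom[gi],
               pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  rec <- function(sample_id, patient_id, sites) {
    if (nrow(sites) == 0L) return(NULL)
    mt <- sample(names(mutation_type_probs), nrow(sites), replace = TRUE,
                 prob = mutation_type_probs)
    fields <- draw_variant_fields(nrow(sites), vp$fail_frac)
    cbind(data.frame(sample = sample_id, patient = patient_id,
                     stringsAsFactors = FALSE),
          sites, data.frame(mutation_type = mt, stringsAsFactors = FALSE),
          fields)
  }

  out <- list()
  # Matched CWM/CLM pairs: draw the patient's site union, share a rounded
  # concordance fraction, split the remainder evenly between the two sides.
  cwm <- samples[samples$group == "CWM", ]
  clm <- samples[samples$group == "CLM", ]
  paired <- intersect(cwm$patient, clm$patient)
  u_mean <- 2 * vp$mean_mutations / (1 + vp$concordance)
  for (p in paired) {
    u <- max(stats::rpois(1, u_mean), 2L)
    sites <- unique(draw_sites(u))
    u <- nrow(sites)
    n_sh <- round(vp$concordance * u)
    n_a <- floor((u - n_sh) / 2)
    shared <- sites[seq_len(n_sh), , drop = FALSE]
    a_only <- sites[n_sh + seq_len(n_a), , drop = FALSE]
    b_only <- sites[setdiff(seq_len(u), seq_len(n_sh + n_a)), , drop = FALSE]
    out[[length(out) + 1L]] <- rec(cwm$sample[cwm$patient == p][1], p,
                                   rbind(shared, a_only))
    out[[length(out) + 1L]] <- rec(clm$sample[clm$patient == p][1], p,
                                   rbind(shared, b_only))
  }
  # Unpaired tumor samples (CNM, plus any unmatched CWM/CLM) get private
  # site sets.
  solo <- samples[samples$group %in% c("CNM", "CWM", "CLM") &
                    !(samples$patient %in% paired &
                        samples$group %in% c("CWM", "CLM")), ]
  for (i in seq_len(nrow(solo))) {
    n <- max(stats::rpois(1, vp$mean_mutations), 1L)
    out[[length(out) + 1L]] <- rec(solo$sample[i], solo$patient[i],
                                   unique(draw_sites(n)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate survival records from module eigengenes
#'
#' Event times are exponential with per-sample log hazard
#' `log(baseline_hazard) + sum(coefficients * eigengene)`; censoring is
#' independent, with the exponential censoring rate set so the expected
#' censored fraction matches `censoring_rate` (1 censors every record).
#' Records are generated for primary tumor samples (groups `CNM`/`CWM`).
#'
#' @param config a [cohort_config()] object.
#' @param eigengenes modules x samples eigengene matrix (rows `GM1`, ...).
#' @param samples sample annotation; defaults to the config's sample sheet.
#' @return data frame with `sample`, `time` (months, > 0) and `event`
#'   (1 = event, 0 = censored).
#' @export
generate_survival <- function(config, eigengenes,
                              samples = cohort_sample_sheet(config)) {
  validate_cohort_config(config)
  sv <- config$survival_params
  set.seed(config$seed + 3L)
  use <- samples$sample[samples$group %in% c("CNM", "CWM")]
  use <- intersect(use, colnames(eigengenes))
  if (length(use) == 0L) stop("no primary tumor samples with eigengenes")
  lp <- rep(0, length(use))
  for (m in names(sv$coefficients)) {
    row <- paste0("GM", m)
    if (!row %in% rownames(eigengenes))
      stop("config error: survival coefficient names unknown module ", row)
    lp <- lp + sv$coefficients[[m]] * eigengenes[row, use]
  }
  hazard <- sv$baseline_hazard * exp(lp)
  t_event <- stats::rexp(length(use), rate = hazard)
  if (sv$censoring_rate >= 1) {
    time <- stats::runif(length(use), 0, t_event)
    event <- rep(0L, length(use))
  } else if (sv$censoring_rate <= 0) {
    time <- t_event
    event <- rep(1L, length(use))
  } else {
    r_c <- mean(hazard) * sv$censoring_rate / (1 - sv$censoring_rate)
    t_cens <- stats::rexp(length(use), rate = r_c)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  data.frame(sample = use, time = pmax(time, .Machine$double.eps),
             event = event, stringsAsFactors = FALSE, row.names = NULL)
}
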