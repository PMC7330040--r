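#' Configuration for the synthetic matched-trio cohort generator
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults describe a desk-scale colorectal-cancer trio design: four sample
#' groups (adjacent normal `AN`, primary tumors without metastasis `CNM`,
#' primary tumors with metastasis `CWM`, and matched liver metastases `CLM`),
#' 2,000 genes of which 1,000 belong to five planted co-expression modules
#' (sizes 300, 250, 200, 150, 100) and 1,000 are uncorrelated background.
#' Module member genes load on a per-module latent factor; the metastasis
#' effect is planted by shifting the factor mean of module 1 in the `CWM`
#' and `CLM` groups.
#'
#' @param n_genes total number of genes.
#' @param module_sizes integer vector of planted module sizes. Together with
#'   `n_background_genes` these must sum to `n_genes`.
#' @param n_background_genes number of pure-noise background genes.
#' @param samples_per_group named integer vector of samples per group label.
#' @param loading_range length-2 numeric, uniform range of factor loadings
#'   for module member genes.
#' @param noise_sd residual standard deviation on the log2 scale. Together
#'   with the loadings it fixes the within-module correlation
#'   \eqn{r = \lambda^2 / (\lambda^2 + \sigma^2)}.
#' @param baseline_range length-2 numeric, uniform range of per-gene log2
#'   baseline expression.
#' @param trait_effects named list; names are planted module indices (as
#'   characters), values are named numeric vectors of per-group shifts of
#'   that module's latent factor. `list()` plants no trait effect.
#' @param celltypes character vector of reference cell-type labels.
#' @param celltype_module_map named list mapping cell-type label to the
#'   planted module indices elevated in that cell type.
#' @param profiles_per_celltype replicate reference profiles per cell type.
#' @param reference_shift mean log2 shift of mapped-module member genes in
#'   the corresponding cell type's reference profiles.
#' @param reference_noise_sd residual sd of reference profiles.
#' @param library_size target per-sample sequencing depth for the count
#'   matrix (counts are Poisson draws around scaled `2^expression`).
#' @param n_chromosomes,gene_length,gene_spacing layout of the toy genome on
#'   which gene models and copy-number segments are placed (1-based, closed
#'   intervals).
#' @param segment_params list with `mean_segment_length` (bp) and
#'   `category_probs`, a named probability vector over the five absolute
#'   copy-number categories.
#' @param variant_params list with `mean_mutations` (expected somatic
#'   variants per tumor sample), `concordance` (fraction of a trio patient's
#'   variant union shared between primary and metastasis, in \[0,1\]) and
#'   `fail_frac` (per-rule probability that a variant is drawn to violate
#'   one filter rule).
#' @param survival_params list with `baseline_hazard` (events per month),
#'   `coefficients` (named by planted module index; per-unit-eigengene
#'   log-hazard) and `censoring_rate` (expected censored fraction in \[0,1\]).
#' @param msi_rate fraction of patients flagged microsatellite-instable.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#'
#' @return A list of class `"cohort_config"`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_genes = 2000L,
                          module_sizes = c(300L, 250L, 200L, 150L, 100L),
                          n_background_genes = 1000L,
                          samples_per_group = c(AN = 16L, CNM = 16L,
                                                CWM = 16L, CLM = 16L),
                          loading_range = c(0.65, 0.95),
                          noise_sd = 0.6,
                          baseline_range = c(5.5, 11),
                          trait_effects = list(`1` = c(CWM = 1.5, CLM = 1.5)),
                          celltypes = c("epithelial", "CAF", "myeloid",
                                        "lymphoid"),
                          celltype_module_map = list(CAF = 1L, myeloid = 2L,
                                                     lymphoid = 3L),
                          profiles_per_celltype = 4L,
                          reference_shift = 2,
                          reference_noise_sd = 0.5,
                          library_size = 2e6,
                          n_chromosomes = 5L,
                          gene_length = 2e4,
                          gene_spacing = 1e5,
                          segment_params = list(
                            mean_segment_length = 1e7,
                            category_probs = c(deletion = 0.03, loss = 0.12,
                                               diploid = 0.70, gain = 0.12,
                                               amplification = 0.03)),
                          variant_params = list(mean_mutations = 40,
                                                concordance = 0.9,
                                                fail_frac = 0.05),
                          survival_params = list(baseline_hazard = 0.02,
                                                 coefficients = c(`1` = 0.8),
                                                 censoring_rate = 0.2),
                          msi_rate = 0.15,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              module_sizes = as.integer(module_sizes),
              n_background_genes = as.integer(n_background_genes),
              samples_per_group = samples_per_group,
              loading_range = loading_range, noise_sd = noise_sd,
              baseline_range = baseline_range, trait_effects = trait_effects,
              celltypes = celltypes,
              celltype_module_map = celltype_module_map,
              profiles_per_celltype = as.integer(profiles_per_celltype),
              reference_shift = reference_shift,
              reference_noise_sd = reference_noise_sd,
              library_size = library_size,
              n_chromosomes = as.integer(n_chromosomes),
              gene_length = gene_length, gene_spacing = gene_spacing,
              segment_params = segment_params,
              variant_params = variant_params,
              survival_params = survival_params,
              msi_rate = msi_rate, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (sum(cfg$module_sizes) + cfg$n_background_genes != cfg$n_genes)
    stop("config error: sum(module_sizes) + n_background_genes must equal ",
         "n_genes")
  if (length(cfg$samples_per_group) == 0L ||
      is.null(names(cfg$samples_per_group)) ||
      any(cfg$samples_per_group < 1L))
    stop("config error: samples_per_group must be a nonempty named vector ",
         "of positive counts")
  if (cfg$noise_sd <= 0 || cfg$reference_noise_sd <= 0)
    stop("config error: noise sds must be > 0")
  if (any(cfg$loading_range <= 0) || diff(cfg$loading_range) < 0)
    stop("config error: loading_range must be a positive interval")
  k <- length(cfg$module_sizes)
  te_idx <- suppressWarnings(as.integer(names(cfg$trait_effects)))
  if (length(cfg$trait_effects) &&
      (anyNA(te_idx) || any(te_idx < 1L | te_idx > k)))
    stop("config error: trait_effects names must be planted module indices")
  cm_idx <- unlist(cfg$celltype_module_map, use.names = FALSE)
  if (length(cm_idx) && any(cm_idx < 1L | cm_idx > k))
    stop("config error: celltype_module_map references unknown module index")
  if (length(cfg$celltype_module_map) &&
      !all(names(cfg$celltype_module_map) %in% cfg$celltypes))
    stop("config error: celltype_module_map names must be listed celltypes")
  p <- cfg$segment_params$category_probs
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop("config error: category_probs must be a probability vector")
  if (!all(names(p) %in% c("deletion", "loss", "diploid", "gain",
                           "amplification")))
    stop("config error: unknown copy-number category in category_probs")
  vc <- cfg$variant_params$concordance
  if (vc < 0 || vc > 1)
    stop("config error: concordance must be in [0, 1]")
  sv <- cfg$survival_params
  if (sv$baseline_hazard <= 0)
    stop("config error: baseline_hazard must be > 0")
  sv_idx <- suppressWarnings(as.integer(names(sv$coefficients)))
  if (length(sv$coefficients) &&
      (anyNA(sv_idx) || any(sv_idx < 1L | sv_idx > k)))
    stop("config error: survival coefficients must name planted modules")
  if (sv$censoring_rate < 0 || sv$censoring_rate > 1)
    stop("config error: censoring_rate must be in [0, 1]")
  invisible(cfg)
}

# Deterministic gene / sample id layouts shared by the sub-generators.
cohort_gene_ids <- function(cfg) {
  sprintf("G%04d", seq_len(cfg$n_genes))
}

cohort_truth_partition <- function(cfg) {
  genes <- cohort_gene_ids(cfg)
  labs <- rep("unassigned", cfg$n_genes)
  at <- 1L
  for (m in seq_along(cfg$module_sizes)) {
    labs[at:(at + cfg$module_sizes[m] - 1L)] <- paste0("GM", m)
    at <- at + cfg$module_sizes[m]
  }
  stats::setNames(labs, genes)
}

cohort_sample_sheet <- function(cfg) {
  groups <- names(cfg$samples_per_group)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- cfg$samples_per_group[[g]]
    # Trio groups (AN/CWM/CLM) share patient ids index-wise, so the i-th
    # AN, CWM and CLM samples belong to the same patient; CNM patients are
    # a separate series (they have no matched metastasis).
    pat <- if (g == "CNM") sprintf("PC%02d", seq_len(n))
           else sprintf("PT%02d", seq_len(n))
    data.frame(sample = sprintf("%s_%02d", g, seq_len(n)),
               patient = pat, group = g, stringsAsFactors = FALSE)
  }))
  out$metastasis <- as.integer(out$group %in% c("CWM", "CLM"))
  rownames(out) <- NULL
  out
}
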