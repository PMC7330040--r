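#' Differential expression between two groups (t-test stand-in)
#'
#' Per-gene Welch two-sample t (or paired t) on log2 expression with BH
#' FDR. The fold change is the group mean difference on the log2 scale.
#' A gene is flagged differentially expressed when `fdr < fdr_max` and
#' `|log2_fc| >= log2(fc_min)` (defaults: FDR < 0.05 and linear fold
#' change >= 2). This is a simple moment-based engine, not a
#' negative-binomial count model; count-model results will differ,
#' especially at low expression.
#'
#' @param expr log2 expression matrix.
#' @param samples sample annotation with `sample`, `group`, `patient`.
#' @param groups length-2 character vector; fold change is
#'   `groups[1] - groups[2]`.
#' @param paired logical; pairs samples by `patient`.
#' @param fdr_max,fc_min DEG thresholds (linear-scale `fc_min`).
#' @return data frame with `gene`, `log2_fc`, `p`, `fdr`, `is_deg`,
#'   `flat` (zero variance in both groups, p set to 1).
#' @export
differential_expression <- function(expr, samples, groups, paired = FALSE,
                                    fdr_max = 0.05, fc_min = 2) {
  check_matrix(expr, "expr")
  stopifnot(length(groups) == 2L)
  sa <- samples[samples$sample %in% colnames(expr), ]
  a <- sa$sample[sa$group == groups[1]]
  b <- sa$sample[sa$group == groups[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 samples per group")
  if (paired) {
    pa <- sa$patient[match(a, sa$sample)]
    pb <- sa$patient[match(b, sa$sample)]
    common <- intersect(pa, pb)
    a <- a[match(common, pa)]
    b <- b[match(common, pb)]
    if (length(a) < 2L) stop("fewer than 2 matched pairs")
  }
  xa <- expr[, a, drop = FALSE]; xb <- expr[, b, drop = FALSE]
  lfc <- rowMeans(xa) - rowMeans(xb)
  flat <- apply(xa, 1, stats::sd) == 0 & apply(xb, 1, stats::sd) == 0
  p <- vapply(seq_len(nrow(expr)), function(i) {
    if (flat[i]) return(1)
    stats::t.test(xa[i, ], xb[i, ], paired = paired)$p.value
  }, numeric(1))
  fdr <- stats::p.adjust(p, "BH")
  data.frame(gene = rownames(expr), log2_fc = unname(lfc), p = p, fdr = fdr,
             is_deg = fdr < fdr_max & abs(lfc) >= log2(fc_min),
             flat = unname(flat), stringsAsFactors = FALSE)
}

#' Mean-split dichotomization of a module score
#'
#' `High` if the score strictly exceeds the cohort mean, `Low` otherwise
#' (scores exactly at the mean are Low).
#'
#' @param scores named numeric vector of per-sample module scores.
#' @return named factor with levels `Low`, `High`.
#' @export
mean_split <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples")
  if (stats::sd(scores) == 0) stop("constant scores cannot be split")
  factor(ifelse(scores > mean(scores), "High", "Low"),
         levels = c("Low", "High"))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard two-group
#' log-rank chi-square (observed vs expected events over the pooled risk
#' sets, hypergeometric variance, 1 df).
#'
#' @param survival_df data frame with `sample`, `time` (> 0) and `event`
#'   (0/1).
#' @param labels named group labels (e.g. from [mean_split()]); names are
#'   sample ids.
#' @return list with `curves` (data frame: group, time, n_risk, n_event,
#'   survival), `chi2`, `p`, and the per-group sample sizes.
#' @export
kaplan_meier_logrank <- function(survival_df, labels) {
  common <- intersect(survival_df$sample, names(labels))
  if (length(common) == 0L) stop("no overlap between survival and labels")
  df <- survival_df[match(common, survival_df$sample), ]
  grp <- droplevels(factor(labels[common]))
  if (nlevels(grp) != 2L)
    stop("exactly two nonempty groups are required")
  if (sum(df$event) == 0L)
    stop("log-rank undefined: no events in the data")
  if (any(df$time <= 0)) stop("times must be > 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = df)
  strata_grp <- rep(sub("^grp=", "", names(fit$strata)),
                    fit$strata)
  curves <- data.frame(group = strata_grp, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       survival = fit$surv, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  chi2 <- unname(sd_$chisq)
  list(curves = curves, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n = table(grp))
}

#' Module score comparison between responders and non-responders
#'
#' Welch two-sample t-test of per-sample module scores by a binary
#' response label.
#'
#' @param scores named numeric vector of module scores.
#' @param response named binary/logical/character labels (two classes).
#' @return list with `statistic`, `p`, and per-class means (`means`,
#'   ordered by class label).
#' @export
responder_comparison <- function(scores, response) {
  common <- intersect(names(scores), names(response))
  if (length(common)) {
    scores <- scores[common]; response <- response[common]
  }
  cls <- factor(response)
  if (nlevels(cls) != 2L) stop("response must have exactly two classes")
  tt <- stats::t.test(scores[cls == levels(cls)[1]],
                      scores[cls == levels(cls)[2]])
  list(statistic = unname(tt$statistic), p = tt$p.value,
       means = tapply(scores, cls, mean))
}
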