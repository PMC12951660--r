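#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-cohort estimates with weights `se^-2`:
#' `pooled_beta = sum(w beta) / sum(w)`, `pooled_se = (sum w)^(-1/2)`,
#' with the between-cohort heterogeneity statistic
#' `q_het = sum w (beta - pooled)^2` referred to chi-square(K - 1)
#' (`p_het = 1` for a single cohort). The pooled effect is also reported on
#' the exponentiated (odds-ratio) scale.
#'
#' @param estimates list of `mr_estimate` objects (one per cohort).
#' @param cohort_ids optional identifiers, recycled from names otherwise.
#' @return A `meta_result` list: `pooled_beta`, `pooled_se`, `pooled_p`,
#'   `or`, `ci_low`, `ci_high`, `q_het`, `p_het`, `k`, `cohorts_used`.
#' @export
fixed_effect_meta <- function(estimates, cohort_ids = names(estimates)) {
  if (!length(estimates)) stop("fixed_effect_meta: no estimates supplied", call. = FALSE)
  beta <- vapply(estimates, function(e) e$beta, numeric(1))
  se <- vapply(estimates, function(e) e$se, numeric(1))
  if (any(se <= 0)) stop("fixed_effect_meta: nonpositive standard error", call. = FALSE)
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  k <- length(beta)
  q <- sum(w * (beta - pooled)^2)
  p_het <- if (k > 1L) stats::pchisq(q, k - 1L, lower.tail = FALSE) else 1
  structure(list(pooled_beta = pooled, pooled_se = pooled_se,
                 pooled_p = max(2 * stats::pnorm(-abs(pooled / pooled_se)),
                                .Machine$double.xmin),
                 or = exp(pooled),
                 ci_low = exp(pooled - z975 * pooled_se),
                 ci_high = exp(pooled + z975 * pooled_se),
                 q_het = q, p_het = p_het, k = k,
                 cohorts_used = if (is.null(cohort_ids)) as.character(seq_len(k)) else cohort_ids),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta (fixed effects, %d cohorts): OR = %.3f [%.3f, %.3f], p = %.3g, p_het = %.3g\n",
              x$k, x$or, x$ci_low, x$ci_high, x$pooled_p, x$p_het))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests in the family.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1", call. = FALSE)
  alpha / n_tests
}

#' Classify an association against Bonferroni and suggestive thresholds
#'
#' `significant` when `p < bonf`; `suggestive` when `bonf <= p < alpha`;
#' `not_associated` otherwise.
#'
#' @param p the pooled IVW p-value.
#' @param bonf Bonferroni threshold (see [bonferroni_threshold()]).
#' @param alpha nominal level bounding the suggestive band.
#' @return One of `"significant"`, `"suggestive"`, `"not_associated"`.
#' @export
classify_association <- function(p, bonf, alpha = 0.05) {
  if (bonf > alpha) stop("bonf must not exceed alpha", call. = FALSE)
  if (p < bonf) "significant" else if (p < alpha) "suggestive" else "not_associated"
}

#' Apply the per-analysis exclusion rules
#'
#' An analysis is excluded from the meta-analysis when any diagnostic
#' fails, checked in a fixed order (first hit wins): fewer than
#' `cfg$min_snps` variants (`too_few_snps`); MR-Egger intercept p below
#' `cfg$alpha` (`pleiotropy_intercept`); MR-PRESSO global p below
#' `cfg$alpha` (`pleiotropy_global`); Cochran's Q p below `cfg$alpha`
#' (`heterogeneity`); and sign discordance between the IVW point estimate
#' and either the weighted-median or MR-Egger slope
#' (`sensitivity_inconsistent`) — the operational reading of "inconsistent
#' with the sensitivity analyses". Diagnostics that are `NA` (not
#' computable) do not trigger their rule.
#'
#' @param panel a [sensitivity_panel()].
#' @param cfg an [analysis_config()].
#' @return A `screen_decision` list: `status` (`"excluded"` or `"pass"`),
#'   `reason` (`"none"` when passing), and the thresholds used.
#' @export
apply_exclusion_rules <- function(panel, cfg = analysis_config()) {
  reason <- "none"
  below <- function(p) !is.null(p) && !is.na(p) && p < cfg$alpha
  sign0 <- function(x) if (x > 0) 1 else if (x < 0) -1 else 0
  discordant <- function(est) {
    !is.null(est) && sign0(est$beta) != 0 && sign0(panel$ivw$beta) != 0 &&
      sign0(est$beta) != sign0(panel$ivw$beta)
  }
  if (panel$n_snp < cfg$min_snps) {
    reason <- "too_few_snps"
  } else if (below(panel$p_intercept)) {
    reason <- "pleiotropy_intercept"
  } else if (below(panel$presso_global_p)) {
    reason <- "pleiotropy_global"
  } else if (below(panel$p_q)) {
    reason <- "heterogeneity"
  } else if (discordant(panel[["wm"]]) || discordant(panel[["egger"]])) {
    reason <- "sensitivity_inconsistent"
  }
  structure(list(status = if (reason == "none") "pass" else "excluded",
                 reason = reason,
                 alpha = cfg$alpha, min_snps = cfg$min_snps),
            class = "screen_decision")
}
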