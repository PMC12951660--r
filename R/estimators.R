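z975 <- stats::qnorm(0.975)

mr_estimate <- function(method, beta, se, n_snp, df = Inf) {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else z975
  p <- if (is.finite(df)) 2 * stats::pt(-abs(beta / se), df) else 2 * stats::pnorm(-abs(beta / se))
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pvalue = max(p, .Machine$double.xmin), n_snp = n_snp),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, %d SNPs\n",
              x$method, x$beta, x$se, exp(x$beta), exp(x$ci_low),
              exp(x$ci_high), x$pvalue, x$n_snp))
  invisible(x)
}

#' Per-variant Wald ratios
#'
#' Computes the variant-level causal estimates `b_y / b_x` with first-order
#' standard errors `se_y / |b_x|` (the uncertainty in `b_x` is ignored, the
#' conventional default) and inverse-variance weights. Variants with
#' `b_x = 0` are dropped with a warning.
#'
#' @param h a `harmonised_set` (see [harmonise()]).
#' @return A `wald_ratios` data frame with columns `variant_id`, `b_x`,
#'   `b_y`, `se_y`, `ratio`, `ratio_se`, `weight`.
#' @export
wald_ratios <- function(h) {
  keep <- h$b_x != 0
  if (any(!keep)) {
    warning(sprintf("wald_ratios: dropped %d variant(s) with zero exposure effect",
                    sum(!keep)), call. = FALSE)
  }
  df <- as.data.frame(h)[keep, , drop = FALSE]
  if (!nrow(df)) stop("no usable variants after dropping zero exposure effects",
                      call. = FALSE)
  out <- data.frame(variant_id = df$variant_id, b_x = df$b_x, b_y = df$b_y,
                    se_y = df$se_y, ratio = df$b_y / df$b_x,
                    ratio_se = df$se_y / abs(df$b_x), stringsAsFactors = FALSE)
  out$weight <- 1 / out$ratio_se^2
  rownames(out) <- NULL
  structure(out, class = c("wald_ratios", "data.frame"))
}

ivw_core <- function(ratio, weight) {
  beta <- sum(weight * ratio) / sum(weight)
  se_fe <- 1 / sqrt(sum(weight))
  q <- sum(weight * (ratio - beta)^2)
  list(beta = beta, se_fe = se_fe, q = q)
}

#' Inverse-variance weighted estimator
#'
#' The precision-weighted mean of the Wald ratios, equal to the
#' no-intercept weighted least-squares slope of `b_y` on `b_x` with weights
#' `se_y^-2`. The fixed-effects standard error is `(sum w)^(-1/2)`; the
#' multiplicative random-effects standard error inflates it by
#' `max(1, sqrt(Q/(J-1)))`, so it never shrinks below the fixed-effects
#' value. A single variant degenerates to the Wald ratio, with a warning.
#'
#' @param w a [wald_ratios] object.
#' @param model `"re"` (multiplicative random effects, the default) or
#'   `"fe"`.
#' @return An `mr_estimate` with normal-theory 95% CI and two-sided p.
#' @export
ivw <- function(w, model = c("re", "fe")) {
  model <- match.arg(model)
  if (!all(is.finite(w$weight)) || all(w$weight == 0)) {
    stop("ivw: weights must be positive and finite", call. = FALSE)
  }
  j <- nrow(w)
  if (j == 1L) {
    warning("ivw: single variant; estimate degenerates to the Wald ratio",
            call. = FALSE)
    return(mr_estimate(paste0("ivw_", model), w$ratio, w$ratio_se, 1L))
  }
  core <- ivw_core(w$ratio, w$weight)
  se <- if (model == "re") {
    core$se_fe * max(1, sqrt(core$q / (j - 1)))
  } else {
    core$se_fe
  }
  mr_estimate(paste0("ivw_", model), core$beta, se, j)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - beta_FE)^2`, referred to a chi-square
#' distribution with J - 1 degrees of freedom (upper tail).
#'
#' @param w a [wald_ratios] object with at least two variants.
#' @return A list with `q` and `p_q`.
#' @export
cochran_q <- function(w) {
  if (nrow(w) < 2L) stop("cochran_q requires at least 2 variants", call. = FALSE)
  core <- ivw_core(w$ratio, w$weight)
  list(q = core$q, p_q = stats::pchisq(core$q, nrow(w) - 1L, lower.tail = FALSE))
}

#' MR-Egger regression with intercept test
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with an intercept (weights `se_y^-2`), after orienting every
#' variant so that `b_x >= 0` (both betas are negated when `b_x < 0`, the
#' orientation the intercept's pleiotropy interpretation requires). The
#' slope is the pleiotropy-adjusted causal estimate; the intercept
#' estimates average directional pleiotropy; a significant intercept flags
#' directional pleiotropy. Inference uses the t distribution with J - 2
#' degrees of freedom.
#'
#' @param h a `harmonised_set` with at least three variants.
#' @return A list with `estimate` (slope `mr_estimate`), `intercept`,
#'   `intercept_se` and `p_intercept`.
#' @export
mr_egger <- function(h) {
  j <- nrow(h)
  if (j < 3L) stop("mr_egger requires at least 3 variants", call. = FALSE)
  sgn <- ifelse(h$b_x < 0, -1, 1)
  bx <- h$b_x * sgn
  by <- h$b_y * sgn
  if (max(bx) - min(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1)) {
    stop("mr_egger: no spread in exposure effects (singular design)", call. = FALSE)
  }
  fit <- stats::lm(by ~ bx, weights = 1 / h$se_y^2)
  co <- summary(fit)$coefficients
  est <- mr_estimate("egger", co["bx", "Estimate"], co["bx", "Std. Error"],
                     j, df = j - 2L)
  list(estimate = est,
       intercept = co["(Intercept)", "Estimate"],
       intercept_se = co["(Intercept)", "Std. Error"],
       p_intercept = co["(Intercept)", "Pr(>|t|)"])
}

weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  p <- weight[ord] / sum(weight)
  s <- cumsum(p) - p / 2
  stats::approx(s, ratio, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Consistent when instruments contributing at least half of the total
#' weight are valid. Ratios are sorted; with normalised weights `p_j` the
#' cumulative midpoint is `s_j = sum_{k<=j} p_k - p_j/2` and the estimate
#' interpolates the ratio against `s` at 0.5. The standard error comes from
#' a parametric bootstrap: each ratio is re-drawn from its normal
#' distribution and the median recomputed; the bootstrap standard deviation
#' feeds a normal-based CI and p-value.
#'
#' @param w a [wald_ratios] object with at least three variants.
#' @param n_boot bootstrap draws.
#' @param seed integer seed (identical seed gives identical output).
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(w, n_boot = 1000L, seed = 1L) {
  j <- nrow(w)
  if (j < 3L) stop("weighted_median requires at least 3 variants", call. = FALSE)
  est <- weighted_median_point(w$ratio, w$weight)
  boots <- withr::with_seed(seed, {
    draws <- matrix(stats::rnorm(j * n_boot, w$ratio, w$ratio_se), nrow = j)
    apply(draws, 2L, weighted_median_point, weight = w$weight)
  })
  mr_estimate("weighted_median", est, stats::sd(boots), j)
}

presso_loo_slopes <- function(bx, by_mat, weight) {
  # Leave-one-out no-intercept WLS slopes, vectorised over columns of by_mat.
  sxx <- sum(weight * bx^2)
  sxy <- colSums(weight * bx * by_mat)
  num <- matrix(sxy, nrow = length(bx), ncol = ncol(by_mat), byrow = TRUE) -
    weight * bx * by_mat
  den <- sxx - weight * bx^2
  num / den
}

#' MR-PRESSO global test and outlier correction
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' statistic is `sum_j (b_y_j - b_x_j beta^(-j))^2` where `beta^(-j)` is
#' the leave-one-out IVW slope. Its null distribution is built from
#' `n_sim` parametric simulations drawing `b_y*_j ~ N(b_x_j beta^(-j),
#' se_y_j^2)` and recomputing the statistic; the global p-value uses the
#' add-one estimator `(1 + #[sim >= obs]) / (n_sim + 1)`. Each variant's
#' outlier p-value compares its observed squared residual with its own
#' simulated residual distribution, Bonferroni-corrected across the J
#' variants; when outliers are found the corrected estimate is the IVW on
#' the remaining variants. Requires at least four variants.
#'
#' @param h a `harmonised_set`.
#' @param n_sim number of parametric simulations.
#' @param seed integer seed.
#' @param outlier_alpha nominal level of the outlier test (Bonferroni
#'   divided by J per variant).
#' @return A list with `global_p`, `outliers` (variant ids),
#'   `corrected` (an `mr_estimate`, or `NULL` when no outlier is found) and
#'   `observed_rss`.
#' @export
mr_presso <- function(h, n_sim = 1000L, seed = 1L, outlier_alpha = 0.05) {
  j <- nrow(h)
  if (j < 4L) stop("mr_presso requires at least 4 variants", call. = FALSE)
  bx <- h$b_x
  by <- h$b_y
  sey <- h$se_y
  weight <- 1 / sey^2
  slopes <- drop(presso_loo_slopes(bx, matrix(by, ncol = 1L), weight))
  resid_obs <- (by - bx * slopes)^2
  rss_obs <- sum(resid_obs)
  sims <- withr::with_seed(seed, {
    by_star <- matrix(stats::rnorm(j * n_sim, mean = bx * slopes, sd = sey),
                      nrow = j)
    slopes_star <- presso_loo_slopes(bx, by_star, weight)
    (by_star - bx * slopes_star)^2
  })
  rss_sim <- colSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_var <- (1 + rowSums(sims >= resid_obs)) / (n_sim + 1)
  out_idx <- which(p_var < outlier_alpha / j)
  corrected <- NULL
  if (length(out_idx) && (j - length(out_idx)) >= 1L) {
    keep <- setdiff(seq_len(j), out_idx)
    w_keep <- wald_ratios(structure(as.data.frame(h)[keep, , drop = FALSE],
                                    class = c("harmonised_set", "data.frame")))
    corrected <- suppressWarnings(ivw(w_keep, model = "re"))
    corrected$method <- "presso_corrected"
  }
  list(global_p = global_p, outliers = h$variant_id[out_idx],
       corrected = corrected, observed_rss = rss_obs)
}

#' Run the full sensitivity suite on one harmonised set
#'
#' Computes the random-effects IVW estimate, Cochran's Q, MR-Egger with
#' intercept test, the weighted median, and MR-PRESSO (when at least four
#' variants are available), bundling them into one `sensitivity_panel`.
#' Estimators whose minimum variant count is not met are `NULL`/`NA` in the
#' output; the screening rules downstream exclude such analyses anyway.
#'
#' @param h a `harmonised_set`.
#' @param cfg an [analysis_config()] supplying `n_boot`, `n_sim`, `alpha`
#'   and the seed.
#' @param seed overrides `cfg$seed` when given.
#' @return A `sensitivity_panel` list: `ivw`, `egger`, `egger_intercept`,
#'   `p_intercept`, `wm`, `presso_global_p`, `presso_outliers`,
#'   `presso_corrected`, `q`, `p_q`, `n_snp`.
#' @export
sensitivity_panel <- function(h, cfg = analysis_config(), seed = cfg$seed) {
  w <- wald_ratios(h)
  j <- nrow(w)
  est_ivw <- suppressWarnings(ivw(w, model = "re"))
  qres <- if (j >= 2L) cochran_q(w) else list(q = NA_real_, p_q = NA_real_)
  egger <- if (j >= 3L) mr_egger(h) else NULL
  wm <- if (j >= 3L) weighted_median(w, cfg$n_boot, seed = seed + 1L) else NULL
  presso <- if (j >= 4L) {
    mr_presso(h, n_sim = cfg$n_sim, seed = seed + 2L, outlier_alpha = cfg$alpha)
  } else NULL
  structure(list(
    ivw = est_ivw,
    egger = if (!is.null(egger)) egger$estimate else NULL,
    egger_intercept = if (!is.null(egger)) egger$intercept else NA_real_,
    p_intercept = if (!is.null(egger)) egger$p_intercept else NA_real_,
    wm = wm,
    presso_global_p = if (!is.null(presso)) presso$global_p else NA_real_,
    presso_outliers = if (!is.null(presso)) presso$outliers else character(0),
    presso_corrected = if (!is.null(presso)) presso$corrected else NULL,
    q = qres$q, p_q = qres$p_q, n_snp = j,
    exposure_id = attr(h, "exposure_id"), outcome_id = attr(h, "outcome_id"),
    cohort_id = attr(h, "cohort_id")),
    class = "sensitivity_panel")
}

#' @export
print.sensitivity_panel <- function(x, ...) {
  cat(sprintf("sensitivity_panel: %s -> %s [%s], %d SNPs\n",
              x$exposure_id, x$outcome_id, x$cohort_id, x$n_snp))
  print(x$ivw)
  if (!is.null(x$egger)) {
    print(x$egger)
    cat(sprintf("  egger intercept %.4f (p = %.3g)\n", x$egger_intercept,
                x$p_intercept))
  }
  if (!is.null(x$wm)) print(x$wm)
  cat(sprintf("  Q = %.3f (p = %.3g), PRESSO global p = %.3g, outliers: %s\n",
              x$q, x$p_q, x$presso_global_p,
              if (length(x$presso_outliers)) paste(x$presso_outliers, collapse = ",") else "none"))
  invisible(x)
}
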