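#' Mediation (indirect) effect by the product of coefficients
#'
#' @param beta_em exposure-to-mediator effect (per SD).
#' @param beta_mo mediator-to-outcome effect (log-odds per SD).
#' @return The indirect effect `beta_em * beta_mo` (log-odds).
#' @export
mediation_effect <- function(beta_em, beta_mo) beta_em * beta_mo

#' Proportion of the total effect that is mediated
#'
#' @param me indirect effect.
#' @param total total exposure-to-outcome effect (log-odds); must be
#'   nonzero.
#' @return `me / total` as a signed fraction. Values outside \[0, 1\]
#'   indicate inconsistent mediation and are returned unclipped.
#' @export
mediated_proportion <- function(me, total) {
  if (total == 0) stop("mediated proportion undefined: total effect is zero",
                       call. = FALSE)
  me / total
}

#' Bootstrap confidence interval for the product of coefficients
#'
#' Draws `n_boot` independent coefficient pairs from
#' `Normal(beta_em, se_em^2)` and `Normal(beta_mo, se_mo^2)`, forms their
#' products, and returns the empirical 2.5/97.5 percentile interval
#' (linear-interpolation percentiles) together with a two-sided sign-based
#' p-value `2 * min(P[me* <= 0], P[me* >= 0])`, floored at
#' `2 / (n_boot + 1)`.
#'
#' @param beta_em,se_em exposure-to-mediator estimate and standard error.
#' @param beta_mo,se_mo mediator-to-outcome estimate and standard error.
#' @param n_boot bootstrap draws (at least 1000 recommended).
#' @param seed integer seed; identical seeds give identical intervals.
#' @return A list with `ci_low`, `ci_high`, `p`.
#' @export
bootstrap_me <- function(beta_em, se_em, beta_mo, se_mo,
                         n_boot = 1000L, seed = 1L) {
  if (se_em < 0 || se_mo < 0) stop("standard errors must be nonnegative", call. = FALSE)
  me_star <- withr::with_seed(seed, {
    stats::rnorm(n_boot, beta_em, se_em) * stats::rnorm(n_boot, beta_mo, se_mo)
  })
  ci <- stats::quantile(me_star, c(0.025, 0.975), names = FALSE, type = 7)
  p <- 2 * min(mean(me_star <= 0), mean(me_star >= 0))
  p <- min(max(p, 2 / (n_boot + 1)), 1)
  list(ci_low = ci[1], ci_high = ci[2], p = p)
}

#' Assemble a full mediation result for one exposure-mediator-outcome triple
#'
#' Combines the two MR legs into the indirect effect (product of
#' coefficients) with its bootstrap CI, the direct effect
#' (`total - indirect`), the mediated proportion, and a delta-method
#' (Sobel) standard error reported for comparison with the bootstrap.
#'
#' @inheritParams bootstrap_me
#' @param total total exposure-to-outcome effect (log-odds), typically the
#'   pooled meta-analysis IVW estimate.
#' @param exposure_id,mediator_id,outcome_id identifiers carried through to
#'   reports.
#' @return A `mediation_result` list.
#' @export
mediation_result <- function(beta_em, se_em, beta_mo, se_mo, total,
                             n_boot = 1000L, seed = 1L,
                             exposure_id = NA_character_,
                             mediator_id = NA_character_,
                             outcome_id = NA_character_) {
  me <- mediation_effect(beta_em, beta_mo)
  boot <- bootstrap_me(beta_em, se_em, beta_mo, se_mo, n_boot, seed)
  sobel_se <- sqrt(beta_mo^2 * se_em^2 + beta_em^2 * se_mo^2)
  prop <- if (total != 0) mediated_proportion(me, total) else NA_real_
  structure(list(exposure_id = exposure_id, mediator_id = mediator_id,
                 outcome_id = outcome_id,
                 beta_em = beta_em, se_em = se_em,
                 beta_mo = beta_mo, se_mo = se_mo,
                 me = me, me_ci_low = boot$ci_low, me_ci_high = boot$ci_high,
                 me_p = boot$p, sobel_se = sobel_se,
                 total = total, direct = total - me,
                 proportion = prop,
                 inconsistent = !is.na(prop) && (prop < 0 || prop > 1),
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: %s -> %s -> %s\n", x$exposure_id, x$mediator_id,
              x$outcome_id))
  cat(sprintf("  indirect effect %.4f [%.4f, %.4f], p = %.3g\n",
              x$me, x$me_ci_low, x$me_ci_high, x$me_p))
  cat(sprintf("  total %.4f, direct %.4f, mediated proportion %.2f%%%s\n",
              x$total, x$direct, 100 * x$proportion,
              if (isTRUE(x$inconsistent)) " (inconsistent mediation)" else ""))
  invisible(x)
}
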