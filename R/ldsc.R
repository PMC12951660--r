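#' Quality control for LD-score regression
#'
#' Removes records unsuitable for LDSC: minor allele frequency below 0.01
#' (or missing frequency), duplicated variant ids (all copies), and
#' strand-ambiguous palindromic (A/T, G/C) variants. Per-reason counts are
#' attached as the `"qc_log"` attribute.
#'
#' @param ss a [summary_stats] object.
#' @return The filtered [summary_stats].
#' @export
ldsc_qc <- function(ss) {
  maf <- pmin(ss$eaf, 1 - ss$eaf)
  bad_maf <- is.na(maf) | maf < 0.01
  dup_ids <- unique(ss$variant_id[duplicated(ss$variant_id)])
  bad_dup <- ss$variant_id %in% dup_ids & !bad_maf
  bad_pal <- is_palindromic(ss$effect_allele, ss$other_allele) & !bad_maf & !bad_dup
  out <- ss_subset(ss, !(bad_maf | bad_dup | bad_pal))
  attr(out, "qc_log") <- c(low_maf = sum(bad_maf), duplicate = sum(bad_dup),
                           ambiguous_strand = sum(bad_pal))
  out
}

# Weighted regression of y on the LD scores with a block jackknife over
# n_blocks contiguous blocks. Returns slope/intercept plus delete-one-block
# pseudovalue standard errors.
ldsc_regression <- function(y, l, n_blocks) {
  wt <- 1 / pmax(l, 1)
  fit <- stats::lm(y ~ l, weights = wt)
  co <- stats::coef(fit)
  blocks <- cut(seq_along(y), breaks = n_blocks, labels = FALSE)
  jk <- vapply(seq_len(n_blocks), function(b) {
    keep <- blocks != b
    stats::coef(stats::lm(y[keep] ~ l[keep], weights = wt[keep]))
  }, numeric(2))
  list(intercept = co[[1]], slope = co[[2]],
       jk_intercept = jk[1, ], jk_slope = jk[2, ])
}

jackknife_se <- function(theta_hat, jk_values) {
  n <- length(jk_values)
  sqrt((n - 1) / n * sum((jk_values - mean(jk_values))^2))
}

#' Univariate LD-score regression
#'
#' Regresses the per-variant chi-square statistics `z^2` on the LD scores
#' with weights `1 / max(l, 1)`. The heritability estimate is
#' `slope * m / N` where `N` is the mean per-variant sample size; the
#' intercept (expected 1 under a well-controlled GWAS) is reported as-is.
#' Standard errors come from a delete-one-block jackknife over `n_blocks`
#' contiguous variant blocks.
#'
#' @param ss a [summary_stats] object (apply [ldsc_qc()] first for real
#'   data).
#' @param panel an [ld_panel] supplying LD scores for every variant.
#' @param m number of variants the heritability is spread over.
#' @param n_blocks jackknife blocks (default 20, suited to desk-scale
#'   panels).
#' @return A list with `h2`, `h2_se`, `intercept`, `intercept_se`, `m`,
#'   `n_blocks`.
#' @export
univariate_ldsc <- function(ss, panel, m = length(panel$variant_ids),
                            n_blocks = 20L) {
  idx <- match(ss$variant_id, panel$variant_ids)
  if (anyNA(idx)) stop("variant(s) missing an LD score", call. = FALSE)
  if (nrow(ss) < 2L * n_blocks) {
    stop("univariate_ldsc: need at least 2 * n_blocks variants", call. = FALSE)
  }
  z2 <- (ss$beta / ss$se)^2
  l <- panel$ld_scores[idx]
  nbar <- mean(ss$n)
  reg <- ldsc_regression(z2, l, n_blocks)
  h2_jk <- reg$jk_slope * m / nbar
  list(h2 = reg$slope * m / nbar,
       h2_se = jackknife_se(reg$slope * m / nbar, h2_jk),
       intercept = reg$intercept,
       intercept_se = jackknife_se(reg$intercept, reg$jk_intercept),
       m = m, n_blocks = n_blocks)
}

#' Cross-trait LD-score regression
#'
#' Estimates the genetic correlation between two traits from their
#' QC-passing shared variants: the products of the two traits' z-values
#' are regressed on the LD scores; the slope scaled by
#' `m / sqrt(N1 N2)` is the genetic covariance, and dividing by the square
#' root of the product of the univariate heritabilities gives `rg`. The
#' `rg` standard error and p-value come from a delete-one-block jackknife
#' of the full calculation (heritabilities included). Estimates are
#' clipped to \[-1.25, 1.25\], with a warning outside \[-1, 1\].
#'
#' @param ss1,ss2 [summary_stats] for the two traits.
#' @param panel an [ld_panel].
#' @param m number of variants the heritability is spread over.
#' @param n_blocks jackknife blocks.
#' @return An `ldsc_result` list: `h2_1`, `h2_2`, `rg`, `rg_se`, `rg_p`,
#'   `gcov`, `intercept_1`, `intercept_2`, `intercept_x`, `m`, `n_blocks`,
#'   `n_shared`.
#' @export
cross_trait_ldsc <- function(ss1, ss2, panel, m = length(panel$variant_ids),
                             n_blocks = 20L) {
  q1 <- ldsc_qc(ss1)
  q2 <- ldsc_qc(ss2)
  shared <- intersect(q1$variant_id, q2$variant_id)
  # order by the panel so that (a, b) and (b, a) see identical data
  shared <- panel$variant_ids[panel$variant_ids %in% shared]
  if (length(shared) < 2L * n_blocks) {
    stop("cross_trait_ldsc: fewer than 2 * n_blocks shared QC-passing variants",
         call. = FALSE)
  }
  i1 <- match(shared, q1$variant_id)
  i2 <- match(shared, q2$variant_id)
  z1 <- q1$beta[i1] / q1$se[i1]
  z2 <- q2$beta[i2] / q2$se[i2]
  l <- panel$ld_scores[match(shared, panel$variant_ids)]
  n1 <- mean(q1$n[i1]); n2 <- mean(q2$n[i2])
  wt <- 1 / pmax(l, 1)

  rg_of <- function(keep) {
    f1 <- stats::coef(stats::lm(z1[keep]^2 ~ l[keep], weights = wt[keep]))
    f2 <- stats::coef(stats::lm(z2[keep]^2 ~ l[keep], weights = wt[keep]))
    fx <- stats::coef(stats::lm(I(z1[keep] * z2[keep]) ~ l[keep], weights = wt[keep]))
    h2_1 <- f1[[2]] * m / n1
    h2_2 <- f2[[2]] * m / n2
    gcov <- fx[[2]] * m / sqrt(n1 * n2)
    c(h2_1 = h2_1, h2_2 = h2_2, gcov = gcov,
      rg = if (h2_1 > 0 && h2_2 > 0) gcov / sqrt(h2_1 * h2_2) else NA_real_,
      i1 = f1[[1]], i2 = f2[[1]], ix = fx[[1]])
  }

  full <- rg_of(rep(TRUE, length(shared)))
  if (is.na(full[["rg"]])) {
    stop("cross_trait_ldsc: nonpositive heritability estimate; rg undefined",
         call. = FALSE)
  }
  blocks <- cut(seq_along(shared), breaks = n_blocks, labels = FALSE)
  jk <- vapply(seq_len(n_blocks), function(b) rg_of(blocks != b)[["rg"]],
               numeric(1))
  jk[is.na(jk)] <- full[["rg"]]
  rg_se <- jackknife_se(full[["rg"]], jk)
  rg <- full[["rg"]]
  if (abs(rg) > 1) {
    warning(sprintf("rg estimate %.3f outside [-1, 1]", rg), call. = FALSE)
  }
  rg <- max(min(rg, 1.25), -1.25)
  structure(list(h2_1 = full[["h2_1"]], h2_2 = full[["h2_2"]],
                 rg = rg, rg_se = rg_se,
                 rg_p = if (rg_se > 0) 2 * stats::pnorm(-abs(rg / rg_se)) else NA_real_,
                 gcov = full[["gcov"]],
                 intercept_1 = full[["i1"]], intercept_2 = full[["i2"]],
                 intercept_x = full[["ix"]],
                 m = m, n_blocks = n_blocks, n_shared = length(shared)),
            class = "ldsc_result")
}

#' @export
print.ldsc_result <- function(x, ...) {
  cat(sprintf("ldsc: h2_1 = %.3f, h2_2 = %.3f, rg = %.3f (se %.3f, p = %.3g), %d shared variants\n",
              x$h2_1, x$h2_2, x$rg, x$rg_se, x$rg_p, x$n_shared))
  invisible(x)
}
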