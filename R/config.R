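#' Analysis configuration
#'
#' Collects every numeric threshold of the instrument-selection and
#' screening stages in one validated object. Defaults follow the standard
#' practice for microbiome / metabolite MR screens: instruments at
#' p < 5e-6 with genome-wide 5e-8 kept for accounting, clumping at
#' 10,000 kb and r^2 < 0.001, weak instruments excluded below F = 10,
#' instruments associated with the outcome at p < 5e-6 excluded, and
#' analyses with fewer than four SNPs dropped (the MR-PRESSO minimum).
#'
#' @param iv_pvalue_threshold instrument-selection p-value threshold.
#' @param genomewide_threshold conventional genome-wide threshold, used only
#'   for accounting summaries.
#' @param clump_window_kb clumping window in kilobases.
#' @param clump_r2 maximum squared correlation tolerated between retained
#'   instruments within the window.
#' @param f_min minimum instrument F-statistic (beta^2/se^2) retained.
#' @param outcome_assoc_threshold instruments with an outcome p-value below
#'   this are excluded (exclusion-restriction guard).
#' @param palindrome_maf_halfwidth palindromic A/T / G/C variants whose
#'   effect-allele frequency lies within this halfwidth of 0.5 are treated
#'   as strand-ambiguous and dropped.
#' @param min_snps minimum number of harmonised SNPs for an analysis to be
#'   eligible (MR-PRESSO requires at least 4).
#' @param alpha nominal significance level for diagnostics and the
#'   suggestive band.
#' @param n_exposure_tests,n_mediator_tests Bonferroni denominators for the
#'   exposure and mediator screens (properties of the input inventory).
#' @param n_boot bootstrap draws for the weighted median and mediation CIs.
#' @param n_sim simulated replicates for the MR-PRESSO global test.
#' @param seed base seed for every stochastic procedure.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(iv_pvalue_threshold = 5e-6,
                            genomewide_threshold = 5e-8,
                            clump_window_kb = 10000L,
                            clump_r2 = 0.001,
                            f_min = 10,
                            outcome_assoc_threshold = 5e-6,
                            palindrome_maf_halfwidth = 0.08,
                            min_snps = 4L,
                            alpha = 0.05,
                            n_exposure_tests = 416L,
                            n_mediator_tests = 1178L,
                            n_boot = 1000L,
                            n_sim = 1000L,
                            seed = 1L) {
  cfg <- list(iv_pvalue_threshold = iv_pvalue_threshold,
              genomewide_threshold = genomewide_threshold,
              clump_window_kb = as.integer(clump_window_kb),
              clump_r2 = clump_r2,
              f_min = f_min,
              outcome_assoc_threshold = outcome_assoc_threshold,
              palindrome_maf_halfwidth = palindrome_maf_halfwidth,
              min_snps = as.integer(min_snps),
              alpha = alpha,
              n_exposure_tests = as.integer(n_exposure_tests),
              n_mediator_tests = as.integer(n_mediator_tests),
              n_boot = as.integer(n_boot),
              n_sim = as.integer(n_sim),
              seed = as.integer(seed))
  probs <- c("iv_pvalue_threshold", "genomewide_threshold",
             "outcome_assoc_threshold", "alpha")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      stop(p, " must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$clump_window_kb <= 0) stop("clump_window_kb must be positive", call. = FALSE)
  if (cfg$clump_r2 < 0) stop("clump_r2 must be nonnegative", call. = FALSE)
  if (cfg$f_min <= 0) stop("f_min must be positive", call. = FALSE)
  if (cfg$palindrome_maf_halfwidth <= 0 || cfg$palindrome_maf_halfwidth >= 0.5) {
    stop("palindrome_maf_halfwidth must lie in (0, 0.5)", call. = FALSE)
  }
  if (cfg$min_snps < 4L) stop("min_snps must be at least 4", call. = FALSE)
  if (cfg$n_exposure_tests < 1L || cfg$n_mediator_tests < 1L) {
    stop("test counts must be positive", call. = FALSE)
  }
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
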