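# Builders for small in-code fixtures.

# Strip container attributes so record payloads can be compared directly.
rec <- function(x) {
  y <- as.data.frame(x)
  attributes(y) <- list(names = names(y), row.names = attr(y, "row.names"))
  class(y) <- "data.frame"
  y
}

make_ss <- function(variant_id, beta, se,
                    pvalue = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
                    effect_allele = "A", other_allele = "G", eaf = 0.3,
                    chromosome = "1", position = seq_along(variant_id) * 1e6,
                    n = 10000, n_case = NA_real_, n_control = NA_real_,
                    trait_id = "trait", trait_type = "continuous",
                    cohort_id = "cohort") {
  k <- length(variant_id)
  summary_stats(data.frame(
    variant_id = variant_id,
    chromosome = rep_len(chromosome, k), position = position,
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
    pvalue = pvalue, n = rep_len(n, k),
    n_case = rep_len(n_case, k), n_control = rep_len(n_control, k),
    stringsAsFactors = FALSE), trait_id, trait_type, cohort_id)
}

make_h <- function(b_x, se_x, b_y, se_y,
                   variant_id = sprintf("rs%d", seq_along(b_x)),
                   eaf_x = 0.3) {
  structure(data.frame(variant_id = variant_id, b_x = b_x,
                       se_x = rep_len(se_x, length(b_x)), b_y = b_y,
                       se_y = rep_len(se_y, length(b_x)),
                       eaf_x = rep_len(eaf_x, length(b_x)), flipped = FALSE,
                       stringsAsFactors = FALSE),
            exposure_id = "x", outcome_id = "y", cohort_id = "c",
            drop_log = c(allele_mismatch = 0L, palindromic_ambiguous = 0L,
                         missing_in_outcome = 0L),
            class = c("harmonised_set", "data.frame"))
}

fake_panel <- function(n_snp = 10L, ivw_beta = 0.2, p_intercept = 0.5,
                       p_global = 0.5, p_q = 0.5, wm_beta = ivw_beta,
                       egger_beta = ivw_beta) {
  structure(list(
    ivw = structure(list(method = "ivw_re", beta = ivw_beta, se = 0.05,
                         ci_low = ivw_beta - 0.1, ci_high = ivw_beta + 0.1,
                         pvalue = 0.01, n_snp = n_snp), class = "mr_estimate"),
    egger = structure(list(method = "egger", beta = egger_beta, se = 0.1,
                           ci_low = egger_beta - 0.2, ci_high = egger_beta + 0.2,
                           pvalue = 0.1, n_snp = n_snp), class = "mr_estimate"),
    egger_intercept = 0.001, p_intercept = p_intercept,
    wm = structure(list(method = "weighted_median", beta = wm_beta, se = 0.06,
                        ci_low = wm_beta - 0.12, ci_high = wm_beta + 0.12,
                        pvalue = 0.02, n_snp = n_snp), class = "mr_estimate"),
    presso_global_p = p_global, presso_outliers = character(0),
    presso_corrected = NULL, q = 10, p_q = p_q, n_snp = n_snp,
    exposure_id = "x", outcome_id = "y", cohort_id = "c"),
    class = "sensitivity_panel")
}

# Null-calibration sim config: 30 independent strong instruments,
# effective outcome sample size 50,000, no causal effect, no pleiotropy.
null_sim_config <- function(seed, theta_em = 0, theta_mo = 0, theta_dir = 0,
                            pleiotropy_mean = 0, pleiotropy_sd = 0) {
  sim_config(n_variants = 30L, n_instruments = 30L,
             n_mediator_instruments = 0L, ld_block_size = 1L, ld_rho = 0,
             h2_exposure = 0.08, h2_mediator = 0,
             theta_em = theta_em, theta_mo = theta_mo, theta_dir = theta_dir,
             pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
             exposure_cohorts = list(EXP = list(n = 50000)),
             mediator_cohorts = list(MED = list(n = 1000)),
             outcome_cohorts = list(OUT = list(n_case = 25000,
                                               n_control = 25000)),
             seed = seed)
}
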