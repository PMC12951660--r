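#' Filter summary statistics by association p-value
#'
#' Retains records with p-value strictly below the instrument-selection
#' threshold, preserving input order.
#'
#' @param ss a [summary_stats] object.
#' @param threshold p-value threshold in (0, 1).
#' @return The filtered [summary_stats].
#' @export
filter_by_pvalue <- function(ss, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
  ss_subset(ss, ss$pvalue < threshold)
}

#' Instrument-strength F-statistic
#'
#' The per-SNP instrument strength, `F = beta^2 / se^2`; values below 10
#' conventionally flag weak instruments.
#'
#' @param beta effect size(s).
#' @param se standard error(s), strictly positive.
#' @return The F-statistic(s), vectorised.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive", call. = FALSE)
  (beta / se)^2
}

#' Exclude weak instruments
#'
#' Retains records whose F-statistic is at least `f_min`; records strictly
#' below the cutoff are excluded.
#'
#' @param ss a [summary_stats] object.
#' @param f_min minimum F-statistic retained (conventionally 10).
#' @return The filtered [summary_stats].
#' @export
filter_weak_instruments <- function(ss, f_min = 10) {
  if (f_min <= 0) stop("f_min must be positive", call. = FALSE)
  if (!nrow(ss)) return(ss)
  ss_subset(ss, f_statistic(ss$beta, ss$se) >= f_min)
}

#' Exclude instruments associated with the outcome
#'
#' Drops instruments whose variant appears in the outcome summary
#' statistics with an outcome p-value below `threshold` (a guard on the
#' exclusion-restriction assumption). Instruments absent from the outcome
#' file are untouched by this filter.
#'
#' @param iv instrument [summary_stats].
#' @param outcome outcome [summary_stats].
#' @param threshold outcome-association p-value threshold.
#' @return The filtered [summary_stats].
#' @export
exclude_outcome_associated <- function(iv, outcome, threshold = 5e-6) {
  if (!nrow(iv)) return(iv)
  idx <- match(iv$variant_id, outcome$variant_id)
  hit <- !is.na(idx) & outcome$pvalue[idx] < threshold
  ss_subset(iv, !hit)
}

#' Greedy LD clumping of summary statistics
#'
#' Sorts records by p-value ascending (ties broken lexicographically by
#' variant id), then repeatedly accepts the best remaining variant and
#' removes every remaining variant on the same chromosome within
#' `window_kb` whose squared correlation with it is at least `r2_max`. The
#' returned set therefore has all pairwise r^2 below `r2_max` within the
#' window. Variants missing from the LD panel are dropped with a warning
#' (tracked in the `"clump_log"` attribute), never an error.
#'
#' @param ss a [summary_stats] object.
#' @param panel an [ld_panel] covering the variants.
#' @param window_kb clumping window in kilobases.
#' @param r2_max maximum tolerated squared correlation.
#' @return The clumped [summary_stats]; `attr(, "clump_log")` counts
#'   variants removed as `clumped` and `not_in_panel`.
#' @export
ld_clump <- function(ss, panel, window_kb = 10000, r2_max = 0.001) {
  in_panel <- ss$variant_id %in% panel$variant_ids
  n_missing <- sum(!in_panel)
  if (n_missing) {
    warning(sprintf("ld_clump: %d variant(s) missing from the LD panel were dropped",
                    n_missing), call. = FALSE)
  }
  df <- as.data.frame(ss)[in_panel, , drop = FALSE]
  ord <- order(df$pvalue, df$variant_id)
  df <- df[ord, , drop = FALSE]
  keep_ids <- character(0)
  active <- seq_len(nrow(df))
  r2 <- panel$r[df$variant_id, df$variant_id, drop = FALSE]^2
  window_bp <- window_kb * 1000
  while (length(active)) {
    best <- active[1L]
    keep_ids <- c(keep_ids, df$variant_id[best])
    rest <- active[-1L]
    if (length(rest)) {
      same_chr <- df$chromosome[rest] == df$chromosome[best]
      near <- same_chr & abs(df$position[rest] - df$position[best]) <= window_bp
      conflict <- near & r2[rest, best] >= r2_max
      active <- rest[!conflict]
    } else {
      active <- integer(0)
    }
  }
  out <- ss_subset(ss, ss$variant_id %in% keep_ids)
  attr(out, "clump_log") <- c(clumped = sum(in_panel) - length(keep_ids),
                              not_in_panel = n_missing)
  out
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

complement_freq <- function(eaf) 1 - eaf

#' Harmonise instrument and outcome summary statistics
#'
#' Aligns the outcome effects onto the exposure's effect alleles for each
#' instrument found in the outcome data:
#' \itemize{
#'   \item allele pairs matching in order are kept as-is;
#'   \item outcome alleles swapped relative to the exposure's have the
#'     outcome beta negated and the outcome frequency complemented
#'     (`flipped = TRUE`);
#'   \item any other allele combination is dropped as `allele_mismatch`
#'     (strand-flip rescue is deliberately not attempted);
#'   \item palindromic variants (A/T or G/C) whose exposure effect-allele
#'     frequency lies within `maf_halfwidth` of 0.5 — or is missing — are
#'     strand-ambiguous and dropped as `palindromic_ambiguous`;
#'   \item instruments absent from the outcome are dropped as
#'     `missing_in_outcome` (proxy variants are never substituted).
#' }
#'
#' @param iv instrument [summary_stats] (the exposure side).
#' @param outcome outcome [summary_stats].
#' @param maf_halfwidth halfwidth of the palindromic ambiguity window
#'   around 0.5.
#' @return A `harmonised_set`: a data frame with columns `variant_id`,
#'   `b_x`, `se_x`, `b_y`, `se_y`, `eaf_x`, `flipped`, with attributes
#'   `exposure_id`, `outcome_id`, `cohort_id` and `drop_log` (named counts
#'   by reason). Every input instrument is either retained or counted
#'   exactly once in the drop log.
#' @export
harmonise <- function(iv, outcome, maf_halfwidth = 0.08) {
  drop_log <- c(allele_mismatch = 0L, palindromic_ambiguous = 0L,
                missing_in_outcome = 0L)
  idx <- match(iv$variant_id, outcome$variant_id)
  rows <- vector("list", nrow(iv))
  for (i in seq_len(nrow(iv))) {
    j <- idx[i]
    if (is.na(j)) {
      drop_log["missing_in_outcome"] <- drop_log["missing_in_outcome"] + 1L
      next
    }
    ea_x <- iv$effect_allele[i]; oa_x <- iv$other_allele[i]
    ea_y <- outcome$effect_allele[j]; oa_y <- outcome$other_allele[j]
    if (ea_x == ea_y && oa_x == oa_y) {
      b_y <- outcome$beta[j]; flipped <- FALSE
    } else if (ea_x == oa_y && oa_x == ea_y) {
      b_y <- -outcome$beta[j]; flipped <- TRUE
    } else {
      drop_log["allele_mismatch"] <- drop_log["allele_mismatch"] + 1L
      next
    }
    if (is_palindromic(ea_x, oa_x)) {
      eaf <- iv$eaf[i]
      # small tolerance keeps the window boundary inclusive under rounding
      if (is.na(eaf) || abs(eaf - 0.5) <= maf_halfwidth + 1e-9) {
        drop_log["palindromic_ambiguous"] <- drop_log["palindromic_ambiguous"] + 1L
        next
      }
    }
    rows[[i]] <- data.frame(variant_id = iv$variant_id[i],
                            b_x = iv$beta[i], se_x = iv$se[i],
                            b_y = b_y, se_y = outcome$se[j],
                            eaf_x = iv$eaf[i], flipped = flipped,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(0), b_x = numeric(0),
                      se_x = numeric(0), b_y = numeric(0), se_y = numeric(0),
                      eaf_x = numeric(0), flipped = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out,
            exposure_id = attr(iv, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            cohort_id = attr(outcome, "cohort_id"),
            drop_log = drop_log,
            class = c("harmonised_set", "data.frame"))
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("harmonised_set: %s -> %s [%s], %d variants\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"),
              attr(x, "cohort_id"), nrow(x)))
  dl <- attr(x, "drop_log")
  if (!is.null(dl) && sum(dl)) {
    cat("  drops:", paste(names(dl)[dl > 0], dl[dl > 0], sep = "=",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full instrument-selection and harmonisation pipeline
#'
#' Chains the selection filters in the conventional order — association
#' p-value threshold, greedy LD clumping, F-statistic filter,
#' outcome-association exclusion — then harmonises against the outcome.
#' The returned drop log accounts for every exposure record exactly once:
#' `p_threshold`, `not_in_panel`, `clumped`, `weak_f`, `outcome_associated`,
#' plus the harmonisation reasons.
#'
#' @param exposure exposure [summary_stats] (all measured variants).
#' @param outcome outcome [summary_stats].
#' @param panel [ld_panel] for clumping.
#' @param cfg an [analysis_config()].
#' @return A `harmonised_set` with the complete `drop_log`.
#' @export
select_instruments <- function(exposure, outcome, panel, cfg = analysis_config()) {
  n0 <- nrow(exposure)
  iv <- filter_by_pvalue(exposure, cfg$iv_pvalue_threshold)
  n_p <- n0 - nrow(iv)
  iv <- ld_clump(iv, panel, cfg$clump_window_kb, cfg$clump_r2)
  clog <- attr(iv, "clump_log")
  n_before_f <- nrow(iv)
  iv <- filter_weak_instruments(iv, cfg$f_min)
  n_f <- n_before_f - nrow(iv)
  n_before_o <- nrow(iv)
  iv <- exclude_outcome_associated(iv, outcome, cfg$outcome_assoc_threshold)
  n_o <- n_before_o - nrow(iv)
  h <- harmonise(iv, outcome, cfg$palindrome_maf_halfwidth)
  attr(h, "drop_log") <- c(p_threshold = n_p, clog["not_in_panel"],
                           clog["clumped"], weak_f = n_f,
                           outcome_associated = n_o, attr(h, "drop_log"))
  h
}
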