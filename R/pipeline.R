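per_cohort_row <- function(exposure_id, outcome_id, cohort_id, sp, decision) {
  has <- function(x) !is.null(x)
  data.frame(
    exposure = exposure_id, outcome = outcome_id, cohort = cohort_id,
    n_snp = if (has(sp)) sp$n_snp else 0L,
    beta = if (has(sp)) sp$ivw$beta else NA_real_,
    se = if (has(sp)) sp$ivw$se else NA_real_,
    or = if (has(sp)) exp(sp$ivw$beta) else NA_real_,
    ci_low = if (has(sp)) exp(sp$ivw$ci_low) else NA_real_,
    ci_high = if (has(sp)) exp(sp$ivw$ci_high) else NA_real_,
    p = if (has(sp)) sp$ivw$pvalue else NA_real_,
    q = if (has(sp)) sp$q else NA_real_,
    p_q = if (has(sp)) sp$p_q else NA_real_,
    intercept = if (has(sp)) sp$egger_intercept else NA_real_,
    p_intercept = if (has(sp)) sp$p_intercept else NA_real_,
    p_global = if (has(sp)) sp$presso_global_p else NA_real_,
    wm_beta = if (has(sp) && !is.null(sp$wm)) sp$wm$beta else NA_real_,
    egger_beta = if (has(sp) && !is.null(sp$egger)) sp$egger$beta else NA_real_,
    status = decision$status, reason = decision$reason,
    stringsAsFactors = FALSE)
}

#' Screen every exposure against every outcome cohort and pool by trait
#'
#' The engine behind the forward and reverse MR stages. For each
#' exposure/outcome pair of summary-statistics sets it selects and
#' harmonises instruments, runs the sensitivity suite, applies the
#' exclusion rules, then pools the surviving per-cohort IVW estimates for
#' each exposure-trait/outcome-trait pair by fixed-effects meta-analysis
#' and classifies the pooled p-value against the Bonferroni and suggestive
#' thresholds. Analyses with zero surviving instruments are logged skips,
#' never failures.
#'
#' @param cfg an [analysis_config()].
#' @param exposures list of [summary_stats] acting as exposures (one trait
#'   in one cohort each; the same trait may appear for several cohorts).
#' @param outcomes list of [summary_stats] acting as outcomes.
#' @param panel an [ld_panel] for clumping.
#' @param n_tests Bonferroni denominator for the exposure family.
#' @return An `mr_results` list with `per_cohort` and `meta` data frames.
#' @export
run_forward_mr <- function(cfg, exposures, outcomes, panel,
                           n_tests = cfg$n_exposure_tests) {
  rows <- list()
  panels <- list()
  counter <- 0L
  for (ex in exposures) {
    for (out in outcomes) {
      counter <- counter + 1L
      key <- sprintf("%s|%s|%s|%s", attr(ex, "trait_id"), attr(ex, "cohort_id"),
                     attr(out, "trait_id"), attr(out, "cohort_id"))
      h <- select_instruments(ex, out, panel, cfg)
      if (!nrow(h)) {
        message("skip (no surviving instruments): ", key)
        rows[[key]] <- per_cohort_row(attr(ex, "trait_id"), attr(out, "trait_id"),
                                      attr(out, "cohort_id"), NULL,
                                      list(status = "excluded", reason = "too_few_snps"))
        next
      }
      sp <- sensitivity_panel(h, cfg, seed = cfg$seed + 13L * counter)
      dec <- apply_exclusion_rules(sp, cfg)
      rows[[key]] <- per_cohort_row(attr(ex, "trait_id"), attr(out, "trait_id"),
                                    attr(out, "cohort_id"), sp, dec)
      panels[[key]] <- sp
    }
  }
  per_cohort <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    per_cohort_row("x", "y", "z", NULL, list(status = "", reason = ""))[0, ]
  }
  meta <- meta_by_trait(per_cohort, panels, cfg, n_tests)
  structure(list(per_cohort = per_cohort, meta = meta), class = "mr_results")
}

meta_by_trait <- function(per_cohort, panels, cfg, n_tests) {
  if (is.null(per_cohort) || !nrow(per_cohort)) {
    return(data.frame(exposure = character(0), outcome = character(0),
                      k = integer(0), n_snp = integer(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0), p = numeric(0),
                      p_het = numeric(0), status = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  bonf <- bonferroni_threshold(cfg$alpha, n_tests)
  groups <- split(seq_len(nrow(per_cohort)),
                  paste(per_cohort$exposure, per_cohort$outcome, sep = "|"))
  # preserve first-appearance order of the trait pairs
  groups <- groups[unique(paste(per_cohort$exposure, per_cohort$outcome, sep = "|"))]
  out <- lapply(groups, function(idx) {
    sub <- per_cohort[idx, , drop = FALSE]
    ok <- sub$status == "pass"
    if (!any(ok)) {
      return(data.frame(exposure = sub$exposure[1], outcome = sub$outcome[1],
                        k = 0L, n_snp = 0L, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, p_het = NA_real_,
                        beta = NA_real_, se = NA_real_,
                        status = "excluded", reason = "no_cohort_passed",
                        stringsAsFactors = FALSE))
    }
    ests <- lapply(which(ok), function(i) {
      list(beta = sub$beta[i], se = sub$se[i])
    })
    mres <- fixed_effect_meta(ests, cohort_ids = sub$cohort[ok])
    data.frame(exposure = sub$exposure[1], outcome = sub$outcome[1],
               k = mres$k, n_snp = sum(sub$n_snp[ok]),
               or = mres$or, ci_low = mres$ci_low, ci_high = mres$ci_high,
               p = mres$pooled_p, p_het = mres$p_het,
               beta = mres$pooled_beta, se = mres$pooled_se,
               status = classify_association(mres$pooled_p, bonf, cfg$alpha),
               reason = "none", stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Reverse MR screen
#'
#' Runs the same selection/estimation/meta machinery with the roles
#' swapped: the disease outcome cohorts act as exposures and each
#' previously identified taxon as the outcome. The output schema is
#' identical to [run_forward_mr()].
#'
#' @param cfg an [analysis_config()].
#' @param outcome_as_exposure list of outcome-cohort [summary_stats] now
#'   used as exposures.
#' @param taxa list of taxon [summary_stats] (the forward-identified
#'   subset).
#' @param panel an [ld_panel].
#' @param n_tests Bonferroni denominator (defaults to the number of taxa).
#' @return An `mr_results` list.
#' @export
run_reverse_mr <- function(cfg, outcome_as_exposure, taxa, panel,
                           n_tests = max(length(taxa), 1L)) {
  run_forward_mr(cfg, outcome_as_exposure, taxa, panel, n_tests = n_tests)
}

#' Enumerate the taxon-metabolite pairs attempted by the mediation stage
#'
#' @param taxa_ids,metabolite_ids identifiers of the forward-identified
#'   taxa and metabolites.
#' @return A data frame with one row per (taxon, metabolite) pair;
#'   `length(taxa_ids) * length(metabolite_ids)` rows.
#' @export
plan_mediation_pairs <- function(taxa_ids, metabolite_ids) {
  if (!length(taxa_ids) || !length(metabolite_ids)) {
    return(data.frame(taxon = character(0), metabolite = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- expand.grid(metabolite = metabolite_ids, taxon = taxa_ids,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("taxon", "metabolite")]
  rownames(out) <- NULL
  out
}

#' Two-step MR mediation over the identified taxa and metabolites
#'
#' For every (identified taxon, identified metabolite) pair a
#' taxon-to-metabolite MR is attempted (the pair count is always the full
#' product, matching the screening design). Pairs whose IVW p-value passes
#' the Bonferroni threshold over the attempted pairs become mediation
#' triples: the indirect effect is the product of the taxon-to-metabolite
#' estimate and the metabolite's pooled metabolite-to-outcome estimate,
#' the total effect is the taxon's pooled taxon-to-outcome estimate, and
#' the bootstrap CI comes from [bootstrap_me()].
#'
#' @param cfg an [analysis_config()].
#' @param taxa_meta,metabolite_meta `meta` data frames from
#'   [run_forward_mr()] for the taxon and metabolite screens (rows with
#'   status `significant`/`suggestive` define the identified sets).
#' @param exposure_stats named list of taxon [summary_stats] keyed by trait
#'   id.
#' @param mediator_stats named list of metabolite [summary_stats] keyed by
#'   trait id.
#' @param panel an [ld_panel].
#' @param pair_screen_threshold p-value threshold a pair must pass to enter
#'   mediation; defaults to Bonferroni over the attempted pairs.
#' @return A list with `attempted` (pair count), `pairs` (per-pair MR
#'   results), `results` (list of `mediation_result`).
#' @export
run_mediation_pipeline <- function(cfg, taxa_meta, metabolite_meta,
                                   exposure_stats, mediator_stats, panel,
                                   pair_screen_threshold = NULL) {
  identified <- function(meta) {
    meta$exposure[meta$status %in% c("significant", "suggestive")]
  }
  taxa_ids <- intersect(identified(taxa_meta), names(exposure_stats))
  met_ids <- intersect(identified(metabolite_meta), names(mediator_stats))
  pairs <- plan_mediation_pairs(taxa_ids, met_ids)
  attempted <- nrow(pairs)
  if (!attempted) {
    message("mediation: no qualifying taxon-metabolite pairs")
    return(list(attempted = 0L, pairs = pairs, results = list()))
  }
  if (is.null(pair_screen_threshold)) {
    pair_screen_threshold <- bonferroni_threshold(cfg$alpha, attempted)
  }
  pair_rows <- vector("list", attempted)
  results <- list()
  for (i in seq_len(attempted)) {
    tx <- pairs$taxon[i]
    mt <- pairs$metabolite[i]
    row <- data.frame(taxon = tx, metabolite = mt, n_snp = 0L,
                      beta_em = NA_real_, se_em = NA_real_, p_em = NA_real_,
                      qualifies = FALSE, stringsAsFactors = FALSE)
    est <- tryCatch({
      h <- select_instruments(exposure_stats[[tx]], mediator_stats[[mt]],
                              panel, cfg)
      if (nrow(h) < cfg$min_snps) NULL else suppressWarnings(ivw(wald_ratios(h), "re"))
    }, error = function(e) NULL)
    if (!is.null(est)) {
      row$n_snp <- est$n_snp
      row$beta_em <- est$beta
      row$se_em <- est$se
      row$p_em <- est$pvalue
      row$qualifies <- est$pvalue < pair_screen_threshold
    }
    pair_rows[[i]] <- row
    if (isTRUE(row$qualifies)) {
      mmeta <- metabolite_meta[metabolite_meta$exposure == mt, , drop = FALSE][1, ]
      tmeta <- taxa_meta[taxa_meta$exposure == tx, , drop = FALSE][1, ]
      results[[paste(tx, mt, sep = "|")]] <- mediation_result(
        beta_em = row$beta_em, se_em = row$se_em,
        beta_mo = mmeta$beta, se_mo = mmeta$se,
        total = tmeta$beta, n_boot = cfg$n_boot,
        seed = cfg$seed + 7L * i,
        exposure_id = tx, mediator_id = mt,
        outcome_id = tmeta$outcome)
    }
  }
  list(attempted = attempted,
       pairs = do.call(rbind, c(pair_rows, list(make.row.names = FALSE))),
       results = results)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

mediation_table <- function(results) {
  if (!length(results)) {
    return(data.frame(exposure = character(0), mediator = character(0),
                      outcome = character(0), beta_em = numeric(0),
                      se_em = numeric(0), beta_mo = numeric(0),
                      se_mo = numeric(0), me = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p = numeric(0), total = numeric(0),
                      proportion_percent = numeric(0), n_boot = integer(0),
                      seed = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(lapply(results, function(r) {
    data.frame(exposure = r$exposure_id, mediator = r$mediator_id,
               outcome = r$outcome_id, beta_em = r$beta_em, se_em = r$se_em,
               beta_mo = r$beta_mo, se_mo = r$se_mo, me = r$me,
               ci_low = r$me_ci_low, ci_high = r$me_ci_high, p = r$me_p,
               total = r$total, proportion_percent = 100 * r$proportion,
               n_boot = r$n_boot, seed = r$seed, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}

#' Write forest-table TSVs, a manifest and a plain-text summary
#'
#' Emits one TSV per results table, a `manifest.tsv` listing every output
#' file with its MD5 checksum and row count, and a short `summary.txt`.
#' Output is deterministic: rerunning on identical results produces
#' byte-identical files.
#'
#' @param results named list of data frames (and optionally `mediation`, a
#'   list of `mediation_result`).
#' @param out_dir output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
generate_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      files <- c(files, write_tsv(x, file.path(out_dir, paste0(nm, ".tsv"))))
    }
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    rows = vapply(files, function(f) length(readLines(f)) - 1L, integer(1)),
    stringsAsFactors = FALSE)
  mpath <- file.path(out_dir, "manifest.tsv")
  write_tsv(manifest, mpath)
  lines <- c("mrmediate run summary",
             sprintf("tables: %d", length(files)),
             sprintf("%s: %d rows", manifest$file, manifest$rows))
  spath <- file.path(out_dir, "summary.txt")
  writeLines(lines, spath)
  invisible(c(files, mpath, spath))
}

#' Run the complete synthetic study end to end
#'
#' Simulates a multi-cohort study, runs the forward taxon and metabolite
#' screens against every outcome cohort, the reverse screen for identified
#' taxa, cross-trait LD-score regression between the exposure and the
#' outcome, and the mediation stage, then writes the full report. The run
#' is a pure function of the two configuration objects: identical
#' configurations (including seeds) give byte-identical output files.
#'
#' @param sim a [sim_config()].
#' @param cfg an [analysis_config()].
#' @param out_dir output directory for the report (optional; no files are
#'   written when `NULL`).
#' @return A list with the simulated `study`, `forward_taxa`,
#'   `forward_metabolites`, `reverse`, `ldsc` (or `NULL` when the rg is
#'   undefined), and `mediation` results.
#' @export
run_study <- function(sim = sim_config(), cfg = analysis_config(),
                      out_dir = NULL) {
  study <- simulate_study(sim)
  forward_taxa <- run_forward_mr(cfg, study$exposure, study$outcome, study$panel,
                                 n_tests = cfg$n_exposure_tests)
  forward_mets <- run_forward_mr(cfg, study$mediator, study$outcome, study$panel,
                                 n_tests = cfg$n_mediator_tests)
  identified_taxa <- forward_taxa$meta$exposure[
    forward_taxa$meta$status %in% c("significant", "suggestive")]
  taxa_ss <- Filter(function(s) attr(s, "trait_id") %in% identified_taxa,
                    study$exposure)
  reverse <- if (length(taxa_ss)) {
    run_reverse_mr(cfg, study$outcome, taxa_ss, study$panel)
  } else {
    run_forward_mr(cfg, list(), list(), study$panel)
  }
  ldsc <- tryCatch(
    cross_trait_ldsc(study$exposure[[1]], study$outcome[[1]], study$panel,
                     n_blocks = min(20L, floor(nrow(study$exposure[[1]]) / 2))),
    error = function(e) {
      message("ldsc: ", conditionMessage(e))
      NULL
    })
  exposure_stats <- stats::setNames(study$exposure[1],
                                    attr(study$exposure[[1]], "trait_id"))
  mediator_stats <- stats::setNames(study$mediator[1],
                                    attr(study$mediator[[1]], "trait_id"))
  mediation <- run_mediation_pipeline(cfg, forward_taxa$meta, forward_mets$meta,
                                      exposure_stats, mediator_stats,
                                      study$panel)
  out <- list(study = study, forward_taxa = forward_taxa,
              forward_metabolites = forward_mets, reverse = reverse,
              ldsc = ldsc, mediation = mediation)
  if (!is.null(out_dir)) {
    tables <- list(forward_taxa_cohort = forward_taxa$per_cohort,
                   forward_taxa_meta = forward_taxa$meta,
                   forward_metabolites_cohort = forward_mets$per_cohort,
                   forward_metabolites_meta = forward_mets$meta,
                   reverse_cohort = reverse$per_cohort,
                   reverse_meta = reverse$meta,
                   mediation_pairs = mediation$pairs,
                   mediation = mediation_table(mediation$results))
    if (!is.null(ldsc)) {
      tables$ldsc <- data.frame(trait1 = attr(study$exposure[[1]], "trait_id"),
                                trait2 = attr(study$outcome[[1]], "trait_id"),
                                m = ldsc$m, h2_1 = ldsc$h2_1, h2_2 = ldsc$h2_2,
                                rg = ldsc$rg, rg_se = ldsc$rg_se,
                                rg_p = ldsc$rg_p,
                                intercept1 = ldsc$intercept_1,
                                intercept2 = ldsc$intercept_2,
                                n_blocks = ldsc$n_blocks,
                                stringsAsFactors = FALSE)
    }
    generate_report(tables, out_dir)
    write_truth_record(study$truth, file.path(out_dir, "truth_record.tsv"))
  }
  invisible(out)
}
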