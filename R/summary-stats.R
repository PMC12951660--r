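#' GWAS summary statistics for one trait in one cohort
#'
#' A `summary_stats` object holds per-variant association records for a
#' single trait measured in a single cohort: the unit every other stage of
#' the pipeline consumes. Records are a data frame with one row per biallelic
#' SNP; effect sizes are per-SD for continuous traits and log-odds for binary
#' traits.
#'
#' @param records data frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`, and for binary traits `n_case`, `n_control`. `eaf` may
#'   be `NA`.
#' @param trait_id identifier for the trait (e.g. a bacterial taxon).
#' @param trait_type `"continuous"` or `"binary"`. Binary traits must carry
#'   `n_case`/`n_control` on every record.
#' @param cohort_id identifier for the source cohort.
#'
#' @return An object of class `summary_stats`: the validated record data
#'   frame with `trait_id`, `trait_type` and `cohort_id` attributes.
#'
#' @details Validation is strict: standard errors must be positive, p-values
#'   in (0, 1], alleles single distinct upper-case bases, variant ids unique,
#'   and `n_case + n_control == n` where both are present. Use
#'   [read_summary_stats()] for tolerant row-wise validation of external
#'   files.
#'
#' @seealso [read_summary_stats()], [write_summary_stats()]
#' @export
summary_stats <- function(records, trait_id, trait_type = c("continuous", "binary"),
                          cohort_id) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records <- normalise_record_columns(records)
  bad <- validate_snp_rows(records, trait_type)
  if (any(bad$mask)) {
    first <- which(bad$mask)[1L]
    stop("invalid summary-statistics record at row ", first, ": ",
         bad$reason[first], call. = FALSE)
  }
  if (anyDuplicated(records$variant_id)) {
    dup <- records$variant_id[duplicated(records$variant_id)][1L]
    stop("duplicate variant_id: ", dup, call. = FALSE)
  }
  structure(records,
            trait_id = trait_id, trait_type = trait_type, cohort_id = cohort_id,
            class = c("summary_stats", "data.frame"))
}

# Canonical internal columns in fixed order; chromosome as character,
# position integer-valued.
.ss_columns <- c("variant_id", "chromosome", "position", "effect_allele",
                 "other_allele", "eaf", "beta", "se", "pvalue", "n",
                 "n_case", "n_control")

normalise_record_columns <- function(records) {
  for (col in c("n_case", "n_control")) {
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  }
  if (is.null(records$eaf)) records$eaf <- NA_real_
  missing_cols <- setdiff(.ss_columns, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[.ss_columns]
  records$variant_id <- as.character(records$variant_id)
  records$chromosome <- as.character(records$chromosome)
  records$position <- as.numeric(records$position)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n", "n_case", "n_control")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  rownames(records) <- NULL
  records
}

# Row-wise validation; returns a logical mask of bad rows and a reason label
# per row (first failed check wins).
validate_snp_rows <- function(records, trait_type) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  flag <- function(cond, label) {
    cond[is.na(cond)] <- TRUE
    hit <- cond & is.na(reason)
    reason[hit] <<- label
  }
  base <- c("A", "C", "G", "T")
  flag(is.na(records$variant_id) | records$variant_id == "", "missing_variant_id")
  flag(!(records$effect_allele %in% base) | !(records$other_allele %in% base),
       "non_biallelic_snp")
  flag(records$effect_allele == records$other_allele, "identical_alleles")
  flag(!is.finite(records$beta), "missing_beta")
  flag(!is.finite(records$se) | records$se <= 0, "nonpositive_se")
  flag(!is.finite(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1,
       "pvalue_out_of_range")
  flag(!is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1),
       "eaf_out_of_range")
  flag(!is.finite(records$n) | records$n <= 0, "nonpositive_n")
  flag(!is.na(records$position) & records$position < 1, "bad_position")
  has_cc <- !is.na(records$n_case) & !is.na(records$n_control)
  flag(has_cc & abs(records$n_case + records$n_control - records$n) > 1e-6,
       "case_control_sum_mismatch")
  if (trait_type == "binary") {
    flag(!has_cc, "missing_case_control_counts")
  }
  list(mask = !is.na(reason), reason = reason)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: trait '%s' (%s), cohort '%s', %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"),
              attr(x, "cohort_id"), nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Accessors for summary-statistics metadata
#'
#' @param ss a [summary_stats] object.
#' @return The trait identifier, cohort identifier or trait type.
#' @name ss-accessors
NULL

#' @rdname ss-accessors
#' @export
trait_id <- function(ss) attr(ss, "trait_id")

#' @rdname ss-accessors
#' @export
cohort_id <- function(ss) attr(ss, "cohort_id")

#' @rdname ss-accessors
#' @export
trait_type <- function(ss) attr(ss, "trait_type")

# Keep attributes when subsetting rows.
ss_subset <- function(ss, keep) {
  out <- as.data.frame(ss)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_id = attr(ss, "trait_id"), trait_type = attr(ss, "trait_type"),
            cohort_id = attr(ss, "cohort_id"),
            class = c("summary_stats", "data.frame"))
}

# GWAS-SSF canonical header names used on disk, in write order, keyed by the
# internal column they map to.
.ssf_names <- c(variant_id = "variant_id", chromosome = "chromosome",
                position = "base_pair_location", effect_allele = "effect_allele",
                other_allele = "other_allele", eaf = "effect_allele_frequency",
                beta = "beta", se = "standard_error", pvalue = "p_value",
                n = "n", n_case = "n_case", n_control = "n_control")

# Alias table for common summary-statistics dialects (case-insensitive).
.ss_aliases <- list(
  variant_id = c("variant_id", "snp", "rsid", "rs_id", "markername", "id", "variant"),
  chromosome = c("chromosome", "chr", "chrom", "#chrom"),
  position = c("base_pair_location", "position", "bp", "pos", "base_pair"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1", "alt"),
  other_allele = c("other_allele", "oa", "a2", "nea", "non_effect_allele",
                   "allele2", "ref"),
  eaf = c("effect_allele_frequency", "eaf", "freq", "af", "maf", "a1freq"),
  beta = c("beta", "b", "effect", "effect_size"),
  se = c("standard_error", "se", "stderr", "sebeta"),
  pvalue = c("p_value", "p", "pval", "pvalue", "p.value"),
  n = c("n", "samplesize", "sample_size", "n_total"),
  n_case = c("n_case", "ncase", "n_cases", "cases"),
  n_control = c("n_control", "ncontrol", "n_controls", "controls")
)

match_ss_header <- function(header) {
  key <- tolower(gsub("[^a-z0-9#._]", "_", tolower(header)))
  out <- rep(NA_character_, length(header))
  taken <- character(0)
  for (canon in names(.ss_aliases)) {
    hit <- which(key %in% .ss_aliases[[canon]] & !(seq_along(key) %in% taken))
    if (length(hit)) {
      out[hit[1L]] <- canon
      taken <- c(taken, hit[1L])
    }
  }
  out
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads a GWAS-SSF-style tab-separated table, normalising common column
#' aliases (e.g. `SNP`/`rsid`, `BETA`/`b`, `P`/`pval`) to the canonical
#' names. Rows violating the record invariants (non-positive standard error,
#' p-value outside (0,1], indel or multi-allelic alleles, ...) are dropped,
#' not fatal; the per-reason drop counts are attached as the `"drop_log"`
#' attribute and reported via [message()].
#'
#' @param path path to a UTF-8, tab-separated file with a header line.
#' @inheritParams summary_stats
#' @return A validated [summary_stats] object; `attr(, "drop_log")` holds a
#'   named integer vector of rejected-row counts by reason.
#' @export
read_summary_stats <- function(path, trait_id, trait_type = c("continuous", "binary"),
                               cohort_id) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  canon <- match_ss_header(names(raw))
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  for (col in required) {
    if (!col %in% canon) {
      stop("required column missing from header: ", col, call. = FALSE)
    }
  }
  keep <- !is.na(canon)
  raw <- raw[keep]
  names(raw) <- canon[keep]
  for (col in setdiff(.ss_columns, names(raw))) raw[[col]] <- rep(NA, nrow(raw))
  records <- normalise_record_columns(raw)
  bad <- validate_snp_rows(records, trait_type)
  drop_log <- integer(0)
  if (any(bad$mask)) {
    drop_log <- table(bad$reason[bad$mask])
    drop_log <- stats::setNames(as.integer(drop_log), names(drop_log))
    message(sprintf("read_summary_stats: dropped %d of %d rows (%s)",
                    sum(bad$mask), nrow(records),
                    paste(names(drop_log), drop_log, sep = "=", collapse = ", ")))
    records <- records[!bad$mask, , drop = FALSE]
    rownames(records) <- NULL
  }
  if (anyDuplicated(records$variant_id)) {
    dup <- records$variant_id[duplicated(records$variant_id)][1L]
    stop("duplicate variant_id in ", path, ": ", dup, call. = FALSE)
  }
  out <- summary_stats(records, trait_id, trait_type, cohort_id)
  attr(out, "drop_log") <- drop_log
  out
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Writes the canonical GWAS-SSF column order (`variant_id`, `chromosome`,
#' `base_pair_location`, `effect_allele`, `other_allele`,
#' `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`,
#' `n_case`, `n_control`), with `NA` for missing fields. Numeric fields are
#' serialised at full double precision so `read_summary_stats()` on the
#' output reproduces the input exactly.
#'
#' @param ss a [summary_stats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ss, path) {
  df <- as.data.frame(ss)
  out <- data.frame(
    df$variant_id, ifelse(is.na(df$chromosome), "NA", df$chromosome),
    fmt_num(df$position), df$effect_allele, df$other_allele,
    fmt_num(df$eaf), fmt_num(df$beta), fmt_num(df$se), fmt_num(df$pvalue),
    fmt_num(df$n), fmt_num(df$n_case), fmt_num(df$n_control),
    stringsAsFactors = FALSE)
  names(out) <- unname(.ssf_names)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
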