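#' Simulate a block-diagonal AR(1) LD panel
#'
#' Variants are grouped into consecutive blocks of `block_size`; within a
#' block the allelic correlation decays as `rho^|j-k|` (AR(1)), across
#' blocks it is exactly zero. Positions are laid out so that variants within
#' a block all sit inside any 10,000-kb clumping window (1 kb spacing) while
#' blocks are separated by 20,000 kb, i.e. guaranteed outside it.
#'
#' @param n_variants number of variants.
#' @param block_size variants per LD block (the last block may be shorter).
#' @param rho within-block AR(1) correlation, `0 <= rho < 1`.
#' @param seed unused source of randomness (the panel is deterministic);
#'   accepted for interface symmetry with the other simulators.
#' @return An [ld_panel] with positive-definite correlation.
#' @export
simulate_ld_panel <- function(n_variants, block_size, rho, seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (n_variants < 1 || block_size < 1) {
    stop("n_variants and block_size must be positive", call. = FALSE)
  }
  block <- rep(seq_len(ceiling(n_variants / block_size)), each = block_size)[seq_len(n_variants)]
  within <- stats::ave(seq_len(n_variants), block, FUN = seq_along)
  r <- matrix(0, n_variants, n_variants)
  for (b in unique(block)) {
    idx <- which(block == b)
    k <- length(idx)
    r[idx, idx] <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
  }
  positions <- (block - 1) * 2e7 + (within - 1) * 1000 + 1
  ld_panel(sprintf("rs%d", seq_len(n_variants)), positions, r)
}

#' Configuration for the synthetic multi-cohort MR study
#'
#' Describes the simulated causal system: a continuous exposure (a bacterial
#' taxon abundance, SD units) measured in one cohort, a continuous mediator
#' (a plasma metabolite, SD units) in a second cohort, and a binary outcome
#' (insomnia, log-odds scale) in three case-control cohorts. Default sample
#' sizes mirror the emulated study sources: 5,959 for the microbiome GWAS,
#' 8,299 for the metabolite GWAS, and outcome cohorts of 4,801/405,229,
#' 234/413,908 and 3,972/52,665 cases/controls.
#'
#' @param n_variants total variants in the panel.
#' @param n_instruments variants with a direct effect on the exposure;
#'   placed one per LD block before doubling up, so clumping at r^2 < 0.001
#'   does not collapse distinct instruments.
#' @param n_mediator_instruments variants with a direct effect on the
#'   mediator only (the mediator's own instruments, needed to estimate the
#'   mediator-to-outcome leg).
#' @param ld_block_size,ld_rho LD panel structure (see [simulate_ld_panel()]).
#' @param h2_exposure,h2_mediator variance explained by the exposure and
#'   mediator instruments (defaults echo the modest instrument strength of
#'   microbiome GWAS).
#' @param theta_em true exposure-to-mediator effect (SD per SD).
#' @param theta_mo true mediator-to-outcome effect (log-odds per SD).
#' @param theta_dir true direct exposure-to-outcome effect (log-odds per SD).
#' @param pleiotropy_mean,pleiotropy_sd distribution of direct
#'   variant-to-outcome effects on the exposure instruments; mean 0 gives
#'   balanced pleiotropy, nonzero mean directional pleiotropy.
#' @param exposure_cohorts,mediator_cohorts,outcome_cohorts named lists of
#'   cohort descriptors: `list(n = ...)` for continuous traits,
#'   `list(n_case = ..., n_control = ...)` for the binary outcome.
#' @param exposure_id,mediator_id,outcome_id trait identifiers.
#' @param maf_range range of the uniform allele-frequency distribution.
#' @param noise_scale multiplier on the sampling noise (0 recovers the
#'   truth-implied marginal effects exactly; testing hook).
#' @param seed integer seed; the same seed reproduces the study bit for bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 300L,
                       n_instruments = 30L,
                       n_mediator_instruments = 30L,
                       ld_block_size = 5L,
                       ld_rho = 0.5,
                       h2_exposure = 0.08,
                       h2_mediator = 0.10,
                       theta_em = 0.3,
                       theta_mo = 0.2,
                       theta_dir = 0.14,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       exposure_cohorts = list(FINRISK = list(n = 5959)),
                       mediator_cohorts = list(CLSA = list(n = 8299)),
                       outcome_cohorts = list(
                         FinnGen = list(n_case = 4801, n_control = 405229),
                         PanUKB = list(n_case = 234, n_control = 413908),
                         GERA = list(n_case = 3972, n_control = 52665)),
                       exposure_id = "taxon_1",
                       mediator_id = "metabolite_1",
                       outcome_id = "insomnia",
                       maf_range = c(0.05, 0.5),
                       noise_scale = 1,
                       seed = 1L) {
  if (n_instruments > n_variants) {
    stop("n_instruments exceeds n_variants", call. = FALSE)
  }
  if (n_instruments + n_mediator_instruments > n_variants) {
    stop("instrument sets exceed the variant panel", call. = FALSE)
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)", call. = FALSE)
  sizes <- c(vapply(exposure_cohorts, function(x) sum(unlist(x)), numeric(1)),
             vapply(mediator_cohorts, function(x) sum(unlist(x)), numeric(1)),
             vapply(outcome_cohorts, function(x) sum(unlist(x)), numeric(1)))
  if (any(sizes <= 0)) stop("all cohort sample sizes must be positive", call. = FALSE)
  rm(sizes)
  structure(as.list(environment()), class = "sim_config")
}

# Effective sample size of a case-control GWAS on the log-odds scale.
n_effective <- function(n_case, n_control) 4 / (1 / n_case + 1 / n_control)

# Instrument placement: fill one slot per LD block before re-using blocks,
# so distinct instruments survive clumping.
place_instruments <- function(n_variants, block_size, k, offset = 0L) {
  block <- rep(seq_len(ceiling(n_variants / block_size)), each = block_size)[seq_len(n_variants)]
  within <- stats::ave(seq_len(n_variants), block, FUN = seq_along)
  ord <- order(within, block)
  ord[seq_len(k) + offset]
}

# Draw correlated noise z ~ MVN(0, R) exploiting the block structure.
block_mvn <- function(panel, n_draws = 1L) {
  m <- length(panel$variant_ids)
  z <- matrix(stats::rnorm(m * n_draws), m, n_draws)
  blocks <- split(seq_len(m), cumsum(c(TRUE, diff(panel$positions) > 1e6)))
  for (idx in blocks) {
    if (length(idx) > 1L) {
      L <- chol(panel$r[idx, idx, drop = FALSE])
      z[idx, ] <- crossprod(L, z[idx, , drop = FALSE])
    }
  }
  z
}

two_sided_p <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)

build_ss <- function(panel, maf, beta, se, trait_id, trait_type, cohort_id,
                     n, n_case = NA_real_, n_control = NA_real_,
                     effect_allele = "A", other_allele = "G") {
  m <- length(beta)
  records <- data.frame(
    variant_id = panel$variant_ids, chromosome = panel$chromosome,
    position = panel$positions,
    effect_allele = rep_len(effect_allele, m),
    other_allele = rep_len(other_allele, m),
    eaf = maf, beta = beta, se = se, pvalue = two_sided_p(beta / se),
    n = n, n_case = n_case, n_control = n_control,
    stringsAsFactors = FALSE)
  summary_stats(records, trait_id, trait_type, cohort_id)
}

#' Simulate a complete multi-cohort MR mediation study
#'
#' Generates GWAS summary statistics for the exposure, mediator and outcome
#' in every configured cohort, under an explicit causal chain: instruments
#' affect the exposure with effects `gamma`; the exposure shifts the
#' mediator by `theta_em` and the outcome directly by `theta_dir`; the
#' mediator shifts the outcome by `theta_mo`; pleiotropic variants may also
#' hit the outcome directly (`alpha`). Estimated betas are the truth-implied
#' marginal effects plus multivariate normal noise whose correlation equals
#' the LD panel and whose per-variant scale is the analytic standard error
#' \eqn{1/\sqrt{2 p_j (1-p_j) N}} (with the effective sample size
#' \eqn{N_{eff} = 4/(1/n_{case} + 1/n_{control})} for the binary outcome).
#' Cohorts receive independent noise; the same seed reproduces the study
#' exactly.
#'
#' @param cfg a [sim_config()].
#' @return A list with `exposure`, `mediator`, `outcome` (each a named list
#'   of [summary_stats] per cohort), the [ld_panel] `panel`, and `truth`, a
#'   `truth_record` holding the simulated estimands: `gamma`, `delta`
#'   (mediator instrument effects), `alpha`, `theta_em`, `theta_mo`,
#'   `theta_dir`, and the derived `theta_total = theta_dir +
#'   theta_em * theta_mo`, `true_me = theta_em * theta_mo`,
#'   `true_prop = true_me / theta_total`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    panel <- simulate_ld_panel(cfg$n_variants, cfg$ld_block_size, cfg$ld_rho)
    m <- cfg$n_variants
    maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    het <- 2 * maf * (1 - maf)

    # instrument effect magnitudes are drawn from a bounded uniform band
    # (0.8-1.2 before scaling to the target variance explained) so every
    # configured instrument is genuinely strong: n_instruments is then the
    # effective instrument count, not an upper bound diluted by near-null
    # effects
    draw_effects <- function(k, h2, idx) {
      raw <- stats::runif(k, 0.8, 1.2) * sample(c(-1, 1), k, replace = TRUE)
      if (!k) return(numeric(0))
      raw * sqrt(h2 / sum(het[idx] * raw^2))
    }
    gamma <- numeric(m)
    idx_x <- place_instruments(m, cfg$ld_block_size, cfg$n_instruments)
    gamma[idx_x] <- draw_effects(cfg$n_instruments, cfg$h2_exposure, idx_x)

    delta <- numeric(m)
    idx_m <- place_instruments(m, cfg$ld_block_size, cfg$n_mediator_instruments,
                               offset = cfg$n_instruments)
    delta[idx_m] <- draw_effects(cfg$n_mediator_instruments, cfg$h2_mediator,
                                 idx_m)

    # pleiotropy is expressed relative to the exposure-increasing allele:
    # a nonzero mean then survives the orientation step of MR-Egger
    alpha <- numeric(m)
    if (cfg$pleiotropy_sd > 0 || cfg$pleiotropy_mean != 0) {
      alpha[idx_x] <- sign(gamma[idx_x]) *
        stats::rnorm(cfg$n_instruments, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    }

    theta_total <- cfg$theta_dir + cfg$theta_em * cfg$theta_mo
    mu <- list(exposure = gamma,
               mediator = gamma * cfg$theta_em + delta,
               outcome = gamma * theta_total + delta * cfg$theta_mo + alpha)

    draw_cohort <- function(trait, trait_id, trait_type, cohort_id, spec) {
      if (trait_type == "binary") {
        n_case <- spec$n_case; n_control <- spec$n_control
        n <- n_case + n_control
        se <- 1 / sqrt(het * n_effective(n_case, n_control))
      } else {
        n <- spec$n; n_case <- NA_real_; n_control <- NA_real_
        se <- 1 / sqrt(het * n)
      }
      beta <- mu[[trait]] + cfg$noise_scale * se * drop(block_mvn(panel))
      build_ss(panel, maf, beta, se, trait_id, trait_type, cohort_id,
               n = n, n_case = n_case, n_control = n_control)
    }

    exposure <- mapply(function(id, spec) {
      draw_cohort("exposure", cfg$exposure_id, "continuous", id, spec)
    }, names(cfg$exposure_cohorts), cfg$exposure_cohorts, SIMPLIFY = FALSE)
    mediator <- mapply(function(id, spec) {
      draw_cohort("mediator", cfg$mediator_id, "continuous", id, spec)
    }, names(cfg$mediator_cohorts), cfg$mediator_cohorts, SIMPLIFY = FALSE)
    outcome <- mapply(function(id, spec) {
      draw_cohort("outcome", cfg$outcome_id, "binary", id, spec)
    }, names(cfg$outcome_cohorts), cfg$outcome_cohorts, SIMPLIFY = FALSE)

    truth <- structure(list(
      gamma = gamma, delta = delta, alpha = alpha,
      theta_em = cfg$theta_em, theta_mo = cfg$theta_mo,
      theta_dir = cfg$theta_dir,
      theta_total = theta_total,
      true_me = cfg$theta_em * cfg$theta_mo,
      true_prop = if (theta_total != 0) cfg$theta_em * cfg$theta_mo / theta_total else NA_real_,
      h2_exposure = cfg$h2_exposure, h2_mediator = cfg$h2_mediator,
      maf = maf, instrument_idx = idx_x, mediator_instrument_idx = idx_m,
      seed = cfg$seed), class = "truth_record")

    list(exposure = exposure, mediator = mediator, outcome = outcome,
         panel = panel, truth = truth)
  })
}

#' Serialise a truth record as a structured text file
#'
#' Writes one `name<TAB>value` line per field; vector fields are
#' comma-separated. Companion to [simulate_study()] so simulated studies can
#' be archived alongside their cohort files.
#'
#' @param truth a `truth_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  lines <- vapply(names(truth), function(nm) {
    paste0(nm, "\t", paste(fmt_num(as.numeric(truth[[nm]])), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate z-score pairs for LD-score regression
#'
#' Draws per-variant z-scores for two traits with no sample overlap:
#' `var(z1_j) = 1 + n1 h2_1 l_j / m`, `var(z2_j) = 1 + n2 h2_2 l_j / m` and
#' `cov(z1_j, z2_j) = rg sqrt(n1 n2 h2_1 h2_2) l_j / m`, where `l_j` is the
#' variant's LD score. Betas and standard errors are back-filled as
#' `z/sqrt(n)` and `1/sqrt(n)`.
#'
#' @param panel an [ld_panel] supplying the LD scores.
#' @param h2_1,h2_2 heritabilities in \[0, 1\].
#' @param rg genetic correlation in \[-1, 1\].
#' @param n1,n2 GWAS sample sizes.
#' @param m number of variants the heritability is spread over (defaults to
#'   the panel size).
#' @param seed integer seed.
#' @return A list of two [summary_stats] (`trait1`, `trait2`).
#' @export
simulate_ldsc_traits <- function(panel, h2_1, h2_2, rg, n1, n2,
                                 m = length(panel$variant_ids), seed = 1L) {
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1) {
    stop("heritabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(rg) > 1) stop("|rg| must not exceed 1", call. = FALSE)
  l <- panel$ld_scores
  a <- 1 + n1 * h2_1 * l / m
  d <- 1 + n2 * h2_2 * l / m
  cv <- rg * sqrt(n1 * n2 * h2_1 * h2_2) * l / m
  det <- a * d - cv^2
  if (any(det <= 0)) {
    stop("per-variant z covariance not positive semidefinite at variant ",
         panel$variant_ids[which(det <= 0)[1L]], call. = FALSE)
  }
  withr::with_seed(seed, {
    k <- length(l)
    u1 <- stats::rnorm(k)
    u2 <- stats::rnorm(k)
    z1 <- sqrt(a) * u1
    z2 <- (cv / sqrt(a)) * u1 + sqrt(d - cv^2 / a) * u2
    maf <- stats::runif(k, 0.05, 0.5)
    list(trait1 = build_ss(panel, maf, z1 / sqrt(n1), rep(1 / sqrt(n1), k),
                           "ldsc_trait1", "continuous", "sim", n = n1),
         trait2 = build_ss(panel, maf, z2 / sqrt(n2), rep(1 / sqrt(n2), k),
                           "ldsc_trait2", "continuous", "sim", n = n2))
  })
}
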