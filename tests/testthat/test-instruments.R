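test_that("p-value filtering is a strict-inequality subset preserving order", {
  ss <- make_ss(c("rs1", "rs2", "rs3"), beta = c(0.3, 0.2, 0.1), se = 0.04,
                pvalue = c(1e-7, 1e-5, 1e-3))
  expect_identical(filter_by_pvalue(ss, 5e-6)$variant_id, "rs1")
  expect_identical(filter_by_pvalue(ss, 1 - 1e-12)$variant_id, ss$variant_id)
  empty <- filter_by_pvalue(ss, 5e-6)[0, ]
  expect_identical(nrow(filter_by_pvalue(ss_all <- ss, 1e-10)), 0L)
  expect_error(filter_by_pvalue(ss, 0), "threshold")
})

test_that("the F-statistic is beta^2/se^2 and sign-invariant", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.5), 0)
  expect_equal(f_statistic(-0.3, 0.1), 9)
  expect_error(f_statistic(0.1, 0), "positive")
})

test_that("weak-instrument filtering excludes strictly below the cutoff", {
  ss <- make_ss(c("rs1", "rs2", "rs3"), beta = c(0.5, 0.3, sqrt(10) * 0.1),
                se = 0.1)  # F = 25, 9, 10
  kept <- filter_weak_instruments(ss, 10)
  expect_identical(kept$variant_id, c("rs1", "rs3"))
  strong <- make_ss(c("a", "b"), beta = c(1, 2), se = 0.01)
  expect_identical(filter_weak_instruments(strong, 10)$variant_id,
                   strong$variant_id)
  expect_identical(nrow(filter_weak_instruments(kept[0, ], 10)), 0L)
})

test_that("outcome-associated instruments are excluded by outcome p-value", {
  iv <- make_ss(c("rs1", "rs2", "rs3"), beta = 0.3, se = 0.04)
  outcome <- make_ss(c("rs1", "rs2"), beta = c(0.5, 0.01), se = 0.05,
                     pvalue = c(1e-8, 0.5))
  kept <- exclude_outcome_associated(iv, outcome, 5e-6)
  expect_identical(kept$variant_id, c("rs2", "rs3"))
})

test_that("greedy clumping keeps the best variant of each correlated pair", {
  r <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2)
  panel <- ld_panel(c("rs1", "rs2"), c(1000, 2000), r)
  ss <- make_ss(c("rs1", "rs2"), beta = c(0.4, 0.35), se = 0.05,
                pvalue = c(1e-8, 1e-7), position = c(1000, 2000))
  out <- ld_clump(ss, panel, window_kb = 10000, r2_max = 0.001)
  expect_identical(out$variant_id, "rs1")

  indep <- simulate_ld_panel(5, 1, 0)
  ss2 <- make_ss(indep$variant_ids, beta = rep(0.3, 5), se = 0.04,
                 position = indep$positions)
  expect_identical(ld_clump(ss2, indep, 10000, 0.001)$variant_id,
                   ss2$variant_id)
})

test_that("clumping satisfies the exhaustive pairwise-r2 oracle", {
  panel <- simulate_ld_panel(5, 5, 0.7)
  set.seed(11)
  p <- runif(5, 1e-9, 1e-5)
  ss <- make_ss(panel$variant_ids, beta = 0.3, se = 0.04, pvalue = p,
                position = panel$positions)
  r2_max <- 0.3
  out <- ld_clump(ss, panel, 10000, r2_max)
  kept <- out$variant_id
  r2 <- panel$r^2
  # no retained pair violates the r2 bound
  if (length(kept) > 1) {
    combos <- combn(kept, 2)
    expect_true(all(r2[t(combos)] < r2_max))
  }
  # every dropped variant conflicts with a retained, better-p variant
  dropped <- setdiff(ss$variant_id, kept)
  for (d in dropped) {
    better <- kept[ss$pvalue[match(kept, ss$variant_id)] <
                     ss$pvalue[match(d, ss$variant_id)]]
    expect_true(any(r2[d, better] >= r2_max))
  }
})

test_that("clumping is invariant to input row order", {
  panel <- simulate_ld_panel(12, 4, 0.8)
  set.seed(3)
  ss <- make_ss(panel$variant_ids, beta = 0.3, se = 0.04,
                pvalue = runif(12, 1e-9, 1e-4), position = panel$positions)
  out1 <- ld_clump(ss, panel, 10000, 0.2)
  perm <- ss_all <- ss[sample(12), ]
  out2 <- ld_clump(summary_stats(as.data.frame(perm), "trait", "continuous",
                                 "cohort"), panel, 10000, 0.2)
  expect_setequal(out1$variant_id, out2$variant_id)
})

test_that("variants missing from the panel are logged drops, not errors", {
  panel <- simulate_ld_panel(3, 1, 0)
  ss <- make_ss(c(panel$variant_ids, "rs_absent"), beta = 0.3, se = 0.04,
                position = c(panel$positions, 999))
  expect_warning(out <- ld_clump(ss, panel, 10000, 0.001), "missing")
  expect_identical(unname(attr(out, "clump_log")["not_in_panel"]), 1L)
  expect_false("rs_absent" %in% out$variant_id)
})

test_that("harmonisation aligns, flips, and drops per the allele rules", {
  iv <- make_ss("rs1", beta = 0.2, se = 0.04, effect_allele = "A",
                other_allele = "G")
  out_swap <- make_ss("rs1", beta = 0.1, se = 0.05, effect_allele = "G",
                      other_allele = "A", eaf = 0.3)
  h <- harmonise(iv, out_swap)
  expect_equal(h$b_y, -0.1)
  expect_true(h$flipped)

  out_mismatch <- make_ss("rs1", beta = 0.1, se = 0.05, effect_allele = "A",
                          other_allele = "C")
  h2 <- harmonise(iv, out_mismatch)
  expect_identical(nrow(h2), 0L)
  expect_identical(unname(attr(h2, "drop_log")["allele_mismatch"]), 1L)

  h3 <- harmonise(iv, make_ss("rs_other", beta = 0.1, se = 0.05))
  expect_identical(unname(attr(h3, "drop_log")["missing_in_outcome"]), 1L)
})

test_that("palindromic variants are dropped only inside the ambiguity window", {
  pal <- function(eaf) make_ss("rs1", beta = 0.2, se = 0.04,
                               effect_allele = "A", other_allele = "T",
                               eaf = eaf)
  out <- make_ss("rs1", beta = 0.1, se = 0.05, effect_allele = "A",
                 other_allele = "T")
  inside <- harmonise(pal(0.50), out, maf_halfwidth = 0.08)
  expect_identical(unname(attr(inside, "drop_log")["palindromic_ambiguous"]), 1L)
  edge <- harmonise(pal(0.42), out, maf_halfwidth = 0.08)
  expect_identical(unname(attr(edge, "drop_log")["palindromic_ambiguous"]), 1L)
  outside <- harmonise(pal(0.10), out, maf_halfwidth = 0.08)
  expect_identical(nrow(outside), 1L)
  missing_eaf <- harmonise(pal(NA), out, maf_halfwidth = 0.08)
  expect_identical(unname(attr(missing_eaf, "drop_log")["palindromic_ambiguous"]),
                   1L)
})

test_that("harmonising a dataset against itself is the identity", {
  set.seed(21)
  ss <- make_ss(sprintf("rs%d", 1:8), beta = rnorm(8), se = 0.05,
                eaf = runif(8, 0.1, 0.35))
  h <- harmonise(ss, ss)
  expect_identical(nrow(h), 8L)
  expect_identical(h$b_y, h$b_x)
  expect_false(any(h$flipped))
})

test_that("the selection pipeline accounts for every exposure record", {
  study <- simulate_study(sim_config(n_variants = 100, ld_block_size = 5,
                                     ld_rho = 0.6, n_instruments = 15,
                                     n_mediator_instruments = 0, seed = 4))
  cfg <- analysis_config()
  h <- select_instruments(study$exposure[[1]], study$outcome[[1]],
                          study$panel, cfg)
  expect_identical(nrow(h) + sum(attr(h, "drop_log")),
                   nrow(study$exposure[[1]]))
  expect_true(all(attr(h, "drop_log") >= 0))
})
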