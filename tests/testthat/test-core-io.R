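test_that("header-only input yields an empty summary_stats", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("variant_id", "chromosome", "base_pair_location",
                     "effect_allele", "other_allele",
                     "effect_allele_frequency", "beta", "standard_error",
                     "p_value", "n"), collapse = "\t"), f)
  ss <- read_summary_stats(f, "t", "continuous", "c")
  expect_s3_class(ss, "summary_stats")
  expect_identical(nrow(ss), 0L)
})

test_that("write then read is the identity on all fields", {
  set.seed(42)
  k <- 10L
  ss <- make_ss(sprintf("rs%d", 1:k), beta = rnorm(k), se = runif(k, 0.01, 0.1),
                eaf = c(runif(k - 1, 0.05, 0.95), NA),
                position = sort(sample.int(1e8, k)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, f)
  back <- read_summary_stats(f, "trait", "continuous", "cohort")
  expect_identical(rec(back), rec(ss))
  # single-record case, exercised separately for the degenerate shape
  one <- make_ss("rs1", beta = 0.1, se = 0.02, pvalue = 1e-7, n = 5000,
                 position = 1234)
  write_summary_stats(one, f)
  expect_identical(rec(read_summary_stats(f, "t", "continuous", "c")),
                   rec(one))
})

test_that("missing eaf is serialised as the literal NA", {
  ss <- make_ss("rs1", beta = 0.1, se = 0.02, eaf = NA, position = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, f)
  row <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_identical(row[6], "NA")
})

test_that("invalid rows are dropped and accounted for", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "variant_id\tchromosome\tbase_pair_location\teffect_allele\tother_allele\teffect_allele_frequency\tbeta\tstandard_error\tp_value\tn",
    "rs1\t1\t100\tA\tG\t0.3\t0.1\t0.02\t1e-7\t5000",
    "rs2\t1\t200\tA\tG\t0.3\t0.1\t0\t1e-7\t5000"), f)
  expect_message(ss <- read_summary_stats(f, "t", "continuous", "c"),
                 "dropped 1 of 2")
  expect_identical(nrow(ss), 1L)
  expect_identical(unname(attr(ss, "drop_log")["nonpositive_se"]), 1L)
})

test_that("validation accounts for every row (accepted + dropped = read)", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "rs1\t1\t100\tA\tG\t0.3\t0.1\t0.02\t1e-7\t5000",   # good
    "rs2\t1\t200\tA\tAG\t0.3\t0.1\t0.02\t1e-7\t5000",  # indel
    "rs3\t1\t300\tA\tA\t0.3\t0.1\t0.02\t1e-7\t5000",   # identical alleles
    "rs4\t1\t400\tA\tG\t0.3\t0.1\t0.02\t1.5\t5000",    # p out of range
    "rs5\t1\t500\tA\tG\t1.3\t0.1\t0.02\t1e-7\t5000",   # eaf out of range
    "rs6\t1\t600\tA\tG\t0.3\t0.1\t0.02\t1e-7\t5000")   # good
  writeLines(c("variant_id\tchromosome\tbase_pair_location\teffect_allele\tother_allele\teffect_allele_frequency\tbeta\tstandard_error\tp_value\tn",
               rows), f)
  ss <- suppressMessages(read_summary_stats(f, "t", "continuous", "c"))
  expect_identical(nrow(ss) + sum(attr(ss, "drop_log")), length(rows))
  expect_identical(ss$variant_id, c("rs1", "rs6"))
})

test_that("column aliases are normalised", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tEA\tNEA\tEAF\tBETA\tSE\tP\tN",
               "rs1\t2\t100\ta\tg\t0.25\t0.1\t0.02\t1e-7\t5000"), f)
  ss <- read_summary_stats(f, "t", "continuous", "c")
  expect_identical(ss$variant_id, "rs1")
  expect_identical(ss$effect_allele, "A")
  expect_equal(ss$beta, 0.1)
})

test_that("format and validation errors are specific", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tNEA\tSE\tP", "rs1\tA\tG\t0.02\t1e-7"), f)
  expect_error(read_summary_stats(f, "t", "continuous", "c"), "beta")
  writeLines(c("SNP\tEA\tNEA\tBETA\tSE\tP\tN",
               "rs1\tA\tG\t0.1\t0.02\t1e-7\t100",
               "rs1\tA\tG\t0.2\t0.02\t1e-7\t100"), f)
  expect_error(read_summary_stats(f, "t", "continuous", "c"), "rs1")
  expect_error(summary_stats(data.frame(variant_id = "rs1"), "t",
                             "continuous", "c"), "missing required column")
})

test_that("binary traits require case/control counts that sum to n", {
  expect_error(make_ss("rs1", 0.1, 0.02, trait_type = "binary"),
               "missing_case_control")
  ok <- make_ss("rs1", 0.1, 0.02, trait_type = "binary", n = 300,
                n_case = 100, n_control = 200)
  expect_identical(nrow(ok), 1L)
  expect_error(make_ss("rs1", 0.1, 0.02, trait_type = "binary", n = 300,
                       n_case = 100, n_control = 150), "sum_mismatch")
})

test_that("LD scores are recomputed row sums of squared correlations", {
  p1 <- ld_panel("rs1", 1, matrix(1, 1, 1))
  expect_equal(p1$ld_scores, c(rs1 = 1))
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  p2 <- ld_panel(c("rs1", "rs2"), c(1, 2), r2)
  expect_equal(unname(p2$ld_scores), c(1.25, 1.25))
  # AR(1), rho = 0.9: against direct double-loop summation
  rho <- 0.9
  r3 <- rho^abs(outer(1:3, 1:3, "-"))
  p3 <- ld_panel(c("a", "b", "c"), 1:3, r3)
  brute <- sapply(1:3, function(j) sum(r3[j, ]^2))
  expect_equal(unname(p3$ld_scores), brute, tolerance = 1e-12)
  expect_true(all(p3$ld_scores >= 1))
})

test_that("LD panel round-trips through its two-file representation", {
  panel <- simulate_ld_panel(7, 3, 0.6)
  vf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".tsv")
  write_ld_panel(panel, vf, mf)
  back <- read_ld_panel(vf, mf)
  expect_identical(back$variant_ids, panel$variant_ids)
  expect_equal(back$r, panel$r, tolerance = 1e-15)
  expect_equal(back$ld_scores, panel$ld_scores, tolerance = 1e-12)
})

test_that("malformed LD panels are rejected", {
  r <- matrix(c(1, 0.5, 0.4, 1), 2)
  expect_error(ld_panel(c("a", "b"), 1:2, r), "asymmetric")
  r2 <- matrix(c(1, 1.5, 1.5, 1), 2)
  expect_error(ld_panel(c("a", "b"), 1:2, r2), "outside")
  r3 <- diag(2); diag(r3) <- c(1, 0.9)
  expect_error(ld_panel(c("a", "b"), 1:2, r3), "diagonal")
  vf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tposition", "a\t1", "b\t2"), vf)
  writeLines(c("1\t0\t0", "0\t1\t0", "0\t0\t1"), mf)
  expect_error(read_ld_panel(vf, mf), "does not match")
})
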