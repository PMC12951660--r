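test_that("Wald ratios follow the first-order formula", {
  h <- make_h(b_x = 0.5, se_x = 0.05, b_y = 0.1, se_y = 0.02)
  w <- wald_ratios(h)
  expect_equal(w$ratio, 0.2)
  expect_equal(w$ratio_se, 0.04)
  expect_equal(w$weight, 1 / 0.04^2)

  h0 <- make_h(b_x = 0.5, se_x = 0.05, b_y = 0, se_y = 0.02)
  expect_equal(wald_ratios(h0)$ratio, 0)

  hneg <- make_h(b_x = -0.5, se_x = 0.05, b_y = -0.1, se_y = 0.02)
  expect_equal(wald_ratios(hneg)$ratio, 0.2)
  expect_equal(wald_ratios(hneg)$ratio_se, 0.04)

  hz <- make_h(b_x = c(0.5, 0), se_x = 0.05, b_y = c(0.1, 0.3), se_y = 0.02)
  expect_warning(wz <- wald_ratios(hz), "zero exposure")
  expect_identical(nrow(wz), 1L)
  expect_error(suppressWarnings(
    wald_ratios(make_h(0, 0.05, 0.1, 0.02))), "no usable")
})

test_that("IVW equals the closed-form weighted mean and degenerates sanely", {
  h1 <- make_h(0.5, 0.05, 0.1, 0.02)
  expect_warning(e1 <- ivw(wald_ratios(h1)), "single variant")
  expect_equal(e1$beta, 0.2)
  expect_equal(e1$se, 0.04)

  w2 <- wald_ratios(make_h(c(0.5, 0.25), 0.05, c(0.15, 0.075),
                           se_y = c(0.02, 0.03)))
  expect_equal(w2$ratio, c(0.3, 0.3))
  e2 <- ivw(w2, "re")
  expect_equal(e2$beta, 0.3)
  expect_equal(e2$se, ivw(w2, "fe")$se)  # Q = 0: random effects = fixed

  w3 <- make_h(rep(1, 3), 0.05, c(0.2, 0.4, 0.3), se_y = c(0.05, 0.1, 0.05))
  w3 <- wald_ratios(w3)
  wts <- c(400, 100, 400)
  expect_equal(ivw(w3, "fe")$beta, sum(wts * c(0.2, 0.4, 0.3)) / sum(wts),
               tolerance = 1e-12)
})

test_that("fixed-effects IVW matches the no-intercept WLS oracle", {
  set.seed(31)
  for (i in 1:20) {
    j <- sample(4:25, 1)
    h <- make_h(b_x = rnorm(j, 0.1, 0.05) + 0.2, se_x = 0.02,
                b_y = rnorm(j, 0.02, 0.02), se_y = runif(j, 0.005, 0.05))
    w <- wald_ratios(h)
    est <- ivw(w, "fe")
    fit <- lm(b_y ~ 0 + b_x, data = h, weights = 1 / h$se_y^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
    se_wls <- sqrt(vcov(fit)[1, 1]) / summary(fit)$sigma
    expect_equal(est$se, unname(se_wls), tolerance = 1e-10)
  }
})

test_that("Cochran's Q matches hand arithmetic and is null-calibrated", {
  w_id <- wald_ratios(make_h(c(0.5, 0.25), 0.05, c(0.15, 0.075),
                             se_y = c(0.02, 0.03)))
  q0 <- cochran_q(w_id)
  expect_equal(q0$q, 0)
  expect_equal(q0$p_q, 1)

  # two variants: ratios .2/.4, weights 400/100 -> beta .24, Q = 3.2
  w2 <- wald_ratios(make_h(rep(1, 2), 0.05, c(0.2, 0.4), se_y = c(0.05, 0.1)))
  q2 <- cochran_q(w2)
  expect_equal(q2$q, 3.2, tolerance = 1e-12)
  expect_equal(q2$p_q, pchisq(3.2, 1, lower.tail = FALSE))

  expect_error(cochran_q(wald_ratios(make_h(1, 0.05, 0.2, 0.05))), "at least 2")

  set.seed(17)
  pvals <- replicate(1000, {
    se <- runif(10, 0.02, 0.08)
    w <- wald_ratios(make_h(rep(1, 10), 0.01, rnorm(10, 0.1, se), se_y = se))
    cochran_q(w)$p_q
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("MR-Egger recovers exact linear data and respects orientation", {
  set.seed(5)
  bx <- runif(6, 0.05, 0.3)
  h <- make_h(bx, 0.02, 0.05 + 0.3 * bx, se_y = runif(6, 0.01, 0.05))
  e <- mr_egger(h)
  expect_equal(e$estimate$beta, 0.3, tolerance = 1e-10)
  expect_equal(e$intercept, 0.05, tolerance = 1e-10)

  # flipping the sign of (b_x, b_y) pairs must not change the fit
  flip <- sample(c(-1, 1), 6, replace = TRUE)
  hf <- make_h(bx * flip, 0.02, (0.05 + 0.3 * bx) * flip,
               se_y = h$se_y)
  ef <- mr_egger(hf)
  expect_equal(ef$estimate$beta, e$estimate$beta, tolerance = 1e-12)
  expect_equal(ef$intercept, e$intercept, tolerance = 1e-12)

  expect_error(mr_egger(make_h(c(1, 2), 0.05, c(0.2, 0.4), 0.05)), "at least 3")
  expect_error(mr_egger(make_h(rep(1, 4), 0.05, c(0.2, 0.4, 0.3, 0.25), 0.05)),
               "singular")
})

test_that("the Egger intercept test is calibrated under balanced pleiotropy", {
  reject <- logical(400)
  for (r in seq_along(reject)) {
    study <- simulate_study(null_sim_config(seed = 5000 + r,
                                            pleiotropy_mean = 0,
                                            pleiotropy_sd = 0.01))
    h <- harmonise(filter_by_pvalue(study$exposure[[1]], 5e-6),
                   study$outcome[[1]])
    reject[r] <- mr_egger(h)$p_intercept < 0.05
  }
  rate <- mean(reject)
  band <- qnorm(0.995) * sqrt(0.05 * 0.95 / length(reject))
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})

test_that("the Egger intercept test detects directional pleiotropy", {
  reject <- logical(200)
  for (r in seq_along(reject)) {
    study <- simulate_study(null_sim_config(seed = 7000 + r,
                                            pleiotropy_mean = 0.05,
                                            pleiotropy_sd = 0.01))
    h <- harmonise(filter_by_pvalue(study$exposure[[1]], 5e-6),
                   study$outcome[[1]])
    reject[r] <- mr_egger(h)$p_intercept < 0.05
  }
  expect_gt(mean(reject), 0.5)
})

test_that("the weighted median interpolates the cumulative weight at 0.5", {
  w3 <- wald_ratios(make_h(rep(1, 3), 0.02, c(0.1, 0.2, 0.9), se_y = 0.05))
  wm <- weighted_median(w3, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.2)

  w_id <- wald_ratios(make_h(rep(1, 3), 0.02, rep(0.25, 3), se_y = 0.05))
  expect_equal(weighted_median(w_id, n_boot = 200, seed = 1)$beta, 0.25)

  # 4 unequal weights: brute-force re-derivation of the interpolation
  ratio <- c(0.05, 0.2, 0.3, 0.6)
  se <- c(0.02, 0.05, 0.03, 0.1)
  w4 <- wald_ratios(make_h(rep(1, 4), 0.02, ratio, se_y = se))
  wt <- 1 / se^2
  ord <- order(ratio)
  p <- wt[ord] / sum(wt)
  s <- cumsum(p) - p / 2
  k <- max(which(s < 0.5))
  brute <- ratio[ord][k] + (ratio[ord][k + 1] - ratio[ord][k]) *
    (0.5 - s[k]) / (s[k + 1] - s[k])
  expect_equal(weighted_median(w4, n_boot = 200, seed = 1)$beta, brute,
               tolerance = 1e-12)

  expect_identical(weighted_median(w4, n_boot = 300, seed = 9)$se,
                   weighted_median(w4, n_boot = 300, seed = 9)$se)
  expect_error(weighted_median(wald_ratios(make_h(c(1, 1), 0.02, c(0.2, 0.3),
                                                  0.05)), 100, 1), "at least 3")
})

test_that("MR-PRESSO flags an implanted outlier and needs four variants", {
  set.seed(13)
  j <- 20
  bx <- abs(rnorm(j, 0.1, 0.02))
  se_y <- rep(0.01, j)
  by <- 0.2 * bx + rnorm(j, 0, se_y)
  by[5] <- by[5] + 10 * se_y[5]
  h <- make_h(bx, 0.02, by, se_y)
  res <- mr_presso(h, n_sim = 1000, seed = 2)
  expect_true(h$variant_id[5] %in% res$outliers)
  expect_lt(res$global_p, 0.05)
  expect_false(is.null(res$corrected))
  expect_lt(res$corrected$n_snp, j)

  res2 <- mr_presso(h, n_sim = 1000, seed = 2)
  expect_identical(res$global_p, res2$global_p)

  expect_error(mr_presso(make_h(c(1, 2, 3), 0.05, c(0.2, 0.4, 0.6), 0.05)),
               "at least 4")
})

test_that("every estimator returns the Wald ratio when all ratios coincide", {
  bx <- c(0.1, 0.2, 0.4, 0.5)
  h <- make_h(bx, 0.02, 0.25 * bx, se_y = 0.03)
  w <- wald_ratios(h)
  expect_equal(ivw(w, "fe")$beta, 0.25, tolerance = 1e-12)
  expect_equal(ivw(w, "re")$beta, 0.25, tolerance = 1e-12)
  expect_equal(weighted_median(w, 100, 1)$beta, 0.25, tolerance = 1e-12)
  expect_equal(mr_egger(h)$estimate$beta, 0.25, tolerance = 1e-8)
})

test_that("the sensitivity panel bundles consistent diagnostics", {
  study <- simulate_study(null_sim_config(seed = 77, theta_dir = 0.2))
  cfg <- analysis_config(n_boot = 200, n_sim = 200, seed = 3)
  h <- select_instruments(study$exposure[[1]], study$outcome[[1]],
                          study$panel, cfg)
  sp <- sensitivity_panel(h, cfg)
  expect_identical(sp$n_snp, nrow(h))
  expect_identical(sp$ivw$n_snp, sp$n_snp)
  expect_identical(sp$egger$n_snp, sp$n_snp)
  expect_true(sp$p_q > 0 && sp$p_q <= 1)
  expect_true(sp$presso_global_p > 0 && sp$presso_global_p <= 1)
  sp2 <- sensitivity_panel(h, cfg)
  expect_identical(sp$wm$se, sp2$wm$se)
})
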