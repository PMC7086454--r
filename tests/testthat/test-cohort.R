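test_that("hwe_test recovers exact equilibrium and strong disequilibrium", {
  # (81, 18, 1): q = 0.1, expected counts equal observed exactly
  r <- hwe_test(81, 18, 1)
  expect_equal(r$q, 0.1)
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  # validation-cohort control distribution is comfortably in equilibrium
  r2 <- hwe_test(215, 35, 0)
  expect_gt(r2$p, 0.05)
  expect_equal(r2$p, 0.234, tolerance = 0.005)

  # all-homozygote table: chi2 = n, emphatic rejection
  r3 <- hwe_test(50, 0, 50)
  expect_equal(r3$chi2, 100, tolerance = 1e-9)
  expect_lt(r3$p, 1e-10)

  # monomorphic convention
  expect_equal(hwe_test(100, 0, 0), list(chi2 = 0, p = 1, q = 0))
})

test_that("hwe chi-square equals the longhand expected-count computation", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(20:400, 1)
    q <- runif(1, 0.02, 0.5)
    g <- rbinom(n, 2, q)
    n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
    if (n1 + 2 * n2 == 0) next
    qhat <- (n1 + 2 * n2) / (2 * n)
    e <- c(n * (1 - qhat)^2, 2 * n * qhat * (1 - qhat), n * qhat^2)
    o <- c(n0, n1, n2)
    chi2 <- sum((o - e)^2 / e)
    expect_equal(hwe_test(n0, n1, n2)$chi2, chi2, tolerance = 1e-12)
  }
})

test_that("exact HWE test is a proper tail probability near the chi-square", {
  ex <- hwe_test(215, 35, 0, method = "exact")
  expect_true(ex$p > 0 && ex$p <= 1)
  expect_gt(ex$p, 0.05)
  # at a common-allele balanced table the two methods roughly agree
  ch <- hwe_test(180, 95, 25)
  ex2 <- hwe_test(180, 95, 25, method = "exact")
  expect_equal(ex2$p, ch$p, tolerance = 0.25)
})

test_that("chi2_sf reproduces the published conversions and the 2-df identity", {
  expect_equal(signif(chi2_sf(12.5, 2), 2), 0.0019)
  expect_equal(signif(chi2_sf(7.28, 2), 2), 0.026)
  expect_equal(round(chi2_sf(7.30, 2), 2), 0.03)
  expect_equal(chi2_sf(0, 1), 1)
  expect_equal(chi2_sf(0, 5), 1)
  x <- seq(0, 50, by = 0.5)
  expect_equal(chi2_sf(x, 2), exp(-x / 2), tolerance = 1e-12)
})

test_that("2x3 association drops empty classes and matches the oracle", {
  # identical distributions
  same <- genotype_assoc_2x3(c(50, 40, 10), c(50, 40, 10))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # published-count example (recomputed value; the printed statistic for
  # this table is not reproducible from its counts)
  a <- genotype_assoc_2x3(c(212, 36, 2), c(238, 12, 0))
  o <- oracle_pearson_chi2(rbind(c(212, 36, 2), c(238, 12, 0)))
  expect_equal(a$chi2, o$chi2, tolerance = 1e-12)
  expect_equal(a$df, 2)
  expect_equal(round(a$chi2, 2), 15.50)

  # dosage-2 column empty in both groups -> collapses to 2x2, df = 1
  b <- genotype_assoc_2x3(c(235, 15, 0), c(215, 35, 0))
  expect_equal(b$df, 1)

  expect_error(genotype_assoc_2x3(c(10, 0, 0), c(20, 0, 0)), "degenerate")
})

test_that("2x3 association equals the generic Pearson oracle on random tables", {
  set.seed(21)
  for (i in 1:1000) {
    m <- matrix(rpois(6, 30) + 1, nrow = 2)
    got <- genotype_assoc_2x3(m[1, ], m[2, ])
    o <- oracle_pearson_chi2(m)
    expect_equal(got$chi2, o$chi2, tolerance = 1e-10)
    expect_equal(got$df, o$df)
  }
})

test_that("allelic OR reproduces the published rs16866133 estimate", {
  r <- allelic_or(c(247, 3, 0), c(235, 15, 0))
  expect_equal(r$a, 3)
  expect_equal(r$c, 15)
  expect_equal(r$or, (3 * 485) / (497 * 15), tolerance = 1e-12)
  expect_equal(round(r$or, 2), 0.20)
  expect_false(r$haldane)
})

test_that("allelic OR symmetry, scaling invariance and Haldane fallback", {
  r <- allelic_or(c(200, 40, 10), c(220, 28, 2))
  s <- allelic_or(c(220, 28, 2), c(200, 40, 10))
  expect_equal(s$or, 1 / r$or, tolerance = 1e-12)

  sc <- allelic_or(3 * c(200, 40, 10), 3 * c(220, 28, 2))
  expect_equal(sc$or, r$or, tolerance = 1e-12)

  h <- allelic_or(c(250, 0, 0), c(240, 10, 0))
  expect_true(h$haldane)
  expect_true(is.finite(h$or) && h$or > 0)
  expect_equal(h$or, (0.5 * 490.5) / (500.5 * 10.5), tolerance = 1e-12)
  expect_true(is.finite(h$ci95_low) && is.finite(h$ci95_high))

  expect_error(allelic_or(c(10, 0, 0), c(10, 0, 0)), "undefined")
})

test_that("genotype frequencies round half-up to one decimal", {
  expect_equal(genotype_frequencies(c(212, 36, 2)), c(84.8, 14.4, 0.8))
  expect_equal(genotype_frequencies(c(1, 0, 0)), c(100, 0, 0))
  # 1/8 = 12.5%: half-up keeps the 5
  expect_equal(genotype_frequencies(c(7, 1, 0)), c(87.5, 12.5, 0))
  set.seed(2)
  for (i in 1:1000) {
    cnt <- rmultinom(1, sample(10:500, 1), c(0.7, 0.25, 0.05))[, 1]
    expect_equal(sum(genotype_frequencies(cnt)), 100, tolerance = 0.1)
  }
})

test_that("response classification follows the platelet criteria", {
  expect_equal(classify_response(10, 120), "complete_response")
  expect_equal(classify_response(20, 50), "response")
  expect_equal(classify_response(12, 28), "nonresponse")  # doubled but < 30
  expect_equal(classify_response(25, 40), "nonresponse")  # >= 30 but < 2x
  expect_equal(classify_response(25, 40, rule = "inclusive"), "response")
  expect_equal(classify_response(12, 28, rule = "inclusive"), "response")
  expect_error(classify_response(-1, 50), ">= 0")
})

test_that("response association mirrors the published qualitative calls", {
  # rs16866133 response table: tiny statistic, clearly non-significant
  r <- response_assoc(c(119, 4, 0), c(63, 0, 0))
  expect_gt(r$p, 0.05)
  expect_lt(r$chi2, 3)
  same <- response_assoc(c(60, 30, 10), c(60, 30, 10))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  # equals the generic oracle on a toy table
  t1 <- response_assoc(c(30, 10, 2), c(20, 18, 5))
  o <- oracle_pearson_chi2(rbind(c(30, 10, 2), c(20, 18, 5)))
  expect_equal(t1$chi2, o$chi2, tolerance = 1e-12)
})

test_that("timepoint comparison flags separated trajectories", {
  days <- c(1, 3, 5, 7, 11, 14)
  # identical groups -> p = 1 everywhere
  a <- matrix(rep(c(10, 20, 40, 60, 70, 75), each = 4), nrow = 4)
  res <- timepoint_compare(a, a, days)
  expect_true(all(res$p == 1))

  # separated plateaus with negligible noise: significant from day 5 on
  sim <- simulate_case_control_genotypes(60, 60, maf_control = 0.3,
                                         or_allelic = 1, seed = 4)
  coh <- sim$cohort
  coh$group <- NULL
  coh <- simulate_treatment_response(
    coh, "snp1", response_prob_by_dosage = c(1, 1),
    trajectory_params = list(noise_sd = 0.1,
                             plateau_by_dosage = c(40, 120)),
    seed = 4)
  carrier <- coh$snp1 >= 1
  plt <- as.matrix(coh[, sprintf("plt_d%d", days)])
  res2 <- timepoint_compare(plt[carrier, ], plt[!carrier, ], days)
  expect_true(all(res2$sig01[res2$day >= 5]))
})

test_that("permuted labels give approximately uniform per-day p-values", {
  set.seed(31)
  sim <- simulate_case_control_genotypes(40, 40, maf_control = 0.3,
                                         or_allelic = 1, seed = 8)
  coh <- simulate_treatment_response(sim$cohort, "snp1", seed = 8)
  days <- c(1, 3, 5, 7, 11, 14)
  plt <- as.matrix(coh[, sprintf("plt_d%d", days)])
  ps <- replicate(200, {
    lab <- sample(c(rep(TRUE, 40), rep(FALSE, 40)))
    timepoint_compare(plt[lab, ], plt[!lab, ], days)$p[3]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})
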