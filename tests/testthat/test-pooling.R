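test_that("compute_raf is the green-channel share", {
  expect_equal(compute_raf(300, 100), 0.75)
  expect_equal(compute_raf(0, 500), 0)
  expect_equal(compute_raf(c(1, 10, 1000), c(1, 10, 1000)),
               rep(0.5, 3))                  # symmetry at equal channels
  expect_true(is.na(compute_raf(0, 0)))      # failed hybridization marker
})

test_that("qc_filter drops failed rows, low-replicate SNPs and non-autosomes", {
  tab <- make_intensity_fixture()             # 3 clean SNPs on 1,2,3
  # SNP with a failed case replicate -> only 2 case reps survive -> dropped
  s4 <- data.frame(snp_id = "s4", chrom = "4", pos = 4000L,
                   pool = rep(c("case", "control"), each = 3),
                   replicate = rep(1:3, 2),
                   green_raw = c(0, 500, 500, 500, 500, 500),
                   red_raw = c(0, 500, 500, 500, 500, 500))
  # SNP on chrY -> dropped
  s5 <- data.frame(snp_id = "s5", chrom = "chrY", pos = 5000L,
                   pool = rep(c("case", "control"), each = 3),
                   replicate = rep(1:3, 2),
                   green_raw = 400, red_raw = 600)
  out <- qc_filter(rbind(tab, s4, s5), min_replicates = 3)
  expect_setequal(unique(out$snp_id), c("s1", "s2", "s3"))
  rep <- qc_report(out)
  expect_equal(rep$n_failed_rows, 1L)
  expect_equal(rep$n_nonautosomal_snps, 1L)
  expect_equal(rep$n_low_replicate_snps, 1L)
  expect_equal(rep$n_retained_snps, 3L)
})

test_that("qc_filter requires min replicates in EITHER pool (3/2 drops)", {
  tab <- make_intensity_fixture()
  drop_one <- tab[!(tab$snp_id == "s2" & tab$pool == "control" &
                      tab$replicate == 3), ]
  out <- qc_filter(drop_one, min_replicates = 3)
  expect_setequal(unique(out$snp_id), c("s1", "s3"))
})

test_that("chrX loci are non-autosomal regardless of label style", {
  tab <- make_intensity_fixture()
  tab$chrom[tab$snp_id == "s1"] <- "X"
  tab$chrom[tab$snp_id == "s2"] <- "chrX"
  out <- qc_filter(tab)
  expect_equal(unique(out$snp_id), "s3")
  expect_equal(qc_report(out)$n_nonautosomal_snps, 2L)
})

test_that("summarize_pools matches the closed-form variance terms", {
  tab <- data.frame(
    snp_id = "s1", chrom = "1", pos = 100L,
    pool = rep(c("case", "control"), each = 3), replicate = rep(1:3, 2),
    green_raw = 1000 * c(0.4, 0.5, 0.6, 0.5, 0.5, 0.5),
    red_raw = 1000 * c(0.6, 0.5, 0.4, 0.5, 0.5, 0.5)
  )
  s <- summarize_pools(tab, N_case = 200, N_control = 200)
  expect_equal(s$f_case, 0.5, tolerance = 1e-12)
  expect_equal(s$f_control, 0.5, tolerance = 1e-12)
  expect_equal(s$v_case, 0.5 * 0.5 / 400, tolerance = 1e-12)
  expect_equal(s$eps2_case, (0.01 + 0 + 0.01) / 6, tolerance = 1e-12)
  expect_equal(s$eps2_control, 0)          # identical replicates
})

test_that("summarize_pools equals brute-force recomputation on 100 SNPs", {
  sim <- simulate_pooled_experiment(n_snps = 100, n_spiked = 5, seed = 42)
  tab <- qc_filter(sim$table)
  s <- summarize_pools(tab, 200, 200)
  o <- oracle_summary(tab, 200, 200)
  o <- o[match(s$snp_id, o$snp_id), ]
  expect_equal(s$f_case, o$f_case, tolerance = 1e-12)
  expect_equal(s$f_control, o$f_control, tolerance = 1e-12)
  expect_equal(s$v_case, o$v_case, tolerance = 1e-12)
  expect_equal(s$v_control, o$v_control, tolerance = 1e-12)
  expect_equal(s$eps2_case, o$eps2_case, tolerance = 1e-12)
  expect_equal(s$eps2_control, o$eps2_control, tolerance = 1e-12)
})

test_that("combined Z-test identities hold", {
  base <- data.frame(snp_id = "s", chrom = "1", pos = 1L,
                     f_case = 0.3, f_control = 0.3,
                     n_case_reps = 3L, n_control_reps = 3L,
                     v_case = 0.3 * 0.7 / 400, v_control = 0.3 * 0.7 / 400,
                     eps2_case = 1e-4, eps2_control = 1e-4)
  # equal means: everything zero, p = 1
  z0 <- combined_z_test(base)
  expect_equal(z0$t1, 0)
  expect_equal(z0$tcomb, 0)
  expect_equal(z0$p_value, 1)

  # zero replicate error: tcomb equals t1 exactly
  b <- base
  b$f_case <- 0.35
  b$eps2_case <- 0
  b$eps2_control <- 0
  b$v_case <- 0.35 * 0.65 / 400
  z1 <- combined_z_test(b)
  expect_identical(z1$tcomb, z1$t1)

  # worked case agrees with the independent evaluator to 1e-12
  b2 <- base
  b2$f_case <- 0.30; b2$f_control <- 0.25
  b2$v_case <- 0.30 * 0.70 / 400; b2$v_control <- 0.25 * 0.75 / 400
  b2$eps2_case <- 1e-4; b2$eps2_control <- 1e-4
  z2 <- combined_z_test(b2)
  o <- oracle_pool_test(0.30, 0.25, 200, 200, 1e-4, 1e-4)
  expect_equal(z2$tcomb, o$tcomb, tolerance = 1e-12)
  expect_equal(z2$t1, o$t1, tolerance = 1e-12)
  expect_equal(z2$z, o$z, tolerance = 1e-12)
})

test_that("pool swap leaves t1/tcomb fixed and negates z and delta", {
  sim <- simulate_pooled_experiment(n_snps = 50, n_spiked = 10, seed = 7)
  s <- summarize_pools(qc_filter(sim$table), 200, 200)
  z <- combined_z_test(s)
  swapped <- s
  swapped[c("f_case", "f_control")] <- s[c("f_control", "f_case")]
  swapped[c("v_case", "v_control")] <- s[c("v_control", "v_case")]
  swapped[c("eps2_case", "eps2_control")] <- s[c("eps2_control", "eps2_case")]
  zs <- combined_z_test(swapped)
  expect_equal(zs$t1, z$t1, tolerance = 1e-12)
  expect_equal(zs$tcomb, z$tcomb, tolerance = 1e-12)
  expect_equal(zs$z, -z$z, tolerance = 1e-12)
  expect_equal(zs$delta_raf, -z$delta_raf, tolerance = 1e-12)
})

test_that("tcomb never exceeds t1 and is monotone in replicate error", {
  set.seed(11)
  f1 <- runif(200, 0.05, 0.95); f2 <- runif(200, 0.05, 0.95)
  s <- data.frame(snp_id = paste0("r", 1:200), chrom = "1", pos = 1:200,
                  f_case = f1, f_control = f2,
                  n_case_reps = 3L, n_control_reps = 3L,
                  v_case = f1 * (1 - f1) / 400, v_control = f2 * (1 - f2) / 400,
                  eps2_case = runif(200, 0, 1e-3),
                  eps2_control = runif(200, 0, 1e-3))
  z <- combined_z_test(s)
  expect_true(all(z$tcomb <= z$t1 + 1e-15))
  s_bigger <- s
  s_bigger$eps2_case <- s$eps2_case + 5e-4
  expect_true(all(combined_z_test(s_bigger)$tcomb <= z$tcomb + 1e-15))
})

test_that("degenerate all-zero-variance SNPs take the flagged path", {
  s <- data.frame(snp_id = c("same", "diff"), chrom = "1", pos = 1:2,
                  f_case = c(1, 1), f_control = c(1, 0),
                  n_case_reps = 3L, n_control_reps = 3L,
                  v_case = 0, v_control = 0,
                  eps2_case = 0, eps2_control = 0)
  z <- combined_z_test(s)
  expect_equal(z$p_value[1], 1)
  expect_false(z$flag_infinite[1])
  expect_true(z$flag_infinite[2])
  expect_equal(z$p_value[2], .Machine$double.xmin)
})

test_that("genome-wide selection is strict and sorted", {
  res <- data.frame(snp_id = letters[1:6],
                    p_value = c(8.06e-8, 6.45e-9, 9.39e-8, 1e-7, 2e-7, 0.5))
  hits <- genomewide_hits(res, alpha = 1e-7)
  expect_equal(hits$snp_id, c("b", "a", "c"))   # p == alpha excluded
  expect_equal(nrow(genomewide_hits(res[0, ], 1e-7)), 0L)
})

test_that("qq_points pairs sorted observed with null quantiles", {
  one <- qq_points(0.01)
  expect_equal(one$expected, -log10(0.5), tolerance = 1e-12)
  expect_equal(one$observed, 2)

  grid <- qq_points(seq(0.1, 0.9, by = 0.1))
  expect_true(max(abs(grid$observed - grid$expected)) < 0.31)

  expect_equal(nrow(qq_points(numeric(0))), 0L)
  expect_warning(clamped <- qq_points(c(0, 0.5)), "clamped")
  expect_true(all(is.finite(clamped$observed)))
})

test_that("manhattan coordinates accumulate chromosome offsets", {
  res <- data.frame(snp_id = c("a", "b", "c"),
                    chrom = c("1", "2", "2"),
                    pos = c(50, 10, 30),
                    p_value = c(0.1, 0.01, 1))
  mp <- manhattan_points(res, chrom_lengths = c(`1` = 100, `2` = 100))
  expect_equal(mp$genome_pos, c(50, 110, 130))
  expect_equal(mp$neglog10_p, -log10(res$p_value))
})

test_that("raf_correlation is squared Pearson r", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.45, 0.5, 0.6, 0.7, 0.8, 0.9)
  y <- c(0.12, 0.18, 0.33, 0.38, 0.47, 0.52, 0.58, 0.72, 0.79, 0.91)
  # textbook formula evaluated longhand
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(raf_correlation(x, y), r^2, tolerance = 1e-12)
  expect_equal(raf_correlation(x, x), 1)
  expect_equal(raf_correlation(c(0, 1), c(1, 0)), 1)  # r = -1, r^2 = 1
  expect_error(raf_correlation(c(1, 1), c(0, 1)), "zero variance")
})
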