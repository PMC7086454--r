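# Stage-2 validation-cohort statistics: Hardy-Weinberg tests, 2x3
# genotype association, allelic odds ratios, glucocorticoid-response
# classification, and per-timepoint platelet comparisons.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Estimates the minor-allele frequency `q = (n1 + 2 n2) / (2n)` from the
#' genotype counts, forms expected counts `n (1-q)^2, 2 n q (1-q), n q^2`,
#' and compares with a 1-df chi-square (3 cells, 1 estimated parameter).
#' A cell with expected 0 and observed 0 contributes nothing. A
#' monomorphic marker (q of 0 or 1) is in trivial equilibrium: chi2 = 0,
#' p = 1. `method = "exact"` runs the standard exact HWE test (conditional
#' on allele counts, summing genotype configurations no more probable than
#' the observed one) for rare-allele tables where the chi-square
#' approximation is poor.
#'
#' @param n0,n1,n2 Counts of minor-allele dosage 0, 1, 2.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return List with `chi2` (NA for exact), `p`, `q`.
#' @export
hwe_test <- function(n0, n1, n2, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n0 + n1 + n2
  if (n < 1) stop("need at least one genotyped subject")
  q <- (n1 + 2 * n2) / (2 * n)
  if (q == 0 || q == 1) return(list(chi2 = 0, p = 1, q = q))
  if (method == "exact") {
    return(list(chi2 = NA_real_, p = .hwe_exact_p(n0, n1, n2), q = q))
  }
  expected <- c(n * (1 - q)^2, 2 * n * q * (1 - q), n * q^2)
  observed <- c(n0, n1, n2)
  keep <- !(expected == 0 & observed == 0)
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), q = q)
}

# exact HWE: condition on the minor-allele count, enumerate heterozygote
# counts of matching parity, sum probabilities <= that of the observed table
.hwe_exact_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- n1 + 2 * n2  # minor-allele copies
  het <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- lchoose(n, (nA - het) / 2) +
    lchoose(n - (nA - het) / 2, het) + het * log(2) -
    lchoose(2 * n, nA)
  # multinomial coefficient n! / (n2! n1! n0!) written as nested chooses
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n1, het)]
  sum(p[p <= obs + 1e-12])
}

#' Upper-tail chi-square probability
#'
#' `P(X >= x)` for `X ~ chi-square(df)`; with 2 df this is exactly
#' `exp(-x/2)`, the conversion behind the validation tables' printed
#' p-values.
#'
#' @param x Observed statistic, `>= 0`.
#' @param df Degrees of freedom, `>= 1`.
#' @return Upper-tail probability.
#' @export
chi2_sf <- function(x, df) {
  if (any(x < 0)) stop("x must be >= 0")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' 2 x genotype-class Pearson chi-square association test
#'
#' Builds the 2 x 3 case/control-by-genotype table, drops genotype columns
#' with zero total (a genotype nobody carries is not a category), and runs
#' the Pearson chi-square with `df = g - 1` surviving classes.
#'
#' @param case_counts,control_counts Length-3 vectors `(n0, n1, n2)` of
#'   minor-allele dosage counts.
#' @return List with `chi2`, `df`, `p`.
#' @export
genotype_assoc_2x3 <- function(case_counts, control_counts) {
  m <- rbind(case = case_counts, control = control_counts)
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0)) stop("each group needs at least one subject")
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2L) stop("degenerate table: only one genotype class present")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Allelic odds ratio with Woolf interval
#'
#' Collapses genotype counts to allele counts (minor `= n1 + 2 n2`, major
#' `= 2 n0 + n1` per group), computes `OR = ad / bc` with `a` = case
#' minor, `b` = case major, `c` = control minor, `d` = control major.
#' With `correction = "when_needed"` (default, the reporting convention)
#' the Haldane-Anscombe +0.5 is added to all four cells only when some
#' cell is zero (flagged in the output); `correction = "always"` applies
#' it unconditionally — the Anscombe estimator, whose log-OR is nearly
#' unbiased for sparse tables and is the right choice when averaging
#' estimates across simulations. The 95% CI is Woolf's
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`; the allelic
#' chi-square is the uncorrected Pearson test on the 2x2 allele table.
#'
#' @param case_counts,control_counts Length-3 genotype count vectors.
#' @param correction `"when_needed"` (default) or `"always"`.
#' @return List: `or`, `ci95_low`, `ci95_high`, `se_log_or`, `chi2`, `p`,
#'   `haldane` (logical), and the allele counts `a`, `b`, `c`, `d`.
#' @export
allelic_or <- function(case_counts, control_counts,
                       correction = c("when_needed", "always")) {
  correction <- match.arg(correction)
  a <- case_counts[2] + 2 * case_counts[3]
  b <- 2 * case_counts[1] + case_counts[2]
  c_ <- control_counts[2] + 2 * control_counts[3]
  d <- 2 * control_counts[1] + control_counts[2]
  if (a == 0 && c_ == 0) stop("odds ratio undefined: no minor alleles observed")
  haldane <- any(c(a, b, c_, d) == 0) || correction == "always"
  aa <- a; bb <- b; cc <- c_; dd <- d
  if (haldane) {
    aa <- a + 0.5; bb <- b + 0.5; cc <- c_ + 0.5; dd <- d + 0.5
  }
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  tab <- rbind(c(a, b), c(c_, d))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(
    or = unname(or),
    ci95_low = unname(exp(log(or) - 1.96 * se)),
    ci95_high = unname(exp(log(or) + 1.96 * se)),
    se_log_or = unname(se),
    chi2 = unname(ct$statistic),
    p = unname(ct$p.value),
    haldane = haldane,
    a = unname(a), b = unname(b), c = unname(c_), d = unname(d)
  )
}

#' Genotype frequencies as report percentages
#'
#' `100 n_i / n`, rounded half-up to one decimal place — the rounding used
#' in the printed genotype-frequency tables (plain `round()` rounds half
#' to even, which would misprint e.g. x.x5 boundaries).
#'
#' @param counts Vector of genotype counts.
#' @return Percentages to 1 decimal place.
#' @export
genotype_frequencies <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("total count must be positive")
  floor(100 * counts / n * 10 + 0.5) / 10
}

#' Classify glucocorticoid treatment response
#'
#' Complete response: post-treatment platelets above 100 (x10^9/L).
#' Response: platelets in 30-100 AND at least doubled from baseline.
#' Everything else is nonresponse. `rule = "inclusive"` switches to the
#' looser reading in which reaching 30 OR doubling suffices.
#'
#' @param baseline_plt,post_plt Platelet counts x10^9/L, `>= 0`.
#' @param rule `"standard"` (default) or `"inclusive"`.
#' @return Character vector in `{complete_response, response, nonresponse}`.
#' @export
classify_response <- function(baseline_plt, post_plt,
                              rule = c("standard", "inclusive")) {
  rule <- match.arg(rule)
  if (any(baseline_plt < 0 | post_plt < 0)) {
    stop("platelet counts must be >= 0")
  }
  resp <- if (rule == "standard") {
    post_plt >= 30 & post_plt >= 2 * baseline_plt
  } else {
    post_plt >= 30 | post_plt >= 2 * baseline_plt
  }
  ifelse(post_plt > 100, "complete_response",
         ifelse(resp, "response", "nonresponse"))
}

#' Genotype association with treatment response
#'
#' The 2x3 Pearson test of [genotype_assoc_2x3()] with the groups being
#' glucocorticoid response vs nonresponse instead of case vs control.
#'
#' @param response_counts,nonresponse_counts Length-3 genotype count
#'   vectors.
#' @return List with `chi2`, `df`, `p`.
#' @export
response_assoc <- function(response_counts, nonresponse_counts) {
  genotype_assoc_2x3(response_counts, nonresponse_counts)
}

#' Per-timepoint comparison of platelet trajectories
#'
#' Welch two-sample t-test of group A vs group B at each day. Degenerate
#' days where both groups are constant give p = 1 when the means agree
#' and p = 0 when they differ.
#'
#' @param series_A,series_B Numeric matrices, subjects x days.
#' @param days Day offsets labelling the columns.
#' @return Data frame: `day`, `mean_A`, `mean_B`, `t`, `p`, `sig05`,
#'   `sig01`.
#' @export
timepoint_compare <- function(series_A, series_B, days) {
  series_A <- as.matrix(series_A)
  series_B <- as.matrix(series_B)
  if (ncol(series_A) != length(days) || ncol(series_B) != length(days)) {
    stop("series must have one column per day")
  }
  if (nrow(series_A) < 2L || nrow(series_B) < 2L) {
    stop("need at least 2 subjects per group")
  }
  res <- lapply(seq_along(days), function(j) {
    a <- series_A[, j]; b <- series_B[, j]
    tt <- tryCatch(stats::t.test(a, b),
                   error = function(e) NULL)  # constant data
    if (is.null(tt)) {
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      t_stat <- if (p == 1) 0 else sign(mean(a) - mean(b)) * Inf
    } else {
      p <- tt$p.value
      t_stat <- unname(tt$statistic)
    }
    data.frame(day = days[j], mean_A = mean(a), mean_B = mean(b),
               t = t_stat, p = p, sig05 = p < 0.05, sig01 = p < 0.01)
  })
  do.call(rbind, res)
}

#' Collapse a genotype cohort to per-group dosage counts
#'
#' @param cohort Data frame from [read_genotypes()] or the simulators.
#' @param snp_id SNP column to tabulate.
#' @param group_col Column holding the two group labels (default
#'   `"group"`).
#' @return Named list of length-3 count vectors `(n0, n1, n2)`, one per
#'   group; missing dosages are excluded per SNP (pairwise, not
#'   subject-wise).
#' @export
genotype_counts <- function(cohort, snp_id, group_col = "group") {
  if (!snp_id %in% names(cohort)) stop("unknown SNP column: ", snp_id)
  g <- cohort[[group_col]]
  dos <- cohort[[snp_id]]
  keep <- !is.na(dos)
  lapply(split(dos[keep], g[keep]), function(d) {
    c(n0 = sum(d == 0), n1 = sum(d == 1), n2 = sum(d == 2))
  })
}
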