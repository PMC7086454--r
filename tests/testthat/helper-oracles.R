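# Independent oracle implementations used to cross-check the package.
# These are written directly from the defining formulas, kept separate
# from the implementation paths they verify.

# combined Z-test statistics evaluated scalar-by-scalar from the formulas
oracle_pool_test <- function(f1, f2, N1, N2, e1sq, e2sq) {
  v1 <- f1 * (1 - f1) / (2 * N1)
  v2 <- f2 * (1 - f2) / (2 * N2)
  d <- f1 - f2
  t1 <- d * d / (v1 + v2)
  tcomb <- d * d / (v1 + v2 + e1sq + e2sq)
  z <- d / sqrt(e1sq + e2sq)
  list(t1 = t1, tcomb = tcomb, z = z,
       p = pchisq(tcomb, df = 1, lower.tail = FALSE))
}

# upper-tail hypergeometric by full enumeration of the overlap support
oracle_hyper_tail <- function(N, K, n, k_obs) {
  j <- k_obs:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Benjamini-Hochberg step-up written out longhand
oracle_bh <- function(p, m_total) {
  ord <- order(p)
  ranked <- p[ord] * m_total / seq_along(p)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

# generic r x c Pearson chi-square from first principles
oracle_pearson_chi2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  list(chi2 = sum((m - e)^2 / e),
       df = (nrow(m) - 1) * (ncol(m) - 1))
}

# FPRP from the two defining formulas
oracle_fprp <- function(p, or_alt, se, pi0) {
  pow <- pnorm(log(or_alt) / se - qnorm(1 - p / 2))
  pow <- min(max(pow, .Machine$double.xmin), 1)
  p * (1 - pi0) / (p * (1 - pi0) + pow * pi0)
}

# brute-force per-SNP per-pool RAF summary over a long intensity table
oracle_summary <- function(tab, N_case, N_control) {
  raf <- tab$green_raw / (tab$green_raw + tab$red_raw)
  snps <- unique(tab$snp_id)
  do.call(rbind, lapply(snps, function(s) {
    out <- list(snp_id = s)
    for (pool in c("case", "control")) {
      f <- raf[tab$snp_id == s & tab$pool == pool]
      n <- length(f)
      fb <- sum(f) / n
      N <- if (pool == "case") N_case else N_control
      out[[paste0("f_", pool)]] <- fb
      out[[paste0("v_", pool)]] <- fb * (1 - fb) / (2 * N)
      out[[paste0("eps2_", pool)]] <- sum((f - fb)^2) / (n * (n - 1))
      out[[paste0("n_", pool)]] <- n
    }
    as.data.frame(out)
  }))
}

# small well-formed intensity fixture builder
make_intensity_fixture <- function() {
  grid <- expand.grid(rep = 1:3, pool = c("case", "control"),
                      snp = c("s1", "s2", "s3"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  raf <- c(0.2, 0.25, 0.22, 0.2, 0.21, 0.19,
           0.5, 0.55, 0.52, 0.48, 0.5, 0.51,
           0.8, 0.79, 0.81, 0.7, 0.72, 0.71)
  data.frame(
    snp_id = grid$snp,
    chrom = c(s1 = "1", s2 = "2", s3 = "3")[grid$snp],
    pos = c(s1 = 1000L, s2 = 2000L, s3 = 3000L)[grid$snp],
    pool = grid$pool,
    replicate = grid$rep,
    green_raw = 1000 * raf,
    red_raw = 1000 * (1 - raf),
    stringsAsFactors = FALSE
  )
}
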