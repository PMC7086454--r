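# Stage-1 pooled-array analysis: RAF estimation, array QC, and the combined
# Z-test. The per-SNP statistic divides the squared case-control difference
# of mean relative allele frequencies by the sum of the binomial
# pool-sampling variances v_k = f(1-f)/(2N_k) and the squared replicate
# standard errors e_k^2 = sum((f_i - fbar)^2) / (n(n-1)).

.AUTOSOMES <- as.character(1:22)

.norm_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  up <- toupper(x)
  x[up %in% c("M", "MT")] <- "MT"
  x[up == "X"] <- "X"
  x[up == "Y"] <- "Y"
  x
}

#' Relative allele frequency from two-channel intensities
#'
#' RAF is the green-channel share of total fluorescence,
#' `f = G / (G + R)`, the pooled-array approximation of the allele-A
#' frequency in the pool for one replicate.
#'
#' @param green_raw,red_raw Non-negative raw fluorescence values.
#' @return Numeric vector in `[0, 1]`; `NA` where both channels are zero or
#'   missing (failed hybridization, handled by QC).
#' @export
compute_raf <- function(green_raw, red_raw) {
  tot <- green_raw + red_raw
  out <- ifelse(!is.na(tot) & tot > 0, green_raw / tot, NA_real_)
  out
}

#' Array quality control for a pooled intensity table
#'
#' Applies the three pre-analysis filters: (1) failed hybridizations (both
#' channels zero or missing) are removed; (2) SNPs left with fewer than
#' `min_replicates` surviving replicates in either pool are removed
#' entirely (too few repetitions make the replicate error estimate
#' unreliable); (3) SNPs on the sex chromosomes and mitochondria are
#' removed, since mixed-sex pools make those loci uninterpretable.
#'
#' @param table Intensity table from [read_pool_intensities()] or
#'   [simulate_pooled_experiment()].
#' @param min_replicates Minimum surviving replicates required per pool.
#' @return The filtered table, with a `qc_report` attribute (named list of
#'   counts per removal category); retrieve it with [qc_report()].
#' @export
qc_filter <- function(table, min_replicates = 3) {
  if (is.null(table$failed)) {
    table$failed <- is.na(table$green_raw) | is.na(table$red_raw) |
      (table$green_raw == 0 & table$red_raw == 0)
  }
  n_input_snps <- length(unique(table$snp_id))
  n_failed_rows <- sum(table$failed)
  tab <- table[!table$failed, , drop = FALSE]

  chrom <- .norm_chrom(tab$chrom)
  nonauto_ids <- unique(tab$snp_id[!chrom %in% .AUTOSOMES])
  tab <- tab[chrom %in% .AUTOSOMES, , drop = FALSE]

  # replicate counts per SNP per pool; a SNP must clear the bar in BOTH pools
  if (nrow(tab) > 0L) {
    cnt <- stats::aggregate(list(n = tab$replicate),
                            by = list(snp_id = tab$snp_id, pool = tab$pool),
                            FUN = length)
    by_snp <- split(cnt, cnt$snp_id)
    ok <- vapply(by_snp, function(d) {
      all(c("case", "control") %in% d$pool) && all(d$n >= min_replicates)
    }, logical(1))
    low_ids <- names(ok)[!ok]
    tab <- tab[!tab$snp_id %in% low_ids, , drop = FALSE]
  } else {
    low_ids <- character(0)
  }

  report <- list(
    n_input_snps = n_input_snps,
    n_failed_rows = n_failed_rows,
    n_nonautosomal_snps = length(nonauto_ids),
    n_low_replicate_snps = length(low_ids),
    n_retained_snps = length(unique(tab$snp_id)),
    min_replicates = min_replicates
  )
  rownames(tab) <- NULL
  attr(tab, "qc_report") <- report
  tab
}

#' Retrieve the QC report attached by [qc_filter()]
#' @param table A QC-filtered intensity table.
#' @return Named list of counts.
#' @export
qc_report <- function(table) attr(table, "qc_report")

#' Per-SNP per-pool RAF summary
#'
#' For each SNP and pool k computes the mean RAF over replicates, the
#' binomial pool-sampling variance `v_k = f(1-f)/(2 N_k)` (2N_k alleles in
#' a pool of N_k individuals), and the squared standard error of the
#' replicate mean `e_k^2 = sum((f_i - fbar)^2) / (n_k (n_k - 1))`.
#'
#' @param table QC-filtered intensity table.
#' @param N_case,N_control Number of individuals in each pool.
#' @return Data frame, one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `f_case`, `f_control`, `n_case_reps`, `n_control_reps`, `v_case`,
#'   `v_control`, `eps2_case`, `eps2_control`.
#' @export
summarize_pools <- function(table, N_case, N_control) {
  if (nrow(table) == 0L) {
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), f_case = numeric(0),
                      f_control = numeric(0), n_case_reps = integer(0),
                      n_control_reps = integer(0), v_case = numeric(0),
                      v_control = numeric(0), eps2_case = numeric(0),
                      eps2_control = numeric(0)))
  }
  raf <- compute_raf(table$green_raw, table$red_raw)
  if (anyNA(raf)) stop("failed rows present; run qc_filter() first")

  key <- paste(table$snp_id, table$pool, sep = "\r")
  grp <- split(raf, key)
  n <- lengths(grp)
  if (any(n < 2L)) {
    stop("replicate standard error undefined with fewer than 2 replicates")
  }
  fbar <- vapply(grp, mean, numeric(1))
  eps2 <- vapply(grp, function(f) {
    sum((f - mean(f))^2) / (length(f) * (length(f) - 1))
  }, numeric(1))

  ks <- strsplit(names(grp), "\r", fixed = TRUE)
  snp <- vapply(ks, `[[`, character(1), 1L)
  pool <- vapply(ks, `[[`, character(1), 2L)

  snps <- unique(table$snp_id)
  idx_case <- match(paste(snps, "case"), paste(snp, pool))
  idx_ctrl <- match(paste(snps, "control"), paste(snp, pool))
  if (anyNA(idx_case) || anyNA(idx_ctrl)) {
    stop("every SNP needs replicates in both pools; run qc_filter() first")
  }
  first <- match(snps, table$snp_id)

  f1 <- fbar[idx_case]
  f2 <- fbar[idx_ctrl]
  out <- data.frame(
    snp_id = snps,
    chrom = table$chrom[first],
    pos = table$pos[first],
    f_case = unname(f1),
    f_control = unname(f2),
    n_case_reps = unname(n[idx_case]),
    n_control_reps = unname(n[idx_ctrl]),
    v_case = unname(f1 * (1 - f1) / (2 * N_case)),
    v_control = unname(f2 * (1 - f2) / (2 * N_control)),
    eps2_case = unname(eps2[idx_case]),
    eps2_control = unname(eps2[idx_ctrl]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Combined Z-test for pooled allele-frequency differences
#'
#' For each SNP computes
#' `T1 = (f1 - f2)^2 / (v1 + v2)` (sampling variance only),
#' `Tcomb = (f1 - f2)^2 / (v1 + v2 + e1^2 + e2^2)` (adding replicate array
#' error), and `Z = (f1 - f2) / sqrt(e1^2 + e2^2)`. The p-value is the
#' upper tail of a chi-square with 1 df at `Tcomb` (a squared standardized
#' difference of two proportions; equivalently a two-sided Normal test on
#' `sqrt(Tcomb)`).
#'
#' Degenerate SNPs where every variance term is zero get `p = 1` when the
#' pool means agree, and the smallest representable p with
#' `flag_infinite = TRUE` when they differ.
#'
#' @param summary RAF summary from [summarize_pools()].
#' @param alpha Genome-wide significance line (strict `<`), default 1e-7.
#' @return Data frame with `snp_id`, `chrom`, `pos`, `t1`, `tcomb`, `z`,
#'   `p_value`, `delta_raf`, `genomewide`, `flag_infinite`.
#' @export
combined_z_test <- function(summary, alpha = 1.0e-7) {
  d <- summary$f_case - summary$f_control
  vsum <- summary$v_case + summary$v_control
  esum <- summary$eps2_case + summary$eps2_control
  denom <- vsum + esum

  t1 <- ifelse(vsum > 0, d^2 / vsum, ifelse(d == 0, 0, Inf))
  tcomb <- ifelse(denom > 0, d^2 / denom, ifelse(d == 0, 0, Inf))
  z <- ifelse(esum > 0, d / sqrt(esum), ifelse(d == 0, 0, sign(d) * Inf))

  p <- stats::pchisq(tcomb, df = 1, lower.tail = FALSE)
  flag <- !is.finite(tcomb)
  tiny <- .Machine$double.xmin
  p[flag] <- tiny
  p[p < tiny] <- tiny          # underflow guard: p must stay in (0, 1]

  out <- data.frame(
    snp_id = summary$snp_id,
    chrom = summary$chrom,
    pos = summary$pos,
    t1 = t1,
    tcomb = tcomb,
    z = z,
    p_value = p,
    delta_raf = d,
    genomewide = p < alpha,
    flag_infinite = flag,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Genome-wide significant hits
#'
#' Selects results with `p < alpha` (strict inequality at the significance
#' criterion, default 1e-7, the Bonferroni-scale threshold for a
#' ~860k-SNP array) and sorts them by ascending p.
#'
#' @param results Association results (needs a `p_value` column).
#' @param alpha Significance threshold.
#' @return The subset of `results` passing, ordered by `p_value`.
#' @export
genomewide_hits <- function(results, alpha = 1.0e-7) {
  hits <- results[results$p_value < alpha, , drop = FALSE]
  hits <- hits[order(hits$p_value), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Quantile-quantile plot coordinates
#'
#' Expected quantiles are `-log10((i - 0.5) / m)` for rank i of m; observed
#' values are the sorted `-log10(p)`, largest first, so row i pairs the
#' i-th smallest p with its null expectation.
#'
#' @param p_values Vector of p-values in `(0, 1]`; zeros are clamped with a
#'   warning.
#' @return Data frame with `expected` and `observed` columns.
#' @export
qq_points <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(data.frame(expected = numeric(0), observed = numeric(0)))
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to smallest representable double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  i <- seq_len(m)
  data.frame(
    expected = -log10((i - 0.5) / m),
    observed = -log10(sort(p_values))
  )
}

#' Chromosome lengths from a gene annotation
#'
#' Convenience for [manhattan_points()]: length of each chromosome taken as
#' the largest annotated end position.
#'
#' @param annotation Data frame from [read_gene_annotation()].
#' @return Named numeric vector of lengths, by chromosome.
#' @export
chrom_lengths_from_annotation <- function(annotation) {
  chrom <- .norm_chrom(annotation$chrom)
  vapply(split(annotation$end, chrom), max, numeric(1))
}

#' Manhattan plot coordinates
#'
#' Lays chromosomes 1..22 end to end and returns, per SNP, the cumulative
#' genome coordinate and `-log10(p)`.
#'
#' @param results Association results with `chrom`, `pos`, `p_value`.
#' @param chrom_lengths Optional named vector of chromosome lengths (e.g.
#'   from [chrom_lengths_from_annotation()]); defaults to the largest
#'   observed position per chromosome.
#' @return Data frame with `snp_id`, `chrom`, `pos`, `genome_pos`,
#'   `neglog10_p`.
#' @export
manhattan_points <- function(results, chrom_lengths = NULL) {
  if (nrow(results) == 0L) {
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = numeric(0), genome_pos = numeric(0),
                      neglog10_p = numeric(0)))
  }
  chrom <- .norm_chrom(results$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(results$pos, chrom), max, numeric(1))
  } else {
    names(chrom_lengths) <- .norm_chrom(names(chrom_lengths))
  }
  ord <- .AUTOSOMES[.AUTOSOMES %in% names(chrom_lengths)]
  extra <- setdiff(unique(chrom), ord)
  if (length(extra) > 0L) {
    stop("chromosome(s) without a length: ", paste(extra, collapse = ", "))
  }
  offsets <- stats::setNames(cumsum(c(0, chrom_lengths[ord][-length(ord)])), ord)
  p <- results$p_value
  p[p == 0] <- .Machine$double.xmin
  data.frame(
    snp_id = results$snp_id,
    chrom = chrom,
    pos = results$pos,
    genome_pos = offsets[chrom] + results$pos,
    neglog10_p = -log10(p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Squared Pearson correlation of pool mean RAFs
#'
#' The case-vs-control scatter of mean RAFs should be almost perfectly
#' correlated genome-wide (most SNPs are null); its r^2 is the standard
#' reliability check for a pooled-array run.
#'
#' @param raf_case,raf_control Equal-length vectors of per-SNP mean RAFs.
#' @return Squared Pearson correlation coefficient.
#' @export
raf_correlation <- function(raf_case, raf_control) {
  if (length(raf_case) != length(raf_control)) {
    stop("vectors must have equal length")
  }
  if (length(raf_case) < 2L) stop("need at least 2 points")
  if (stats::sd(raf_case) == 0 || stats::sd(raf_control) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(raf_case, raf_control)^2
}
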