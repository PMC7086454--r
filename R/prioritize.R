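# Post-GWAS hit prioritization: odds ratios from pooled allele
# frequencies, false positive report probability (FPRP), and window-based
# SNP-to-gene mapping against a BED annotation.

#' Allelic odds ratio from pooled allele frequencies
#'
#' `OR = f1 (1 - f2) / (f2 (1 - f1))` with the allele-count approximation
#' of the log-OR standard error from pooled frequencies,
#' `se = sqrt(1/(2 N1 f1 (1-f1)) + 1/(2 N2 f2 (1-f2)))`, and the Wald 95%
#' interval `exp(log OR +/- 1.96 se)`.
#'
#' @param f1,f2 Mean case and control allele frequencies, strictly in
#'   `(0, 1)`.
#' @param N1,N2 Pool sizes in individuals.
#' @return Data frame with `or`, `ci95_low`, `ci95_high`, `se_log_or`.
#' @export
or_from_raf <- function(f1, f2, N1, N2) {
  if (any(f1 <= 0 | f1 >= 1 | f2 <= 0 | f2 >= 1)) {
    stop("allele frequencies at 0 or 1: apply continuity handling upstream ",
         "before computing an odds ratio")
  }
  or <- (f1 * (1 - f2)) / (f2 * (1 - f1))
  se <- sqrt(1 / (2 * N1 * f1 * (1 - f1)) + 1 / (2 * N2 * f2 * (1 - f2)))
  data.frame(
    or = or,
    ci95_low = exp(log(or) - 1.96 * se),
    ci95_high = exp(log(or) + 1.96 * se),
    se_log_or = se
  )
}

#' False positive report probability
#'
#' Wacholder-style posterior probability that a reported association is a
#' false positive, given the observed p-value, the study's power to detect
#' an alternative odds ratio `or_alt` at that p-value threshold, and a
#' prior probability `prior_pi` that the association is real:
#' power `1 - beta = Phi(log(or_alt)/se - z_{1 - p/2})`, and
#' `FPRP = p (1 - pi) / (p (1 - pi) + (1 - beta) pi)`.
#'
#' @param p_value Observed p-value.
#' @param or_alt Alternative odds ratio at which power is evaluated
#'   (default 1.5).
#' @param se_log_or Standard error of the log odds ratio.
#' @param prior_pi Prior probability the association is real.
#' @return FPRP in `[0, 1]` (vectorized over the inputs).
#' @export
fprp <- function(p_value, or_alt = 1.5, se_log_or, prior_pi) {
  if (any(prior_pi < 0 | prior_pi > 1)) stop("prior_pi must be in [0, 1]")
  if (any(or_alt <= 0)) stop("or_alt must be positive")
  if (any(se_log_or <= 0)) stop("se_log_or must be positive")
  power <- stats::pnorm(log(or_alt) / se_log_or -
                          stats::qnorm(1 - p_value / 2))
  # clamp to (0, 1]: zero power with a nonzero prior must still give the
  # limit FPRP of 1, not 0/0
  power <- pmin(pmax(power, .Machine$double.xmin), 1)
  num <- p_value * (1 - prior_pi)
  den <- num + power * prior_pi
  out <- num / den
  out[num == 0 & prior_pi > 0] <- 0
  out[prior_pi == 0] <- 1
  out[prior_pi == 0 & p_value == 0] <- NaN
  out
}

.annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = .norm_chrom(annotation$chrom),
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    gene_symbol = annotation$gene_symbol
  )
}

#' Map SNPs to genes with a flanking window
#'
#' A SNP is assigned to every gene whose span, extended by `window_bp`
#' upstream and downstream (inclusive at exactly `window_bp`), contains the
#' SNP position (`relation = "within_window"`, distance 0 for overlap,
#' otherwise distance to the nearer gene edge). If no gene qualifies, the
#' nearest gene on each side is reported instead
#' (`relation = "nearest_flank"`, up to one gene per side; equidistant
#' same-side ties are all kept).
#'
#' @param snps Data frame with `snp_id`, `chrom`, `pos`, and optionally
#'   `p_value` (carried through).
#' @param annotation Gene annotation from [read_gene_annotation()].
#' @param window_bp Window size in bp, default 20000.
#' @return Data frame with `snp_id`, `chrom`, `pos`, `gene_symbol`,
#'   `relation`, `distance_bp`, `p_value`. SNPs on chromosomes absent from
#'   the annotation are dropped with a warning.
#' @export
map_snps_to_genes <- function(snps, annotation, window_bp = 20000) {
  if (window_bp < 0) stop("window_bp must be >= 0")
  p <- if ("p_value" %in% names(snps)) snps$p_value else rep(NA_real_, nrow(snps))
  chrom <- .norm_chrom(snps$chrom)
  known <- chrom %in% unique(.norm_chrom(annotation$chrom))
  if (any(!known)) {
    warning("SNP(s) on chromosome(s) absent from the annotation left ",
            "unassigned: ", paste(snps$snp_id[!known], collapse = ", "))
  }
  idx <- which(known)
  if (length(idx) == 0L) {
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = numeric(0), gene_symbol = character(0),
                      relation = character(0), distance_bp = numeric(0),
                      p_value = numeric(0)))
  }
  gene_gr <- .annotation_granges(annotation)
  win_gr <- gene_gr
  GenomicRanges::start(win_gr) <- pmax(1L, GenomicRanges::start(gene_gr) - window_bp)
  GenomicRanges::end(win_gr) <- GenomicRanges::end(gene_gr) + window_bp
  snp_gr <- GenomicRanges::GRanges(
    seqnames = chrom[idx],
    ranges = IRanges::IRanges(start = snps$pos[idx], width = 1L)
  )
  GenomeInfoDb::seqlevels(snp_gr) <- GenomeInfoDb::seqlevels(win_gr)
  ov <- GenomicRanges::findOverlaps(snp_gr, win_gr)

  dist_to_gene <- function(pos, g) {
    s <- annotation$start[g]; e <- annotation$end[g]
    ifelse(pos < s, s - pos, ifelse(pos > e, pos - e, 0))
  }

  rows <- list()
  if (length(ov) > 0L) {
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    rows[["within"]] <- data.frame(
      snp_id = snps$snp_id[idx][qi],
      chrom = chrom[idx][qi],
      pos = snps$pos[idx][qi],
      gene_symbol = annotation$gene_symbol[si],
      relation = "within_window",
      distance_bp = dist_to_gene(snps$pos[idx][qi], si),
      p_value = p[idx][qi],
      stringsAsFactors = FALSE
    )
  }

  unhit <- setdiff(seq_along(idx), unique(S4Vectors::queryHits(ov)))
  ann_chrom <- .norm_chrom(annotation$chrom)
  flank_rows <- lapply(unhit, function(j) {
    i <- idx[j]
    pos <- snps$pos[i]
    g <- which(ann_chrom == chrom[i])
    d <- dist_to_gene(pos, g)
    side <- ifelse(annotation$end[g] < pos, "left",
                   ifelse(annotation$start[g] > pos, "right", "overlap"))
    pick <- integer(0)
    for (s in c("left", "right")) {
      gs <- g[side == s]
      if (length(gs) > 0L) {
        ds <- d[side == s]
        pick <- c(pick, gs[ds == min(ds)])
      }
    }
    if (length(pick) == 0L) return(NULL)
    data.frame(
      snp_id = snps$snp_id[i], chrom = chrom[i], pos = pos,
      gene_symbol = annotation$gene_symbol[pick],
      relation = "nearest_flank",
      distance_bp = dist_to_gene(pos, pick),
      p_value = p[i],
      stringsAsFactors = FALSE
    )
  })
  rows <- c(rows, flank_rows)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(snp_id = character(0), chrom = character(0),
                      pos = numeric(0), gene_symbol = character(0),
                      relation = character(0), distance_bp = numeric(0),
                      p_value = numeric(0))
  }
  out <- out[order(out$snp_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Slash-joined gene label for a SNP's assignments
#'
#' Multi-gene assignments are reported "A/B" (e.g. a SNP between two genes
#' or inside overlapping genes).
#'
#' @param assignments Output of [map_snps_to_genes()].
#' @return Named character vector, one label per SNP.
#' @export
gene_labels <- function(assignments) {
  vapply(split(assignments$gene_symbol, assignments$snp_id),
         function(g) paste(unique(g), collapse = "/"), character(1))
}

#' Collapse SNP-gene assignments to one record per gene
#'
#' When several SNPs map to the same gene the gene keeps its smallest
#' p-value; ties are broken by smaller position.
#'
#' @param assignments Output of [map_snps_to_genes()] (p-values required).
#' @return Data frame `gene_symbol`, `snp_id`, `pos`, `p_value`, ordered by
#'   ascending p.
#' @export
gene_level_best <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(data.frame(gene_symbol = character(0), snp_id = character(0),
                      pos = numeric(0), p_value = numeric(0)))
  }
  ord <- order(assignments$gene_symbol, assignments$p_value, assignments$pos)
  a <- assignments[ord, , drop = FALSE]
  best <- a[!duplicated(a$gene_symbol),
            c("gene_symbol", "snp_id", "pos", "p_value"), drop = FALSE]
  best <- best[order(best$p_value, best$pos), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Select the enrichment study set
#'
#' Genes with `p < alpha` (strict), default 1e-5, in stable order of
#' ascending p — the relaxed threshold used to build a workable study set
#' when too few genes clear the genome-wide line.
#'
#' @param gene_records Output of [gene_level_best()].
#' @param alpha Inclusion threshold.
#' @return Character vector of gene symbols.
#' @export
select_gene_set <- function(gene_records, alpha = 1.0e-5) {
  sel <- gene_records[gene_records$p_value < alpha, , drop = FALSE]
  sel <- sel[order(sel$p_value), , drop = FALSE]
  sel$gene_symbol
}
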