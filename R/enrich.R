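# Pathway over-representation: one-sided hypergeometric tail with
# expected-count and enrichment-ratio bookkeeping, plus Benjamini-Hochberg
# adjustment with an overridable total test count.

#' Hypergeometric over-representation of a study set in one pathway
#'
#' With a reference universe of `N` genes of which `K` belong to the
#' pathway, and a study set of `n` genes of which `k_obs` fall in the
#' pathway, computes the exact upper tail `P(X >= k_obs)` for
#' `X ~ Hypergeom(N, K, n)`, the expected overlap `K n / N`, and the
#' enrichment ratio `E = k_obs / expected`.
#'
#' @param study_set Character vector of study genes.
#' @param pathway_set Character vector of pathway genes.
#' @param reference_size Size `N` of the reference universe.
#' @param pathway_name Optional label carried into the result.
#' @return One-row data frame: `pathway_name`, `total` (K), `observed`,
#'   `expected`, `e_ratio`, `p_hyper`.
#' @export
hypergeometric_overrep <- function(study_set, pathway_set, reference_size,
                                   pathway_name = NA_character_) {
  study <- unique(study_set)
  pathway <- unique(pathway_set)
  N <- as.integer(reference_size)
  K <- length(pathway)
  n <- length(study)
  k_obs <- length(intersect(study, pathway))
  if (N < max(K, n)) stop("reference_size smaller than a gene set")
  stopifnot(k_obs <= min(K, n))  # impossible overlap means corrupt inputs
  p <- stats::phyper(k_obs - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  expected <- K * n / N
  data.frame(
    pathway_name = pathway_name,
    total = K,
    observed = k_obs,
    expected = expected,
    e_ratio = if (expected > 0) k_obs / expected else NA_real_,
    p_hyper = p,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with an explicit total test count `m_total`, which may
#' exceed the number of p-values supplied — used when only a subset of the
#' tested categories is carried forward but the adjustment must account
#' for all of them.
#'
#' @param p_values Raw p-values in `(0, 1]`.
#' @param m_total Total number of tests; defaults to `length(p_values)`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values, m_total = length(p_values)) {
  if (m_total < length(p_values)) {
    stop("m_total must be at least the number of p-values")
  }
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p_values, method = "BH", n = m_total)
}

#' Over-representation across a pathway database
#'
#' Runs [hypergeometric_overrep()] for every pathway and BH-adjusts the
#' pathways with at least one study-set gene. Unless overridden,
#' `m_total` is the number of pathways with a nonzero overlap — the
#' categories actually in play; pathways with no overlap keep
#' `p_hyper = adj_p = 1`.
#'
#' @param study_set Character vector of study genes.
#' @param pathway_db List with `pathways` and `reference_size`, from
#'   [read_gmt()].
#' @param reference_size Override for the reference universe size.
#' @param m_total Override for the BH total test count.
#' @return Data frame, one row per pathway, sorted by `p_hyper`, with an
#'   `adj_p` column.
#' @export
enrich_pathways <- function(study_set, pathway_db, reference_size = NULL,
                            m_total = NULL) {
  if (is.null(reference_size)) reference_size <- pathway_db$reference_size
  rows <- lapply(names(pathway_db$pathways), function(nm) {
    hypergeometric_overrep(study_set, pathway_db$pathways[[nm]],
                           reference_size, pathway_name = nm)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(pathway_name = character(0), total = integer(0),
                      observed = integer(0), expected = numeric(0),
                      e_ratio = numeric(0), p_hyper = numeric(0),
                      adj_p = numeric(0)))
  }
  tested <- res$observed >= 1
  if (is.null(m_total)) m_total <- sum(tested)
  res$adj_p <- 1
  if (any(tested)) {
    res$adj_p[tested] <- bh_adjust(res$p_hyper[tested], m_total = m_total)
  }
  res <- res[order(res$p_hyper, res$pathway_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}
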