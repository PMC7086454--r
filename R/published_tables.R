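# Accessors for the small published summary tables bundled with the
# package: the validation cohort's genotype counts, the treatment-response
# counts, the four genome-wide pooled p-values, and the published pathway
# enrichment rows. These are the study's printed numbers and serve as
# inputs to the stage-2 statistics (the raw array deposit is not shipped).

.extdata <- function(name) {
  system.file("extdata", name, package = "poolgwas", mustWork = TRUE)
}

#' Validation-cohort genotype counts (published)
#'
#' Genotype counts of the three TaqMan-genotyped loci in 250 ITP cases and
#' 250 controls, one row per SNP x group, with the printed chi-square, OR
#' and p-value carried in `*_printed` columns for comparison against
#' recomputation.
#'
#' @return Data frame with `snp_id`, `group`, `n0`, `n1`, `n2` (minor-
#'   allele dosage counts) and the printed statistics.
#' @export
itp_validation_counts <- function() {
  utils::read.table(.extdata("validation_genotype_counts.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Glucocorticoid-response genotype counts (published)
#'
#' Genotype counts of the same loci in the 120 glucocorticoid responders
#' and 63 nonresponders.
#'
#' @return Data frame with `snp_id`, `group`, `n0`, `n1`, `n2` and printed
#'   statistics.
#' @export
itp_response_counts <- function() {
  utils::read.table(.extdata("response_genotype_counts.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Genome-wide pooled-GWAS hits (published)
#'
#' The four loci reported below the 1e-7 line in the pooled scan, with
#' chromosome, GRCh37 position and the reported p-value.
#'
#' @return Data frame with `snp_id`, `closest_genes`, `chrom`, `pos`,
#'   `p_value`.
#' @export
itp_reported_hits <- function() {
  utils::read.table(.extdata("reported_gwas_pvalues.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Published pathway over-representation rows
#'
#' The three over-represented KEGG categories with their reference-set
#' size, observed study-set overlap, enrichment ratio, raw hypergeometric
#' p and BH-adjusted p as printed.
#'
#' @return Data frame, one row per pathway.
#' @export
itp_pathway_table <- function() {
  utils::read.table(.extdata("pathway_enrichment_published.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Synthetic annotation of the reported loci neighborhoods
#'
#' A small BED of synthetic gene spans (not real coordinates) around the
#' four reported loci, for exercising window mapping end to end.
#'
#' @return Path to the bundled BED file.
#' @export
synthetic_loci_bed <- function() .extdata("synthetic_loci_genes.bed")

#' Synthetic pathway gene sets
#'
#' A small synthetic GMT over the loci's gene symbols plus filler genes.
#'
#' @return Path to the bundled GMT file.
#' @export
synthetic_pathways_gmt <- function() .extdata("synthetic_pathways.gmt")
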