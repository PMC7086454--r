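#!/usr/bin/env Rscript
# Stage 1b: hit prioritization. Odds ratios and FPRP for the strongest
# signals of the synthetic scan, and window mapping of the four published
# loci onto the bundled synthetic neighborhood annotation.

suppressPackageStartupMessages(library(poolgwas))

dir.create("results/prioritize", showWarnings = FALSE, recursive = TRUE)

assoc <- read_results("results/assoc/assoc.tsv")
summ_tab <- read_pool_intensities("results/data/intensities.tsv.gz")
summ <- summarize_pools(qc_filter(summ_tab), 200, 200)

# OR + FPRP for the top 20 SNPs by Tcomb (the scan's high-ranking set)
top <- assoc[order(-assoc$tcomb)[1:20], ]
ts <- summ[match(top$snp_id, summ$snp_id), ]
ors <- or_from_raf(ts$f_case, ts$f_control, 200, 200)
priors <- c(0.25, 0.1, 0.01, 0.001)
fp <- sapply(priors, function(pi0)
  fprp(top$p_value, or_alt = 1.5, se_log_or = ors$se_log_or,
       prior_pi = pi0))
colnames(fp) <- paste0("fprp_pi_", priors)
top20 <- cbind(top[, c("snp_id", "chrom", "pos", "tcomb", "p_value",
                       "delta_raf")], ors, fp)
write_results(top20, "results/prioritize/top20_or_fprp.tsv")
cat("top signal:", top20$snp_id[1], " OR =", round(top20$or[1], 2),
    " FPRP(pi=0.001) =", signif(top20$fprp_pi_0.001[1], 3), "\n")

# window mapping of the published loci against the synthetic neighborhood
# annotation (spans are synthetic stand-ins, not real gene coordinates)
hits <- itp_reported_hits()
ann <- read_gene_annotation(synthetic_loci_bed())
assign <- map_snps_to_genes(hits, ann, window_bp = 20000)
write_results(assign, "results/prioritize/reported_loci_genes.tsv")
labels <- gene_labels(assign)
for (s in names(labels)) cat(s, "->", labels[[s]], "\n")

genes <- gene_level_best(assign)
study <- select_gene_set(genes, alpha = 1e-5)
writeLines(study, "results/prioritize/gene_set.txt")
cat(length(study), "genes selected at p < 1e-5 for enrichment\n")
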