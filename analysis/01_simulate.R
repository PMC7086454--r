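#!/usr/bin/env Rscript
# Stage 0: generate the synthetic study inputs with known ground truth.
#
# The pooled scan emulates the discovery design: two pools of 200
# individuals, 3 replicate arrays each, 10,000 autosomal SNPs of which 10
# carry a 0.15 case-control allele-frequency differential. The validation
# cohort emulates the second stage: 250 cases / 250 controls genotyped at
# one locus with control MAF 0.024 and allelic OR 3.5 (the rs5998634-like
# design point), plus glucocorticoid response and platelet trajectories
# linked to carrier status.

suppressPackageStartupMessages(library(poolgwas))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20260924

sim <- simulate_pooled_experiment(n_snps = 10000, n_spiked = 10,
                                  delta_f = 0.15, N_case = 200,
                                  N_control = 200, n_reps = 3,
                                  noise_sd = 0.01, seed = seed)
write_pool_intensities(sim$table, "results/data/intensities.tsv.gz")
write_results(data.frame(snp_id = sim$truth$snp_id,
                         f_case_true = sim$truth$f_case_true,
                         f_control_true = sim$truth$f_control_true,
                         spiked = sim$truth$snp_id %in% sim$truth$spiked_ids),
              "results/data/truth.tsv")
cat("pooled scan:", length(sim$truth$snp_id), "SNPs,",
    length(sim$truth$spiked_ids), "spiked at delta_f =",
    sim$truth$delta_f, "\n")

cohort <- simulate_case_control_genotypes(250, 250, maf_control = 0.024,
                                          or_allelic = 3.5,
                                          snp_id = "rs_sim1", seed = seed)
cat("cohort: true case MAF", round(cohort$truth$maf_case, 4),
    "vs control", cohort$truth$maf_control, "\n")

# response + platelet series for the simulated ITP cases only
cases <- cohort$cohort[cohort$cohort$group == "case", ]
cases <- simulate_treatment_response(cases, "rs_sim1", seed = seed + 1)
write_genotypes(cohort$cohort, "results/data/cohort.tsv")
write_genotypes(cases, "results/data/cases_response.tsv")
cat("response rates by carrier status:\n")
print(tapply(cases$response == "response" |
               cases$response == "complete_response",
             cases$rs_sim1 >= 1, mean))
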