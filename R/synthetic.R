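# Seeded synthetic-data generators with known ground truth. They emulate
# the study design — two pools of 200 individuals on 3 replicate arrays
# each for stage 1, a 250/250 diploid cohort for stage 2 — so every
# downstream stage can be tested without the raw array deposit.

#' Simulate a pooled-array experiment
#'
#' Generative model, per SNP: the control truth `f0 ~ Uniform(0.05, 0.95)`;
#' spiked SNPs get case truth `f0 + delta_f` (clamped to 1), others `f0`.
#' Each pool's realized allele frequency is drawn binomially from its
#' `2N` allele copies (this is the variance component the test's `v_k`
#' models). Each replicate observes the realized frequency plus
#' `Normal(0, noise_sd)` array error, truncated to `[0, 1]` (the `e_k^2`
#' component). Channel intensities share one multiplicative array factor
#' `(1 + u)`, `u ~ Normal(0, 0.02)`: `green = scale * RAF * (1 + u)`,
#' `red = scale * (1 - RAF) * (1 + u)`, so `G/(G+R)` returns the replicate
#' RAF exactly and no unmodeled frequency noise enters.
#'
#' @param n_snps Number of SNPs.
#' @param n_spiked Number of SNPs given a true case-control differential.
#' @param delta_f Allele-frequency differential at spiked SNPs, in
#'   `[0, 1]`.
#' @param N_case,N_control Pool sizes in individuals (default 200/200).
#' @param n_reps Replicate arrays per pool (default 3).
#' @param intensity_scale Total fluorescence scale per probe.
#' @param noise_sd Replicate-to-replicate RAF error SD (default 0.01).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return List with `table` (a pooled intensity table) and `truth`
#'   (per-SNP true frequencies, spiked ids, parameters, seed).
#' @export
simulate_pooled_experiment <- function(n_snps, n_spiked = 0, delta_f = 0.15,
                                       N_case = 200, N_control = 200,
                                       n_reps = 3, intensity_scale = 1000,
                                       noise_sd = 0.01, seed = 1) {
  if (n_spiked > n_snps) stop("n_spiked must not exceed n_snps")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (delta_f < 0 || delta_f > 1) stop("delta_f must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)

  snp_id <- sprintf("snp%06d", seq_len(n_snps))
  chrom <- as.character(rep_len(1:22, n_snps))
  pos <- 10000L * as.integer(stats::ave(seq_len(n_snps), chrom,
                                        FUN = seq_along))

  f0 <- stats::runif(n_snps, 0.05, 0.95)
  spiked <- if (n_spiked > 0) sort(sample.int(n_snps, n_spiked)) else integer(0)
  f_case <- f0
  f_case[spiked] <- pmin(1, f0[spiked] + delta_f)

  realized_case <- stats::rbinom(n_snps, 2 * N_case, f_case) / (2 * N_case)
  realized_ctrl <- stats::rbinom(n_snps, 2 * N_control, f0) / (2 * N_control)

  grid <- expand.grid(rep = seq_len(n_reps), snp = seq_len(n_snps),
                      KEEP.OUT.ATTRS = FALSE)
  make_rows <- function(pool, realized) {
    raf <- realized[grid$snp] +
      stats::rnorm(nrow(grid), 0, noise_sd)
    raf <- pmin(1, pmax(0, raf))          # truncation, not reflection
    u <- stats::rnorm(nrow(grid), 0, 0.02)
    scale_u <- pmax(0, intensity_scale * (1 + u))
    data.frame(
      snp_id = snp_id[grid$snp],
      chrom = chrom[grid$snp],
      pos = pos[grid$snp],
      pool = pool,
      replicate = grid$rep,
      green_raw = scale_u * raf,
      red_raw = scale_u * (1 - raf),
      stringsAsFactors = FALSE
    )
  }
  tab <- rbind(make_rows("case", realized_case),
               make_rows("control", realized_ctrl))
  tab <- tab[order(tab$snp_id, tab$pool, tab$replicate), , drop = FALSE]
  rownames(tab) <- NULL
  tab$failed <- tab$green_raw == 0 & tab$red_raw == 0

  truth <- list(
    snp_id = snp_id,
    f_case_true = f_case,
    f_control_true = f0,
    realized_case = realized_case,
    realized_control = realized_ctrl,
    spiked_ids = snp_id[spiked],
    delta_f = delta_f,
    N_case = N_case, N_control = N_control,
    n_reps = n_reps, noise_sd = noise_sd,
    seed = seed
  )
  list(table = tab, truth = truth)
}

#' Simulate a case-control genotype cohort
#'
#' Control minor-allele frequency `q = maf_control`; the case frequency is
#' solved from the allelic odds ratio, `p = OR q / (1 - q + OR q)`.
#' Genotypes are drawn under Hardy-Weinberg equilibrium within each group
#' (dosage ~ Binomial(2, freq)).
#'
#' @param n_cases,n_controls Group sizes (default 250/250, the validation
#'   cohort design).
#' @param maf_control Control minor-allele frequency in `(0, 0.5]`.
#' @param or_allelic True allelic odds ratio, `> 0`.
#' @param snp_id Name of the genotype column (default `"snp1"`).
#' @param seed Integer seed.
#' @return List with `cohort` (subject_id, group, dosage column) and
#'   `truth` (the frequencies, OR, seed).
#' @export
simulate_case_control_genotypes <- function(n_cases = 250, n_controls = 250,
                                            maf_control, or_allelic,
                                            snp_id = "snp1", seed = 1) {
  if (maf_control <= 0 || maf_control > 0.5) {
    stop("maf_control must be in (0, 0.5]")
  }
  if (or_allelic <= 0) stop("or_allelic must be > 0")
  set.seed(seed)
  q <- maf_control
  p_case <- (or_allelic * q) / (1 - q + or_allelic * q)
  dos_case <- stats::rbinom(n_cases, 2, p_case)
  dos_ctrl <- stats::rbinom(n_controls, 2, q)
  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_cases + n_controls)),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    stringsAsFactors = FALSE
  )
  cohort[[snp_id]] <- c(dos_case, dos_ctrl)
  attr(cohort, "snp_cols") <- snp_id
  truth <- list(maf_control = q, maf_case = p_case,
                or_allelic = or_allelic, snp_id = snp_id, seed = seed)
  list(cohort = cohort, truth = truth)
}

#' Simulate glucocorticoid response and platelet trajectories
#'
#' Adds to a genotype cohort a Bernoulli response label whose probability
#' depends on carrying the minor allele, and a platelet time series: a
#' logistic rise from a low baseline (`< 30 x10^9/L`, the ITP range)
#' toward a dosage-dependent plateau, plus Normal measurement noise,
#' floored at 0.
#'
#' @param cohort Genotype cohort data frame.
#' @param snp_id Genotype column driving the response.
#' @param response_prob_by_dosage Length-2 vector: response probability
#'   for dosage 0 and for dosage >= 1. Defaults `c(0.60, 0.89)`, the
#'   observed response rates of the validation cohort's CC vs CT/TT
#'   carriers.
#' @param trajectory_params List with `days` (default
#'   `c(1, 3, 5, 7, 11, 14)`), `plateau_by_dosage` (length 2, default
#'   `c(60, 110)`), `rate` (logistic steepness per day, default 0.5),
#'   `midpoint_day` (default 5), `noise_sd` (default 8).
#' @param seed Integer seed.
#' @return The cohort with added `response`, `baseline_plt` and
#'   `plt_d<day>` columns.
#' @export
simulate_treatment_response <- function(cohort, snp_id,
                                        response_prob_by_dosage = c(0.60, 0.89),
                                        trajectory_params = list(),
                                        seed = 1) {
  if (!snp_id %in% names(cohort)) stop("unknown snp_id: ", snp_id)
  tp <- utils::modifyList(
    list(days = c(1, 3, 5, 7, 11, 14),
         plateau_by_dosage = c(60, 110),
         rate = 0.5, midpoint_day = 5, noise_sd = 8),
    trajectory_params
  )
  set.seed(seed)
  dos <- cohort[[snp_id]]
  carrier <- as.integer(!is.na(dos) & dos >= 1)
  p_resp <- response_prob_by_dosage[carrier + 1L]
  responded <- stats::rbinom(nrow(cohort), 1, p_resp) == 1
  cohort$response <- ifelse(responded, "response", "nonresponse")

  baseline <- stats::runif(nrow(cohort), 5, 25)
  cohort$baseline_plt <- baseline
  plateau <- tp$plateau_by_dosage[carrier + 1L]
  # nonresponders stay near baseline regardless of genotype
  plateau[!responded] <- pmin(plateau[!responded], 25)
  for (d in tp$days) {
    rise <- 1 / (1 + exp(-tp$rate * (d - tp$midpoint_day)))
    mu <- baseline + (plateau - baseline) * rise
    cohort[[sprintf("plt_d%d", d)]] <-
      pmax(0, mu + stats::rnorm(nrow(cohort), 0, tp$noise_sd))
  }
  cohort
}
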