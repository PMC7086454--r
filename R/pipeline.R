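# Orchestration: a validated configuration object carrying every tunable
# constant of the workflow, and run_full(), which executes
# simulate (optional) -> assoc -> annotate -> enrich -> validate and
# writes versioned outputs plus a machine-readable manifest so a run can
# be replayed exactly.

#' Workflow configuration
#'
#' Collects every tunable constant of the analysis with the study's values
#' as defaults: QC minimum replicates 3, genome-wide line 1e-7,
#' gene-set line 1e-5, mapping window 20 kb, FPRP prior grid and
#' alternative OR, pool sizes 200/200, validation cohort 250/250.
#'
#' @param min_replicates QC minimum surviving replicates per pool.
#' @param genomewide_alpha Genome-wide significance threshold.
#' @param geneset_alpha Gene-set inclusion threshold.
#' @param window_bp SNP-to-gene mapping window (bp).
#' @param fprp_priors Prior-probability grid for FPRP.
#' @param fprp_or_alt Alternative odds ratio for FPRP power.
#' @param bh_m_total Optional BH total-test-count override.
#' @param reference_size Optional reference-universe override for
#'   enrichment.
#' @param N_case,N_control Stage-1 pool sizes (individuals).
#' @param seed Integer seed used by any simulated stage.
#' @param simulate List of arguments for [simulate_pooled_experiment()]
#'   (or `NULL` to analyse user-supplied intensities).
#' @param intensities,genes_bed,pathways_gmt,genotypes Input paths (any
#'   may be `NULL` to skip the stage that needs it).
#' @return A classed list (`poolgwas_config`).
#' @export
pool_config <- function(min_replicates = 3,
                        genomewide_alpha = 1.0e-7,
                        geneset_alpha = 1.0e-5,
                        window_bp = 20000,
                        fprp_priors = c(0.25, 0.1, 0.01, 0.001),
                        fprp_or_alt = 1.5,
                        bh_m_total = NULL,
                        reference_size = NULL,
                        N_case = 200, N_control = 200,
                        seed = 1,
                        simulate = NULL,
                        intensities = NULL,
                        genes_bed = NULL,
                        pathways_gmt = NULL,
                        genotypes = NULL) {
  stopifnot(genomewide_alpha > 0, genomewide_alpha <= 1,
            geneset_alpha > 0, geneset_alpha <= 1,
            window_bp >= 0, min_replicates >= 1)
  structure(
    list(min_replicates = min_replicates,
         genomewide_alpha = genomewide_alpha,
         geneset_alpha = geneset_alpha,
         window_bp = window_bp,
         fprp_priors = fprp_priors,
         fprp_or_alt = fprp_or_alt,
         bh_m_total = bh_m_total,
         reference_size = reference_size,
         N_case = N_case, N_control = N_control,
         seed = seed,
         simulate = simulate,
         intensities = intensities,
         genes_bed = genes_bed,
         pathways_gmt = pathways_gmt,
         genotypes = genotypes),
    class = "poolgwas_config"
  )
}

#' Load a workflow configuration from YAML
#'
#' Reads a YAML mapping and merges it over the [pool_config()] defaults;
#' unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `poolgwas_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pool_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pool_config, vals)
}

.log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full workflow
#'
#' Executes, in order: optional simulation of the pooled experiment, the
#' pooled association scan (QC, RAF summary, combined Z-test, QQ and
#' Manhattan coordinates, RAF correlation), hit annotation (gene mapping,
#' OR, FPRP), pathway enrichment on the selected gene set, and
#' validation-cohort statistics when a genotype table is supplied. All
#' result tables are written under `outdir` together with `manifest.json`
#' (config, seed, input digests) and `run.log`. Re-running with the same
#' config and inputs reproduces byte-identical result tables.
#'
#' @param config A [pool_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_full <- function(config, outdir) {
  stopifnot(inherits(config, "poolgwas_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  cat("", file = log_path)
  results <- list()
  inputs <- character(0)

  # -- stage: simulate / load intensities -------------------------------
  if (!is.null(config$simulate)) {
    .log_line(log_path, "simulate: generating pooled experiment (seed ",
              config$seed, ")")
    sim_args <- utils::modifyList(list(seed = config$seed), config$simulate)
    sim <- do.call(simulate_pooled_experiment, sim_args)
    tab <- sim$table
    truth_path <- file.path(outdir, "truth.tsv")
    write_results(data.frame(snp_id = sim$truth$snp_id,
                             f_case_true = sim$truth$f_case_true,
                             f_control_true = sim$truth$f_control_true,
                             spiked = sim$truth$snp_id %in%
                               sim$truth$spiked_ids),
                  truth_path)
    results$truth <- sim$truth
  } else if (!is.null(config$intensities)) {
    .log_line(log_path, "load: reading intensities from ", config$intensities)
    tab <- read_pool_intensities(config$intensities)
    inputs <- c(inputs, config$intensities)
  } else {
    stop("config must provide either `simulate` parameters or an ",
         "`intensities` path")
  }

  # -- stage: assoc ------------------------------------------------------
  qcd <- qc_filter(tab, min_replicates = config$min_replicates)
  rep_qc <- qc_report(qcd)
  .log_line(log_path, "qc: ", rep_qc$n_retained_snps, "/",
            rep_qc$n_input_snps, " SNPs retained (",
            rep_qc$n_failed_rows, " failed rows, ",
            rep_qc$n_nonautosomal_snps, " non-autosomal, ",
            rep_qc$n_low_replicate_snps, " low-replicate)")
  jsonlite::write_json(rep_qc, file.path(outdir, "qc.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  summ <- summarize_pools(qcd, config$N_case, config$N_control)
  assoc <- combined_z_test(summ, alpha = config$genomewide_alpha)
  write_results(assoc, file.path(outdir, "assoc.tsv"))
  write_results(qq_points(assoc$p_value), file.path(outdir, "qq.tsv"))
  write_results(manhattan_points(assoc), file.path(outdir, "manhattan.tsv"))
  r2 <- if (nrow(summ) >= 2) raf_correlation(summ$f_case, summ$f_control)
        else NA_real_
  hits <- genomewide_hits(assoc, alpha = config$genomewide_alpha)
  .log_line(log_path, "assoc: ", nrow(assoc), " SNPs tested, ",
            nrow(hits), " genome-wide hits, RAF r^2 = ",
            formatC(r2, digits = 4, format = "f"))
  results$summary <- summ
  results$assoc <- assoc
  results$hits <- hits
  results$raf_r2 <- r2

  # -- stage: annotate ---------------------------------------------------
  if (!is.null(config$genes_bed)) {
    ann <- read_gene_annotation(config$genes_bed)
    inputs <- c(inputs, config$genes_bed)
    assign_in <- merge(assoc[, c("snp_id", "chrom", "pos", "p_value")],
                       summ[, c("snp_id", "f_case", "f_control")],
                       by = "snp_id")
    assignments <- map_snps_to_genes(assign_in, ann,
                                     window_bp = config$window_bp)
    genes <- gene_level_best(assignments)
    study_set <- select_gene_set(genes, alpha = config$geneset_alpha)
    # OR + FPRP for the genome-wide hits (frequencies strictly inside (0,1))
    hit_sum <- summ[summ$snp_id %in% hits$snp_id, , drop = FALSE]
    ok <- hit_sum$f_case > 0 & hit_sum$f_case < 1 &
      hit_sum$f_control > 0 & hit_sum$f_control < 1
    hit_sum <- hit_sum[ok, , drop = FALSE]
    if (nrow(hit_sum) > 0L) {
      ors <- or_from_raf(hit_sum$f_case, hit_sum$f_control,
                         config$N_case, config$N_control)
      pv <- assoc$p_value[match(hit_sum$snp_id, assoc$snp_id)]
      fp <- sapply(config$fprp_priors, function(pi0) {
        fprp(pv, or_alt = config$fprp_or_alt,
             se_log_or = ors$se_log_or, prior_pi = pi0)
      })
      fp <- matrix(fp, nrow = nrow(hit_sum))
      colnames(fp) <- paste0("fprp_pi_", config$fprp_priors)
      hit_report <- cbind(
        data.frame(snp_id = hit_sum$snp_id, p_value = pv), ors, fp)
      write_results(hit_report, file.path(outdir, "hits_annotated.tsv"))
      results$hit_report <- hit_report
    }
    write_results(genes, file.path(outdir, "genes.tsv"))
    writeLines(study_set, file.path(outdir, "gene_set.txt"))
    .log_line(log_path, "annotate: ", nrow(genes), " genes, ",
              length(study_set), " in the study set (p < ",
              config$geneset_alpha, ")")
    results$assignments <- assignments
    results$genes <- genes
    results$study_set <- study_set
  }

  # -- stage: enrich -----------------------------------------------------
  if (!is.null(config$pathways_gmt) && !is.null(results$study_set)) {
    db <- read_gmt(config$pathways_gmt)
    inputs <- c(inputs, config$pathways_gmt)
    enr <- enrich_pathways(results$study_set, db,
                           reference_size = config$reference_size,
                           m_total = config$bh_m_total)
    write_results(enr, file.path(outdir, "enrich.tsv"))
    .log_line(log_path, "enrich: ", nrow(enr), " pathways, ",
              sum(enr$adj_p < 0.05), " with adj-p < 0.05")
    results$enrichment <- enr
  }

  # -- stage: validate ---------------------------------------------------
  if (!is.null(config$genotypes)) {
    cohort <- read_genotypes(config$genotypes)
    inputs <- c(inputs, config$genotypes)
    snp_cols <- attr(cohort, "snp_cols")
    rows <- lapply(snp_cols, function(s) {
      cnt <- genotype_counts(cohort, s)
      if (!all(c("case", "control") %in% names(cnt))) return(NULL)
      hw_ca <- hwe_test(cnt$case[1], cnt$case[2], cnt$case[3])
      hw_co <- hwe_test(cnt$control[1], cnt$control[2], cnt$control[3])
      as23 <- tryCatch(genotype_assoc_2x3(cnt$case, cnt$control),
                       error = function(e) list(chi2 = NA, df = NA, p = NA))
      orr <- tryCatch(allelic_or(cnt$case, cnt$control),
                      error = function(e) NULL)
      data.frame(
        snp_id = s,
        case_n0 = cnt$case[1], case_n1 = cnt$case[2], case_n2 = cnt$case[3],
        control_n0 = cnt$control[1], control_n1 = cnt$control[2],
        control_n2 = cnt$control[3],
        hwe_p_case = hw_ca$p, hwe_p_control = hw_co$p,
        chi2_2x3 = as23$chi2, df_2x3 = as23$df, p_2x3 = as23$p,
        or_allelic = if (is.null(orr)) NA_real_ else orr$or,
        or_ci_low = if (is.null(orr)) NA_real_ else orr$ci95_low,
        or_ci_high = if (is.null(orr)) NA_real_ else orr$ci95_high,
        p_allelic = if (is.null(orr)) NA_real_ else orr$p,
        row.names = NULL
      )
    })
    validate <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (!is.null(validate)) {
      write_results(validate, file.path(outdir, "validate.tsv"))
      .log_line(log_path, "validate: ", nrow(validate), " SNPs")
      results$validate <- validate
    }
  }

  manifest <- list(
    package = "poolgwas",
    version = as.character(utils::packageVersion("poolgwas")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  .log_line(log_path, "done: outputs in ", outdir)
  invisible(results)
}
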