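# Readers/writers for the tabular dialects the workflow touches.
# Every reader accepts plain or gzip text: gzfile() transparently reads both.

.read_con <- function(path) gzfile(path, "rt")

.write_con <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Read a pooled-array intensity table
#'
#' Reads the project's two-channel intensity dialect: a tab-separated table
#' with header `snp_id chrom pos pool replicate green red`, one row per
#' SNP x pool x replicate, `.` marking a missing intensity. Rows whose
#' channels are both zero (or missing) record a failed hybridization; they
#' are retained and flagged so QC can count them before dropping them.
#'
#' @param path Path to a TSV file (optionally gzip-compressed).
#' @return A data frame with columns `snp_id`, `chrom`, `pos`, `pool`,
#'   `replicate`, `green_raw`, `red_raw` and logical `failed`.
#' @export
read_pool_intensities <- function(path) {
  con <- .read_con(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          na.strings = ".", stringsAsFactors = FALSE,
                          colClasses = c(snp_id = "character",
                                         chrom = "character"))
  required <- c("snp_id", "chrom", "pos", "pool", "replicate", "green", "red")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("intensity table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  # line numbers reported to the user count the header as line 1
  lineno <- seq_len(nrow(df)) + 1L

  bad_pos <- which(!is.finite(df$pos) | df$pos < 1)
  if (length(bad_pos) > 0L) {
    stop("intensity table value error: pos must be >= 1 at line(s) ",
         paste(lineno[bad_pos], collapse = ", "))
  }
  bad_pool <- which(!df$pool %in% c("case", "control"))
  if (length(bad_pool) > 0L) {
    stop("intensity table value error: pool must be 'case' or 'control' at line(s) ",
         paste(lineno[bad_pool], collapse = ", "))
  }
  bad_rep <- which(!is.finite(df$replicate) | df$replicate < 1 |
                     df$replicate != round(df$replicate))
  if (length(bad_rep) > 0L) {
    stop("intensity table value error: replicate must be an integer >= 1 at line(s) ",
         paste(lineno[bad_rep], collapse = ", "))
  }
  bad_neg <- which((!is.na(df$green) & df$green < 0) |
                     (!is.na(df$red) & df$red < 0))
  if (length(bad_neg) > 0L) {
    stop("intensity table value error: negative intensity at line(s) ",
         paste(lineno[bad_neg], collapse = ", "))
  }
  key <- paste(df$snp_id, df$pool, df$replicate, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("intensity table duplicate error: duplicated (snp_id, pool, replicate) key(s): ",
         paste(unique(key[dup]), collapse = ", "))
  }
  out <- data.frame(
    snp_id = df$snp_id,
    chrom = df$chrom,
    pos = as.integer(df$pos),
    pool = df$pool,
    replicate = as.integer(df$replicate),
    green_raw = as.numeric(df$green),
    red_raw = as.numeric(df$red),
    stringsAsFactors = FALSE
  )
  out$failed <- is.na(out$green_raw) | is.na(out$red_raw) |
    (out$green_raw == 0 & out$red_raw == 0)
  out
}

#' Write a pooled-array intensity table
#'
#' Inverse of [read_pool_intensities()]; missing intensities are written as
#' `.`. The `failed` flag is recomputed on read, not stored.
#'
#' @param table Data frame as returned by [read_pool_intensities()].
#' @param path Output path (gzip if it ends in `.gz`).
#' @export
write_pool_intensities <- function(table, path) {
  out <- data.frame(
    snp_id = table$snp_id, chrom = table$chrom, pos = table$pos,
    pool = table$pool, replicate = table$replicate,
    green = table$green_raw, red = table$red_raw,
    stringsAsFactors = FALSE
  )
  con <- .write_con(path)
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read gene annotation from BED
#'
#' Reads BED4+ (chrom, 0-based half-open chromStart/chromEnd, name) via
#' `rtracklayer` and converts to the workflow's internal 1-based inclusive
#' coordinates: `start = chromStart + 1`, `end = chromEnd`. Records are
#' returned sorted by (chrom, start). Zero-length records are rejected.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @return Data frame with `gene_symbol`, `chrom`, `start`, `end`, `strand`
#'   (one of `+`, `-`, `unknown`).
#' @export
read_gene_annotation <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) {
      stop("BED value error: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(gr) > 0L && any(GenomicRanges::width(gr) < 1L)) {
    stop("BED value error: zero-length record (chromStart >= chromEnd)")
  }
  nm <- if (length(gr) > 0L) S4Vectors::mcols(gr)$name else character(0)
  if (is.null(nm) || any(is.na(nm) | nm == "")) {
    stop("BED format error: every record needs a non-empty name (BED4+)")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "unknown"
  ann <- data.frame(
    gene_symbol = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  ann <- ann[order(ann$chrom, ann$start, ann$end, ann$gene_symbol), ,
             drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write gene annotation as BED
#'
#' Converts the internal 1-based inclusive spans back to BED's 0-based
#' half-open convention, so read -> write reproduces the original
#' coordinates.
#'
#' @param annotation Data frame as returned by [read_gene_annotation()].
#' @param path Output BED path.
#' @export
write_gene_annotation <- function(annotation, path) {
  strand <- annotation$strand
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = strand,
    name = annotation$gene_symbol,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read pathway gene sets from GMT
#'
#' Standard GMT: one pathway per line, tab-separated `name description
#' gene1 gene2 ...`. Genes duplicated within a set are deduplicated; if the
#' same pathway name occurs on several lines the last one wins with a
#' warning. The reference universe size defaults to the size of the union
#' of all sets when not supplied.
#'
#' @param path Path to a GMT file (optionally gzipped).
#' @param reference_size Optional integer, the number of genes in the
#'   reference universe the sets are drawn from.
#' @return List with `pathways` (named list of character vectors) and
#'   `reference_size`.
#' @export
read_gmt <- function(path, reference_size = NULL) {
  con <- .read_con(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pathways <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT format error: line ", i, " has fewer than 3 fields")
    }
    name <- fields[[1]]
    genes <- unique(fields[-c(1L, 2L)])
    genes <- genes[nzchar(genes)]
    if (name %in% names(pathways)) {
      warning("GMT: pathway '", name, "' listed more than once; last wins")
    }
    pathways[[name]] <- genes
  }
  if (is.null(reference_size)) {
    reference_size <- length(unique(unlist(pathways, use.names = FALSE)))
  }
  if (length(pathways) > 0L &&
      reference_size < max(lengths(pathways))) {
    stop("GMT value error: reference_size smaller than the largest set")
  }
  list(pathways = pathways, reference_size = as.integer(reference_size))
}

#' Read a genotype cohort table
#'
#' Dialect: TSV with header `subject_id group <snp> <snp> ...` where each
#' SNP column holds a minor-allele dosage 0/1/2 or `NA`. Optional
#' non-genotype columns are `response` (character), `baseline_plt` and
#' `plt_d<day>` (platelet counts x10^9/L).
#'
#' @param path Path to a TSV file (optionally gzipped).
#' @return Data frame; SNP columns are integer dosages, and the vector of
#'   SNP column names is attached as attribute `snp_cols`.
#' @export
read_genotypes <- function(path) {
  con <- .read_con(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          na.strings = "NA", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("genotype table format error: need 'subject_id' and 'group' columns")
  }
  special <- c("subject_id", "group", "response", "baseline_plt")
  snp_cols <- setdiff(names(df),
                      c(special, grep("^plt_d", names(df), value = TRUE)))
  for (sc in snp_cols) {
    v <- df[[sc]]
    if (!all(is.na(v) | v %in% c(0, 1, 2))) {
      stop("genotype table value error: dosage outside {0,1,2,NA} in column ", sc)
    }
    df[[sc]] <- as.integer(v)
  }
  plt_cols <- grep("^plt_d", names(df), value = TRUE)
  bad_plt <- unlist(lapply(c(intersect("baseline_plt", names(df)), plt_cols),
                           function(cc) any(df[[cc]] < 0, na.rm = TRUE)))
  if (any(bad_plt)) stop("genotype table value error: negative platelet count")
  attr(df, "snp_cols") <- snp_cols
  df
}

#' Write a genotype cohort table
#' @param cohort Data frame as returned by [read_genotypes()].
#' @param path Output path.
#' @export
write_genotypes <- function(cohort, path) {
  con <- .write_con(path)
  on.exit(close(con))
  utils::write.table(cohort, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a results table at full precision
#'
#' Numeric columns are rendered with 15 significant digits so a written
#' table re-reads equal to the original well beyond reporting precision.
#'
#' @param results Data frame of results.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  out <- results
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- out[[nm]]
      s <- sprintf("%.15g", v)
      s[is.na(v)] <- NA_character_
      out[[nm]] <- s
    }
  }
  con <- .write_con(path)
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_results <- function(path) {
  con <- .read_con(path)
  on.exit(close(con))
  utils::read.table(con, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
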