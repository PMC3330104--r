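#' Read a genotype matrix from VCF or dosage TSV
#'
#' VCF input is parsed with \pkg{vcfR}; the GT field is converted to
#' dosages 0/1/2 with \code{"./."} as missing, and multi-allelic records
#' are skipped with their count logged.  TSV input must be a dosage
#' matrix written by \code{\link{write_genotypes_tsv}} (SNP metadata
#' columns followed by one column per individual).
#'
#' @param path File path; format chosen by extension (\code{.vcf} /
#'   \code{.vcf.gz} versus anything else = TSV).
#' @param pop Population label stored on the result (default the file
#'   name without extension).
#' @return A \code{genotype_matrix}.
#' @export
read_genotypes <- function(path, pop = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(pop)) pop <- sub("\\.(vcf|tsv)(\\.gz)?$", "", basename(path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi)) message(sum(multi), " multi-allelic record(s) skipped")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA)
    bad <- !is.na(clean) & !clean %in% names(lut)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop("malformed GT '", clean[bad][1], "' at record ", w[1])
    }
    dos[] <- lut[clean]
    snp_info <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           ref = fix[, "REF"], alt = fix[, "ALT"],
                           stringsAsFactors = FALSE)
    rownames(dos) <- snp_info$snp_id
  } else {
    d <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
    meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
    snp_info <- d[, meta_cols]
    dos <- as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE])
    rownames(dos) <- snp_info$snp_id
  }
  structure(list(dosage = dos, snp_info = snp_info, pop = pop),
            class = "genotype_matrix")
}

## "# key=value" provenance header lines
.prov_header <- function(config = list()) {
  if (!length(config)) return(character(0))
  sprintf("# %s=%s", names(config),
          vapply(config, function(v) paste(v, collapse = ","), ""))
}

#' Write a genotype matrix as VCF
#'
#' Minimal VCFv4.2 with a GT field; missing dosages become \code{"./."}.
#'
#' @param geno A \code{genotype_matrix}.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(geno$dosage)),
                     collapse = "\t")), con)
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix(gtmap[geno$dosage + 1L], nrow(geno$dosage))
  gt[is.na(geno$dosage)] <- "./."
  si <- geno$snp_info
  lines <- paste(si$chrom, si$pos, si$snp_id, si$ref, si$alt, ".", "PASS",
                 ".", "GT", apply(gt, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
}

#' Write a genotype matrix as dosage TSV
#'
#' @param geno A \code{genotype_matrix}.
#' @param path Output path.
#' @param config Optional named list echoed as \code{# key=value} header
#'   comments.
#' @export
write_genotypes_tsv <- function(geno, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(config), con)
  d <- cbind(geno$snp_info,
             as.data.frame(geno$dosage, check.names = FALSE))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write an expression matrix as TSV
#'
#' The processing stage and any config entries are echoed as
#' \code{# key=value} header comments; rows are probes, columns are
#' sample identifiers.
#'
#' @param expr An \code{expression_matrix}.
#' @param path Output path.
#' @param config Optional named list of provenance entries.
#' @export
write_expression_tsv <- function(expr, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(c(list(stage = expr$stage), config)), con)
  d <- cbind(probe_id = rownames(expr$values),
             as.data.frame(expr$values, check.names = FALSE))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression TSV written by \code{\link{write_expression_tsv}}
#'
#' @param path File path.
#' @param sample_meta Optional sample metadata to attach (matched by
#'   sample id).
#' @return An \code{expression_matrix}; the stage is recovered from the
#'   \code{# stage=} header comment (default \code{"raw"}).
#' @export
read_expression_tsv <- function(path, sample_meta = NULL) {
  hdr <- readLines(path, n = 50)
  hdr <- hdr[startsWith(hdr, "#")]
  stage <- sub("^# stage=", "", grep("^# stage=", hdr, value = TRUE))
  if (!length(stage)) stage <- "raw"
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (!is.null(sample_meta))
    sample_meta <- sample_meta[match(colnames(m), sample_meta$sample_id), ,
                               drop = FALSE]
  expression_matrix(m, stage = stage, sample_meta = sample_meta)
}

#' Write probe annotation as TSV (1-based inclusive coordinates)
#'
#' @param annot Annotation data frame (probe_id, gene_id, chrom, tss,
#'   strand, snp_in_probe, and optionally eligible).
#' @param path Output path.
#' @param config Optional provenance entries.
#' @export
write_annotation_tsv <- function(annot, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(config), con)
  utils::write.table(annot, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read probe annotation TSV
#' @param path File path.
#' @return Annotation data frame.
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Validated pipeline run configuration
#'
#' @param alpha Discovery permutation tail level (default 0.01).
#' @param alpha_strict Stricter reporting level (default 0.001).
#' @param n_perms Permutations per gene (default 10000).
#' @param window Cis window half-width (default 1e6).
#' @param maf,missingness SNP filters (defaults 0.05, 0.20).
#' @param n_hidden Hidden factors for the reduced dataset (default 32).
#' @param seed Run seed (recorded in every output header).
#' @return A validated list of class \code{run_config}.
#' @export
run_config <- function(alpha = 0.01, alpha_strict = 0.001, n_perms = 10000,
                       window = 1e6, maf = 0.05, missingness = 0.20,
                       n_hidden = 32, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, alpha_strict > 0, alpha_strict <= alpha,
            n_perms >= 100, window > 0, maf >= 0, maf < 0.5,
            missingness > 0, missingness <= 1, n_hidden >= 0)
  structure(list(alpha = alpha, alpha_strict = alpha_strict,
                 n_perms = n_perms, window = window, maf = maf,
                 missingness = missingness, n_hidden = n_hidden,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a simulated or loaded study
#'
#' Stages, in order: replicate quantile normalization + median
#' normalization; per-population genotype-PCA stratification correction;
#' ARD factor analysis ("reduced" residuals); cis mapping on both the
#' stratification-corrected and the reduced data; stepwise conditional
#' mapping; V_ST scan; sharing summaries.  When \code{out_dir} is given,
#' every table is written as TSV with a config + seed provenance header
#' and a per-stage log is kept.
#'
#' @param study An \code{eqtl_sim} (or a list with the same elements:
#'   genotypes, expr, annot).
#' @param config A \code{\link{run_config}}.
#' @param out_dir Optional output directory (created if needed).
#' @return List: per-population \code{scans_corrected} and
#'   \code{scans_reduced} (\code{cis_scan} objects), \code{stepwise},
#'   \code{vst}, \code{sharing}, \code{annot_selected}, \code{log}.
#' @export
run_pipeline <- function(study, config = run_config(), out_dir = NULL) {
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- "normalize"
  result <- tryCatch({
    annot <- select_probes(study$annot)
    note("probes eligible: ", sum(annot$eligible), " of ", nrow(annot))

    norm <- median_normalize(quantile_normalize_replicates(study$expr))
    pops <- names(study$genotypes)
    split_expr <- lapply(pops, function(p) {
      keep <- norm$sample_meta$population == p
      expression_matrix(norm$values[, keep, drop = FALSE],
                        stage = norm$stage,
                        sample_meta = norm$sample_meta[keep, , drop = FALSE])
    })
    names(split_expr) <- pops

    stage <- "stratification-correct"
    corrected <- lapply(pops, function(p) {
      pcs <- genotype_pca(study$genotypes[[p]], n_axes = 10,
                          maf = config$maf, missingness = config$missingness)
      residualize_covariates(split_expr[[p]], pcs)
    })
    names(corrected) <- pops

    stage <- "reduce"
    reduced <- lapply(pops, function(p)
      fit_factor_residuals(corrected[[p]], n_hidden = config$n_hidden))
    names(reduced) <- pops
    note("reduced datasets fitted (",
         paste0(vapply(reduced, `[[`, 0L, "n_effective"), collapse = "/"),
         " effective factors per population)")

    stage <- "map-cis"
    scans_corr <- lapply(pops, function(p)
      map_cis(corrected[[p]], study$genotypes[[p]], annot,
              alpha = config$alpha, n_perms = config$n_perms,
              window = config$window, maf = config$maf,
              missingness = config$missingness, seed = config$seed))
    names(scans_corr) <- pops
    scans_red <- lapply(pops, function(p)
      map_cis(reduced[[p]]$residuals, study$genotypes[[p]], annot,
              alpha = config$alpha, n_perms = config$n_perms,
              window = config$window, maf = config$maf,
              missingness = config$missingness, seed = config$seed))
    names(scans_red) <- pops
    for (p in pops)
      note(p, ": ", scans_corr[[p]]$n_significant, " significant (corrected), ",
           scans_red[[p]]$n_significant, " (reduced); FDR ",
           round(scans_corr[[p]]$fdr, 3), " / ", round(scans_red[[p]]$fdr, 3))

    stage <- "stepwise"
    stepwise <- lapply(pops, function(p) {
      sc <- scans_corr[[p]]
      sig <- sc$genes[sc$genes$significant, , drop = FALSE]
      do.call(rbind, lapply(sig$gene_id, function(g)
        stepwise_independent(g, sc$assoc, corrected[[p]],
                             study$genotypes[[p]],
                             sc$thresholds$threshold_p[
                               sc$thresholds$gene_id == g])))
    })
    names(stepwise) <- pops

    stage <- "vst"
    vst_res <- vst_scan(norm)

    stage <- "share"
    sig_sets <- lapply(scans_corr, function(s)
      s$genes$gene_id[s$genes$significant])
    share <- sharing_matrix(sig_sets)
    note("nonredundant significant genes: ", share$n_nonredundant,
         " (", share$pct_ge2, "% in >= 2 populations)")

    list(scans_corrected = scans_corr, scans_reduced = scans_red,
         stepwise = stepwise, vst = vst_res, sharing = share,
         corrected = corrected, reduced = reduced,
         annot_selected = annot, config = config, log = log)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- unclass(config)
    for (p in names(result$scans_corrected)) {
      a <- result$scans_corrected[[p]]$assoc
      a$threshold_p <- result$scans_corrected[[p]]$thresholds$threshold_p[
        match(a$gene_id, result$scans_corrected[[p]]$thresholds$gene_id)]
      a$significant <- a$p_nominal < a$threshold_p
      .write_tsv(a, file.path(out_dir, paste0("assoc_corrected_", p, ".tsv")),
                 cfg)
      .write_tsv(result$scans_corrected[[p]]$genes,
                 file.path(out_dir, paste0("genes_corrected_", p, ".tsv")), cfg)
      if (!is.null(result$stepwise[[p]]))
        .write_tsv(result$stepwise[[p]],
                   file.path(out_dir, paste0("stepwise_", p, ".tsv")), cfg)
    }
    .write_tsv(result$vst$table, file.path(out_dir, "vst.tsv"), cfg)
    .write_tsv(result$vst$summary, file.path(out_dir, "vst_summary.tsv"), cfg)
    writeLines(result$log, file.path(out_dir, "pipeline.log"))
  }
  result
}

.write_tsv <- function(d, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(config), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
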