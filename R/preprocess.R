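#' Expression matrix container
#'
#' A probe x sample matrix of log2-scale intensities together with its
#' processing stage and per-sample metadata.  Stages advance in the
#' documented order raw -> normalized -> strat_corrected -> reduced.
#'
#' @param values Numeric matrix, probes in rows, samples in columns; must
#'   carry dimnames and contain no infinite values.
#' @param stage One of \code{"raw"}, \code{"normalized"},
#'   \code{"strat_corrected"}, \code{"reduced"}.
#' @param sample_meta Data frame with one row per column of \code{values};
#'   must include \code{sample_id} matching the column names, and
#'   typically \code{individual}, \code{population}, \code{gender}.
#' @return Object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, stage = "raw", sample_meta = NULL) {
  stage <- match.arg(stage, c("raw", "normalized", "strat_corrected", "reduced"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe rownames and sample colnames")
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample_id = colnames(values),
                              stringsAsFactors = FALSE)
  if (!identical(sample_meta$sample_id, colnames(values)))
    stop("sample_meta$sample_id must match the column names of values")
  structure(list(values = values, stage = stage, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix [", x$stage, "]: ", nrow(x$values), " probes x ",
      ncol(x$values), " samples\n", sep = "")
  if ("population" %in% names(x$sample_meta))
    print(table(x$sample_meta$population))
  invisible(x)
}

.stage_order <- c(raw = 1, normalized = 2, strat_corrected = 3, reduced = 4)

.advance_stage <- function(expr, to) {
  if (.stage_order[[to]] < .stage_order[[expr$stage]])
    stop("stage may not move backwards (", expr$stage, " -> ", to, ")")
  expr$stage <- to
  expr
}

## quantile-normalize the columns of a small matrix to their common
## distribution of mean order statistics; average ranks for ties, with
## linear interpolation at half ranks
.qnorm_cols <- function(m) {
  if (ncol(m) == 1) return(m)
  ref <- rowMeans(matrix(apply(m, 2, sort), nrow(m)))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

#' Quantile-normalize replicate hybridizations and collapse to individuals
#'
#' Within each individual, the replicate columns are quantile normalized
#' to a common distribution (rank k maps to the mean of the k-th order
#' statistics across that individual's replicates) and then averaged to a
#' single column per individual.  Stage advances to \code{"normalized"}
#' only after \code{\link{median_normalize}}; here the stage is kept at
#' \code{"raw"} because the paper-standard recipe applies both steps.
#'
#' @param expr \code{expression_matrix}, typically at stage \code{"raw"},
#'   whose sample metadata has an \code{individual} column.
#' @return \code{expression_matrix} with one column per individual.
#' @export
quantile_normalize_replicates <- function(expr) {
  meta <- expr$sample_meta
  if (is.null(meta$individual))
    stop("sample_meta must contain an 'individual' column")
  inds <- unique(meta$individual)
  vals <- matrix(0, nrow(expr$values), length(inds),
                 dimnames = list(rownames(expr$values), inds))
  for (ind in inds) {
    cols <- which(meta$individual == ind)
    if (!length(cols)) stop("individual ", ind, " has no replicate columns")
    vals[, ind] <- rowMeans(.qnorm_cols(expr$values[, cols, drop = FALSE]))
  }
  keep <- !duplicated(meta$individual)
  new_meta <- meta[keep, setdiff(names(meta), c("sample_id", "replicate")),
                   drop = FALSE]
  new_meta <- cbind(sample_id = inds, new_meta, stringsAsFactors = FALSE)
  rownames(new_meta) <- NULL
  expression_matrix(vals, stage = expr$stage, sample_meta = new_meta)
}

#' Median-normalize samples
#'
#' Each sample column is shifted additively (log2 scale) so that its
#' median equals the grand median of the per-sample medians; afterwards
#' all column medians are equal.
#'
#' @param expr \code{expression_matrix} with >= 2 samples.
#' @return \code{expression_matrix} at stage \code{"normalized"}.
#' @export
median_normalize <- function(expr) {
  if (ncol(expr$values) < 2) stop("median normalization needs >= 2 samples")
  meds <- apply(expr$values, 2, stats::median)
  grand <- stats::median(meds)
  expr$values <- sweep(expr$values, 2, meds - grand)
  .advance_stage(expr, "normalized")
}

#' Select probes eligible for association mapping
#'
#' A probe is eligible when it maps to exactly one gene and that gene is
#' autosomal.  Probes overlapping a common SNP are retained but flagged
#' (\code{snp_in_probe}), so downstream analyses can test for artifact
#' enrichment rather than discard them.  Probes lacking coordinates are
#' marked ineligible with a warning.
#'
#' @param annot Data frame with one row per probe-gene mapping: columns
#'   \code{probe_id}, \code{gene_id}, \code{chrom}, \code{tss},
#'   \code{strand} and optionally \code{snp_in_probe}.
#' @param autosomes Character vector of autosomal chromosome labels
#'   (default \code{as.character(1:22)}).
#' @return One row per probe with an added logical \code{eligible} column;
#'   multi-gene probes keep their first mapping row but are ineligible.
#' @export
select_probes <- function(annot, autosomes = as.character(1:22)) {
  if (is.null(annot$snp_in_probe)) annot$snp_in_probe <- FALSE
  n_genes <- table(annot$probe_id)
  first <- annot[!duplicated(annot$probe_id), , drop = FALSE]
  multi <- names(n_genes)[n_genes > 1]
  no_coord <- is.na(first$tss) | is.na(first$chrom)
  if (any(no_coord))
    warning(sum(no_coord), " probe(s) lack coordinates; marked ineligible")
  first$eligible <- !(first$probe_id %in% multi) &
    !no_coord & first$chrom %in% autosomes
  rownames(first) <- NULL
  first
}

#' Intra-population genotype PCA for stratification correction
#'
#' SNPs are filtered to MAF > \code{maf} and missingness <
#' \code{missingness}; missing dosages are mean-imputed per SNP; the
#' dosage matrix is standardized per SNP and decomposed by SVD.  Scores
#' are the principal component projections of the samples, centred at 0
#' and ordered by variance explained.
#'
#' @param geno A \code{genotype_matrix}.
#' @param n_axes Number of axes requested (default 10); if the matrix
#'   rank is lower, the available axes are returned with a warning.
#' @param maf,missingness SNP filters (defaults 0.05 and 0.20).
#' @return Sample x axis score matrix with an attribute
#'   \code{"var_explained"}.
#' @export
genotype_pca <- function(geno, n_axes = 10, maf = 0.05, missingness = 0.20) {
  keep <- genotype_maf(geno) > maf & genotype_missingness(geno) < missingness
  m <- geno$dosage[keep, , drop = FALSE]
  if (!nrow(m)) stop("no SNPs pass the MAF/missingness filters")
  # mean-impute per SNP, then standardize
  mu <- rowMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, 1]]
  m <- m - mu
  s <- sqrt(rowMeans(m^2))
  m <- m[s > 0, , drop = FALSE] / s[s > 0]
  sv <- svd(t(m))                      # samples x SNPs
  r <- sum(sv$d > sv$d[1] * 1e-8)
  k <- min(n_axes, r)
  if (k < n_axes)
    warning("only ", k, " axes available (rank ", r, "); returning those")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  scores <- sweep(scores, 2, colMeans(scores))
  dimnames(scores) <- list(colnames(geno$dosage), paste0("PC", seq_len(k)))
  attr(scores, "var_explained") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  scores
}

#' Residualize expression on sample covariates
#'
#' Per probe, ordinary least-squares regression of expression on the
#' covariates (plus an intercept); the residuals replace the expression
#' values.  Collinear covariate columns are detected by pivoted QR and
#' dropped with a message.
#'
#' @param expr \code{expression_matrix}.
#' @param covars Sample x covariate numeric matrix aligned with the
#'   expression columns (rownames checked when present).
#' @param stage Stage tag of the result (default \code{"strat_corrected"}).
#' @return \code{expression_matrix} of residuals.
#' @export
residualize_covariates <- function(expr, covars, stage = "strat_corrected") {
  covars <- as.matrix(covars)
  if (nrow(covars) != ncol(expr$values))
    stop("covariate rows must match expression samples")
  if (!is.null(rownames(covars)) &&
      !identical(rownames(covars), colnames(expr$values)))
    stop("covariate rownames do not align with expression samples")
  X <- cbind(`(Intercept)` = 1, covars)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_n <- ncol(X) - qx$rank
    message("dropping ", drop_n, " collinear covariate column(s)")
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  expr$values <- t(qr.resid(qx, t(expr$values)))
  .advance_stage(expr, stage)
}
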