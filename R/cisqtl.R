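#' Enumerate cis SNP-probe pairs
#'
#' All and only pairs with |SNP position - TSS| <= \code{window} on the
#' same chromosome (closed interval, 1-based coordinates), restricted to
#' SNPs passing the MAF and missingness filters in this population.  The
#' signed distance is SNP position minus TSS irrespective of strand.
#'
#' @param annot Probe annotation as returned by
#'   \code{\link{select_probes}} (only eligible probes are paired).
#' @param geno A \code{genotype_matrix}.
#' @param window Cis window half-width in bp (default 1e6).
#' @param maf,missingness SNP filters (defaults 0.05, 0.20).
#' @return Data frame: probe_id, gene_id, snp_id, chrom, pos, tss,
#'   distance.
#' @export
enumerate_cis_pairs <- function(annot, geno, window = 1e6,
                                maf = 0.05, missingness = 0.20) {
  ann <- annot[annot$eligible %in% TRUE, , drop = FALSE]
  no_tss <- is.na(ann$tss)
  if (any(no_tss)) {
    warning(sum(no_tss), " probe(s) without TSS skipped")
    ann <- ann[!no_tss, , drop = FALSE]
  }
  keep <- genotype_maf(geno) > maf & genotype_missingness(geno) < missingness
  si <- geno$snp_info[keep, , drop = FALSE]
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    hit <- si$chrom == ann$chrom[i] & abs(si$pos - ann$tss[i]) <= window
    if (!any(hit)) next
    out[[i]] <- data.frame(
      probe_id = ann$probe_id[i], gene_id = ann$gene_id[i],
      snp_id = si$snp_id[hit], chrom = ann$chrom[i], pos = si$pos[hit],
      tss = ann$tss[i], distance = si$pos[hit] - ann$tss[i],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(probe_id = character(), gene_id = character(),
                      snp_id = character(), chrom = character(),
                      pos = integer(), tss = integer(), distance = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Spearman rank correlation association
#'
#' Mid-rank (average ranks for ties) Pearson correlation of genotype
#' dosage against expression, with a two-sided p-value from the
#' t-distribution approximation on n - 2 degrees of freedom.  Pairs with
#' missing dosage are dropped pairwise.
#'
#' @param dosage Numeric genotype vector (0/1/2, NA = missing).
#' @param expr Numeric expression vector of equal length.
#' @return List with \code{rho}, \code{p} and \code{n} (pairs used);
#'   \code{rho = NA} when either vector has zero variance after dropping
#'   missing pairs.
#' @export
spearman_assoc <- function(dosage, expr) {
  ok <- !is.na(dosage) & !is.na(expr)
  n <- sum(ok)
  if (n < 10) stop("fewer than 10 paired non-missing observations")
  d <- dosage[ok]; e <- expr[ok]
  if (length(unique(d)) < 2 || length(unique(e)) < 2)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(rank(d), rank(e))
  list(rho = r, p = .t_pvalue(r, n), n = n)
}

## two-sided p from the t approximation; |r| = 1 maps to the smallest
## representable positive p rather than 0
.t_pvalue <- function(r, n) {
  r2 <- pmin(r * r, 1 - 1e-15)
  tt <- abs(r) * sqrt((n - 2) / (1 - r2))
  pmax(2 * stats::pt(tt, n - 2, lower.tail = FALSE), .Machine$double.xmin)
}

## rank columns of a matrix, standardize to zero mean / unit norm
.rank_std <- function(m) {
  r <- apply(m, 2, rank, ties.method = "average")
  r <- sweep(r, 2, colMeans(r))
  nrm <- sqrt(colSums(r^2))
  nrm[nrm == 0] <- Inf
  sweep(r, 2, nrm, "/")
}

## Spearman rho of one expression vector against each column of a dosage
## matrix (n x S), pairwise-complete; returns rho vector with the number
## of pairs used as attribute
.spearman_vec <- function(expr, dos) {
  n_full <- length(expr)
  complete <- !anyNA(dos)
  if (complete) {
    zd <- .rank_std(dos)
    ze <- .rank_std(matrix(expr, ncol = 1))
    rho <- as.vector(crossprod(zd, ze))
    nn <- rep(n_full, ncol(dos))
  } else {
    rho <- numeric(ncol(dos)); nn <- integer(ncol(dos))
    for (j in seq_len(ncol(dos))) {
      ok <- !is.na(dos[, j])
      nn[j] <- sum(ok)
      d <- dos[ok, j]
      if (length(unique(d)) < 2) { rho[j] <- NA; next }
      rho[j] <- stats::cor(rank(d), rank(expr[ok]))
    }
  }
  attr(rho, "n") <- nn
  rho
}

#' Empirical tail quantile of permutation minimum p-values
#'
#' The threshold is the order statistic \code{floor(alpha * n)} of the
#' sorted minima (strict order statistic, no interpolation); an observed
#' minimum p is significant only when strictly below it.
#'
#' @param min_p Vector of permutation minimum p-values.
#' @param alpha Tail level; \code{length(min_p)} must be >= 1/alpha.
#' @return The alpha-quantile threshold.
#' @export
perm_quantile <- function(min_p, alpha) {
  n <- length(min_p)
  if (n < 1 / alpha) stop("need at least 1/alpha permutation minima")
  k <- floor(alpha * n)
  sort(min_p, partial = k)[k]
}

#' Per-gene permutation min-p significance thresholds
#'
#' For each permutation the expression phenotype is permuted across
#' individuals, every cis SNP is retested, and the minimum nominal
#' p-value is recorded; the threshold is the empirical alpha-quantile of
#' those minima, taken as the order statistic \code{floor(alpha *
#' n_perms)}.  A gene is later called significant when its observed
#' minimum p is strictly below the threshold.
#'
#' Permutations are drawn per gene from one seeded stream;
#' \code{share_permutations = TRUE} reuses a single permutation matrix
#' across genes (faster, preserves cross-gene correlation).
#'
#' @param pairs Cis pair table from \code{\link{enumerate_cis_pairs}}.
#' @param expr \code{expression_matrix} (one column per individual).
#' @param geno \code{genotype_matrix} for the same individuals.
#' @param n_perms Number of permutations (default 10000; must be >=
#'   1/alpha).
#' @param alpha Tail level (default 0.01).
#' @param seed Integer seed.
#' @param share_permutations Reuse one permutation matrix for all genes.
#' @return Data frame: gene_id, probe_id, alpha, threshold_p, n_perms,
#'   min_p_observed, n_cis.
#' @export
permutation_thresholds <- function(pairs, expr, geno, n_perms = 10000,
                                   alpha = 0.01, seed = 1L,
                                   share_permutations = FALSE) {
  if (n_perms < 1 / alpha)
    stop("n_perms must be at least 1/alpha to resolve the quantile")
  if (n_perms < 100) stop("n_perms must be >= 100")
  genes <- unique(pairs$gene_id)
  samples <- colnames(expr$values)
  n <- length(samples)
  set.seed(seed)
  perm_shared <- if (share_permutations)
    replicate(n_perms, sample.int(n)) else NULL

  res <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    gp <- pairs[pairs$gene_id == g, , drop = FALSE]
    e <- expr$values[gp$probe_id[1], samples]
    dos <- t(geno$dosage[gp$snp_id, samples, drop = FALSE])   # n x S
    P <- if (share_permutations) perm_shared
         else replicate(n_perms, sample.int(n))
    minp <- .min_p_perms(e, dos, P)
    thr <- perm_quantile(minp, alpha)
    rho_obs <- .spearman_vec(e, dos)
    p_obs <- .t_pvalue(rho_obs, attr(rho_obs, "n"))
    p_obs[is.na(rho_obs)] <- NA
    res[[gi]] <- data.frame(
      gene_id = g, probe_id = gp$probe_id[1], alpha = alpha,
      threshold_p = thr, n_perms = n_perms,
      min_p_observed = suppressWarnings(min(p_obs, na.rm = TRUE)),
      n_cis = nrow(gp), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## minimum nominal p over SNP columns for each permutation of expr;
## P is an n x n_perms matrix of permutation indices
.min_p_perms <- function(expr, dos, P) {
  n <- length(expr)
  n_perms <- ncol(P)
  er <- rank(expr, ties.method = "average")
  er <- (er - mean(er))
  er <- er / sqrt(sum(er^2))
  complete_cols <- colSums(is.na(dos)) == 0
  minp <- rep(Inf, n_perms)
  if (any(complete_cols)) {
    zd <- .rank_std(dos[, complete_cols, drop = FALSE])       # n x S
    EP <- matrix(er[P], n, n_perms)                           # permuted std ranks
    rho <- crossprod(zd, EP)                                  # S x n_perms
    pm <- matrix(.t_pvalue(rho, n), nrow(rho), n_perms)
    minp <- pmin(minp, apply(pm, 2, min))
  }
  if (any(!complete_cols)) {
    EPfull <- matrix(expr[P], n, n_perms)
    for (j in which(!complete_cols)) {
      ok <- !is.na(dos[, j])
      d <- dos[ok, j]
      if (length(unique(d)) < 2) next
      nj <- sum(ok)
      zd <- rank(d); zd <- zd - mean(zd); zd <- zd / sqrt(sum(zd^2))
      # permuted expression restricted to the SNP's non-missing subset,
      # re-ranked within the subset (single radix sort over all columns;
      # continuous phenotypes make within-column ties negligible)
      EP <- EPfull[ok, , drop = FALSE]
      o <- order(rep.int(seq_len(n_perms), rep.int(nj, n_perms)), EP)
      r <- integer(nj * n_perms)
      r[o] <- rep.int(seq_len(nj), n_perms)
      ER <- matrix(r - (nj + 1) / 2, nj, n_perms)
      nrm <- sqrt(nj * (nj * nj - 1) / 12)
      rho <- as.vector(crossprod(zd, ER)) / nrm
      minp <- pmin(minp, .t_pvalue(rho, nj))
    }
  }
  minp
}

#' Score all cis pairs in one population
#'
#' @param pairs Cis pair table.
#' @param expr \code{expression_matrix}.
#' @param geno \code{genotype_matrix}.
#' @return The pair table with rho, p_nominal and n_used columns; pairs
#'   with zero dosage variance get NA and are logged via a message.
#' @export
score_cis_pairs <- function(pairs, expr, geno) {
  samples <- colnames(expr$values)
  rho <- numeric(nrow(pairs)); pv <- numeric(nrow(pairs))
  nn <- integer(nrow(pairs))
  for (g in unique(pairs$gene_id)) {
    ix <- which(pairs$gene_id == g)
    e <- expr$values[pairs$probe_id[ix[1]], samples]
    dos <- t(geno$dosage[pairs$snp_id[ix], samples, drop = FALSE])
    r <- .spearman_vec(e, dos)
    rho[ix] <- r
    nn[ix] <- attr(r, "n")
    pv[ix] <- ifelse(is.na(r), NA, .t_pvalue(r, attr(r, "n")))
  }
  n_skip <- sum(is.na(rho))
  if (n_skip) message(n_skip, " pair(s) with degenerate dosage skipped (NA)")
  pairs$rho <- rho
  pairs$p_nominal <- pv
  pairs$n_used <- nn
  pairs
}

#' Call significant genes against permutation thresholds
#'
#' Per gene, the most significant SNP is retained (ties broken by
#' smallest p, then smallest |distance to TSS|, then lexicographic
#' snp_id) and the gene is flagged significant when its best nominal p is
#' strictly below the gene's permutation threshold.
#'
#' @param assoc Scored pair table from \code{\link{score_cis_pairs}}.
#' @param thresholds Threshold table from
#'   \code{\link{permutation_thresholds}}.
#' @return Data frame, one row per gene: gene_id, probe_id, snp_id,
#'   distance, rho, p_nominal, threshold_p, significant.
#' @export
call_significant_genes <- function(assoc, thresholds) {
  ord <- order(assoc$gene_id, assoc$p_nominal, abs(assoc$distance),
               assoc$snp_id, na.last = TRUE)
  a <- assoc[ord, , drop = FALSE]
  best <- a[!duplicated(a$gene_id), , drop = FALSE]
  m <- match(best$gene_id, thresholds$gene_id)
  best$threshold_p <- thresholds$threshold_p[m]
  best$significant <- !is.na(best$p_nominal) &
    best$p_nominal < best$threshold_p
  rownames(best) <- NULL
  best[, c("gene_id", "probe_id", "snp_id", "chrom", "pos", "distance",
           "rho", "p_nominal", "n_used", "threshold_p", "significant")]
}

#' Expected-count false discovery rate
#'
#' FDR = (genes tested x per-gene threshold) / significant genes, capped
#' at 1; the numerator is the count of genes expected to pass the
#' permutation threshold by chance.
#'
#' @param n_genes_tested Number of genes tested.
#' @param alpha Per-gene permutation tail level.
#' @param n_significant Number of genes called significant.
#' @return FDR estimate in [0, 1]; NA when \code{n_significant} is 0.
#' @export
fdr_expected <- function(n_genes_tested, alpha, n_significant) {
  if (n_significant == 0) return(NA_real_)
  min(1, n_genes_tested * alpha / n_significant)
}

#' Replication-based false discovery rate
#'
#' A discovery gene replicates when its best SNP-probe pair reaches
#' nominal p < \code{p_rep} with the same rho sign in at least one other
#' population; FDR = 1 - replicated / total.  Genes whose best SNP is
#' untyped (or filtered) in every other population are counted as
#' non-replicated and tallied in the \code{"n_untestable"} attribute.
#'
#' @param discovery Per-gene best-pair table (significant genes only)
#'   from \code{\link{call_significant_genes}}.
#' @param other_assoc Named list of scored pair tables for the other
#'   populations.
#' @param p_rep Replication nominal p threshold (default 0.005).
#' @return FDR estimate with attributes \code{n_replicated} and
#'   \code{n_untestable}; NA when there are no discovery genes.
#' @export
fdr_replication <- function(discovery, other_assoc, p_rep = 0.005) {
  disc <- discovery[discovery$significant, , drop = FALSE]
  if (!nrow(disc)) return(NA_real_)
  rep_flag <- logical(nrow(disc))
  testable <- logical(nrow(disc))
  for (tab in other_assoc) {
    key <- paste(tab$probe_id, tab$snp_id)
    m <- match(paste(disc$probe_id, disc$snp_id), key)
    hit <- !is.na(m)
    testable <- testable | hit
    ok <- hit & !is.na(tab$p_nominal[m]) &
      tab$p_nominal[m] < p_rep &
      sign(tab$rho[m]) == sign(disc$rho)
    rep_flag <- rep_flag | (ok %in% TRUE)
  }
  fdr <- 1 - sum(rep_flag) / nrow(disc)
  attr(fdr, "n_replicated") <- sum(rep_flag)
  attr(fdr, "n_untestable") <- sum(!testable)
  fdr
}

#' Stepwise conditional mapping of independent cis signals
#'
#' Iteratively declares the currently most significant SNP independent,
#' regresses its additive dosage effect out of the expression values,
#' rescreens the remaining initially-significant SNPs with the Spearman
#' model on the residuals, and keeps those still passing the gene's
#' original permutation threshold; stops when none pass.  Missing
#' dosages are mean-imputed for the regression step only.
#'
#' @param gene_id Gene to analyze.
#' @param assoc Scored pair table for the population.
#' @param expr \code{expression_matrix}.
#' @param geno \code{genotype_matrix}.
#' @param threshold_p The gene's permutation threshold.
#' @return Data frame: gene_id, step, snp_id, p_at_step (empty when the
#'   gene has no SNP below threshold).
#' @export
stepwise_independent <- function(gene_id, assoc, expr, geno, threshold_p) {
  ga <- assoc[assoc$gene_id == gene_id & !is.na(assoc$p_nominal), , drop = FALSE]
  sig <- ga[ga$p_nominal < threshold_p, , drop = FALSE]
  samples <- colnames(expr$values)
  e <- expr$values[ga$probe_id[1], samples]
  chosen <- character(0); pvals <- numeric(0)
  remaining <- sig
  step <- 0L
  while (nrow(remaining)) {
    step <- step + 1L
    ord <- order(remaining$p_nominal, abs(remaining$distance), remaining$snp_id)
    top <- remaining[ord[1], ]
    chosen <- c(chosen, top$snp_id)
    pvals <- c(pvals, top$p_nominal)
    # regress the chosen SNP's additive effect out of expression
    d <- geno$dosage[top$snp_id, samples]
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    e <- stats::residuals(stats::lm(e ~ d))
    # rescreen remaining initially-significant SNPs on the residuals
    rest <- remaining[remaining$snp_id != top$snp_id, , drop = FALSE]
    if (!nrow(rest)) break
    dos <- t(geno$dosage[rest$snp_id, samples, drop = FALSE])
    r <- .spearman_vec(e, dos)
    p <- ifelse(is.na(r), NA, .t_pvalue(r, attr(r, "n")))
    keep <- !is.na(p) & p < threshold_p
    remaining <- rest[keep, , drop = FALSE]
    remaining$p_nominal <- p[keep]
  }
  data.frame(gene_id = rep(gene_id, length(chosen)),
             step = seq_along(chosen), snp_id = chosen,
             p_at_step = pvals, stringsAsFactors = FALSE)
}

#' Map cis-eQTLs in one population
#'
#' The full single-population pipeline step: enumerate cis pairs, score
#' them with the Spearman model, calibrate per-gene significance by
#' permutation, call significant genes and compute the expected-count
#' FDR.
#'
#' @param expr \code{expression_matrix} (columns = individuals of one
#'   population).
#' @param geno \code{genotype_matrix} for the same individuals.
#' @param annot Probe annotation with eligibility flags.
#' @param alpha Permutation tail level (default 0.01).
#' @param n_perms Permutations per gene (default 10000).
#' @param window,maf,missingness Cis window and SNP filters.
#' @param seed Integer seed for the permutation stream.
#' @param share_permutations See \code{\link{permutation_thresholds}}.
#' @return Object of class \code{cis_scan}: list with \code{assoc}
#'   (scored pairs), \code{thresholds}, \code{genes} (per-gene best pair
#'   + significance), \code{n_genes_tested}, \code{n_significant},
#'   \code{fdr}, \code{alpha}, \code{population}, \code{seed}.
#' @export
map_cis <- function(expr, geno, annot, alpha = 0.01, n_perms = 10000,
                    window = 1e6, maf = 0.05, missingness = 0.20,
                    seed = 1L, share_permutations = FALSE) {
  pairs <- enumerate_cis_pairs(annot, geno, window, maf, missingness)
  if (!nrow(pairs))
    stop("no cis pairs to test")
  assoc <- score_cis_pairs(pairs, expr, geno)
  thr <- permutation_thresholds(pairs, expr, geno, n_perms = n_perms,
                                alpha = alpha, seed = seed,
                                share_permutations = share_permutations)
  genes <- call_significant_genes(assoc, thr)
  n_sig <- sum(genes$significant)
  pop <- if (!is.null(expr$sample_meta$population))
    expr$sample_meta$population[1] else NA_character_
  structure(list(assoc = assoc, thresholds = thr, genes = genes,
                 n_genes_tested = nrow(thr), n_significant = n_sig,
                 fdr = fdr_expected(nrow(thr), alpha, n_sig),
                 alpha = alpha, n_perms = n_perms,
                 population = pop, seed = seed),
            class = "cis_scan")
}

#' @export
print.cis_scan <- function(x, ...) {
  cat("cis-eQTL scan", if (!is.na(x$population)) paste0(" [", x$population, "]"),
      ": ", x$n_significant, " of ", x$n_genes_tested,
      " genes significant at the ", x$alpha, " permutation threshold\n",
      sep = "")
  cat("  expected-count FDR: ",
      if (is.na(x$fdr)) "NA" else sprintf("%.3f", x$fdr),
      "  (", x$n_perms, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
summary.cis_scan <- function(object, ...) {
  sig <- object$genes[object$genes$significant, , drop = FALSE]
  out <- list(population = object$population,
              alpha = object$alpha,
              n_genes_tested = object$n_genes_tested,
              n_significant = object$n_significant,
              fdr_expected = object$fdr,
              rho_range = if (nrow(sig)) range(abs(sig$rho)) else c(NA, NA),
              median_abs_distance = if (nrow(sig))
                stats::median(abs(sig$distance)) else NA)
  class(out) <- "summary.cis_scan"
  out
}

#' @export
print.summary.cis_scan <- function(x, ...) {
  cat("cis-eQTL scan summary",
      if (!is.na(x$population)) paste0(" [", x$population, "]"), "\n", sep = "")
  cat("  genes tested:      ", x$n_genes_tested, "\n")
  cat("  significant (alpha=", x$alpha, "): ", x$n_significant, "\n", sep = "")
  cat("  expected-count FDR:", round(x$fdr_expected, 3), "\n")
  if (!is.na(x$rho_range[1]))
    cat("  |rho| range:       ", sprintf("%.3f-%.3f", x$rho_range[1],
                                         x$rho_range[2]), "\n")
  if (!is.na(x$median_abs_distance))
    cat("  median |TSS dist|: ", x$median_abs_distance, "bp\n")
  invisible(x)
}

#' Map cis-eQTLs in every population
#'
#' @param exprs Named list of per-population \code{expression_matrix}.
#' @param genotypes Named list of \code{genotype_matrix}.
#' @param annot Probe annotation with eligibility flags.
#' @param ... Passed to \code{\link{map_cis}}.
#' @return Named list of \code{cis_scan} objects.
#' @export
map_cis_all <- function(exprs, genotypes, annot, ...) {
  pops <- names(exprs)
  out <- lapply(pops, function(p) map_cis(exprs[[p]], genotypes[[p]],
                                          annot, ...))
  names(out) <- pops
  out
}
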