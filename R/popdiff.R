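#' V_ST expression differentiation between two populations
#'
#' V_ST = (V_T - V_S) / V_T, where V_T is the total variance across the
#' pooled individuals of the two populations and V_S is the average
#' within-population variance weighted by sample size,
#' V_S = (V1 n1 + V2 n2) / (n1 + n2).  Variances use the denominator-n
#' (maximum-likelihood) convention so that two identical samples give
#' exactly 0; negative values are clamped to 0 and the result lies in
#' [0, 1].  When the pooled variance is 0 the statistic is defined as 0.
#'
#' @param expr1,expr2 Numeric vectors of expression values for the two
#'   populations (each of length >= 2).
#' @param unbiased Use the n-1 variance convention instead (default
#'   FALSE; values are then still clamped to [0, 1]).
#' @return List: v1, v2, n1, n2, v_s, v_t, vst.
#' @export
vst <- function(expr1, expr2, unbiased = FALSE) {
  n1 <- length(expr1); n2 <- length(expr2)
  if (n1 < 2 || n2 < 2) stop("each population needs >= 2 values")
  vf <- if (unbiased) stats::var else function(x) mean((x - mean(x))^2)
  v1 <- vf(expr1); v2 <- vf(expr2)
  v_s <- (v1 * n1 + v2 * n2) / (n1 + n2)
  v_t <- vf(c(expr1, expr2))
  v <- if (v_t <= 0) 0 else min(max((v_t - v_s) / v_t, 0), 1)
  list(v1 = v1, v2 = v2, n1 = n1, n2 = n2, v_s = v_s, v_t = v_t, vst = v)
}

#' V_ST for every probe and population pair
#'
#' @param expr \code{expression_matrix} whose sample metadata has a
#'   \code{population} column.
#' @param probes Optional probe subset (default all rows).
#' @param vst_cut Threshold for the per-pair high-V_ST count summary
#'   (default 0.2).
#' @return List with \code{table} (long data frame: probe_id, pop1, pop2,
#'   v1, v2, v_s, v_t, vst) and \code{summary} (per pair: n probes,
#'   count above \code{vst_cut}, median, mean).  Populations with fewer
#'   than 2 samples are skipped with a warning.
#' @export
vst_scan <- function(expr, probes = NULL, vst_cut = 0.2) {
  pop <- expr$sample_meta$population
  if (is.null(pop)) stop("sample metadata lacks a population column")
  if (is.null(probes)) probes <- rownames(expr$values)
  tab_pop <- table(pop)
  pops <- names(tab_pop)[tab_pop >= 2]
  skipped <- setdiff(names(tab_pop), pops)
  if (length(skipped))
    warning("population(s) with < 2 samples skipped: ",
            paste(skipped, collapse = ", "))
  cmb <- utils::combn(pops, 2)
  V <- expr$values[probes, , drop = FALSE]
  # ML variances per probe per population, vectorized
  means <- sapply(pops, function(p) rowMeans(V[, pop == p, drop = FALSE]))
  vars <- sapply(pops, function(p) {
    m <- V[, pop == p, drop = FALSE]
    rowMeans(m^2) - rowMeans(m)^2
  })
  ns <- tab_pop[pops]
  out <- vector("list", ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    p1 <- cmb[1, k]; p2 <- cmb[2, k]
    n1 <- ns[[p1]]; n2 <- ns[[p2]]
    v1 <- vars[, p1]; v2 <- vars[, p2]
    v_s <- (v1 * n1 + v2 * n2) / (n1 + n2)
    mu <- (means[, p1] * n1 + means[, p2] * n2) / (n1 + n2)
    v_t <- v_s + (n1 * (means[, p1] - mu)^2 + n2 * (means[, p2] - mu)^2) /
      (n1 + n2)
    vv <- ifelse(v_t <= 0, 0, pmin(pmax((v_t - v_s) / v_t, 0), 1))
    out[[k]] <- data.frame(probe_id = probes, pop1 = p1, pop2 = p2,
                           v1 = v1, v2 = v2, v_s = v_s, v_t = v_t, vst = vv,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  smry <- do.call(rbind, lapply(out, function(d) data.frame(
    pop1 = d$pop1[1], pop2 = d$pop2[1], n_probes = nrow(d),
    n_high = sum(d$vst > vst_cut),
    median_vst = stats::median(d$vst), mean_vst = mean(d$vst),
    stringsAsFactors = FALSE)))
  list(table = tab, summary = smry)
}

#' Hudson pairwise F_ST
#'
#' Hudson-style estimator per SNP, combined as a ratio of averages
#' within windows of \code{window} consecutive SNPs, then averaged
#' across windows.  With \code{sample_sizes} supplied (haploid counts),
#' the numerator gets the finite-sample correction
#' p(1-p)/(n-1) per population; without them the infinite-sample form
#' (p1-p2)^2 / (p1(1-p2)+p2(1-p1)) is used.  SNPs monomorphic in both
#' populations are skipped.
#'
#' @param p1,p2 Allele frequency vectors for the two populations.
#' @param window SNPs per window (default 10000).
#' @param sample_sizes Optional length-2 vector of haploid sample sizes.
#' @return List: \code{fst} (mean of window values), \code{windows}
#'   (per-window ratio-of-averages), \code{per_snp} (per-SNP values,
#'   NA where skipped).
#' @export
fst_pairwise <- function(p1, p2, window = 10000, sample_sizes = NULL) {
  stopifnot(length(p1) == length(p2))
  keep <- !(p1 %in% c(0, 1) & p2 == p1)
  num <- (p1 - p2)^2
  if (!is.null(sample_sizes)) {
    n1 <- sample_sizes[1]; n2 <- sample_sizes[2]
    num <- num - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  }
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  per_snp <- ifelse(keep & den > 0, num / den, NA_real_)
  idx <- which(keep & den > 0)
  win <- ceiling(seq_along(idx) / window)
  wvals <- vapply(split(idx, win), function(ix)
    sum(num[ix]) / sum(den[ix]), 0)
  list(fst = mean(wvals), windows = unname(wvals), per_snp = per_snp)
}

#' F_ST distance matrix across populations
#'
#' Genome-average Hudson F_ST (ratio of averages per window of
#' \code{window} SNPs) for every pair of populations, computed from
#' non-missing genotype dosages.
#'
#' @param genotypes Named list of \code{genotype_matrix}.
#' @param window SNPs per window (default 10000).
#' @param sample_correction Apply the finite-sample correction using the
#'   per-population haploid counts (default TRUE).
#' @return Symmetric matrix of pairwise F_ST values (0 diagonal).
#' @export
fst_matrix <- function(genotypes, window = 10000, sample_correction = TRUE) {
  pops <- names(genotypes)
  freqs <- sapply(genotypes, function(g) rowMeans(g$dosage, na.rm = TRUE) / 2)
  nhap <- vapply(genotypes, function(g) 2 * ncol(g$dosage), 0)
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1):length(pops)) {
    ss <- if (sample_correction) nhap[c(i, j)] else NULL
    f <- fst_pairwise(freqs[, i], freqs[, j], window = window,
                      sample_sizes = ss)$fst
    D[i, j] <- D[j, i] <- max(f, 0)
  }
  D
}

#' One-sided Fisher exact term enrichment in a top set
#'
#' For each term, tests enrichment (one-sided, \code{"greater"}) of the
#' term's genes within the top set against the universe of eligible
#' probes via the 2x2 table {in top} x {in term}.  Terms with no
#' annotated genes in the universe are skipped.
#'
#' @param top_set Character vector of probes in the top set.
#' @param term_map Named list: term id -> character vector of probe ids.
#' @param universe Character vector of all eligible probes.
#' @return Data frame: term_id, n_top_term, n_top, n_term, n_universe,
#'   p_one_sided.
#' @export
term_enrichment <- function(top_set, term_map, universe) {
  top_set <- intersect(top_set, universe)
  out <- lapply(names(term_map), function(tm) {
    genes <- intersect(term_map[[tm]], universe)
    if (!length(genes)) return(NULL)
    a <- length(intersect(top_set, genes))
    b <- length(top_set) - a
    c_ <- length(genes) - a
    d <- length(universe) - a - b - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2),
                            alternative = "greater")$p.value
    data.frame(term_id = tm, n_top_term = a, n_top = length(top_set),
               n_term = length(genes), n_universe = length(universe),
               p_one_sided = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(term_id = character(), n_top_term = integer(),
                      n_top = integer(), n_term = integer(),
                      n_universe = integer(), p_one_sided = numeric())
  rownames(res) <- NULL
  res
}

#' Fisher's combined probability
#'
#' X = -2 sum(log p); combined p is the upper tail of a chi-square with
#' 2k degrees of freedom.  Zero p-values are clamped to the smallest
#' positive double with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Combined probability.
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(p_values <= 0)) {
    warning("p-value(s) <= 0 clamped to the smallest positive double")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  X <- -2 * sum(log(p_values))
  stats::pchisq(X, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Top-5% V_ST probe sets per population pair
#'
#' Probes ranked by V_ST within each pair; ties broken by probe id for
#' determinism.
#'
#' @param vst_table Long table from \code{\link{vst_scan}}.
#' @param top_frac Fraction selected (default 0.05).
#' @return Named list (\code{"pop1|pop2"}) of probe id vectors.
#' @export
vst_top_sets <- function(vst_table, top_frac = 0.05) {
  key <- paste(vst_table$pop1, vst_table$pop2, sep = "|")
  lapply(split(vst_table, key), function(d) {
    k <- max(1, floor(top_frac * nrow(d)))
    d$probe_id[order(-d$vst, d$probe_id)][seq_len(k)]
  })
}

#' Population-specific differentiated terms
#'
#' Combines per-pair enrichment p-values (Fisher's method) over the
#' pairs involving the focal population, filters out terms whose
#' combined p over the non-focal pairs is also below \code{p_cut}, and
#' reports the top \code{n_top} surviving terms by focal combined p.
#'
#' @param enrich_tables Named list (\code{"pop1|pop2"}) of
#'   \code{\link{term_enrichment}} tables covering all pairs.
#' @param focal Focal population label.
#' @param p_cut Significance cutoff applied to both combined p-values
#'   (default 0.05).
#' @param n_top Number of terms reported (default 10); fewer survivors
#'   are all reported with a message.
#' @return Data frame: term_id, p_combined_focal, p_combined_other,
#'   ordered by focal combined p.
#' @export
population_specific_terms <- function(enrich_tables, focal,
                                      p_cut = 0.05, n_top = 10) {
  pairs <- strsplit(names(enrich_tables), "|", fixed = TRUE)
  has_focal <- vapply(pairs, function(p) focal %in% p, TRUE)
  comb <- function(tabs) {
    terms <- unique(unlist(lapply(tabs, `[[`, "term_id")))
    vapply(terms, function(tm) {
      ps <- unlist(lapply(tabs, function(t) t$p_one_sided[t$term_id == tm]))
      fisher_combine(ps)
    }, 0)
  }
  pf <- comb(enrich_tables[has_focal])
  po <- comb(enrich_tables[!has_focal])
  terms <- names(pf)
  d <- data.frame(term_id = terms,
                  p_combined_focal = pf,
                  p_combined_other = po[terms],
                  stringsAsFactors = FALSE)
  d <- d[d$p_combined_focal < p_cut &
           !(d$p_combined_other < p_cut) %in% TRUE, , drop = FALSE]
  d <- d[order(d$p_combined_focal), , drop = FALSE]
  if (nrow(d) < n_top)
    message(nrow(d), " surviving term(s) (< ", n_top, " requested)")
  rownames(d) <- NULL
  utils::head(d, n_top)
}

#' Cross-population informativeness of expression differentiation
#'
#' For terms significantly differentiated in population A versus the
#' rest (excluding B), summarizes the distribution of those terms'
#' combined p-values in B versus the rest (excluding A): the fraction
#' below \code{p_cut} and a Wilcoxon rank-sum statistic against the
#' remaining terms.
#'
#' @param enrich_tables Named list (\code{"pop1|pop2"}) of enrichment
#'   tables for all pairs.
#' @param pop_a,pop_b The two populations compared.
#' @param p_cut Significance cutoff (default 0.05).
#' @return List: n_sig_a, frac_b_below, wilcox_p (NA summary when A has
#'   no significant terms).
#' @export
cross_population_informativeness <- function(enrich_tables, pop_a, pop_b,
                                             p_cut = 0.05) {
  pairs <- strsplit(names(enrich_tables), "|", fixed = TRUE)
  sel <- function(focal, excl) vapply(pairs, function(p)
    focal %in% p && !(excl %in% p), TRUE)
  comb <- function(keep) {
    tabs <- enrich_tables[keep]
    terms <- unique(unlist(lapply(tabs, `[[`, "term_id")))
    vapply(terms, function(tm) {
      ps <- unlist(lapply(tabs, function(t) t$p_one_sided[t$term_id == tm]))
      fisher_combine(ps)
    }, 0)
  }
  pa <- comb(sel(pop_a, pop_b))
  pb <- comb(sel(pop_b, pop_a))
  sig_a <- names(pa)[pa < p_cut]
  if (!length(sig_a))
    return(list(n_sig_a = 0L, frac_b_below = NA_real_, wilcox_p = NA_real_))
  in_b <- pb[intersect(sig_a, names(pb))]
  rest_b <- pb[setdiff(names(pb), sig_a)]
  w <- if (length(in_b) && length(rest_b))
    suppressWarnings(stats::wilcox.test(in_b, rest_b,
                                        alternative = "less")$p.value)
  else NA_real_
  list(n_sig_a = length(sig_a),
       frac_b_below = mean(in_b < p_cut),
       wilcox_p = w)
}
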