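#' Cross-population sharing of significant genes
#'
#' @param sig_sets Named list: population -> character vector of
#'   significant gene ids (all at one alpha).
#' @return List: \code{pair_counts} (symmetric matrix of genes significant
#'   in both populations of each pair), \code{histogram} (genes by number
#'   of populations shared, levels 1..n_pops), \code{n_nonredundant},
#'   \code{n_ge2}, \code{n_all}, \code{pct_ge2}, \code{pct_all}.
#' @export
sharing_matrix <- function(sig_sets) {
  pops <- names(sig_sets)
  np <- length(pops)
  genes <- unique(unlist(sig_sets))
  member <- sapply(sig_sets, function(s) genes %in% s)
  if (length(genes) == 1) member <- matrix(member, nrow = 1)
  n_shared <- if (length(genes)) rowSums(member) else integer(0)
  pair_counts <- matrix(0L, np, np, dimnames = list(pops, pops))
  if (np >= 2 && length(genes))
    for (i in 1:(np - 1)) for (j in (i + 1):np)
      pair_counts[i, j] <- pair_counts[j, i] <-
        sum(member[, i] & member[, j])
  hist_tab <- tabulate(n_shared, nbins = np)
  names(hist_tab) <- as.character(seq_len(np))
  n_nr <- length(genes)
  n_ge2 <- sum(n_shared >= 2)
  n_all <- sum(n_shared == np)
  list(pair_counts = pair_counts, histogram = hist_tab,
       n_shared = stats::setNames(n_shared, genes),
       n_nonredundant = n_nr, n_ge2 = n_ge2, n_all = n_all,
       pct_ge2 = if (n_nr) round(100 * n_ge2 / n_nr) else NA_real_,
       pct_all = if (n_nr) round(100 * n_all / n_nr) else NA_real_)
}

#' Allelic direction concordance between two populations
#'
#' Among SNP-probe pairs significant in both populations (same dosage
#' allele in both), the proportion whose Spearman rho has the same sign.
#' Pairs with rho exactly 0 in either population are excluded.
#'
#' @param best_a,best_b Per-gene best-pair tables (with
#'   \code{significant} flags) from \code{\link{call_significant_genes}}
#'   for the two populations.
#' @return Proportion in [0, 1] with attribute \code{n_shared}; NA when
#'   no pairs are shared.
#' @export
direction_concordance <- function(best_a, best_b) {
  a <- best_a[best_a$significant, , drop = FALSE]
  b <- best_b[best_b$significant, , drop = FALSE]
  key_a <- paste(a$probe_id, a$snp_id)
  key_b <- paste(b$probe_id, b$snp_id)
  m <- match(key_a, key_b)
  hit <- !is.na(m)
  ra <- a$rho[hit]; rb <- b$rho[m[hit]]
  nz <- ra != 0 & rb != 0
  if (!sum(nz)) {
    out <- NA_real_
    attr(out, "n_shared") <- 0L
    return(out)
  }
  out <- mean(sign(ra[nz]) == sign(rb[nz]))
  attr(out, "n_shared") <- sum(nz)
  out
}

#' Homozygote fold-change effect size
#'
#' Absolute difference between the median log2 expression of the two
#' homozygote dosage classes (0 and 2).  Requires at least
#' \code{min_class} individuals in each class (singleton medians are
#' noise); otherwise NA with a reason attribute.
#'
#' @param expr Numeric expression vector.
#' @param dosage Genotype dosage vector (0/1/2, NA allowed).
#' @param min_class Minimum homozygote class size (default 2).
#' @return Absolute log2 fold-change, or NA with attribute
#'   \code{"reason"}.
#' @export
homozygote_fold_change <- function(expr, dosage, min_class = 2) {
  h0 <- expr[!is.na(dosage) & dosage == 0]
  h2 <- expr[!is.na(dosage) & dosage == 2]
  if (length(h0) < min_class || length(h2) < min_class) {
    out <- NA_real_
    attr(out, "reason") <- sprintf(
      "homozygote class too small (n0=%d, n2=%d, need >= %d)",
      length(h0), length(h2), min_class)
    return(out)
  }
  abs(stats::median(h2) - stats::median(h0))
}

#' Effect size versus population sharing
#'
#' Pearson correlation (with p-value) of per-gene homozygote
#' fold-changes against the number of populations sharing the gene's
#' eQTL.
#'
#' @param fold_changes Numeric vector of fold-changes (NA allowed).
#' @param n_shared Integer vector of sharing counts, same genes.
#' @param min_genes Minimum usable genes (default 30).
#' @return List: r, p, n; NA values when variance is degenerate or too
#'   few genes are usable.
#' @export
effect_size_vs_sharing <- function(fold_changes, n_shared, min_genes = 30) {
  ok <- !is.na(fold_changes) & !is.na(n_shared)
  if (sum(ok) < min_genes)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  x <- fold_changes[ok]; y <- n_shared[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' pi1 replication enrichment estimate
#'
#' Storey-type estimate of the fraction of true positives among a set of
#' replication p-values: pi0 = #\{p > lambda\} / ((1 - lambda) m),
#' clamped to [0, 1], and pi1 = 1 - pi0.
#'
#' @param p_values Replication p-values.
#' @param lambda Tuning point in (0, 1), default 0.5.
#' @return pi1 in [0, 1]; NA for empty input; warns below 50 p-values.
#' @export
pi1_estimate <- function(p_values, lambda = 0.5) {
  p_values <- p_values[!is.na(p_values)]
  m <- length(p_values)
  if (!m) return(NA_real_)
  if (m < 50) warning("fewer than 50 p-values; pi1 estimate is unstable")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  pi0 <- sum(p_values > lambda) / ((1 - lambda) * m)
  1 - min(max(pi0, 0), 1)
}

#' TSS distance distributions stratified by sharing level
#'
#' @param best Combined best-pair table across populations (significant
#'   rows only are used) with \code{gene_id} and \code{distance}.
#' @param n_shared Named integer vector gene -> number of populations
#'   sharing (from \code{\link{sharing_matrix}}).
#' @param probs Quantiles reported per stratum (default quartiles).
#' @return List: \code{strata} (per sharing level: n, quantiles of
#'   |distance|, median), \code{trend_rho} and \code{trend_p} (Spearman
#'   correlation of median |distance| against sharing level; NA with a
#'   single stratum).
#' @export
tss_distance_by_sharing <- function(best, n_shared,
                                    probs = c(0.25, 0.5, 0.75)) {
  b <- best[best$significant, , drop = FALSE]
  b$level <- n_shared[b$gene_id]
  b <- b[!is.na(b$level), , drop = FALSE]
  levs <- sort(unique(b$level))
  strata <- lapply(levs, function(l) {
    d <- abs(b$distance[b$level == l])
    c(n = length(d), stats::quantile(d, probs), median = stats::median(d))
  })
  names(strata) <- as.character(levs)
  med <- vapply(strata, `[[`, 0, "median")
  if (length(levs) < 2) {
    trend <- list(rho = NA_real_, p = NA_real_)
  } else {
    ct <- suppressWarnings(
      stats::cor.test(levs, med, method = "spearman"))
    trend <- list(rho = unname(ct$estimate), p = ct$p.value)
  }
  list(strata = strata, trend_rho = trend$rho, trend_p = trend$p)
}

#' Multi-gene eQTL clusters
#'
#' Groups genes whose best eQTL SNP is identical; clusters of >= 2 genes
#' suggest a shared regulatory variant.  Clusters observed in >= 2
#' populations are flagged replicated, and cluster-SNP |TSS distances|
#' are compared with single-gene eQTL distances by rank-sum test.
#'
#' @param best_by_pop Named list of per-population best-pair tables.
#' @return List: \code{clusters} (snp_id, population, n_genes, genes),
#'   \code{n_cluster_genes}, \code{replicated} (snp ids in clusters in
#'   >= 2 populations), \code{wilcox_p}, \code{median_cluster_dist},
#'   \code{median_single_dist}.
#' @export
multi_gene_clusters <- function(best_by_pop) {
  rows <- do.call(rbind, lapply(names(best_by_pop), function(p) {
    b <- best_by_pop[[p]]
    b <- b[b$significant, , drop = FALSE]
    if (!nrow(b)) return(NULL)
    b$population <- p
    b
  }))
  if (is.null(rows) || !nrow(rows))
    return(list(clusters = data.frame(), n_cluster_genes = 0L,
                replicated = character(0), wilcox_p = NA_real_,
                median_cluster_dist = NA_real_,
                median_single_dist = NA_real_))
  key <- paste(rows$population, rows$snp_id)
  sizes <- stats::ave(seq_along(key), key, FUN = length)
  rows$in_cluster <- sizes >= 2
  cl <- rows[rows$in_cluster, , drop = FALSE]
  clusters <- do.call(rbind, lapply(
    split(cl, paste(cl$population, cl$snp_id)), function(d)
      data.frame(snp_id = d$snp_id[1], population = d$population[1],
                 n_genes = nrow(d),
                 genes = paste(sort(d$gene_id), collapse = ","),
                 stringsAsFactors = FALSE)))
  if (is.null(clusters)) clusters <- data.frame()
  rownames(clusters) <- NULL
  rep_snps <- if (nrow(clusters))
    names(which(tapply(clusters$population, clusters$snp_id,
                       function(x) length(unique(x))) >= 2))
  else character(0)
  dc <- abs(rows$distance[rows$in_cluster])
  ds <- abs(rows$distance[!rows$in_cluster])
  w <- if (length(dc) && length(ds))
    suppressWarnings(stats::wilcox.test(dc, ds,
                                        alternative = "greater")$p.value)
  else NA_real_
  list(clusters = clusters,
       n_cluster_genes = length(unique(cl$gene_id)),
       replicated = rep_snps, wilcox_p = w,
       median_cluster_dist = if (length(dc)) stats::median(dc) else NA_real_,
       median_single_dist = if (length(ds)) stats::median(ds) else NA_real_)
}

#' Neighbour-joining population tree from an F_ST distance matrix
#'
#' @param fst_mat Symmetric pairwise F_ST matrix (e.g. from
#'   \code{\link{fst_matrix}}).
#' @return An \code{ape} \code{phylo} tree, midpoint-rooted so that clade
#'   (MRCA) queries are well defined, with non-negative branch lengths.
#' @export
population_tree <- function(fst_mat) {
  tr <- ape::nj(stats::as.dist(fst_mat))
  tr$edge.length[tr$edge.length < 0] <- 0
  phangorn::midpoint(tr)
}

## smallest clade (node) of the tree covering a leaf set; a single leaf
## maps to its tip node, an uncoverable set to the root
.covering_node <- function(tree, leaves) {
  tips <- match(leaves, tree$tip.label)
  if (any(is.na(tips))) stop("population(s) absent from tree: ",
                             paste(leaves[is.na(tips)], collapse = ", "))
  if (length(tips) == 1) return(tips)
  ape::getMRCA(tree, tips)
}

#' Parsimony analysis of eQTL sharing on the population tree
#'
#' Each gene contributes one eQTL (chosen at random with the run seed
#' when a gene has several); the eQTL's population set is the discovery
#' population (alpha 0.01 call) plus every population where it also
#' passes the lenient (alpha 0.1) permutation threshold.  The eQTL is
#' assigned to the smallest tree node whose clade covers its population
#' set (root when no clade does).  Node counts are compared with
#' \code{n_random} randomizations: mode \code{"labels"} permutes the
#' leaf labels of the tree; mode \code{"sets"} replaces each eQTL's
#' population set by a random set of the same size.  A node is flagged
#' enriched when its observed count exceeds the 95th percentile of the
#' randomized counts.
#'
#' @param tree \code{phylo} population tree.
#' @param gene_pops Named list: gene id -> character vector of
#'   populations sharing that gene's eQTL (discovery + lenient calls).
#' @param n_random Number of randomizations (default 100).
#' @param seed Integer seed (tie-breaks and randomizations).
#' @param mode \code{"labels"} (default) or \code{"sets"}.
#' @return List: \code{node_counts} (named by node number),
#'   \code{enriched} (logical per node), \code{null_q95},
#'   \code{assignments} (gene -> node).
#' @export
parsimony_sharing <- function(tree, gene_pops, n_random = 100, seed = 1L,
                              mode = c("labels", "sets")) {
  mode <- match.arg(mode)
  set.seed(seed)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  count_nodes <- function(tr, sets) {
    nodes <- vapply(sets, function(s) .covering_node(tr, s), 0L)
    tabulate(nodes, nbins = n_nodes)
  }
  obs <- count_nodes(tree, gene_pops)
  null_counts <- matrix(0L, n_random, n_nodes)
  for (r in seq_len(n_random)) {
    if (mode == "labels") {
      tr <- tree
      tr$tip.label <- sample(tree$tip.label)
      null_counts[r, ] <- count_nodes(tr, gene_pops)
    } else {
      sets <- lapply(gene_pops, function(s)
        sample(tree$tip.label, length(s)))
      null_counts[r, ] <- count_nodes(tree, sets)
    }
  }
  q95 <- apply(null_counts, 2, stats::quantile, 0.95)
  nodes <- vapply(gene_pops, function(s) .covering_node(tree, s), 0L)
  list(node_counts = stats::setNames(obs, seq_len(n_nodes)),
       enriched = obs > q95, null_q95 = q95,
       assignments = nodes)
}

#' Choose one eQTL per gene and collect lenient sharing sets
#'
#' Helper for \code{\link{parsimony_sharing}}: from per-population
#' strict (discovery) and lenient significance calls, builds for each
#' discovered gene the set of populations where it is discovered or
#' leniently replicated.  When a gene is discovered in several
#' populations one discovery is chosen at random with the seed.
#'
#' @param strict_sets Named list population -> genes significant at the
#'   discovery alpha.
#' @param lenient_sets Named list population -> genes significant at the
#'   lenient alpha.
#' @param seed Integer seed for the random per-gene choice.
#' @return Named list gene -> population set.
#' @export
sharing_sets <- function(strict_sets, lenient_sets, seed = 1L) {
  set.seed(seed)
  genes <- unique(unlist(strict_sets))
  pops <- names(strict_sets)
  out <- lapply(genes, function(g) {
    disc <- pops[vapply(strict_sets, function(s) g %in% s, TRUE)]
    disc <- sample(disc, 1)                     # one association per gene
    len <- pops[vapply(lenient_sets, function(s) g %in% s, TRUE)]
    sort(unique(c(disc, len)))
  })
  names(out) <- genes
  out
}
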