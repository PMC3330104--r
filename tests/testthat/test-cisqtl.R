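make_geno <- function(dosage, pos, chrom = "1") {
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("i%03d", seq_len(ncol(dosage)))
  structure(list(dosage = dosage,
                 snp_info = data.frame(snp_id = rownames(dosage),
                                       chrom = chrom, pos = pos,
                                       ref = "A", alt = "G",
                                       stringsAsFactors = FALSE),
                 pop = "T"), class = "genotype_matrix")
}

test_that("cis pair enumeration respects the closed 1 Mb window and filters", {
  set.seed(41)
  dos <- matrix(rbinom(3 * 30, 2, 0.5), 3, 30)
  g <- make_geno(dos, pos = c(1000000L, 3000001L, 500000L))
  annot <- data.frame(probe_id = "pr1", gene_id = "g1", chrom = "1",
                      tss = 2000000L, strand = "+", snp_in_probe = FALSE,
                      eligible = TRUE, stringsAsFactors = FALSE)
  pairs <- enumerate_cis_pairs(annot, g)
  # boundary SNP at exactly -1,000,000 kept; +1,000,001 and -1,500,000 excluded
  expect_equal(pairs$snp_id, "s001")
  expect_equal(pairs$distance, -1000000L)

  # a 4% MAF SNP yields no pairs
  dos2 <- matrix(rbinom(30, 2, 0.04), 1, 30)
  dos2[1, ] <- c(rep(1L, 2), rep(0L, 28))    # MAF ~3.3%
  g2 <- make_geno(dos2, pos = 2000000L)
  expect_equal(nrow(enumerate_cis_pairs(annot, g2)), 0L)
})

test_that("pair enumeration matches an exhaustive double-loop oracle", {
  set.seed(42)
  n_genes <- 5; n_snps <- 200; n <- 40
  tss <- sort(sample.int(8e6, n_genes))
  pos <- sort(sample.int(8e6, n_snps))
  dos <- matrix(rbinom(n_snps * n, 2, runif(n_snps, 0.1, 0.5)), n_snps, n)
  g <- make_geno(dos, pos = pos)
  annot <- data.frame(probe_id = paste0("pr", 1:n_genes),
                      gene_id = paste0("g", 1:n_genes), chrom = "1",
                      tss = tss, strand = "+", snp_in_probe = FALSE,
                      eligible = TRUE, stringsAsFactors = FALSE)
  pairs <- enumerate_cis_pairs(annot, g)
  maf <- genotype_maf(g)
  count <- 0L
  for (i in 1:n_genes) for (j in 1:n_snps)
    if (maf[j] > 0.05 && abs(pos[j] - tss[i]) <= 1e6) count <- count + 1L
  expect_equal(nrow(pairs), count)
})

test_that("Spearman association matches the brute-force rank-Pearson oracle", {
  # frozen worked example: tied dosages against a monotone phenotype
  r <- spearman_assoc(c(0, 0, 1, 1, 2, 2, 0, 1, 2, 2),
                      c(1, 2, 3, 4, 5, 6, 1.5, 3.2, 5.5, 6.2))
  expect_equal(r$rho,
               oracle_spearman(c(0, 0, 1, 1, 2, 2, 0, 1, 2, 2),
                               c(1, 2, 3, 4, 5, 6, 1.5, 3.2, 5.5, 6.2)),
               tolerance = 1e-12)
  # the six-point textbook case (n >= 10 enforced; check the raw statistic)
  d6 <- c(0, 0, 1, 1, 2, 2); e6 <- 1:6
  expect_equal(oracle_spearman(d6, e6), 0.9561829, tolerance = 1e-6)

  # strictly decreasing, no ties -> rho = -1
  r2 <- spearman_assoc(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9), 10:1)
  expect_equal(r2$rho, -1)

  # 100 random instances against the oracle, including ties and missing
  set.seed(43)
  for (k in 1:100) {
    n <- sample(10:40, 1)
    d <- rbinom(n, 2, runif(1, 0.2, 0.8))
    e <- rnorm(n)
    if (length(unique(d)) < 2) next
    got <- spearman_assoc(d, e)
    expect_equal(got$rho, oracle_spearman(d, e), tolerance = 1e-12)
    # p-value equals the t-approximation of cor.test
    ct <- suppressWarnings(cor.test(d, e, method = "spearman", exact = FALSE))
    expect_equal(got$p, ct$p.value, tolerance = 1e-9)
  }
})

test_that("null Spearman p-values are uniform", {
  set.seed(44)
  # balanced dosage classes keep the rank lattice fine enough for a
  # meaningful Kolmogorov-Smirnov check at 10,000 null draws
  d <- rep(c(0, 1, 2), c(12, 26, 12))
  ps <- replicate(10000, spearman_assoc(d, rnorm(50))$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Spearman statistics obey negation and joint-permutation symmetry", {
  set.seed(45)
  d <- rbinom(25, 2, 0.4); e <- rnorm(25)
  a <- spearman_assoc(d, e); b <- spearman_assoc(d, -e)
  expect_equal(a$rho, -b$rho)
  expect_equal(a$p, b$p)
  perm <- sample(25)
  c_ <- spearman_assoc(d[perm], e[perm])
  expect_equal(a$rho, c_$rho)
})

test_that("the permutation threshold is the floor(alpha n) order statistic", {
  minp <- 0.0001 * (1:10000)
  expect_equal(perm_quantile(minp, 0.01), 0.0100)
  expect_equal(perm_quantile(sample(minp), 0.01), 0.0100)
  expect_error(perm_quantile(minp[1:50], 0.01), "1/alpha")
  # monotone in alpha
  set.seed(46)
  m <- runif(1000)
  expect_lte(perm_quantile(m, 0.001 * 10), perm_quantile(m, 0.05))
})

test_that("significance calls use a strict inequality at the threshold", {
  assoc <- data.frame(gene_id = "g1", probe_id = "p1", snp_id = "s1",
                      chrom = "1", pos = 100L, tss = 50L, distance = 50L,
                      rho = 0.5, p_nominal = 0.01, n_used = 50L,
                      stringsAsFactors = FALSE)
  thr <- data.frame(gene_id = "g1", threshold_p = 0.01)
  expect_false(call_significant_genes(assoc, thr)$significant)
  thr$threshold_p <- 0.0100001
  expect_true(call_significant_genes(assoc, thr)$significant)
})

test_that("best-SNP tie-breaking is deterministic: p, |distance|, snp_id", {
  assoc <- data.frame(
    gene_id = "g1", probe_id = "p1",
    snp_id = c("s_b", "s_a", "s_c"),
    chrom = "1", pos = c(100L, 200L, 300L), tss = 150L,
    distance = c(-50L, 50L, 150L),
    rho = 0.5, p_nominal = c(0.001, 0.001, 0.0005), n_used = 50L,
    stringsAsFactors = FALSE)
  thr <- data.frame(gene_id = "g1", threshold_p = 0.01)
  best <- call_significant_genes(assoc, thr)
  expect_equal(best$snp_id, "s_c")          # smallest p wins
  assoc$p_nominal <- 0.001
  best <- call_significant_genes(assoc, thr)
  expect_equal(best$snp_id, "s_a")          # |distance| tie-break, then id
})

test_that("expected-count FDR reproduces the printed arithmetic", {
  expect_equal(round(fdr_expected(18226, 0.01, 657), 2), 0.28)
  expect_equal(round(fdr_expected(18226, 0.001, 411), 2), 0.04)
  expect_equal(fdr_expected(100, 0.05, 10), 0.5)
  expect_true(is.na(fdr_expected(100, 0.05, 0)))
  expect_equal(fdr_expected(100, 0.5, 10), 1)   # capped
})

test_that("replication FDR counts same-direction sub-threshold hits", {
  disc <- data.frame(gene_id = paste0("g", 1:10), probe_id = paste0("p", 1:10),
                     snp_id = paste0("s", 1:10), rho = rep(0.5, 10),
                     significant = TRUE, stringsAsFactors = FALSE)
  other <- data.frame(probe_id = paste0("p", 1:10), snp_id = paste0("s", 1:10),
                      rho = c(rep(0.4, 6), rep(-0.4, 2), rep(0.4, 2)),
                      p_nominal = c(rep(0.001, 6), 0.001, 0.001, 0.5, 0.5),
                      stringsAsFactors = FALSE)
  fdr <- fdr_replication(disc, list(other))
  expect_equal(as.numeric(fdr), 0.4)         # 6 of 10 replicate
  attr(fdr, "n_replicated") <- NULL; attr(fdr, "n_untestable") <- NULL
  other$rho <- 0.4; other$p_nominal <- 1e-4
  expect_equal(as.numeric(fdr_replication(disc, list(other))), 0)
})

test_that("permutation thresholds are monotone in alpha per gene", {
  sim <- small_study()
  norm <- median_normalize(quantile_normalize_replicates(sim$expr))
  e <- split_by_pop(norm)$P1
  annot <- select_probes(sim$annot)
  pairs <- enumerate_cis_pairs(annot, sim$genotypes$P1)
  pairs <- pairs[pairs$gene_id %in% unique(pairs$gene_id)[1:5], ]
  t01 <- permutation_thresholds(pairs, e, sim$genotypes$P1, n_perms = 1000,
                                alpha = 0.01, seed = 5,
                                share_permutations = TRUE)
  t001 <- permutation_thresholds(pairs, e, sim$genotypes$P1, n_perms = 1000,
                                 alpha = 0.001, seed = 5,
                                 share_permutations = TRUE)
  expect_true(all(t001$threshold_p <= t01$threshold_p))
  expect_error(permutation_thresholds(pairs, e, sim$genotypes$P1,
                                      n_perms = 500, alpha = 0.001),
               "1/alpha")
})

test_that("stepwise mapping resolves independent signals and collapses clones", {
  set.seed(47)
  n <- 100
  dA <- rbinom(n, 2, 0.5); dB <- rbinom(n, 2, 0.5)
  expr_v <- dA + dB + rnorm(n, 0, 0.25)
  pos <- c(1000L, 2000L, 3000L)
  recover2 <- 0
  for (rep_i in 1:10) {
    dA <- rbinom(n, 2, 0.5); dB <- rbinom(n, 2, 0.5)
    expr_v <- dA + dB + rnorm(n, 0, 0.25)
    dos <- rbind(sA = dA, sB = dB)
    g <- make_geno(dos, pos = pos[1:2])
    vals <- matrix(expr_v, 1, n, dimnames = list("p1", colnames(g$dosage)))
    e <- expression_matrix(vals, stage = "strat_corrected")
    assoc <- score_cis_pairs(
      data.frame(probe_id = "p1", gene_id = "g1", snp_id = c("sA", "sB"),
                 chrom = "1", pos = pos[1:2], tss = 1500L,
                 distance = c(-500L, 500L), stringsAsFactors = FALSE),
      e, g)
    st <- stepwise_independent("g1", assoc, e, g, threshold_p = 1e-4)
    if (nrow(st) == 2) recover2 <- recover2 + 1
  }
  expect_gte(recover2, 9)

  # perfect clone: exactly one independent SNP
  dos <- rbind(sA = dA, sClone = dA)
  g <- make_geno(dos, pos = pos[1:2])
  vals <- matrix(dA + rnorm(n, 0, 0.25), 1, n,
                 dimnames = list("p1", colnames(g$dosage)))
  e <- expression_matrix(vals, stage = "strat_corrected")
  assoc <- score_cis_pairs(
    data.frame(probe_id = "p1", gene_id = "g1", snp_id = c("sA", "sClone"),
               chrom = "1", pos = pos[1:2], tss = 1500L,
               distance = c(-500L, 500L), stringsAsFactors = FALSE), e, g)
  st <- stepwise_independent("g1", assoc, e, g, threshold_p = 1e-4)
  expect_equal(nrow(st), 1L)

  # termination bound: never more steps than significant SNPs
  expect_lte(nrow(st), 2L)
})

test_that("joint individual permutation leaves the scan unchanged", {
  sim <- small_study()
  norm <- median_normalize(quantile_normalize_replicates(sim$expr))
  e <- split_by_pop(norm)$P1
  annot <- select_probes(sim$annot)
  pairs <- enumerate_cis_pairs(annot, sim$genotypes$P1)
  a1 <- score_cis_pairs(pairs, e, sim$genotypes$P1)
  perm <- sample(ncol(e$values))
  e2 <- expression_matrix(e$values[, perm],
                          sample_meta = e$sample_meta[perm, ],
                          stage = e$stage)
  g2 <- sim$genotypes$P1
  g2$dosage <- g2$dosage[, perm]
  a2 <- score_cis_pairs(pairs, e2, g2)
  expect_equal(a1$rho, a2$rho, tolerance = 1e-12)
})
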