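test_that("sharing matrix counts pairs, histogram and printed percentages", {
  sets <- list(CEU = c("g1", "g2"), CHB = c("g1", "g3"), YRI = c("g1"))
  sm <- sharing_matrix(sets)
  expect_equal(sm$n_nonredundant, 3L)
  expect_equal(unname(sm$histogram), c(2L, 0L, 1L))
  expect_equal(sm$pair_counts["CEU", "CHB"], 1L)
  expect_equal(sm$pair_counts["CEU", "YRI"], 1L)
  expect_equal(sm$n_ge2, 1L)
  expect_equal(sm$n_all, 1L)

  # a gene significant everywhere contributes to all pairs
  sets8 <- setNames(rep(list("gX"), 8), paste0("P", 1:8))
  sm8 <- sharing_matrix(sets8)
  expect_true(all(sm8$pair_counts[upper.tri(sm8$pair_counts)] == 1L))
  expect_equal(sum(upper.tri(sm8$pair_counts)), 28L)

  # printed-percentage arithmetic from the study's published counts
  expect_equal(round(100 * 1074 / 3130), 34)
  sm_art <- sharing_matrix(list(A = paste0("g", 1:3130),
                                B = paste0("g", 1:1074)))
  expect_equal(sm_art$pct_ge2, 34)
})

test_that("direction concordance is the same-sign fraction and symmetric", {
  best <- function(ids, rho) data.frame(
    gene_id = ids, probe_id = paste0("pr_", ids), snp_id = paste0("s_", ids),
    rho = rho, significant = TRUE, stringsAsFactors = FALSE)
  a <- best(c("g1", "g2"), c(0.5, 0.6))
  b <- best(c("g1", "g2"), c(0.4, 0.7))
  expect_equal(as.numeric(direction_concordance(a, b)), 1.0)
  b2 <- best(c("g1", "g2"), c(-0.4, 0.7))
  expect_equal(as.numeric(direction_concordance(a, b2)), 0.5)
  expect_equal(as.numeric(direction_concordance(b2, a)), 0.5)  # symmetry
  # nothing shared -> NA
  c_ <- best("g9", 0.5)
  expect_true(is.na(direction_concordance(a, c_)))
})

test_that("homozygote fold-change follows the median arithmetic", {
  expr <- c(5, 5.2, 4.8, 3, 3.1, 2.9, 4, 4.1)
  dos <- c(2, 2, 2, 0, 0, 0, 1, 1)
  expect_equal(homozygote_fold_change(expr, dos), 2.0)
  expect_equal(homozygote_fold_change(rep(1, 8), dos), 0)
  # invariant under constant shifts
  expect_equal(homozygote_fold_change(expr + 7, dos),
               homozygote_fold_change(expr, dos))
  # singleton homozygote class -> NA with reason
  r <- homozygote_fold_change(expr, c(2, 1, 1, 0, 0, 0, 1, 1))
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "class too small")
  # additive planted effect of beta implies ~2 beta between homozygotes
  set.seed(61)
  fc <- replicate(50, {
    d <- rbinom(120, 2, 0.5)
    homozygote_fold_change(1 * d + rnorm(120, 0, 0.3), d)
  })
  expect_lt(abs(mean(fc) - 2.0), 0.1)
})

test_that("effect size vs sharing correlation behaves at the boundaries", {
  set.seed(62)
  n_shared <- sample(1:8, 300, replace = TRUE)
  fc <- 0.3 * n_shared + rexp(300, 2)
  r <- effect_size_vs_sharing(fc, n_shared)
  expect_gt(r$r, 0); expect_lt(r$p, 0.05)
  # constant sharing -> NA
  expect_true(is.na(effect_size_vs_sharing(fc, rep(3, 300))$r))
  # shuffled labels -> near-zero correlation
  r0 <- effect_size_vs_sharing(fc, sample(n_shared))
  expect_lt(abs(r0$r), 0.15)
  # too few genes -> NA
  expect_true(is.na(effect_size_vs_sharing(fc[1:10], n_shared[1:10])$r))
})

test_that("pi1 estimation is calibrated on known mixtures", {
  expect_equal(pi1_estimate(rep(1e-4, 100)), 1)
  set.seed(63)
  p_unif <- runif(10000)
  se <- sqrt(0.5 * 0.5 / 10000) / 0.5
  expect_lt(abs(pi1_estimate(p_unif)), 3 * se + 0.01)
  # 50/50 mixture of uniforms and near-zero p-values
  p_mix <- c(runif(5000), rep(1e-6, 5000))
  expect_lt(abs(pi1_estimate(p_mix) - 0.5), 0.03)
  # bounds and lambda monotonicity beyond the null support
  expect_true(pi1_estimate(runif(100)) >= 0)
  p <- c(runif(500), rep(1e-5, 500))
  expect_gte(pi1_estimate(p, lambda = 0.2), pi1_estimate(p, lambda = 0.8) - 0.05)
  expect_true(is.na(pi1_estimate(numeric(0))))
  expect_warning(pi1_estimate(runif(10)), "unstable")
})

test_that("TSS distance by sharing level reports strata and trend", {
  best <- data.frame(gene_id = paste0("g", 1:60),
                     distance = rep(0L, 60), significant = TRUE,
                     stringsAsFactors = FALSE)
  ns <- setNames(rep(1:3, each = 20), best$gene_id)
  r <- tss_distance_by_sharing(best, ns)
  expect_true(all(vapply(r$strata, `[[`, 0, "median") == 0))
  # single sharing level -> trend NA
  r1 <- tss_distance_by_sharing(best, setNames(rep(2L, 60), best$gene_id))
  expect_true(is.na(r1$trend_rho))
  # tightening pattern: median distance decreasing with sharing level
  set.seed(64)
  best$distance <- as.integer(round(rnorm(60, 0, 2e5 / ns)))
  r2 <- tss_distance_by_sharing(best, ns)
  med <- vapply(r2$strata, `[[`, 0, "median")
  expect_lt(r2$trend_rho, 0)
  expect_true(med["3"] <= med["1"])
})

test_that("multi-gene clusters are found, replicated, and distance-tested", {
  best <- function(genes, snps, dist, pop) data.frame(
    gene_id = genes, probe_id = paste0("pr_", genes), snp_id = snps,
    distance = dist, rho = 0.5, significant = TRUE,
    stringsAsFactors = FALSE)
  bp <- list(
    A = best(c("g1", "g2", "g3", "g4"), c("s1", "s1", "s2", "s3"),
             c(500000L, 480000L, 1000L, 2000L), "A"),
    B = best(c("g1", "g2", "g5"), c("s1", "s1", "s9"),
             c(500000L, 480000L, 1500L), "B"))
  r <- multi_gene_clusters(bp)
  expect_equal(sort(unique(r$clusters$snp_id)), "s1")
  expect_equal(r$clusters$n_genes, c(2L, 2L))
  expect_equal(r$replicated, "s1")
  expect_gt(r$median_cluster_dist, r$median_single_dist)
  # no shared SNP -> no clusters
  bp2 <- list(A = best(c("g1", "g2"), c("s1", "s2"), c(1L, 2L), "A"))
  expect_equal(nrow(multi_gene_clusters(bp2)$clusters), 0L)
})

test_that("parsimony sharing assigns eQTLs to covering clades", {
  pops <- LETTERS[1:8]
  fst <- matrix(0.12, 8, 8, dimnames = list(pops, pops))
  fst[1:3, 1:3] <- 0.01                        # {A,B,C} form a tight clade
  fst[4:8, 4:8] <- 0.08
  diag(fst) <- 0
  tree <- population_tree(fst)
  expect_setequal(tree$tip.label, pops)

  # all eQTLs shared by exactly {A,B,C}: their clade node is heavily loaded
  gp <- setNames(rep(list(c("A", "B", "C")), 30), paste0("g", 1:30))
  r <- parsimony_sharing(tree, gp, n_random = 100, seed = 3)
  expect_equal(sum(r$node_counts), 30)         # conservation
  abc_node <- r$assignments[[1]]
  expect_true(all(r$assignments == abc_node))
  expect_gt(abc_node, ape::Ntip(tree))         # an internal node
  expect_true(r$enriched[abc_node])

  # single-population eQTLs sit at the leaves; internal nodes empty
  gp1 <- setNames(as.list(pops), paste0("h", 1:8))
  r1 <- parsimony_sharing(tree, gp1, n_random = 50, seed = 4)
  expect_equal(sum(r1$node_counts[1:8]), 8)
  expect_equal(sum(r1$node_counts[-(1:8)]), 0)

  # random assignment: few false flags under the set-randomization null
  set.seed(65)
  gpr <- lapply(1:60, function(i) sample(pops, sample(1:3, 1)))
  names(gpr) <- paste0("r", 1:60)
  rr <- parsimony_sharing(tree, gpr, n_random = 100, seed = 5, mode = "sets")
  expect_lte(sum(rr$enriched), 3)
})

test_that("sharing sets pool discovery and lenient replication calls", {
  strict <- list(A = c("g1", "g2"), B = c("g1"), C = character(0))
  lenient <- list(A = c("g1", "g2"), B = c("g1", "g2"), C = c("g1"))
  ss <- sharing_sets(strict, lenient, seed = 1)
  expect_setequal(names(ss), c("g1", "g2"))
  expect_setequal(ss$g1, c("A", "B", "C"))
  expect_setequal(ss$g2, c("A", "B"))
})
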