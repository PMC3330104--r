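test_that("V_ST reproduces hand-computed cases and its boundary conventions", {
  # all variance between populations
  expect_equal(vst(c(0, 0), c(1, 1))$vst, 1)
  # identical samples: no divergence
  r <- vst(c(0, 1), c(0, 1))
  expect_equal(r$vst, 0)
  expect_equal(r$v_s, r$v_t)
  # hand-derived: {1,2,3} vs {4,5,6}
  r2 <- vst(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$v1, 2 / 3); expect_equal(r2$v_s, 2 / 3)
  expect_equal(r2$v_t, 35 / 12)
  expect_equal(r2$vst, (35 / 12 - 2 / 3) / (35 / 12), tolerance = 1e-12)
  expect_equal(r2$vst, 0.7714286, tolerance = 1e-6)
  # degenerate: identical constants -> defined as 0
  expect_equal(vst(c(2, 2), c(2, 2))$vst, 0)
  # V_S weighting is exact
  r3 <- vst(rnorm(5), rnorm(9))
  expect_equal(r3$v_s, (r3$v1 * 5 + r3$v2 * 9) / 14, tolerance = 1e-12)
})

test_that("V_ST is invariant to affine transformations and matches the oracle", {
  set.seed(51)
  for (k in 1:100) {
    x1 <- rnorm(sample(3:20, 1)); x2 <- rnorm(sample(3:20, 1), mean = runif(1, 0, 2))
    expect_equal(vst(x1, x2)$vst, oracle_vst(x1, x2), tolerance = 1e-12)
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 4)
    expect_equal(vst(x1 + a, x2 + a)$vst, vst(x1, x2)$vst, tolerance = 1e-9)
    expect_equal(vst(b * x1, b * x2)$vst, vst(x1, x2)$vst, tolerance = 1e-9)
  }
})

test_that("vst_scan handles identical populations, label permutation, and divergence", {
  set.seed(52)
  vals <- matrix(rnorm(20 * 12, 8), 20, 12)
  vals <- cbind(vals, vals)   # populations B is a copy of A
  dimnames(vals) <- list(paste0("p", 1:20), paste0("i", 1:24))
  meta <- data.frame(sample_id = colnames(vals),
                     population = rep(c("A", "B"), each = 12))
  e <- expression_matrix(vals, stage = "normalized", sample_meta = meta)
  res <- vst_scan(e)
  expect_true(all(res$table$vst == 0))

  # divergence increases the high-V_ST count monotonically
  counts <- sapply(c(0, 0.5, 1.5, 3), function(shift) {
    v2 <- vals
    v2[, 13:24] <- v2[, 13:24] + rep(rnorm(20, 0, shift), 12)
    e2 <- expression_matrix(v2, stage = "normalized", sample_meta = meta)
    vst_scan(e2)$summary$n_high
  })
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[4], counts[1])

  # permuting population labels jointly leaves the summary invariant
  perm <- sample(24)
  e3 <- expression_matrix(vals[, perm], stage = "normalized",
                          sample_meta = meta[perm, ])
  expect_equal(vst_scan(e3)$summary, res$summary, tolerance = 1e-12)
})

test_that("Hudson F_ST matches estimator arithmetic", {
  # identical frequencies
  expect_lt(fst_pairwise(rep(0.3, 100), rep(0.3, 100))$fst, 1e-12)
  # fixed difference
  expect_equal(fst_pairwise(0.0, 1.0)$per_snp, 1)
  # infinite-sample arithmetic: 0.36 / 0.68
  f <- fst_pairwise(rep(0.2, 50), rep(0.8, 50))
  expect_equal(f$fst, 0.36 / 0.68, tolerance = 1e-12)
  # symmetry in population order, random instances
  set.seed(53)
  for (k in 1:100) {
    p1 <- runif(200, 0.05, 0.95); p2 <- runif(200, 0.05, 0.95)
    a <- fst_pairwise(p1, p2, window = 50)$fst
    b <- fst_pairwise(p2, p1, window = 50)$fst
    expect_equal(a, b, tolerance = 1e-12)
    # per-SNP oracle arithmetic on the first SNP
    expect_equal(fst_pairwise(p1, p2)$per_snp[1],
                 (p1[1] - p2[1])^2 / (p1[1] * (1 - p2[1]) + p2[1] * (1 - p1[1])),
                 tolerance = 1e-12)
  }
})

test_that("term enrichment equals the hypergeometric tail", {
  universe <- paste0("g", 1:100)
  top <- universe[1:5]
  term_map <- list(t_exact = top, t_all = universe, t_none = character(0))
  res <- term_enrichment(top, term_map, universe)
  expect_equal(nrow(res), 2)                     # empty term skipped
  expect_equal(res$p_one_sided[res$term_id == "t_exact"], 1 / choose(100, 5),
               tolerance = 1e-12)
  expect_equal(res$p_one_sided[res$term_id == "t_all"], 1)

  # 100 random instances against the explicit hypergeometric oracle
  set.seed(54)
  for (k in 1:100) {
    n_univ <- sample(30:80, 1)
    univ <- paste0("g", seq_len(n_univ))
    top_k <- sample(univ, sample(3:10, 1))
    term <- sample(univ, sample(3:15, 1))
    p <- term_enrichment(top_k, list(t = term), univ)$p_one_sided
    a <- length(intersect(top_k, term))
    expect_equal(p, oracle_hyper(a, length(top_k), length(term), n_univ),
                 tolerance = 1e-9)
  }
})

test_that("term enrichment p-values are calibrated under independence", {
  set.seed(55)
  universe <- paste0("g", 1:200)
  top <- sample(universe, 20)
  terms <- lapply(1:1000, function(i) sample(universe, 20))
  names(terms) <- paste0("t", 1:1000)
  res <- term_enrichment(top, terms, universe)
  frac <- mean(res$p_one_sided < 0.05)
  # discrete test is conservative; fraction at or below the nominal level
  expect_lt(frac, 0.08)
  expect_gt(frac, 0.005)
})

test_that("Fisher's combined probability matches the chi-square tail", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(c(0.5, 0.5)), 0.5965736, tolerance = 1e-6)
  expect_equal(fisher_combine(0.123), 0.123, tolerance = 1e-12)
  expect_warning(p0 <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(p0 >= 0 && p0 <= 1)
  # closed form for k = 2: P = q (1 - ln q) with q = p1 p2
  set.seed(56)
  for (k in 1:100) {
    p <- runif(2)
    q <- prod(p)
    expect_equal(fisher_combine(p), q * (1 - log(q)), tolerance = 1e-9)
  }
  # monotone: shrinking any p never increases the combination
  p <- c(0.2, 0.6, 0.9)
  expect_lte(fisher_combine(c(0.1, 0.6, 0.9)), fisher_combine(p))
})

test_that("population-specific terms survive only focal-specific enrichment", {
  pops <- c("A", "B", "C", "D")
  pairs <- combn(pops, 2)
  mk <- function(p_focal_only, p_everywhere) {
    out <- list()
    for (k in seq_len(ncol(pairs))) {
      p1 <- pairs[1, k]; p2 <- pairs[2, k]
      has_a <- "A" %in% c(p1, p2)
      out[[paste(p1, p2, sep = "|")]] <- data.frame(
        term_id = c("t_focal", "t_global", "t_null"),
        n_top_term = 1L, n_top = 5L, n_term = 10L, n_universe = 100L,
        p_one_sided = c(if (has_a) p_focal_only else 0.8,
                        p_everywhere, 0.7),
        stringsAsFactors = FALSE)
    }
    out
  }
  tabs <- mk(0.001, 0.001)
  res <- suppressMessages(population_specific_terms(tabs, "A"))
  expect_true("t_focal" %in% res$term_id)
  expect_false("t_global" %in% res$term_id)   # enriched everywhere: filtered
  expect_false("t_null" %in% res$term_id)
})

test_that("cross-population informativeness distinguishes replicate from noise", {
  pops <- c("A", "B", "C", "D", "E")
  pairs <- combn(pops, 2)
  terms <- paste0("t", 1:40)
  set.seed(57)
  base <- ifelse(seq_along(terms) <= 10, 1e-4, runif(40, 0.2, 1))
  mk_tab <- function(pvec) data.frame(term_id = terms, n_top_term = 1L,
                                      n_top = 5L, n_term = 10L,
                                      n_universe = 100L, p_one_sided = pvec,
                                      stringsAsFactors = FALSE)
  # B behaves as a replicate of A: every pair shares the same term signal
  tabs <- list()
  for (k in seq_len(ncol(pairs)))
    tabs[[paste(pairs[1, k], pairs[2, k], sep = "|")]] <- mk_tab(base)
  res <- cross_population_informativeness(tabs, "A", "B")
  expect_gt(res$frac_b_below, 0.9)
  # symmetric when the tables are identical
  res_ba <- cross_population_informativeness(tabs, "B", "A")
  expect_equal(res$frac_b_below, res_ba$frac_b_below)

  # independent: signals scrambled per pair
  tabs2 <- tabs
  for (k in names(tabs2)) tabs2[[k]]$p_one_sided <- sample(base)
  res2 <- cross_population_informativeness(tabs2, "A", "B")
  expect_lt(res2$frac_b_below, res$frac_b_below)
})
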