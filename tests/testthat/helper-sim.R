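# Shared small fixtures, generated in code (no stored data).

two_pop_specs <- function(n = 60, F = 0.05) {
  list(population_spec("P1", n, F), population_spec("P2", n, F))
}

# small two-population study with strong shared eQTLs, reused across files
small_study <- function(seed = 11, ...) {
  args <- list(pops = two_pop_specs(), n_genes = 40, n_snps = 600,
               n_eqtl = 10, prop_shared_all = 1, beta_range = c(1, 1.4),
               apply_decay = FALSE, noise_sd = 0.25, replicate_sd = 0.2,
               n_factors = 0, missing_rate = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulate_study, args)
}

# split a normalized expression matrix by population
split_by_pop <- function(expr) {
  pops <- unique(expr$sample_meta$population)
  out <- lapply(pops, function(p) {
    keep <- expr$sample_meta$population == p
    expression_matrix(expr$values[, keep, drop = FALSE], stage = expr$stage,
                      sample_meta = expr$sample_meta[keep, , drop = FALSE])
  })
  names(out) <- pops
  out
}

# brute-force Spearman rho: mid-ranks + explicit Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# direct-arithmetic V_ST oracle (denominator-n variances)
oracle_vst <- function(x1, x2) {
  mlvar <- function(v) mean((v - mean(v))^2)
  vs <- (mlvar(x1) * length(x1) + mlvar(x2) * length(x2)) /
    (length(x1) + length(x2))
  vt <- mlvar(c(x1, x2))
  if (vt <= 0) 0 else min(max((vt - vs) / vt, 0), 1)
}

# hypergeometric upper-tail oracle for one-sided enrichment
oracle_hyper <- function(a, n_top, n_term, n_univ) {
  kk <- a:min(n_top, n_term)
  sum(choose(n_term, kk) * choose(n_univ - n_term, n_top - kk)) /
    choose(n_univ, n_top)
}
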