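#' Describe one simulated population sample
#'
#' A population is characterized by its sample size and a Balding-Nichols
#' drift (divergence) coefficient relative to a shared ancestral allele
#' frequency pool.  Populations may optionally belong to a continental
#' pool (two-level drift, which creates a clade structure in the F_ST
#' tree) and may be admixed, in which case each individual carries
#' Dirichlet-distributed mixing weights over two or more pools.
#'
#' @param name Population label (e.g. \code{"CEU"}).
#' @param n_individuals Number of diploid individuals (>= 2).
#' @param divergence Drift coefficient F in (0, 1); the per-population
#'   allele frequency for a SNP with (pool) frequency p is drawn from
#'   Beta(p(1-F)/F, (1-p)(1-F)/F), so Var = F p(1-p).
#' @param pool Optional continental pool label; pools drift from the
#'   ancestral frequencies with their own coefficients (see
#'   \code{\link{simulate_allele_freqs}}).
#' @param admixture_props Optional named numeric vector of mixing weights
#'   over pool labels; must sum to 1 (tolerance 1e-9).
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(name, n_individuals, divergence,
                            pool = NULL, admixture_props = NULL) {
  if (n_individuals < 2)
    stop("population '", name, "': n_individuals must be >= 2")
  if (!is.finite(divergence) || divergence <= 0 || divergence >= 1)
    stop("population '", name, "': divergence must lie in (0, 1)")
  if (!is.null(admixture_props)) {
    if (is.null(names(admixture_props)) || any(!nzchar(names(admixture_props))))
      stop("admixture_props must be a named vector of pool weights")
    if (abs(sum(admixture_props) - 1) > 1e-9)
      stop("population '", name, "': admixture_props must sum to 1")
    if (any(admixture_props < 0))
      stop("population '", name, "': admixture_props must be non-negative")
  }
  structure(list(name = name, n_individuals = as.integer(n_individuals),
                 divergence = divergence, pool = pool,
                 admixture_props = admixture_props),
            class = "population_spec")
}

#' Default eight-population design
#'
#' The simulator's default study layout mirrors an eight-population
#' lymphoblastoid panel: CEU (109), CHB (80), GIH (82), JPT (82),
#' LWK (82), MEX (45), MKK (138), YRI (108), grouped into African,
#' European/South-Asian and East-Asian pools, with MEX admixed between
#' the European and East-Asian pools and MKK lightly admixed with the
#' European pool.  Drift coefficients are chosen to reproduce the usual
#' human F_ST hierarchy (within-continent pairs ~0.01, across-continent
#' ~0.10).
#'
#' @param n_individuals Optional named integer vector overriding the
#'   per-population sample sizes (useful for reduced test scale).
#' @return List of \code{population_spec} objects.
#' @export
default_populations <- function(n_individuals = NULL) {
  sizes <- c(CEU = 109L, CHB = 80L, GIH = 82L, JPT = 82L,
             LWK = 82L, MEX = 45L, MKK = 138L, YRI = 108L)
  if (!is.null(n_individuals))
    sizes[names(n_individuals)] <- as.integer(n_individuals)
  pools <- c(CEU = "EUR", CHB = "ASN", GIH = "EUR", JPT = "ASN",
             LWK = "AFR", MEX = "EUR", MKK = "AFR", YRI = "AFR")
  div <- c(CEU = 0.01, CHB = 0.008, GIH = 0.02, JPT = 0.008,
           LWK = 0.012, MEX = 0.03, MKK = 0.015, YRI = 0.01)
  admix <- list(MEX = c(EUR = 0.6, ASN = 0.4), MKK = c(AFR = 0.85, EUR = 0.15))
  lapply(names(sizes), function(p)
    population_spec(p, sizes[[p]], div[[p]], pool = pools[[p]],
                    admixture_props = admix[[p]]))
}

#' Simulate per-population allele frequencies under Balding-Nichols drift
#'
#' Ancestral frequencies are drawn uniformly in \code{ancestral_maf_range};
#' each pool (if \code{pool_divergence} is given) drifts from the ancestral
#' pool, and each population drifts from its pool (or directly from the
#' ancestral pool when it has none).  For an admixed population the
#' population-level frequency column is the admixture-weighted average of
#' its pool frequencies (individual-level mixing happens in
#' \code{\link{simulate_genotypes}}).
#'
#' @param n_snps Number of SNPs (>= 1).
#' @param pops List of \code{\link{population_spec}} objects.
#' @param ancestral_maf_range Interval within (0, 1) for ancestral
#'   frequencies; default \code{c(0.05, 0.95)}.
#' @param pool_divergence Named numeric vector of drift coefficients for
#'   pools referenced by the specs; default 0.10 for every referenced pool.
#' @param seed Integer seed; fixed seed gives identical tables.
#' @return A list with \code{ancestral} (numeric vector), \code{pools}
#'   (matrix SNP x pool, or NULL), and \code{freqs} (matrix SNP x population).
#' @export
simulate_allele_freqs <- function(n_snps, pops,
                                  ancestral_maf_range = c(0.05, 0.95),
                                  pool_divergence = NULL, seed = 1L) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (length(ancestral_maf_range) != 2 ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] >= 1 ||
      ancestral_maf_range[1] >= ancestral_maf_range[2])
    stop("ancestral_maf_range must be an interval inside (0, 1)")
  set.seed(seed)
  anc <- stats::runif(n_snps, ancestral_maf_range[1], ancestral_maf_range[2])

  pool_names <- unique(unlist(c(
    lapply(pops, function(p) p$pool),
    lapply(pops, function(p) names(p$admixture_props)))))
  pool_freqs <- NULL
  if (length(pool_names)) {
    if (is.null(pool_divergence))
      pool_divergence <- stats::setNames(rep(0.10, length(pool_names)), pool_names)
    missing_pools <- setdiff(pool_names, names(pool_divergence))
    if (length(missing_pools))
      stop("pool_divergence missing for pool(s): ",
           paste(missing_pools, collapse = ", "))
    pool_freqs <- sapply(pool_names, function(pl)
      .bn_draw(anc, pool_divergence[[pl]]))
    rownames(pool_freqs) <- NULL
  }

  freqs <- sapply(pops, function(p) {
    base <- if (!is.null(p$admixture_props)) {
      w <- p$admixture_props
      as.vector(pool_freqs[, names(w), drop = FALSE] %*% w)
    } else if (!is.null(p$pool)) {
      pool_freqs[, p$pool]
    } else anc
    .bn_draw(base, p$divergence)
  })
  colnames(freqs) <- vapply(pops, `[[`, "", "name")
  list(ancestral = anc, pools = pool_freqs, freqs = freqs)
}

## Balding-Nichols Beta draw around base frequency p with drift F.
## Beta(p(1-F)/F, (1-p)(1-F)/F); degenerate p in {0,1} passes through.
.bn_draw <- function(p, F) {
  if (F <= 0 || F >= 1) stop("divergence must lie in (0, 1)")
  k <- (1 - F) / F
  out <- stats::rbeta(length(p), p * k, (1 - p) * k)
  out[p <= 0] <- 0
  out[p >= 1] <- 1
  out
}

#' Simulate diploid genotypes from allele frequencies
#'
#' Genotype dosages are Binomial(2, freq) under Hardy-Weinberg.  For an
#' admixed population each individual draws fixed mixing weights from a
#' Dirichlet centred on the population's admixture proportions
#' (concentration \code{admix_concentration}) and uses the weighted pool
#' frequencies for every SNP, so genotype PCA can recover individual
#' admixture variation.  Missing calls are planted completely at random
#' at rate \code{missing_rate} and stored as \code{NA}.
#'
#' @param freqs Result of \code{\link{simulate_allele_freqs}}.
#' @param pops List of \code{population_spec} objects (same order).
#' @param missing_rate Proportion of calls set missing, in [0, 1).
#' @param seed Integer seed.
#' @param snp_info Optional data frame (snp_id, chrom, pos, ref, alt); by
#'   default SNPs are placed uniformly on one synthetic chromosome.
#' @param admix_concentration Dirichlet concentration multiplier for
#'   individual admixture weights (default 10).
#' @return Named list of \code{genotype_matrix} objects (one per
#'   population), each with \code{dosage} (SNP x individual, NA = missing),
#'   \code{snp_info} and \code{pop}.
#' @export
simulate_genotypes <- function(freqs, pops, missing_rate = 0, seed = 1L,
                               snp_info = NULL, admix_concentration = 10) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  fmat <- freqs$freqs
  if (any(fmat < 0 | fmat > 1)) stop("frequencies must lie in [0, 1]")
  n_snps <- nrow(fmat)
  set.seed(seed)
  if (is.null(snp_info)) {
    snp_info <- data.frame(
      snp_id = sprintf("snp%05d", seq_len(n_snps)),
      chrom = "1",
      pos = sort(sample.int(5e7, n_snps)),
      ref = "A", alt = "G",
      stringsAsFactors = FALSE)
  }
  out <- lapply(pops, function(p) {
    n <- p$n_individuals
    if (!is.null(p$admixture_props)) {
      w <- p$admixture_props
      a <- admix_concentration * w
      # Dirichlet via normalized gammas, one weight vector per individual
      gm <- matrix(stats::rgamma(n * length(w), shape = rep(a, each = n)),
                   nrow = n)
      gm <- gm / rowSums(gm)
      pf <- freqs$pools[, names(w), drop = FALSE]
      indfreq <- pf %*% t(gm)                  # SNP x individual
      dos <- matrix(stats::rbinom(n_snps * n, 2, as.vector(indfreq)),
                    nrow = n_snps)
    } else {
      f <- fmat[, p$name]
      dos <- matrix(stats::rbinom(n_snps * n, 2, rep(f, n)), nrow = n_snps)
    }
    if (missing_rate > 0) {
      miss <- stats::runif(length(dos)) < missing_rate
      dos[miss] <- NA_integer_
    }
    dimnames(dos) <- list(snp_info$snp_id,
                          sprintf("%s_%03d", p$name, seq_len(n)))
    structure(list(dosage = dos, snp_info = snp_info, pop = p$name),
              class = "genotype_matrix")
  })
  names(out) <- vapply(pops, `[[`, "", "name")
  out
}

#' Minor allele frequency from a dosage matrix
#'
#' Computed on non-missing calls only; returns the minor (folded)
#' frequency per SNP.
#' @param geno A \code{genotype_matrix}.
#' @return Numeric vector of MAFs (NA where every call is missing).
#' @export
genotype_maf <- function(geno) {
  p <- rowMeans(geno$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-SNP missingness proportion
#' @param geno A \code{genotype_matrix}.
#' @return Numeric vector of missing-call proportions.
#' @export
genotype_missingness <- function(geno) {
  rowMeans(is.na(geno$dosage))
}

#' Simulate raw replicate expression with planted cis-eQTLs
#'
#' Expression for individual i, probe g is
#' baseline_g + sum(beta * dosage) over planted eQTLs active in i's
#' population + loadings %*% scores hidden-confounder term + individual
#' noise; each individual is then measured twice with independent
#' replicate noise, emulating duplicate hybridizations.  Probes flagged
#' as SNP-in-probe receive an additional artifact term proportional to
#' the dosage of the overlapping SNP (hybridization attenuation).
#'
#' @param genotypes Named list of \code{genotype_matrix} (one per population).
#' @param annot Probe annotation data frame with columns probe_id, gene_id,
#'   chrom, tss, strand, snp_in_probe (see \code{\link{simulate_study}}).
#' @param planted Data frame with columns gene_id, snp_id, beta, shared_in
#'   (comma-separated population labels) and tss_distance.
#' @param n_factors Number of hidden global confounders (default 8).
#' @param factor_sd Standard deviation of hidden-factor loadings (default 0.6).
#' @param noise_sd Individual-level residual SD on the log2 scale (default 0.5).
#' @param replicate_sd Replicate (hybridization) noise SD (default 0.3).
#' @param baseline_mean,baseline_sd Probe baseline distribution (default 8, 1).
#' @param artifact_beta SNP-in-probe artifact slope per allele copy of the
#'   in-probe SNP (default -0.5).
#' @param sharing_mode How an eQTL is inactive outside \code{shared_in}:
#'   \code{"beta"} sets its effect to zero there.  Under the default study
#'   generator the alternative frequency mechanism (SNP too rare outside
#'   the sharing set) is arranged upstream at frequency-simulation time,
#'   in which case the effect is active everywhere and \code{shared_in}
#'   records where the SNP is common.
#' @param seed Integer seed.
#' @return List with \code{expr} (an \code{expression_matrix} at stage
#'   \code{"raw"}, two replicate columns per individual) and \code{truth}
#'   (planted table, hidden factor loadings/scores, snp-in-probe ids, seed).
#' @export
simulate_expression <- function(genotypes, annot, planted,
                                n_factors = 8, factor_sd = 0.6,
                                noise_sd = 0.5, replicate_sd = 0.3,
                                baseline_mean = 8, baseline_sd = 1,
                                artifact_beta = -0.5,
                                sharing_mode = c("all", "beta"),
                                seed = 1L) {
  sharing_mode <- match.arg(sharing_mode)
  set.seed(seed)
  probes <- unique(annot$probe_id)
  n_probes <- length(probes)
  all_inds <- unlist(lapply(genotypes, function(g) colnames(g$dosage)))
  ind_pop <- rep(names(genotypes),
                 vapply(genotypes, function(g) ncol(g$dosage), 0L))
  n_ind <- length(all_inds)

  if (nrow(planted)) {
    snp_ids <- genotypes[[1]]$snp_info$snp_id
    bad <- setdiff(planted$snp_id, snp_ids)
    if (length(bad)) stop("planted SNP(s) absent from genotypes: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(planted$gene_id, annot$gene_id)
    if (length(bad)) stop("planted gene(s) lack TSS annotation: ",
                          paste(bad, collapse = ", "))
    # a planted SNP must segregate in every population it is shared in
    for (k in seq_len(nrow(planted))) {
      pops_k <- strsplit(planted$shared_in[k], ",")[[1]]
      for (pp in pops_k) {
        d <- genotypes[[pp]]$dosage[planted$snp_id[k], ]
        if (length(unique(d[!is.na(d)])) < 2)
          stop("planted SNP ", planted$snp_id[k],
               " is monomorphic in population ", pp)
      }
    }
  }

  baseline <- stats::rnorm(n_probes, baseline_mean, baseline_sd)
  names(baseline) <- probes

  # genetic signal, per individual
  signal <- matrix(0, n_probes, n_ind, dimnames = list(probes, all_inds))
  for (k in seq_len(nrow(planted))) {
    pr <- annot$probe_id[annot$gene_id == planted$gene_id[k]][1]
    pops_k <- strsplit(planted$shared_in[k], ",")[[1]]
    for (pp in names(genotypes)) {
      if (sharing_mode == "beta" && !(pp %in% pops_k)) next
      d <- genotypes[[pp]]$dosage[planted$snp_id[k], ]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      cols <- colnames(genotypes[[pp]]$dosage)
      signal[pr, cols] <- signal[pr, cols] + planted$beta[k] * d
    }
  }

  # SNP-in-probe hybridization artifacts
  sip_probes <- annot$probe_id[annot$snp_in_probe]
  sip_snp <- character(0)
  if (length(sip_probes)) {
    snp_ids <- genotypes[[1]]$snp_info$snp_id
    sip_snp <- stats::setNames(sample(snp_ids, length(sip_probes),
                                      replace = length(snp_ids) < length(sip_probes)),
                               sip_probes)
    for (pr in sip_probes) {
      for (pp in names(genotypes)) {
        d <- genotypes[[pp]]$dosage[sip_snp[[pr]], ]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        cols <- colnames(genotypes[[pp]]$dosage)
        signal[pr, cols] <- signal[pr, cols] + artifact_beta * d
      }
    }
  }

  # hidden global confounders
  if (n_factors > 0) {
    loadings <- matrix(stats::rnorm(n_probes * n_factors, 0, factor_sd),
                       n_probes, n_factors,
                       dimnames = list(probes, sprintf("hf%02d", 1:n_factors)))
    scores <- matrix(stats::rnorm(n_ind * n_factors), n_ind, n_factors,
                     dimnames = list(all_inds, colnames(loadings)))
    confound <- loadings %*% t(scores)
  } else {
    loadings <- matrix(0, n_probes, 0); scores <- matrix(0, n_ind, 0)
    confound <- 0
  }

  base_ind <- baseline + signal + confound +
    matrix(stats::rnorm(n_probes * n_ind, 0, noise_sd), n_probes, n_ind)

  vals <- matrix(0, n_probes, 2 * n_ind)
  samp_ids <- as.vector(t(outer(all_inds, c("r1", "r2"), paste, sep = "_")))
  vals[, seq(1, 2 * n_ind, 2)] <- base_ind +
    matrix(stats::rnorm(n_probes * n_ind, 0, replicate_sd), n_probes, n_ind)
  vals[, seq(2, 2 * n_ind, 2)] <- base_ind +
    matrix(stats::rnorm(n_probes * n_ind, 0, replicate_sd), n_probes, n_ind)
  dimnames(vals) <- list(probes, samp_ids)

  meta <- data.frame(
    sample_id = samp_ids,
    individual = rep(all_inds, each = 2),
    replicate = rep(1:2, n_ind),
    population = rep(ind_pop, each = 2),
    gender = rep(sample(c("F", "M"), n_ind, replace = TRUE), each = 2),
    stringsAsFactors = FALSE)

  expr <- expression_matrix(vals, stage = "raw", sample_meta = meta)
  truth <- list(planted = planted,
                hidden_factor_loadings = loadings,
                hidden_factor_scores = scores,
                snp_in_probe_ids = sip_probes,
                snp_in_probe_map = sip_snp,
                seed = seed)
  list(expr = expr, truth = truth)
}

#' Simulate a complete multi-population eQTL study
#'
#' End-to-end generator: populations (default the eight-population
#' design), Balding-Nichols allele frequencies, Hardy-Weinberg genotypes,
#' probe annotation on a synthetic chromosome, and replicate expression
#' with planted cis-eQTLs, hidden confounders and SNP-in-probe artifacts.
#'
#' Each planted eQTL picks a random eligible gene and plants a causal SNP
#' at a signed TSS distance drawn from a Laplace-like double exponential
#' (scale \code{tss_scale}); its effect size is drawn from
#' \code{beta_range} (random sign) and, when \code{apply_decay} is TRUE,
#' attenuated by \code{0.5^(|distance| / decay_half)} so that distal
#' effects are weaker.  Sharing across populations follows
#' \code{sharing_mode}: under the default \code{"freq"} mechanism the
#' causal SNP's allele frequency is forced below the MAF threshold in
#' populations outside the sharing set (non-replication by frequency,
#' the dominant mechanism in real panels); under \code{"beta"} the effect
#' is simply switched off there.
#'
#' @param pops List of \code{population_spec}; default
#'   \code{default_populations()}.
#' @param n_genes,n_snps Numbers of genes (one probe each) and SNPs.
#' @param n_eqtl Number of planted cis-eQTLs.
#' @param prop_shared_all Proportion of planted eQTLs shared by every
#'   population; the rest are assigned a random subset of populations.
#' @param beta_range Magnitude range for planted effects (log2 units per
#'   allele copy).
#' @param tss_scale Scale (bp) of the double-exponential TSS-distance draw.
#' @param decay_half Half-distance (bp) of the effect-size decay
#'   (default 20000).
#' @param apply_decay Attenuate |beta| with TSS distance (default TRUE).
#' @param sharing_mode \code{"freq"} (default) or \code{"beta"}; see above.
#' @param n_proxy Number of planted eQTLs that also receive a correlated
#'   proxy SNP (clone with correlation \code{proxy_r}) for stepwise tests.
#' @param proxy_r Dosage correlation of the proxy clone (1 = exact copy).
#' @param snp_in_probe_rate Proportion of probes flagged SNP-in-probe.
#' @param missing_rate Genotype missingness rate.
#' @param maf_threshold MAF threshold used by the frequency sharing
#'   mechanism (default 0.05).
#' @param seed Integer seed for the whole study.
#' @param ... Passed to \code{\link{simulate_expression}} (noise levels,
#'   factor structure, ...).
#' @return Object of class \code{eqtl_sim}: list with \code{genotypes},
#'   \code{expr} (raw), \code{annot}, \code{truth}, \code{pops},
#'   \code{seed}.
#' @export
simulate_study <- function(pops = default_populations(),
                           n_genes = 300, n_snps = 5000, n_eqtl = 50,
                           prop_shared_all = 0.5,
                           beta_range = c(0.8, 1.5),
                           tss_scale = 5e4, decay_half = 2e4,
                           apply_decay = TRUE,
                           sharing_mode = c("freq", "beta"),
                           n_proxy = 0, proxy_r = 1.0,
                           snp_in_probe_rate = 0.064,
                           missing_rate = 0.01,
                           maf_threshold = 0.05,
                           seed = 1L, ...) {
  sharing_mode <- match.arg(sharing_mode)
  pop_names <- vapply(pops, `[[`, "", "name")
  set.seed(seed)

  # gene TSSs spread over the chromosome; one probe per gene
  chrom_len <- 5e7
  tss <- sort(sample.int(chrom_len - 2e6, n_genes)) + 1e6
  annot <- data.frame(
    probe_id = sprintf("probe%04d", seq_len(n_genes)),
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = "1", tss = tss,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    snp_in_probe = stats::runif(n_genes) < snp_in_probe_rate,
    stringsAsFactors = FALSE)

  # background SNP positions
  pos <- sort(sample.int(chrom_len, n_snps))

  # planted eQTLs: gene, TSS distance, effect size, sharing set
  egenes <- sample.int(n_genes, n_eqtl)
  dist <- round(stats::rexp(n_eqtl, 1 / tss_scale)) *
    sample(c(-1L, 1L), n_eqtl, replace = TRUE)
  dist <- pmax(pmin(dist, 999999L), -999999L)
  beta <- stats::runif(n_eqtl, beta_range[1], beta_range[2]) *
    sample(c(-1, 1), n_eqtl, replace = TRUE)
  if (apply_decay) beta <- beta * 0.5^(abs(dist) / decay_half)
  shared <- lapply(seq_len(n_eqtl), function(k) {
    if (length(pop_names) == 1 || stats::runif(1) < prop_shared_all) pop_names
    else sort(sample(pop_names, sample.int(length(pop_names) - 1, 1)))
  })
  planted_pos <- pmax(pmin(annot$tss[egenes] + dist, chrom_len), 1)

  # replace the nearest background SNP position with each causal position
  snp_pos <- pos
  causal_idx <- integer(n_eqtl)
  for (k in seq_len(n_eqtl)) {
    j <- which.min(abs(snp_pos - planted_pos[k]))
    snp_pos[j] <- planted_pos[k]
    causal_idx[k] <- j
  }
  ord <- order(snp_pos)
  snp_pos <- snp_pos[ord]
  causal_idx <- match(causal_idx, ord)
  snp_info <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(n_snps)),
    chrom = "1", pos = snp_pos, ref = "A", alt = "G",
    stringsAsFactors = FALSE)

  freqs <- simulate_allele_freqs(n_snps, pops, seed = seed + 1L)

  # frequency sharing mechanism: causal SNP common in shared pops, rare
  # elsewhere (below the MAF threshold)
  for (k in seq_len(n_eqtl)) {
    j <- causal_idx[k]
    freqs$freqs[j, shared[[k]]] <- stats::runif(length(shared[[k]]), 0.2, 0.8)
    if (sharing_mode == "freq") {
      off <- setdiff(pop_names, shared[[k]])
      if (length(off))
        freqs$freqs[j, off] <- stats::runif(length(off), 0, maf_threshold / 2)
    }
  }

  genotypes <- simulate_genotypes(freqs, pops, missing_rate = missing_rate,
                                  seed = seed + 2L, snp_info = snp_info)

  # causal genotypes for admixed pops come from individual-level pool
  # mixing; overwrite causal rows with draws from the forced frequencies
  # so the sharing mechanism holds exactly
  for (pp in pop_names) {
    sp <- pops[[match(pp, pop_names)]]
    if (is.null(sp$admixture_props)) next
    n <- sp$n_individuals
    for (k in seq_len(n_eqtl)) {
      j <- causal_idx[k]
      g <- stats::rbinom(n, 2, freqs$freqs[j, pp])
      if (missing_rate > 0) g[stats::runif(n) < missing_rate] <- NA_integer_
      genotypes[[pp]]$dosage[j, ] <- g
    }
  }

  planted <- data.frame(
    gene_id = annot$gene_id[egenes],
    snp_id = snp_info$snp_id[causal_idx],
    beta = beta,
    shared_in = vapply(shared, paste, "", collapse = ","),
    tss_distance = snp_pos[causal_idx] - annot$tss[egenes],
    stringsAsFactors = FALSE)

  # optional proxy clones with controlled correlation, for stepwise tests
  if (n_proxy > 0) {
    take <- seq_len(min(n_proxy, n_eqtl))
    for (k in take) {
      j <- causal_idx[k]
      newpos <- pmax(pmin(snp_pos[j] + 1000L, chrom_len), 1)
      prox_id <- sprintf("snpprox%02d", k)
      for (pp in pop_names) {
        d <- genotypes[[pp]]$dosage[j, ]
        if (proxy_r >= 1) pd <- d
        else {
          flip <- stats::runif(length(d)) > proxy_r
          pd <- d
          f <- mean(d, na.rm = TRUE) / 2
          pd[flip] <- stats::rbinom(sum(flip), 2, f)
        }
        genotypes[[pp]]$dosage <- rbind(genotypes[[pp]]$dosage,
                                        matrix(pd, 1, dimnames = list(prox_id)))
        genotypes[[pp]]$snp_info <- rbind(
          genotypes[[pp]]$snp_info,
          data.frame(snp_id = prox_id, chrom = "1", pos = newpos,
                     ref = "A", alt = "G", stringsAsFactors = FALSE))
      }
    }
  }

  sim <- simulate_expression(genotypes, annot, planted,
                             sharing_mode = if (sharing_mode == "freq") "all" else "beta",
                             seed = seed + 3L, ...)
  structure(list(genotypes = genotypes, expr = sim$expr, annot = annot,
                 truth = sim$truth, pops = pops, seed = seed),
            class = "eqtl_sim")
}

#' @export
print.eqtl_sim <- function(x, ...) {
  cat("Synthetic multi-population eQTL study (seed ", x$seed, ")\n", sep = "")
  cat("  populations: ", paste(names(x$genotypes), collapse = ", "), "\n", sep = "")
  cat("  SNPs: ", nrow(x$genotypes[[1]]$dosage),
      ";  probes: ", nrow(x$expr$values),
      ";  planted eQTLs: ", nrow(x$truth$planted), "\n", sep = "")
  invisible(x)
}
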