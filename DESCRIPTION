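Package: popeqtl
Title: Cross-Population cis-eQTL Mapping with Permutation Thresholds and
    Expression Differentiation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping cis-acting expression quantitative trait
    loci (eQTLs) across multiple human population samples and for
    quantifying population differentiation of gene expression.  Includes
    a Balding-Nichols multi-population genotype and expression simulator
    with planted eQTLs and hidden confounders; quantile and median
    normalization of replicate microarray hybridizations; genotype-PCA
    stratification correction; an ARD-regularized variational Bayesian
    factor analysis that produces residual ("reduced") expression
    profiles; Spearman rank-correlation cis association with per-gene
    permutation min-p thresholds, expected-count and replication false
    discovery rates, and stepwise conditional mapping of independent
    signals; the V_ST expression differentiation statistic with Hudson
    F_ST, Fisher-exact term enrichment and Fisher-combined probabilities;
    and cross-population eQTL sharing summaries (allelic direction
    concordance, homozygote fold-change, pi1 replication enrichment,
    TSS-distance stratification, multi-gene eQTL clusters, and a
    neighbour-joining parsimony sharing analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
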