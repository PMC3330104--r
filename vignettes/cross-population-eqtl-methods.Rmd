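---
title: "Methods: cross-population cis-eQTL mapping with popeqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-population cis-eQTL mapping with popeqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popeqtl)
```

This vignette is the package's own account of its models, the choices
behind its defaults, and what its synthetic benchmarks do and do not
demonstrate about real data.

## The association model and its calibration

The elementary statistic is the Spearman rank correlation between
genotype dosage and expression, chosen for its robustness to the heavy
tails and occasional outliers of microarray intensities. Mid-ranks are
used for ties (dosage vectors have at most three distinct values), and
the two-sided p-value comes from the t-approximation on $n-2$ degrees
of freedom. Two properties matter here:

* The t-approximation is not exact for small $n$ or heavy ties, but
  every gene-level significance decision is made against a *permutation*
  distribution of the same statistic, so only monotonicity of the
  p-value in $|\rho|$ is actually load-bearing.
* With a three-level dosage, the mid-rank correlation has a tie ceiling
  below 1: for a balanced Hardy–Weinberg split ($n = 60$, MAF 0.5) a
  perfectly separating effect reaches $\rho \approx 0.92$, and skewed
  allele frequencies push the ceiling lower. Tests of "near-perfect"
  association are therefore formulated on balanced genotype classes.

Multiple testing across the *cis* window (closed interval $\pm$1 Mb
around the TSS, signed distance = SNP position − TSS irrespective of
strand) is handled per gene: the expression phenotype is permuted
across individuals, all *cis* SNPs are retested, the minimum nominal p
is recorded, and the per-gene threshold is the $\lfloor \alpha
n_\mathrm{perm} \rfloor$-th order statistic of the minima (strict order
statistic, no interpolation — the conservative reading when the
quantile falls between order statistics). Significance requires the
observed minimum p to fall *strictly below* the threshold, so a tie at
the boundary is not significant. `n_perms` defaults to 10,000 and must
be at least $1/\alpha$, otherwise the quantile is unresolvable and the
function refuses to run. Permutations are drawn per gene from one
seeded stream; `share_permutations = TRUE` reuses one permutation
matrix across genes, which is faster and preserves cross-gene
correlation under the null, at the cost of correlated thresholds.

Missing genotypes are dropped pairwise, and the permutation engine
re-ranks the permuted phenotype within each SNP's non-missing subset,
so the null distribution respects the per-SNP sample size exactly. MAF
(> 5%) and missingness (< 20%) filters are computed on non-missing
calls only.

Tie-breaking for the "most significant SNP" of a gene is smallest p,
then smallest $|$distance to TSS$|$, then lexicographic SNP id — an
arbitrary but deterministic rule that makes results reproducible.

## False discovery rates

Two estimators are reported. The expected-count form divides the number
of genes expected to pass their threshold by chance (genes tested
$\times \alpha$) by the number observed to pass. The replication form
asks, for each significant gene in a discovery population, whether its
best SNP–probe pair reaches nominal $p < 0.005$ with the same $\rho$
sign in at least one other population, and reports
$1 - \mathrm{replicated}/\mathrm{total}$. Genes whose best SNP is
untyped or filtered in every other population count as non-replicated
(the conservative choice; they are tallied separately so the user can
judge), because excluding them from the denominator would make the
estimate depend on panel overlap.

## Normalization and confounder correction

The raw data model is two replicate hybridizations per individual on a
log2 scale. Within each individual, replicates are quantile-normalized
to the mean of their order statistics and then averaged to one column —
averaging is the natural collapse because every downstream analysis is
per-individual. Across individuals, each column is shifted so its
median equals the grand median of column medians. Both steps together
are idempotent.

Population stratification (and cryptic relatedness) is corrected per
population by residualizing each probe on the top ten axes of an
intra-population PCA of the standardized dosage matrix (missing dosages
mean-imputed per SNP). Ten axes is the conventional choice; collinear
axes are dropped by QR rank detection.

The "reduced" dataset is the residual of a variational Bayesian factor
analysis with automatic relevance determination (ARD): per sample,
$y = W s + \varepsilon$ with standard-normal hidden factors, per-gene
noise precisions, and a per-factor Gamma prior on weight precisions
that switches superfluous factors off. Known covariates (a gender
indicator by default) enter as factors with fixed scores. The fit runs
separately per population; population indicators would be constant
within such a run, so they are only meaningful in the optional pooled
mode (`known_covariates`), and the per-population default models gender
only. Convergence is declared when the expected data log-likelihood
improves by less than $10^{-6}$ relatively, with a 1000-iteration cap
(non-convergence returns the best iterate and says so).

The ARD prior defaults to shape 21,800 and rate 0.022 — the shape is
interpreted as scaled with the number of probes in the model, so at $G$
probes the effective shape is $21{,}800 \cdot G / 21{,}800 = G$. This
parameterization (Gamma shape/rate on weight precisions) reproduces the
intended regularization strength to order of magnitude rather than
bit-exactly; both numbers and the scaling switch are exposed. The
default of 32 hidden factors follows the same convention as the panel
the defaults emulate; at the reduced synthetic scales of the examples
8–10 factors behave identically because ARD prunes the rest.

## V_ST, F_ST, and term enrichment

$V_{ST} = (V_T - V_S)/V_T$ with $V_S$ the sample-size-weighted average
within-population variance. Variances use the denominator-$n$
(maximum-likelihood) convention: with the paper-standard weighting this
makes two identical samples give exactly $V_{ST} = 0$, whereas the
unbiased convention can go negative. Negative values (possible under
the switchable unbiased convention) are clamped to 0, honoring the
statistic's [0, 1] range; a probe with zero pooled variance is defined
as 0. The summary reports the count of probes with $V_{ST} > 0.2$ per
population pair, the conventional "high differentiation" cutoff.

F$_{ST}$ uses the Hudson estimator — chosen for its low sample-size
bias; with haploid sample sizes supplied, the numerator gets the
finite-sample correction — combined as a ratio of averages within
10,000-SNP windows and averaged across windows. Under Balding–Nichols
drift with coefficient $F$ in two populations from a shared ancestral
pool, the ratio-of-averages estimator converges to $F$ itself
(numerator $2F\,\overline{p(1-p)}$, denominator $2\,\overline{p(1-p)}$);
the test suite freezes the value 0.100 for $F = 0.1$, computed with a
$10^6$-draw Monte-Carlo oracle before the implementation was trusted.

"Top differentiated probes" are operationalized as the top 5% ranked by
$V_{ST}$ within each population pair (ties broken by probe id), since
no separate significance test for $V_{ST}$ is defined. Term enrichment
is a one-sided Fisher exact test of the 2×2 table {in top set} ×
{annotated to term} against the universe of eligible probes; the
gene→term map is an arbitrary user-supplied list (tests use synthetic
maps — no live ontology download). Per-pair p-values are combined with
Fisher's method ($-2\sum\ln p$ against $\chi^2_{2k}$), and
population-specific terms are those whose combined p over the focal
pairs is significant while the combination over non-focal pairs is not.

## Sharing statistics

Alleles are harmonized before any cross-population comparison: the
dosage allele is the alphabetically smaller allele string everywhere,
and SNPs with mismatched allele pairs across files are dropped with a
log entry. Direction concordance is the same-sign fraction of $\rho$
among SNP–probe pairs significant in both populations (exact zeros
excluded). The effect-size measure is the absolute difference of median
log2 expression between the two homozygote classes, requiring at least
two individuals per class — medians of singletons are noise.
$\pi_1 = 1 - \pi_0$ with $\pi_0 = \#\{p > \lambda\}/((1-\lambda)m)$ at
$\lambda = 0.5$, clamped to [0, 1].

The parsimony analysis builds a neighbour-joining tree from the
pairwise F$_{ST}$ matrix, midpoint-roots it so clade queries are well
defined, and assigns each gene's eQTL (one association per gene, chosen
at random with the run seed) to the smallest clade covering its
population set — the discovery population at $\alpha = 0.01$ plus every
population passing a recomputed lenient permutation threshold at
$\alpha = 0.1$; a set no clade covers goes to the root. The
"smallest-covering-clade" rule is one reading of node-respecting
sharing and is documented as such. Enrichment is declared when a node's
observed count exceeds the 95th percentile over 100 randomizations,
either permuting the tree's leaf labels (conservative) or resampling
each eQTL's population set (the second mode catches within-subtree
excess that label permutation cannot).

## The synthetic study generator

The generator's defaults emulate an eight-population lymphoblastoid
panel: CEU 109, CHB 80, GIH 82, JPT 82, LWK 82, MEX 45, MKK 138, YRI
108 individuals, grouped into African, European/South-Asian, and
East-Asian pools with two-level Balding–Nichols drift (pool
coefficients 0.10; population coefficients 0.008–0.03) so that the
F$_{ST}$ hierarchy — within-continent pairs near 0.01, cross-continent
near 0.1 — and hence a meaningful NJ tree emerge. MEX is admixed
between the European and East-Asian pools (0.6/0.4) and MKK lightly
with the European pool (0.85/0.15); each admixed individual draws fixed
Dirichlet mixing weights (concentration 10 × the proportions), giving
genotype PCA a real admixture axis to find. These drift and admixture
values are the package's choice of a realistic human-panel
configuration and are not revisited per analysis.

Planted *cis*-eQTLs draw a signed TSS distance from a double
exponential (scale 50 kb), an effect magnitude from 0.8–1.5 log2 units
per allele copy, and by default attenuate the effect by
$0.5^{|d|/20\,\mathrm{kb}}$ — an exponential decay with a 20 kb
half-distance that reproduces the qualitative tightening of strongly
shared eQTLs around the TSS without asserting a quantitative law.
Non-replication across populations is simulated by default through
allele frequencies (the causal SNP is driven below the 5% MAF threshold
outside the eQTL's sharing set), matching the dominant mechanism in
real panels; a switch instead zeroes the effect outside the set. Hidden
global confounders (8 factors, loading sd 0.6 by default), individual
noise (sd 0.5), replicate noise (sd 0.3), 1% genotype missingness, and
SNP-in-probe hybridization artifacts (6.4% of probes, −0.5 per allele
copy of the overlapping SNP) complete the raw data model.

What the generator does *not* emulate: linkage disequilibrium beyond an
optional proxy-SNP clone with controlled correlation (used by the
stepwise tests), sequence-level processes, sex chromosomes, batch
structure with a known design, or the age/passage history of real cell
lines — the hidden-factor term is a generic stand-in for all global
non-genetic variation. Consequently, passing benchmarks demonstrates
the statistical machinery (calibration, recovery, direction
consistency, power ordering), not robustness to the full artifact
spectrum of a real array study.

## Benchmark scales and numerical choices

The test suite and the acceptance script run at deliberately reduced
scales chosen to exercise every code path while keeping a laptop-class
runtime: null calibration uses 200 genes × 1,000 permutations in one
population of 80; recovery uses 50 planted eQTLs shared across three
populations of 80 with $|\beta| \ge 1$ and noise sd 0.25; the power
comparison uses 150 genes with 60 moderate effects under six strong
confounders; stepwise recovery uses 50 replicates of two independent
SNPs at $n = 100$. The permutation count of 1,000 resolves the 0.01
tail with 10 order statistics, which is the minimum the threshold rule
accepts without interpolation.

Numerical edge cases are pinned down explicitly: $|\rho| = 1$ maps to
the smallest positive double rather than p = 0; zero-variance dosage or
expression vectors are skipped and logged rather than producing NaN;
Fisher combination clamps p = 0 inputs with a warning; $V_{ST}$ with
zero total variance is 0; the factor analysis returns its best iterate
with a flag when the iteration cap is hit; and permutation thresholds
refuse to run when `n_perms` cannot resolve the requested tail.
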