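---
title: "Methods: stratified cell-type TWAS discovery and prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified cell-type TWAS discovery and prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stratwas` implements a discovery-and-prioritization pipeline for genes
whose association with a binary disease phenotype depends on APOE\*4
carrier status and acts through cell-type-specific gene expression.  This
vignette documents the statistical model behind each stage, the defaults
and why they were chosen, the design decisions that were genuinely open,
and what the synthetic-data generator does and does not emulate.

## 1. Discovery model

### Stratified GWAS and meta-analysis

Within each stratum, disease is regressed on per-variant allele dosage plus
covariates by maximum-likelihood logistic regression (Wald z, two-sided
normal p).  We deliberately use plain logistic ML rather than a
mixed-model scan: the synthetic cohorts contain no relatedness or
population structure, so the mixed model's random effect would be
estimating a zero component.  Monomorphic variants, non-converged fits and
quasi-separated fits (|beta| > 15 or SE > 100) are flagged and their
statistics set missing rather than reported.

Cohorts are combined per stratum by inverse-variance fixed-effects
meta-analysis after allele harmonization to an anchor cohort's (A1, A2)
orientation; swapped alleles flip the sign of beta and z and complement the
frequency, strand-ambiguous A/T and C/G palindromes are dropped, and
variants must be present in the anchor set with genotyping rate ≥ 0.9 in
every cohort.  Effective sample sizes use `N_eff = 4 N v (1 − v)`
(`v` the case fraction), with proxy-phenotype cohorts divided by 4 *before*
any summation across cohorts.  Written without the total-N factor the
formula could not yield realistic effective sample sizes, so the standard
total-N form is used throughout.  Cross-ancestry combination of TWAS
z-scores uses the sample-size-weighted (Stouffer) form
`Z = Σ√n_i z_i / √Σn_i`, which is the appropriate scheme when per-cohort
effect scales differ.

### Expression weights

For each gene, cis variants within ±1 Mb of the TSS are screened for any
genetic contribution to expression with a permutation test: the statistic
is the maximum squared marginal correlation across cis variants, and the p
is `(1 + #{permutations ≥ observed}) / (B + 1)` with B = 1000 by default.
This replaces a variance-component (REML) heritability test with an exact,
assumption-light screen whose null distribution is correct by construction;
its smallest attainable p (1/(B+1)) is far below the 0.05 gate.

Genes passing the screen get expression weights from the better of two
candidate models under k-fold cross-validation (k = 5): the single best
marginal eQTL ("top1") and ridge regression over all cis variants with
penalty chosen by CV.  This preserves the screen-then-fit-then-test
architecture of weight-based TWAS while keeping every component auditable;
sparse-prior models add nothing detectable at the cis dimensionalities the
package targets (tens of variants).  Weights are on the
standardized-genotype scale (dosages mean-imputed, unit variance).  Genes
where neither candidate beats the intercept-only model out-of-fold
(CV R² ≤ 0) are dropped with a logged reason.

### TWAS statistic

For weights **w**, stratum GWAS z-scores **z** and LD correlation matrix
**R** over the same variants (all in the anchor allele orientation),

`z_TWAS = wᵀz / √(wᵀRw)`.

**R** is taken from the same reference genotypes used to fit weights
(in-sample LD), the standard single-cohort choice.  The quadratic form is
floored at ε = 1e-8; degenerate weight/LD combinations yield a missing
result rather than an inflated statistic.  The statistic is invariant to
simultaneous variant reordering and to allele flips applied consistently to
**w**, **z** and **R** (both properties are tested).

## 2. Stratum-heterogeneity filtering

FDR is Benjamini–Hochberg, computed within stratum and pooled across all
(cell type, gene) pairs — the stricter and simpler reading when the
per-cell-type universe is not stated.  A pair is biased to stratum *s* when
`q_s < 0.05` and, in the other stratum, either `p > 0.05` with the same
effect direction, or an opposite effect direction.  The opposite-direction
clause is applied literally — it does not additionally require the other
stratum to be non-significant (a gene can flip sign and be significant in
both strata; such a pair is genuinely stratum-heterogeneous).  A zero z in
the other stratum counts as same-direction (tie), and missing results make
the flag false.

Loci are formed by single-linkage clustering of significant genes' TSS at
1 Mb reach on each chromosome (TSS-to-TSS linkage was preferred over fixed
±500 kb windows because the reach describes gene-to-gene proximity).  The
locus rule: identify the most significant pair (smallest p over both
strata; ties broken by smaller q, then lexicographic gene id, logged).  If
that top pair is not itself stratum-biased in the stratum of its best p,
*every* pair at the locus is discarded; otherwise pairs that individually
pass the criterion are retained.  The rationale is that an unbiased top
signal indicates the locus association is not stratum-specific, and weaker
co-located signals are likely LD shadows of it.

Cross-ancestry consistency requires the meta-analyzed p in the pair's own
stratum to *strictly* improve over the primary-ancestry p while the
opposite stratum's meta p stays above 0.05.

## 3. Prioritization layers

**Colocalization.**  Per-variant Wakefield log approximate Bayes factors,
`lABF = ½log(V/(V+W)) + (z²/2)·W/(V+W)`, with prior effect SDs 0.2
(case-control log-odds) and 0.15 (quantitative eQTL) — the conventional
values for these trait types.  Hypothesis sums (H0–H4) are accumulated
entirely in log space (log-sum-exp), which keeps the enumeration exact for
|z| well beyond 40.  Two prior schemes are evaluated: default
(p1 = p2 = 1e-4, p12 = 1e-5) and an "adjusted" scheme with p12 = 1e-4
reflecting that tested pairs were already selected for association with
both traits; the exact adjusted values used in prior work are not
published, so the ten-fold p12 increase is the package's own documented
choice and is configurable.  The best PP4 across schemes is tiered at
≥ 0.4 (suggestive) and ≥ 0.7 (strong).  The "top colocalizing variant" is
the one with the largest share of the shared-variant hypothesis,
`exp(lABF1 + lABF2)` normalized, in the winning scheme.  Multi-causal
(fine-mapping-based) colocalization is out of scope; the best-of-schemes
rule operates over the two ABF schemes only.

**SMR / HEIDI.**  With the top cis eQTL as instrument,
`T_SMR = z_G²z_E²/(z_G²+z_E²)` is chi-square(1) and
`b_xy = b_GWAS / b_eQTL`.  HEIDI compares the Wald ratio at surrounding
SNPs with the top SNP's ratio: eligible SNPs have eQTL p < 1.57e-3
(|z| > 3.16) and r² with the top instrument in [0.05, 0.9], at most 20
kept — the cited method's conventions, adopted because no alternatives are
stated.  The covariance of the ratio differences is obtained by the delta
method from the LD matrix, and the p-value of the sum of squared
standardized differences is computed by seeded Monte-Carlo from the implied
multivariate normal (10⁴ draws) rather than an analytic quadratic-form
approximation: simpler, verifiable, and accurate at these dimensions.
Fewer than 3 eligible SNPs leaves HEIDI missing; by default such pairs do
*not* count as SMR-supported (configurable waiver).  SMR support =
`P_FDR < 0.05` (BH pooled across tested pairs) and `P_HEIDI > 0.05`.

**Open chromatin.**  The top colocalizing variant and all panel variants
with r² ≥ 0.8 are intersected with peaks of the pair's own cell type.
BED intervals are 0-based half-open; a 1-based variant position p overlaps
[start, end) iff `start < p ≤ end` — the boundary cases are tested
explicitly.  The threshold is applied inclusively so that a perfect proxy
(r² = 1) is always included.

**Differential expression.**  Pseudobulk counts are TMM-normalized; the
implementation follows the reference TMM algorithm exactly (f75 reference
selection, 30%/5% two-sided trims on M and A, inverse asymptotic-variance
weighting, geometric-mean-1 rescaling) and is cross-checked against
`edgeR::calcNormFactors` to 1e-6 in the test suite.  Each gene's log2-CPM
(pseudocount 0.5, TMM-scaled library sizes) is regressed on the phenotype
plus sex, post-mortem interval, age at death, APOE\*2/\*4 dosage and batch
by OLS with t-tests.  Empirical-Bayes variance moderation is deliberately
omitted: plain OLS keeps the per-gene statistic exactly
oracle-checkable, and at the package's sample sizes moderation mainly
affects ranking, not the 0.05 support gate.  Within a stratum, constant
covariates (e.g. APOE\*4 dosage among non-carriers) are dropped with a log
message.  Non-stratified support is p < 0.05; stratified support
additionally requires an opposite direction or |logFC| ≥ 1.5× the other
stratum's.  The 1.5 rule is multiplicative ("1.5 larger compared to" a
magnitude); an additive reading would be scale-dependent and nearly
unattainable for pseudobulk effect sizes.  Two phenotypes are analyzed
(binary status and a quantitative pathology score); support for any one
phenotype suffices (configurable any/all).

**Evidence tiers.**  Six layers (cross-ancestry, colocalization, SMR,
open chromatin, non-stratified DE, stratified DE); "at least half" = ≥ 3,
"more than half" = ≥ 4.  Missing layers count as unsupported but are
recorded as missing, not failed.

**Drug targets.**  Genes at tier ≥ 4 are intersected with a druggable-gene
list (case-insensitive symbol match), expanded by first-degree interaction
neighbors restricted to druggable genes (seeds always retained; single-hop
expansion — deeper traversal is left configurable), and tested for
compound-set over-representation with a one-sided hypergeometric test, BH
across all sets.  Reported compounds need q < 0.05 and ≥ 2 *prioritized*
genes in the overlap (the filter counts seed genes, not expanded neighbors,
by default).  The universe is all genes of the annotation intersected with
the GMT database.

## 4. The synthetic-data generator

The generator exists so the pipeline can be exercised end-to-end with known
ground truth; its defaults are the study conditions the package's own tests
run under.

*Genotypes* follow a Gaussian-copula threshold model: per locus, two latent
haplotype vectors with AR(1) correlation `ld_rho` are thresholded at
`qnorm(maf)` and summed.  This gives exact control of allele frequency and
a realistic monotone LD decay, at the price of a stylized correlation
structure (no haplotype blocks, no recombination hotspots).  Ancestries
share variants and alleles but draw independent frequencies; they differ in
no other way, which is sufficient to exercise the cross-ancestry
consistency rule but is not an admixture model.

*Expression* of each cis gene is a genotype score rescaled so its genetic
variance is `h2_cis`, plus Gaussian noise; pseudobulk counts are negative
binomial with mean `exp(library offset + gene baseline + latent)`.
Background genes (pure noise) pad each cell type's matrix for
normalization, DE nulls and the enrichment universe.  Each gene in a locus
is regulated by its own contiguous block of the locus's variants: genes
that share a locus therefore have (near-)independent cis architectures
(adjacent-block correlation ~`ld_rho`^8 under the defaults), so the
generator's "null genes" are genuinely null for disease.  Shared-LD locus
behaviour — where co-located genes *do* tag one signal — is covered by
constructed-table tests of the locus-exclusion rule instead.

*Disease* is Bernoulli with log-odds
`intercept + Σ_g β_g · latent_g · 1[subject ∈ causal stratum of g]`.
Because causality runs expression → disease, case-control differences in
expression arise in the reference cohort by conditioning, which is what
gives the DE layers genuine (if modest) signal.

Default conditions, chosen once: 20 loci × 25 variants, `ld_rho = 0.6`,
MAF 0.05–0.5; 60 cis genes over the seven canonical brain cell types
(astrocytes, excitatory/inhibitory neurons, microglia, oligodendrocytes,
OPCs, endothelial), 10 of them causal in exactly one stratum
(alternating), `h2_cis = 0.25` and `β = 0.4` log-odds per SD of expression
— about 1.2% of liability variance, a strong but realistic
cis-mediated effect; 6000 subjects per stratum in the primary case-control
cohort, a half-size proxy cohort (effective sample size divided by 4) and
a quarter-size secondary-ancestry cohort; a 424-subject expression
reference with 50% carriers; NB dispersion 0.2; 500 bp peaks centered on
eQTL variants.  The proxy cohort has three variants with ~12% missing
dosages so the genotyping-rate filter has something to remove.  Compound
sets in the GMT are seeded with each stratum's causal genes plus random
fillers, alongside decoy sets; the druggable list and interaction edges are
constructed so causal genes have druggable neighbors.

What passing tests on these data do **not** show: robustness to realistic
human LD panels, imputation error, relatedness, population stratification,
cell-type misassignment, or compositional effects in pseudobulk — none of
which the generator emulates.

## 5. Numerical and reproducibility choices

* All randomness derives from one config seed via labeled child streams
  (`derive_seed`), so a fixed seed reproduces the bundle and every analysis
  byte-identically; the caller's RNG state is always restored.
* Permutation and Monte-Carlo p-values use the `(1 + #{≥}) / (B + 1)`
  form, so they are never zero.
* Colocalization sums, including the H3 difference term, are computed in
  log space; the one-variant H3 degeneracy returns probability zero with a
  warning.
* A near-singular HEIDI covariance is ridge-regularized by 1e-8 on the
  diagonal with a warning.
* P = 0 in summary-statistic files is clamped to the smallest positive
  double on load, with a warning; invalid SE or out-of-range P are hard
  schema errors naming the file and line.
* Ties for a locus's top pair are broken by smaller q, then gene id, and
  logged.

## 6. Problem sizes used by the test suite

The suite runs the full synthetic study at its default scale (6000 per
stratum; ~30 s), 200-replicate null-calibration batteries at reduced sizes
(n = 300 GWAS; n = 50, B = 299 heritability screen; 200-gene DE;
15-SNP HEIDI with 2000 draws), and 50-replicate discrimination runs at
n = 20 000 with 1% trait variance for colocalization and SMR.  These sizes
were chosen so each property is measured with useful precision while the
whole suite stays interactive.

## 7. Known limitations

* The cTWAS stage tests genes marginally; overlapping genes at one locus
  are handled by the exclusion rule, not by conditional or fine-mapped
  joint modeling.
* Colocalization assumes at most one causal variant per trait per locus.
* The HEIDI delta-method covariance is first-order; with very weak eQTL
  instruments it becomes anti-conservative (mitigated by the |z| > 3.16
  eligibility gate).
* Proxy-phenotype cohorts are emulated only through the effective-sample-
  size division; no phenotype misclassification model is included.
* The interaction-network expansion is a single hop over a supplied edge
  list; no live database access.
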