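#' Summary-data Mendelian randomization test for one gene
#'
#' Uses the top cis eQTL (largest `|z_eqtl|`) as instrument:
#' `T_SMR = z_gwas^2 z_eqtl^2 / (z_gwas^2 + z_eqtl^2)`, chi-square(1) p,
#' and the Wald ratio `b_xy = b_gwas / b_eqtl` as the effect of expression on
#' disease.
#'
#' @param b_gwas,se_gwas GWAS effect and SE at the instrument.
#' @param b_eqtl,se_eqtl eQTL effect and SE at the instrument.
#' @return list `b_xy, t_smr, p_smr, z_gwas, z_eqtl`; both z zero yields all
#'   missing.
#' @export
smr_test <- function(b_gwas, se_gwas, b_eqtl, se_eqtl) {
  zg <- b_gwas / se_gwas
  ze <- b_eqtl / se_eqtl
  if (!is.finite(zg) || !is.finite(ze) || (zg == 0 && ze == 0))
    return(list(b_xy = NA_real_, t_smr = NA_real_, p_smr = NA_real_,
                z_gwas = zg, z_eqtl = ze))
  t <- zg^2 * ze^2 / (zg^2 + ze^2)
  list(b_xy = b_gwas / b_eqtl, t_smr = t,
       p_smr = pchisq(t, df = 1, lower.tail = FALSE),
       z_gwas = zg, z_eqtl = ze)
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant from linkage of distinct
#' variants by comparing the Wald ratio `b_xy` at cis SNPs in LD with the top
#' eQTL against the top SNP's ratio.  Eligible SNPs have eQTL
#' `p < eqtl_p_max` and `r^2` with the top instrument inside
#' `[r2_lo, r2_hi]`; up to `max_snps` strongest are kept.  Differences
#' `d_i = b_xy(i) - b_xy(top)` get a delta-method covariance from the LD
#' matrix, and the p-value of `sum((d_i/sd_i)^2)` is computed by seeded
#' Monte-Carlo from the implied multivariate normal.
#'
#' @param gwas,eqtl data.frames with `variant, beta, se, z` over the same cis
#'   variants (aligned orientation).
#' @param R LD correlation matrix (dimnames = variant keys).
#' @param r2_lo,r2_hi eligible LD window with the top instrument.
#' @param max_snps maximum SNPs used besides the top.
#' @param eqtl_p_max eligibility threshold on the eQTL p (default 1.57e-3,
#'   i.e. |z| > 3.16).
#' @param n_draws Monte-Carlo draws (seed the RNG for reproducibility).
#' @return list `p_heidi, n_snps, top_variant`; fewer than 3 eligible SNPs
#'   gives `p_heidi = NA` with a message.
#' @export
heidi_test <- function(gwas, eqtl, R, r2_lo = 0.05, r2_hi = 0.9,
                       max_snps = 20, eqtl_p_max = 1.57e-3, n_draws = 1e4) {
  stopifnot(identical(gwas$variant, eqtl$variant))
  ze <- eqtl$beta / eqtl$se
  top <- which.max(abs(ze))
  top_v <- gwas$variant[top]
  r2 <- R[top_v, gwas$variant]^2
  pe <- 2 * pnorm(-abs(ze))
  elig <- which(gwas$variant != top_v & pe < eqtl_p_max &
                  r2 >= r2_lo & r2 <= r2_hi &
                  is.finite(gwas$se) & gwas$se > 0)
  if (length(elig) < 3L) {
    message(sprintf("heidi_test: only %d eligible SNPs (<3); p_heidi missing",
                    length(elig)))
    return(list(p_heidi = NA_real_, n_snps = length(elig), top_variant = top_v))
  }
  if (length(elig) > max_snps)
    elig <- elig[order(-abs(ze[elig]))][seq_len(max_snps)]
  sel <- c(top, elig)
  bG <- gwas$beta[sel]; sG <- gwas$se[sel]
  bE <- eqtl$beta[sel]; sE <- eqtl$se[sel]
  r <- R[gwas$variant[sel], gwas$variant[sel]]
  ## delta-method covariance of the Wald ratios (traits independent):
  ## cov(bxy_i, bxy_j) = r_ij sG_i sG_j / (bE_i bE_j)
  ##                   + bG_i bG_j r_ij sE_i sE_j / (bE_i^2 bE_j^2)
  C <- r * outer(sG, sG) / outer(bE, bE) +
    outer(bG, bG) * r * outer(sE, sE) / outer(bE^2, bE^2)
  k <- length(sel)
  ## d_i = bxy_i - bxy_top (top is index 1)
  A <- cbind(-1, diag(k - 1L))
  Cd <- A %*% C %*% t(A)
  sd_d <- sqrt(pmax(diag(Cd), 1e-300))
  d <- (bG / bE)[-1] - bG[1] / bE[1]
  T_obs <- sum((d / sd_d)^2)
  draws <- tryCatch(MASS::mvrnorm(n_draws, mu = rep(0, k - 1L), Sigma = Cd),
                    error = function(e) {
                      warnf("heidi_test: covariance ridge-regularized")
                      MASS::mvrnorm(n_draws, mu = rep(0, k - 1L),
                                    Sigma = Cd + diag(1e-8, k - 1L))
                    })
  T_null <- rowSums(sweep(draws, 2, sd_d, "/")^2)
  p <- (1 + sum(T_null >= T_obs)) / (n_draws + 1)
  list(p_heidi = p, n_snps = k - 1L, top_variant = top_v)
}

#' SMR support rule
#'
#' A pair has SMR support when its FDR-adjusted SMR p (BH across all tested
#' pairs) is below `alpha` and the HEIDI test does not reject linkage
#' (`p_heidi > alpha`).  Pairs with missing HEIDI (too few eligible SNPs)
#' count as supported only when `allow_missing_heidi = TRUE`.
#'
#' @param p_smr_fdr FDR-adjusted SMR p-values.
#' @param p_heidi HEIDI p-values (`NA` allowed).
#' @param alpha level (default 0.05).
#' @param allow_missing_heidi waiver for missing HEIDI (default FALSE).
#' @return logical vector.
#' @export
smr_support <- function(p_smr_fdr, p_heidi, alpha = 0.05,
                        allow_missing_heidi = FALSE) {
  heidi_ok <- ifelse(is.na(p_heidi), allow_missing_heidi, p_heidi > alpha)
  ok <- p_smr_fdr < alpha & heidi_ok
  ok[is.na(p_smr_fdr)] <- FALSE
  ok
}
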