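#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample TMM factors for a genes x samples count matrix,
#' following the standard algorithm: the reference sample is the one whose
#' 75th percentile of count/library-size is closest to the mean across
#' samples; per sample, gene-wise log2 ratios (M) and mean log2 abundances
#' (A) against the reference are trimmed (30% of each M tail, 5% of each A
#' tail) and the factor is two to the power of the weighted mean of the
#' remaining M values, weighted by inverse asymptotic binomial variance.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts nonnegative integer matrix, genes in rows, samples in
#'   columns.
#' @param logratio_trim,abund_trim tail-trim fractions for M and A.
#' @return numeric vector of normalization factors (one per sample).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abund_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stopf("tmm_factors: need at least 2 samples")
  if (any(counts < 0)) stopf("tmm_factors: negative counts")
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero))
    stopf("tmm_factors: sample(s) with all-zero counts: %s",
          paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) quantile(counts[, j] / lib[j], 0.75), 0)
  ref <- if (median(f75) < 1e-20) which.max(colSums(sqrt(counts)))
         else which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, abund_trim)
  }, 0)
  fac / exp(mean(log(fac)))
}

# TMM factor of one sample against the reference sample.
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abund_trim) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * abund_trim) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' log2 counts-per-million with TMM-scaled library sizes
#'
#' @param counts genes x samples count matrix.
#' @param factors TMM normalization factors (default: computed here).
#' @return genes x samples matrix of `log2((count + 0.5) / (lib * f + 1) * 1e6)`.
#' @export
cpm_log2 <- function(counts, factors = tmm_factors(counts)) {
  lib <- colSums(counts) * factors
  log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)
}

#' Per-gene differential expression by ordinary least squares
#'
#' Regresses each gene's log2-CPM on the phenotype plus covariates and
#' reports the phenotype coefficient (log2 fold change per unit) with its
#' t-test p-value.  Constant covariate columns (e.g. APOE*4 dosage inside a
#' stratum) are dropped with a message; genuinely collinear designs are an
#' error naming the offending columns.
#'
#' @param logcpm genes x samples matrix (see [cpm_log2()]).
#' @param phenotype binary (0/1) or quantitative vector, one per sample.
#' @param covariates data.frame of adjustment covariates.
#' @return data.frame `gene, logFC, t, p, n_samples`.
#' @export
fit_de <- function(logcpm, phenotype, covariates) {
  stopifnot(ncol(logcpm) == length(phenotype))
  cov_use <- covariates
  const <- vapply(cov_use, function(col) length(unique(col)) <= 1L, TRUE)
  if (any(const)) {
    message("fit_de: dropping constant covariate(s): ",
            paste(names(cov_use)[const], collapse = ", "))
    cov_use <- cov_use[, !const, drop = FALSE]
  }
  df <- data.frame(..pheno = phenotype, cov_use)
  X <- model.matrix(~ ., data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("fit_de: rank-deficient design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  n <- nrow(X)
  dfree <- n - ncol(X)
  if (dfree < 2L) stopf("fit_de: not enough residual degrees of freedom")
  coefs <- qr.coef(qx, t(logcpm))
  resid <- qr.resid(qx, t(logcpm))
  sigma2 <- colSums(resid^2) / dfree
  XtXinv <- chol2inv(qr.R(qx))
  j <- match("..pheno", colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  b <- coefs[j, ]
  tval <- b / se
  data.frame(gene = rownames(logcpm), logFC = unname(b), t = unname(tval),
             p = unname(2 * stats::pt(-abs(tval), dfree)),
             n_samples = n, stringsAsFactors = FALSE)
}

#' Differential-expression support rules
#'
#' Non-stratified scope: support is `p < alpha` for the pair's gene and cell
#' type.  Stratified scope: support requires `p < alpha` in the pair's
#' stratum and either an opposite effect direction in the other stratum or an
#' absolute log-fold change at least 1.5 times larger
#' (`|logFC_s| >= 1.5 |logFC_other|`).
#'
#' @param p_s nominal p in the scope under test.
#' @param logfc_s,logfc_other log-fold changes in the two strata (stratified
#'   scope only; leave `logfc_other = NULL` for non-stratified support).
#' @param alpha level (default 0.05).
#' @param fc_ratio multiplicative threshold (default 1.5).
#' @return logical (vectorized); missing other-stratum values give `FALSE`.
#' @export
deg_support <- function(p_s, logfc_s = NULL, logfc_other = NULL,
                        alpha = 0.05, fc_ratio = 1.5) {
  if (is.null(logfc_other)) {
    ok <- p_s < alpha
    ok[is.na(p_s)] <- FALSE
    return(ok)
  }
  opposite <- sign(logfc_s) != sign(logfc_other)
  larger <- abs(logfc_s) >= fc_ratio * abs(logfc_other)
  ok <- p_s < alpha & (opposite | larger)
  ok[is.na(p_s) | is.na(logfc_s) | is.na(logfc_other)] <- FALSE
  ok
}
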