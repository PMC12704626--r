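#' Per-stratum logistic genome-wide association scan
#'
#' Fits, within each APOE*4 stratum, a per-variant logistic regression of
#' disease status on allele dosage plus covariates (maximum likelihood, Wald
#' z and two-sided normal p).  Monomorphic variants are flagged and their
#' statistics set missing; the same applies to non-converged or separated
#' fits.  Missing dosages are dropped per variant and recorded as the
#' variant's genotyping rate.
#'
#' @param genotypes n x variants dosage matrix (columns named by variant
#'   key; `NA` allowed).
#' @param variants variant table (`variant, chrom, pos, a1, a2`).
#' @param labels 0/1 disease status.
#' @param covariates data.frame of adjustment covariates (numeric or
#'   factor/character; character columns are expanded via model.matrix).
#' @param stratum character vector per subject, `"carrier"` /
#'   `"non-carrier"`.
#' @param is_proxy whether this cohort is a proxy-phenotype GWAS (recorded in
#'   the output and used for effective-sample-size down-weighting).
#' @return named list (one element per stratum) of summary-statistic
#'   data.frames with columns `variant, chrom, pos, a1, a2, freq_a1, beta,
#'   se, z, p, n_cases, n_controls, geno_rate, is_proxy, note`.
#' @export
run_stratified_gwas <- function(genotypes, variants, labels, covariates,
                                stratum, is_proxy = FALSE) {
  stopifnot(nrow(genotypes) == length(labels),
            length(stratum) == length(labels))
  strata <- c("carrier", "non-carrier")
  out <- lapply(strata, function(s) {
    idx <- which(stratum == s)
    y <- labels[idx]
    if (sum(y == 1) < 2 || sum(y == 0) < 2)
      stopf("stratum '%s' has fewer than 2 cases or 2 controls", s)
    cov_s <- droplevels(covariates[idx, , drop = FALSE])
    keep <- vapply(cov_s, function(col) length(unique(col)) > 1L, TRUE)
    X0 <- model.matrix(~ ., data = cov_s[, keep, drop = FALSE])
    gwas_scan(genotypes[idx, , drop = FALSE], variants, y, X0, is_proxy)
  })
  names(out) <- strata
  out
}

# One logistic scan over all variants for a fixed design matrix X0.
gwas_scan <- function(G, variants, y, X0, is_proxy) {
  n_cases <- sum(y == 1); n_controls <- sum(y == 0)
  p0 <- ncol(X0)
  res <- data.frame(variant = variants$variant, chrom = variants$chrom,
                    pos = variants$pos, a1 = variants$a1, a2 = variants$a2,
                    freq_a1 = NA_real_, beta = NA_real_, se = NA_real_,
                    z = NA_real_, p = NA_real_,
                    n_cases = n_cases, n_controls = n_controls,
                    geno_rate = NA_real_, is_proxy = is_proxy,
                    note = "", stringsAsFactors = FALSE)
  for (j in seq_len(nrow(variants))) {
    g <- G[, variants$variant[j]]
    ok <- !is.na(g)
    res$geno_rate[j] <- mean(ok)
    res$freq_a1[j] <- mean(g[ok]) / 2
    if (var(g[ok]) == 0) { res$note[j] <- "monomorphic"; next }
    fit <- tryCatch(
      suppressWarnings(glm.fit(cbind(X0[ok, , drop = FALSE], g[ok]), y[ok],
                               family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
      res$note[j] <- "non-converged"; next
    }
    k <- fit$rank
    Rm <- qr.R(fit$qr)[seq_len(k), seq_len(k), drop = FALSE]
    cov_piv <- chol2inv(Rm)
    piv <- fit$qr$pivot[seq_len(k)]
    gi <- match(p0 + 1L, piv)
    if (is.na(gi)) { res$note[j] <- "aliased"; next }
    b <- fit$coefficients[p0 + 1L]
    se <- sqrt(cov_piv[gi, gi])
    if (!is.finite(se) || se > 100 || abs(b) > 15) {
      res$note[j] <- "separation"; next
    }
    res$beta[j] <- b; res$se[j] <- se; res$z[j] <- b / se
    res$p[j] <- 2 * pnorm(-abs(b / se))
  }
  res
}

#' Effective sample size of a case-control (or proxy) GWAS
#'
#' `N_eff = 4 * N * v * (1 - v)` with `v = n_cases / N`; proxy-phenotype
#' cohorts are further divided by 4.  Equals total N for balanced designs.
#'
#' @param n_cases,n_controls case/control counts (vectorized).
#' @param is_proxy logical; divide the result by 4 for proxy-GWAS cohorts.
#' @return numeric effective sample size(s).
#' @export
effective_n <- function(n_cases, n_controls, is_proxy = FALSE) {
  total <- n_cases + n_controls
  if (any(total <= 0)) stopf("effective_n: zero total sample size")
  v <- n_cases / total
  ne <- 4 * total * v * (1 - v)
  ifelse(is_proxy, ne / 4, ne)
}
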