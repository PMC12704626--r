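#' Harmonize summary statistics to an anchor allele orientation
#'
#' Variants are matched on (chrom, pos).  If the cohort's alleles equal the
#' anchor's (A1, A2) the row is kept as is; if they are swapped, beta/z signs
#' are flipped and the frequency complemented; otherwise the variant is
#' dropped.  Strand-ambiguous A/T and C/G palindromes are dropped.
#' Duplicated variant keys keep the first occurrence.  Harmonization is
#' involutive: re-harmonizing the output is a no-op.
#'
#' @param stats summary-statistic data.frame (see [run_stratified_gwas()]).
#' @param anchor data.frame with `chrom, pos, a1, a2` defining the target
#'   orientation (only variants present here are kept).
#' @return list with `stats` (harmonized, anchor orientation) and `dropped`
#'   (data.frame of dropped keys and reasons).
#' @export
harmonize_stats <- function(stats, anchor) {
  key_s <- variant_key(stats$chrom, stats$pos)
  key_a <- variant_key(anchor$chrom, anchor$pos)
  dup <- duplicated(key_s)
  dropped <- data.frame(variant = character(), reason = character())
  if (any(dup)) {
    dropped <- rbind(dropped, data.frame(variant = key_s[dup], reason = "duplicate-key"))
    stats <- stats[!dup, , drop = FALSE]; key_s <- key_s[!dup]
  }
  m <- match(key_s, key_a)
  absent <- is.na(m)
  if (any(absent))
    dropped <- rbind(dropped, data.frame(variant = key_s[absent], reason = "absent-from-anchor"))
  stats <- stats[!absent, , drop = FALSE]; m <- m[!absent]
  a1 <- anchor$a1[m]; a2 <- anchor$a2[m]
  pal <- is_palindromic(stats$a1, stats$a2)
  same <- stats$a1 == a1 & stats$a2 == a2
  swap <- stats$a1 == a2 & stats$a2 == a1
  bad <- pal | !(same | swap)
  if (any(bad)) {
    reason <- ifelse(pal[bad], "palindromic", "allele-mismatch")
    dropped <- rbind(dropped,
                     data.frame(variant = variant_key(stats$chrom, stats$pos)[bad],
                                reason = reason))
  }
  flip <- swap & !bad
  if (any(flip)) {
    stats$beta[flip] <- -stats$beta[flip]
    if ("z" %in% names(stats)) stats$z[flip] <- -stats$z[flip]
    if ("freq_a1" %in% names(stats)) stats$freq_a1[flip] <- 1 - stats$freq_a1[flip]
    tmp <- stats$a1[flip]; stats$a1[flip] <- stats$a2[flip]; stats$a2[flip] <- tmp
  }
  list(stats = stats[!bad, , drop = FALSE], dropped = dropped)
}

#' Variant intersection and genotyping-rate filter
#'
#' Retains variants that are present in the anchor cohort set and have
#' genotyping rate at least `min_rate` in every cohort.  Cohort statistics
#' are assumed already harmonized to the anchor orientation.
#'
#' @param stats_list named list of harmonized summary-statistic data.frames.
#' @param anchor data.frame with `chrom, pos` (the anchor variant set).
#' @param min_rate minimum genotyping rate (default 0.9).
#' @return character vector of retained variant keys.
#' @export
filter_variants <- function(stats_list, anchor, min_rate = 0.9) {
  keep <- variant_key(anchor$chrom, anchor$pos)
  for (st in stats_list) {
    key <- variant_key(st$chrom, st$pos)
    rate <- st$geno_rate %||% rep(1, nrow(st))
    ok <- key[!is.na(rate) & rate >= min_rate]
    keep <- intersect(keep, ok)
  }
  keep
}

#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' @param beta,se per-cohort effects and standard errors (NAs dropped
#'   pairwise; at least one finite se required).
#' @return list `beta, se, z, p`; all-`NA` input yields all-`NA` output.
#' @export
meta_fixed_effects <- function(beta, se) {
  ok <- is.finite(beta) & is.finite(se) & se > 0
  if (!any(ok)) return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_))
  w <- 1 / se[ok]^2
  b <- sum(w * beta[ok]) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s, z = b / s, p = 2 * pnorm(-abs(b / s)))
}

#' Sample-size-weighted (Stouffer) combination of z-scores
#'
#' `Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))` with effective sample sizes as
#' weights; invariant to cohort ordering.
#'
#' @param z per-cohort z-scores, aligned to a common effect orientation.
#' @param n_eff per-cohort effective sample sizes.
#' @return list `z, p`.
#' @export
meta_stouffer <- function(z, n_eff) {
  ok <- is.finite(z) & is.finite(n_eff) & n_eff > 0
  if (!any(ok)) stopf("meta_stouffer: no cohort with positive effective n")
  Z <- sum(sqrt(n_eff[ok]) * z[ok]) / sqrt(sum(n_eff[ok]))
  list(z = Z, p = 2 * pnorm(-abs(Z)))
}

#' Row-aligned fixed-effects meta-analysis of cohort summary statistics
#'
#' Pools harmonized cohorts over a shared retained-variant set; effective
#' sample sizes (proxy cohorts already down-weighted) are summed.
#'
#' @param stats_list named list of harmonized summary-statistic data.frames.
#' @param keys variant keys to pool (e.g. from [filter_variants()]).
#' @return pooled summary-statistic data.frame with an `n_eff` column.
#' @export
meta_stats_table <- function(stats_list, keys) {
  aligned <- lapply(stats_list, function(st) {
    st[match(keys, variant_key(st$chrom, st$pos)), , drop = FALSE]
  })
  base <- aligned[[1]]
  B <- sapply(aligned, function(a) a$beta)
  S <- sapply(aligned, function(a) a$se)
  NE <- sapply(aligned, function(a) effective_n(a$n_cases, a$n_controls, a$is_proxy))
  pooled <- t(vapply(seq_along(keys), function(i) {
    m <- meta_fixed_effects(B[i, ], S[i, ])
    c(m$beta, m$se, m$z, m$p)
  }, numeric(4)))
  data.frame(variant = keys, chrom = base$chrom, pos = base$pos,
             a1 = base$a1, a2 = base$a2,
             freq_a1 = rowMeans(sapply(aligned, function(a) a$freq_a1), na.rm = TRUE),
             beta = pooled[, 1], se = pooled[, 2], z = pooled[, 3], p = pooled[, 4],
             n_cases = rowSums(sapply(aligned, function(a) a$n_cases)),
             n_controls = rowSums(sapply(aligned, function(a) a$n_controls)),
             n_eff = rowSums(NE, na.rm = TRUE),
             geno_rate = apply(sapply(aligned, function(a) a$geno_rate), 1, min),
             is_proxy = FALSE, note = "", stringsAsFactors = FALSE)
}
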