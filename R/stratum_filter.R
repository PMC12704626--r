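#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over the step-up procedure (`stats::p.adjust`), preserving
#' `NA`s and returning an empty vector for empty input.
#'
#' @param p p-values in (0, 1].
#' @return adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' APOE*4 heterogeneity criterion for one stratum
#'
#' A pair is biased to stratum s when it is FDR-significant there
#' (`q_s < alpha`) and, in the opposite stratum, is either non-significant
#' (`p_other > alpha`) with the same effect direction, or has an opposite
#' effect direction.  A zero z in the other stratum counts as
#' same-direction; a missing other-stratum result yields `FALSE`.
#'
#' @param q_s FDR-adjusted p in the stratum under test.
#' @param z_s,z_other TWAS z-scores in the two strata.
#' @param p_other nominal p in the opposite stratum.
#' @param alpha significance level for both clauses (default 0.05).
#' @return logical (vectorized).
#' @export
heterogeneity_flag <- function(q_s, z_s, p_other, z_other, alpha = 0.05) {
  same_dir <- sign(z_s) == sign(z_other) | z_other == 0
  flag <- q_s < alpha & ((p_other > alpha & same_dir) | !same_dir)
  flag[is.na(q_s) | is.na(z_s) | is.na(p_other) | is.na(z_other)] <- FALSE
  flag
}

#' Add FDR columns and heterogeneity flags to a cTWAS pair table
#'
#' FDR is computed within stratum, pooled across all (cell-type, gene)
#' pairs.  `heterogeneity_stratum` records which stratum (if any) the pair is
#' biased to; in the rare case both criteria hold, the stratum with the
#' smaller nominal p wins.
#'
#' @param pairs output of [run_ctwas()].
#' @param alpha level for FDR and the non-significance clause.
#' @return `pairs` with `q_carrier, q_noncarrier, flag_carrier,
#'   flag_noncarrier, heterogeneity_stratum` appended.
#' @export
add_heterogeneity <- function(pairs, alpha = 0.05) {
  pairs$q_carrier <- bh_fdr(pairs$p_carrier)
  pairs$q_noncarrier <- bh_fdr(pairs$p_noncarrier)
  pairs$flag_carrier <- heterogeneity_flag(pairs$q_carrier, pairs$z_carrier,
                                           pairs$p_noncarrier, pairs$z_noncarrier,
                                           alpha)
  pairs$flag_noncarrier <- heterogeneity_flag(pairs$q_noncarrier, pairs$z_noncarrier,
                                              pairs$p_carrier, pairs$z_carrier,
                                              alpha)
  pairs$heterogeneity_stratum <- ifelse(
    pairs$flag_carrier & pairs$flag_noncarrier,
    ifelse(pairs$p_carrier <= pairs$p_noncarrier, "carrier", "non-carrier"),
    ifelse(pairs$flag_carrier, "carrier",
           ifelse(pairs$flag_noncarrier, "non-carrier", "none")))
  pairs
}

#' Single-linkage locus clustering of significant genes
#'
#' Genes whose TSS lie within `reach` of any member of a cluster (on the
#' same chromosome) join that cluster; on a line this is equivalent to
#' cutting sorted TSS positions at gaps larger than `reach`.
#'
#' @param chrom,tss genomic coordinates of the pairs to cluster.
#' @param reach linkage distance in bp (default 1 Mb).
#' @return integer vector of locus ids (same order as input).
#' @export
cluster_loci <- function(chrom, tss, reach = 1e6) {
  stopifnot(length(chrom) == length(tss), !anyNA(tss))
  locus <- integer(length(tss))
  nxt <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    o <- idx[order(tss[idx])]
    newc <- c(TRUE, diff(tss[o]) > reach)
    locus[o] <- nxt + cumsum(newc)
    nxt <- max(locus[o])
  }
  locus
}

#' Locus-level exclusion rule
#'
#' Within each locus the most significant pair (smallest p over both strata;
#' ties broken by smaller q, then lexicographic gene id, logged) is
#' identified.  If that top pair does not pass the heterogeneity criterion in
#' the stratum of its best p, every pair at the locus is dropped; otherwise
#' the pairs that individually pass are retained.
#'
#' @param pairs output of [add_heterogeneity()], restricted to the
#'   significant pairs of interest, with a `locus` column (see
#'   [cluster_loci()]).
#' @return `pairs` subset to the retained rows.
#' @export
locus_exclusion <- function(pairs) {
  stopifnot("locus" %in% names(pairs))
  keep <- logical(nrow(pairs))
  for (l in unique(pairs$locus)) {
    idx <- which(pairs$locus == l)
    pmin_ <- pmin(pairs$p_carrier[idx], pairs$p_noncarrier[idx], na.rm = TRUE)
    top_cand <- idx[pmin_ == min(pmin_)]
    if (length(top_cand) > 1L) {
      message(sprintf("locus_exclusion: tie for top pair at locus %s, breaking by q then gene id", l))
      qmin_ <- pmin(pairs$q_carrier[top_cand], pairs$q_noncarrier[top_cand], na.rm = TRUE)
      top_cand <- top_cand[qmin_ == min(qmin_)]
      top_cand <- top_cand[order(pairs$gene[top_cand])]
    }
    top <- top_cand[1]
    best_str <- if (isTRUE(pairs$p_carrier[top] <= pairs$p_noncarrier[top]) ||
                    is.na(pairs$p_noncarrier[top])) "carrier" else "non-carrier"
    top_ok <- if (best_str == "carrier") pairs$flag_carrier[top] else pairs$flag_noncarrier[top]
    if (isTRUE(top_ok))
      keep[idx] <- pairs$heterogeneity_stratum[idx] != "none"
  }
  pairs[keep, , drop = FALSE]
}

#' Cross-ancestry consistency of a stratum-biased pair
#'
#' Meta-analyzes the primary- and secondary-ancestry TWAS z-scores per
#' stratum by sample-size-weighted combination ([meta_stouffer()]).  The
#' pair is consistent when the meta p in its own (respective) stratum is
#' strictly smaller than the primary-ancestry p, while the opposite stratum's
#' meta p stays above `alpha`.
#'
#' @param z_primary,z_secondary named numeric vectors
#'   (`carrier`, `non-carrier`) of TWAS z-scores; any missing secondary value
#'   makes the result `FALSE`.
#' @param n_primary,n_secondary effective sample sizes per stratum (named the
#'   same way).
#' @param respective which stratum the pair is biased to.
#' @param alpha level for the opposite-stratum clause.
#' @return logical.
#' @export
cross_ancestry_consistent <- function(z_primary, z_secondary,
                                      n_primary, n_secondary,
                                      respective = c("carrier", "non-carrier"),
                                      alpha = 0.05) {
  respective <- match.arg(respective)
  opposite <- setdiff(c("carrier", "non-carrier"), respective)
  if (anyNA(z_secondary[c(respective, opposite)])) {
    message("cross_ancestry_consistent: missing secondary-ancestry result; FALSE")
    return(FALSE)
  }
  meta_r <- meta_stouffer(c(z_primary[respective], z_secondary[respective]),
                          c(n_primary[respective], n_secondary[respective]))
  meta_o <- meta_stouffer(c(z_primary[opposite], z_secondary[opposite]),
                          c(n_primary[opposite], n_secondary[opposite]))
  p_primary_r <- 2 * pnorm(-abs(z_primary[[respective]]))
  isTRUE(meta_r$p < p_primary_r && meta_o$p > alpha)
}
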