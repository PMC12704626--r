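#' Summary-statistic TWAS association for one gene
#'
#' Combines GWAS z-scores over a gene's cis variants with its expression
#' weights and the local LD matrix:
#' `z_twas = w'z / sqrt(w'Rw)`, two-sided normal p.  The quadratic form is
#' floored at `eps`; degenerate weights (w'Rw < eps) yield a missing result.
#'
#' @param w `weight_set` (or a named numeric weight vector).
#' @param z GWAS z-scores named by variant key, aligned to the weights'
#'   allele orientation.
#' @param R LD (correlation) matrix with dimnames matching the weights'
#'   variants; must be positive semi-definite with unit diagonal.
#' @param eps floor for the quadratic form (default 1e-8).
#' @return list `z, p, n_variants`.
#' @export
twas_associate <- function(w, z, R, eps = 1e-8) {
  wv <- if (inherits(w, "weight_set")) w$weights else w
  vars <- names(wv)
  if (is.null(vars)) stopf("twas_associate: weights must be named by variant")
  miss <- setdiff(vars, names(z))
  if (length(miss))
    stopf("twas_associate: variants missing from z: %s", paste(miss, collapse = ", "))
  miss_r <- setdiff(vars, rownames(R))
  if (length(miss_r))
    stopf("twas_associate: variants missing from LD matrix: %s",
          paste(miss_r, collapse = ", "))
  zv <- z[vars]
  Rm <- R[vars, vars, drop = FALSE]
  q <- as.numeric(t(wv) %*% Rm %*% wv)
  if (!is.finite(q) || q < eps)
    return(list(z = NA_real_, p = NA_real_, n_variants = length(vars)))
  zt <- sum(wv * zv) / sqrt(q)
  list(z = zt, p = 2 * pnorm(-abs(zt)), n_variants = length(vars))
}

#' Cell-type TWAS over both APOE*4 strata
#'
#' Applies [twas_associate()] to every weight set against the carrier and
#' non-carrier GWAS summary statistics, using LD from a reference panel.
#' Genes with no weight variant present in a stratum's GWAS are dropped (with
#' a message); a stratum with partial overlap restricts the weights to the
#' shared variants.
#'
#' @param weight_sets list of `weight_set` objects.
#' @param stats_by_stratum named list (`carrier`, `non-carrier`) of
#'   harmonized summary-statistic data.frames (same allele orientation as the
#'   weights' reference panel).
#' @param ld_ref either a correlation matrix over all variants (dimnames =
#'   variant keys) or a dosage matrix from which correlations are computed.
#' @return data.frame of pair results: `gene, cell_type, chrom, tss,
#'   n_variants, z_carrier, p_carrier, z_noncarrier, p_noncarrier`.
#' @export
run_ctwas <- function(weight_sets, stats_by_stratum, ld_ref) {
  stopifnot(all(c("carrier", "non-carrier") %in% names(stats_by_stratum)))
  ld_is_matrix <- is.matrix(ld_ref) && nrow(ld_ref) == ncol(ld_ref) &&
    !is.null(rownames(ld_ref)) && identical(rownames(ld_ref), colnames(ld_ref))
  zmaps <- lapply(stats_by_stratum, function(st)
    setNames(st$z, variant_key(st$chrom, st$pos)))
  rows <- lapply(weight_sets, function(ws) {
    shared <- ws$variants
    for (zm in zmaps) shared <- intersect(shared, names(zm)[!is.na(zm)])
    if (length(shared) == 0L) {
      message(sprintf("run_ctwas: %s/%s dropped (no GWAS overlap)",
                      ws$gene, ws$cell_type))
      return(NULL)
    }
    wv <- ws$weights[shared]
    if (all(wv == 0)) return(NULL)
    R <- if (ld_is_matrix) ld_ref[shared, shared, drop = FALSE]
         else cor(ld_ref[, shared, drop = FALSE])
    res <- lapply(zmaps, function(zm) twas_associate(wv, zm[shared], R))
    chrom <- as.integer(sub(":.*", "", shared[1]))
    data.frame(gene = ws$gene, cell_type = ws$cell_type, chrom = chrom,
               tss = ws$tss, n_variants = length(shared),
               z_carrier = res$carrier$z, p_carrier = res$carrier$p,
               z_noncarrier = res$`non-carrier`$z,
               p_noncarrier = res$`non-carrier`$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
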