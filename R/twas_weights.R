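# Genotype standardization used throughout weight fitting and LD:
# mean-impute missing dosages, then scale columns to mean 0, variance 1.
standardize_genotypes <- function(G) {
  G <- apply(G, 2, function(g) { g[is.na(g)] <- mean(g, na.rm = TRUE); g })
  sds <- apply(G, 2, sd)
  sds[sds == 0] <- 1
  scale(G, center = TRUE, scale = sds)
}

#' Permutation screen for cis heritability of expression
#'
#' Tests for any cis genetic contribution to an expression trait using the
#' maximum squared marginal correlation across cis variants as the statistic
#' and its permutation distribution (expression permuted, genotypes fixed)
#' as the reference.  The returned p is `(1 + #{perm >= obs}) / (B + 1)`, so
#' the smallest attainable value is `1/(B+1)`.
#'
#' @param expr expression vector (one gene).
#' @param G cis genotype matrix for the same subjects.
#' @param n_perm number of permutations B (>= 1000 recommended; seed the RNG
#'   for reproducibility).
#' @return the permutation p-value; constant expression returns 1.
#' @export
screen_heritability <- function(expr, G, n_perm = 1000) {
  if (is.null(dim(G)) || ncol(G) < 1L) stopf("screen_heritability: no cis variants")
  if (nrow(G) < 20L) stopf("screen_heritability: fewer than 20 subjects")
  if (sd(expr) == 0) return(1)
  n <- length(expr)
  Gs <- standardize_genotypes(G)
  ys <- as.vector(scale(expr))
  obs <- max((crossprod(Gs, ys) / (n - 1))^2)
  perm_idx <- replicate(n_perm, sample.int(n))
  Yp <- matrix(ys[perm_idx], n, n_perm)
  stat <- apply((crossprod(Gs, Yp) / (n - 1))^2, 2, max)
  (1 + sum(stat >= obs)) / (n_perm + 1)
}

#' Per-variant marginal eQTL statistics
#'
#' Simple-regression effect of each dosage column on expression (raw allele
#' scale), as produced by standard matrix-eQTL scans; used by the
#' colocalization and Mendelian-randomization stages.
#'
#' @param expr expression vector.
#' @param G dosage matrix.
#' @return data.frame `variant, beta, se, z, p`.
#' @export
eqtl_marginal <- function(expr, G) {
  n <- length(expr)
  y <- expr - mean(expr)
  res <- t(apply(G, 2, function(g) {
    g <- g - mean(g)
    ssx <- sum(g^2)
    if (ssx == 0) return(c(NA, NA, NA, NA))
    b <- sum(g * y) / ssx
    s2 <- (sum(y^2) - b^2 * ssx) / (n - 2)
    se <- sqrt(s2 / ssx)
    c(b, se, b / se, 2 * pnorm(-abs(b / se)))
  }))
  data.frame(variant = colnames(G), beta = res[, 1], se = res[, 2],
             z = res[, 3], p = res[, 4], row.names = NULL)
}

#' Fit cis expression weights for one gene
#'
#' Fits two candidate predictors of expression from standardized cis
#' dosages -- the single best marginal eQTL (`top1`) and a ridge regression
#' over all cis variants with penalty chosen by k-fold cross-validation --
#' and returns the candidate with the higher cross-validated R^2.  Genes
#' where neither candidate predicts better than the mean (CV R^2 <= 0) are
#' dropped (returns `NULL`).
#'
#' @param expr expression vector (caller is expected to have passed the
#'   heritability screen).
#' @param G cis dosage matrix (columns named by variant key).
#' @param gene,cell_type,tss identifiers carried into the weight set.
#' @param folds number of CV folds (seed the RNG for reproducible fold
#'   assignment).
#' @param h2_p the gene's heritability-screen p, carried along.
#' @return a `weight_set` list (`gene, cell_type, tss, variants, weights,
#'   model_tag, cv_r2, h2_p`) with weights on the standardized-genotype
#'   scale, or `NULL` if the gene is dropped.
#' @export
fit_weights <- function(expr, G, gene = "gene", cell_type = "ct", tss = NA,
                        folds = 5, h2_p = NA) {
  n <- length(expr)
  Gs <- standardize_genotypes(G)
  y <- expr - mean(expr)
  vary <- mean(y^2)
  if (vary == 0) return(NULL)
  foldid <- sample(rep(seq_len(folds), length.out = n))

  ## candidate 1: top marginal eQTL only
  marg <- as.vector(crossprod(Gs, y) / (n - 1))
  sse_top1 <- 0
  for (f in seq_len(folds)) {
    tr <- foldid != f
    m_tr <- as.vector(crossprod(Gs[tr, , drop = FALSE], y[tr]) / (sum(tr) - 1))
    jbest <- which.max(abs(m_tr))
    b <- m_tr[jbest] / var(Gs[tr, jbest])
    pred <- (Gs[!tr, jbest] - mean(Gs[tr, jbest])) * b + mean(y[tr])
    sse_top1 <- sse_top1 + sum((y[!tr] - pred)^2)
  }
  r2_top1 <- 1 - (sse_top1 / n) / vary

  ## candidate 2: ridge over all cis variants (needs >= 2 columns)
  r2_ridge <- -Inf
  ridge_w <- NULL
  if (ncol(Gs) >= 2) {
    cvfit <- cv.glmnet(Gs, y, alpha = 0, foldid = foldid, standardize = FALSE)
    r2_ridge <- 1 - min(cvfit$cvm) / vary
    ridge_w <- as.vector(coef(cvfit, s = "lambda.min"))[-1]
  }

  if (max(r2_top1, r2_ridge) <= 0) {
    message(sprintf("fit_weights: gene %s dropped (all CV R^2 <= 0)", gene))
    return(NULL)
  }
  if (r2_top1 >= r2_ridge) {
    w <- numeric(ncol(Gs))
    jbest <- which.max(abs(marg))
    w[jbest] <- marg[jbest]
    tag <- "top1"; r2 <- r2_top1
  } else {
    w <- ridge_w; tag <- "ridge"; r2 <- r2_ridge
  }
  names(w) <- colnames(G)
  structure(list(gene = gene, cell_type = cell_type, tss = tss,
                 variants = colnames(G), weights = w, model_tag = tag,
                 cv_r2 = r2, h2_p = h2_p),
            class = "weight_set")
}

#' @exportS3Method base::print
print.weight_set <- function(x, ...) {
  cat("<weight_set>", x$gene, "/", x$cell_type, ":", length(x$variants),
      "variants, model", x$model_tag, sprintf("(cv R2 %.3f)\n", x$cv_r2))
  invisible(x)
}

#' Screen and fit weights for every gene in a reference panel
#'
#' Convenience loop over cis genes: runs [screen_heritability()] on each
#' gene's expression (log2-CPM of its cell type's pseudobulk counts) and
#' [fit_weights()] for genes passing `h2_alpha`.
#'
#' @param expr_by_gene named list of expression vectors.
#' @param geno_by_gene named list of cis dosage matrices.
#' @param meta data.frame with `gene, cell_type, tss` rows matching the list
#'   names.
#' @param h2_alpha heritability screen level (default 0.05).
#' @param n_perm permutations for the screen.
#' @return list of `weight_set` objects (screened-out or dropped genes
#'   omitted).
#' @export
build_weights <- function(expr_by_gene, geno_by_gene, meta,
                          h2_alpha = 0.05, n_perm = 1000) {
  out <- list()
  for (g in names(expr_by_gene)) {
    i <- match(g, meta$gene)
    hp <- screen_heritability(expr_by_gene[[g]], geno_by_gene[[g]], n_perm)
    if (hp >= h2_alpha) next
    ws <- fit_weights(expr_by_gene[[g]], geno_by_gene[[g]], gene = g,
                      cell_type = meta$cell_type[i], tss = meta$tss[i],
                      h2_p = hp)
    if (!is.null(ws)) out[[g]] <- ws
  }
  out
}
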