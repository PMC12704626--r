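#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a normal effect prior
#' of standard deviation `sd_prior`, the log ABF in favor of a nonzero effect
#' is `0.5 * log(V/(V+W)) + (z^2/2) * W/(V+W)` with `V = se^2`,
#' `W = sd_prior^2`, `z = beta/se`.
#'
#' @param beta,se effect estimate(s) and standard error(s) (vectorized).
#' @param sd_prior prior effect standard deviation W^0.5 (> 0); conventional
#'   values are 0.2 for case-control log-odds and 0.15 for quantitative
#'   traits.
#' @return log ABF (same length as `beta`).
#' @export
wakefield_labf <- function(beta, se, sd_prior) {
  if (sd_prior <= 0) stopf("wakefield_labf: sd_prior must be > 0")
  if (any(se <= 0, na.rm = TRUE)) stopf("wakefield_labf: se must be > 0")
  V <- se^2
  W <- sd_prior^2
  r <- W / (V + W)
  z2 <- (beta / se)^2
  0.5 * log(1 - r) + 0.5 * z2 * r
}

#' Approximate-Bayes-factor colocalization of two traits
#'
#' Enumerates the five hypotheses over a shared variant set -- no
#' association (H0), trait-1 only (H1), trait-2 only (H2), two distinct
#' causal variants (H3), one shared causal variant (H4) -- with per-variant
#' log ABFs and single-causal-variant priors `p1, p2, p12`.  All sums are
#' accumulated in log space.
#'
#' @param labf1,labf2 per-variant log ABFs for the two traits, aligned over
#'   the same variants in the same order.
#' @param p1,p2,p12 prior probabilities that a variant is associated with
#'   trait 1 only, trait 2 only, or both.
#' @param scheme_tag label recorded in the result (e.g. `"default"`,
#'   `"adjusted"`).
#' @return object of class `coloc_result`: `pp` (named pp0..pp4, summing to
#'   1), `priors`, `scheme_tag`, `n_variants`, and `h4_share` (per-variant
#'   posterior share of the shared-variant hypothesis, used to pick the top
#'   colocalizing variant).
#' @export
coloc_abf <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      scheme_tag = "default") {
  if (length(labf1) != length(labf2))
    stopf("coloc_abf: traits must share an aligned variant set")
  if (length(labf1) < 2L)
    warnf("coloc_abf: fewer than 2 variants; H3 is degenerate")
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)
  lh <- c(h0 = 0,
          h1 = log(p1) + l1,
          h2 = log(p2) + l2,
          h3 = log(p1) + log(p2) + logdiffexp(l1 + l2, l12),
          h4 = log(p12) + l12)
  m <- logsumexp(lh)
  pp <- exp(lh - m)
  names(pp) <- paste0("pp", 0:4)
  share <- exp((labf1 + labf2) - l12)
  names(share) <- names(labf1) %||% seq_along(labf1)
  structure(list(pp = pp, priors = c(p1 = p1, p2 = p2, p12 = p12),
                 scheme_tag = scheme_tag, n_variants = length(labf1),
                 h4_share = share),
            class = "coloc_result")
}

#' @exportS3Method base::print
print.coloc_result <- function(x, ...) {
  cat("<coloc_result>", x$scheme_tag, ":",
      paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " "), "\n")
  invisible(x)
}

#' Best PP4 across colocalization schemes, with support tier
#'
#' Takes the maximum PP4 over the supplied scheme results and assigns
#' suggestive (`>= 0.4`) or strong (`>= 0.7`) support; also reports the top
#' colocalizing variant (largest shared-hypothesis share in the winning
#' scheme) for downstream open-chromatin overlap.
#'
#' @param results list of `coloc_result` objects.
#' @return list `pp4_best, tier` (`"none"`, `"suggestive"`, `"strong"`),
#'   `scheme_tag, top_variant`.
#' @export
best_pp4 <- function(results) {
  if (length(results) == 0L) stopf("best_pp4: need at least one result")
  pp4 <- vapply(results, function(r) unname(r$pp["pp4"]), 0)
  i <- which.max(pp4)
  tier <- if (pp4[i] >= 0.7) "strong" else if (pp4[i] >= 0.4) "suggestive" else "none"
  share <- results[[i]]$h4_share
  list(pp4_best = pp4[i], tier = tier,
       scheme_tag = results[[i]]$scheme_tag,
       top_variant = names(share)[which.max(share)])
}

# Standard and adjusted prior schemes used by the pipeline's coloc stage.
coloc_schemes <- function() {
  list(default = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
       adjusted = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-4))
}
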