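#' Simulate LD-blocked genotypes for one cohort
#'
#' Genotypes are drawn from a Gaussian-copula threshold model: per locus, two
#' latent haplotype Gaussians per subject with AR(1) correlation `ld_rho`
#' between adjacent variants are thresholded at `qnorm(maf)` and summed, so
#' dosages take values in `{0, 1, 2}` with exactly the configured allele
#' frequency and LD decay `ld_rho^distance` on the latent scale.
#'
#' @param config a [sim_config()].
#' @param stratum cohort label used only to derive the random stream
#'   ("carrier", "non-carrier", "mixed", "reference", ...); allele
#'   frequencies do not differ between strata.
#' @param ancestry ancestry label; frequencies (not alleles or positions)
#'   are ancestry-specific.
#' @param n number of subjects (default `2 * n_per_stratum`).
#' @return list with `genotypes` (n x variants integer matrix, columns named
#'   by variant key, A1-dosage coded) and `variants` (the ancestry's
#'   [variant_table()]).
#' @export
simulate_genotypes <- function(config, stratum = "mixed", ancestry = "EUR",
                               n = 2L * config$n_per_stratum) {
  validate_sim_config(config)
  vt <- variant_table(config, ancestry)
  m <- config$n_variants
  thr <- qnorm(vt$maf)
  G <- with_seed(derive_seed(config$seed, "geno", stratum, ancestry, n), {
    out <- matrix(0L, n, nrow(vt))
    # AR(1) haplotype latents built by recursion: z_j = rho z_{j-1} + e_j
    rho <- config$ld_rho
    sc <- sqrt(1 - rho^2)
    for (l in seq_len(config$n_loci)) {
      cols <- which(vt$locus == l)
      g <- matrix(0L, n, m)
      for (h in 1:2) {
        z <- matrix(rnorm(n * m), n, m)
        if (rho > 0 && m > 1) for (j in 2:m) z[, j] <- rho * z[, j - 1] + sc * z[, j]
        g <- g + (z < rep(thr[cols], each = n))
      }
      out[, cols] <- g
    }
    out
  })
  colnames(G) <- vt$variant
  list(genotypes = G, variants = vt)
}
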