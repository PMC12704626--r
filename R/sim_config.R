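#' Simulation configuration for the synthetic study
#'
#' Bundles every knob of the synthetic-data generator: an LD-blocked genotype
#' model, a cell-type cis-eQTL architecture, a stratum-specific liability
#' model for the binary disease phenotype, and negative-binomial pseudobulk
#' counts.  Defaults describe the study conditions the package is tested
#' under: 20 independent loci of 25 variants, 60 cis-heritable genes spread
#' over seven brain cell types, of which 10 are causal in exactly one
#' APOE*4 stratum with a liability effect of 0.4 log-odds per SD of
#' expression (about 1.2% of liability variance at `h2_cis = 0.25`).
#'
#' @param n_per_stratum subjects per APOE*4 stratum in the primary
#'   case-control cohort (the proxy and secondary-ancestry cohorts are scaled
#'   from this; see [emit_fixture_bundle()]).
#' @param n_variants variants per locus.
#' @param n_loci number of independent LD blocks.
#' @param ld_rho AR(1) correlation of adjacent variants' latent haplotype
#'   Gaussians, in `[0, 1)`.
#' @param maf_range minor-allele-frequency interval, within `(0, 0.5]`.
#' @param cell_types character vector of cell-type labels.
#' @param n_genes cis genes per locus (each gene is assigned to one cell
#'   type, cycling through `cell_types`).
#' @param h2_cis cis-heritability of the latent expression of eQTL genes.
#' @param beta_liability log-odds effect of one SD of (latent) expression on
#'   disease for causal genes.
#' @param stratum_specificity fraction of causal genes causal in exactly one
#'   stratum (the rest are causal in both).
#' @param prevalence_logit_intercept baseline log-odds of disease.
#' @param nb_dispersion negative-binomial dispersion of pseudobulk counts
#'   (`size = 1/dispersion`).
#' @param carrier_prob probability that a subject in a mixed cohort carries
#'   APOE*4.
#' @param n_reference subjects in the expression reference panel.
#' @param n_background_genes non-cis "background" genes per cell type, used
#'   for normalization, differential-expression nulls and the enrichment
#'   universe.
#' @param peak_width width (bp) of synthetic open-chromatin peaks centered on
#'   eQTL variants.
#' @param seed integer random seed; every stochastic stage derives its own
#'   stream from it via [derive_seed()].
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_stratum = 6000,
                       n_variants = 25,
                       n_loci = 20,
                       ld_rho = 0.6,
                       maf_range = c(0.05, 0.5),
                       cell_types = c("Ast", "Exc", "Inh", "Mic", "Oli", "Opc", "End"),
                       n_genes = 3,
                       h2_cis = 0.25,
                       beta_liability = 0.4,
                       stratum_specificity = 1,
                       prevalence_logit_intercept = 0,
                       nb_dispersion = 0.2,
                       carrier_prob = 0.5,
                       n_reference = 424,
                       n_background_genes = 40,
                       peak_width = 500,
                       seed = 1L) {
  cfg <- list(
    n_per_stratum = as.integer(n_per_stratum), n_variants = as.integer(n_variants),
    n_loci = as.integer(n_loci), ld_rho = ld_rho, maf_range = maf_range,
    cell_types = as.character(cell_types), n_genes = as.integer(n_genes),
    h2_cis = h2_cis, beta_liability = beta_liability,
    stratum_specificity = stratum_specificity,
    prevalence_logit_intercept = prevalence_logit_intercept,
    nb_dispersion = nb_dispersion, carrier_prob = carrier_prob,
    n_reference = as.integer(n_reference),
    n_background_genes = as.integer(n_background_genes),
    peak_width = as.integer(peak_width), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!(cfg$ld_rho >= 0 && cfg$ld_rho < 1))
    stopf("configuration error: ld_rho must be in [0, 1), got %s", cfg$ld_rho)
  if (length(cfg$maf_range) != 2L || any(!is.finite(cfg$maf_range)) ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stopf("configuration error: maf_range must be an increasing interval within (0, 0.5]")
  if (!(cfg$h2_cis >= 0 && cfg$h2_cis <= 1))
    stopf("configuration error: h2_cis must be in [0, 1]")
  if (cfg$stratum_specificity < 0 || cfg$stratum_specificity > 1)
    stopf("configuration error: stratum_specificity must be in [0, 1]")
  counts <- c(cfg$n_per_stratum, cfg$n_variants, cfg$n_loci, cfg$n_genes,
              cfg$n_reference, cfg$peak_width)
  if (any(counts <= 0)) stopf("configuration error: all counts must be positive")
  if (cfg$nb_dispersion <= 0) stopf("configuration error: nb_dispersion must be > 0")
  invisible(cfg)
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_loci, "loci x", x$n_variants, "variants;",
      x$n_loci * x$n_genes, "cis genes over", length(x$cell_types),
      "cell types; seed", x$seed, "\n")
  invisible(x)
}

# Deterministic genomic layout: locus l sits on chromosome ((l-1) %% 10) + 1,
# same-chromosome loci 20 Mb apart so 1 Mb locus clustering never merges them.
locus_layout <- function(config) {
  l <- seq_len(config$n_loci)
  data.frame(locus = l,
             chrom = ((l - 1L) %% 10L) + 1L,
             base = 10e6 + ((l - 1L) %/% 10L) * 20e6)
}

#' Variant table for one ancestry
#'
#' Alleles are shared across ancestries (the same physical SNPs); allele
#' frequencies are ancestry-specific.  Positions are strictly increasing
#' within each chromosome.
#'
#' @param config a [sim_config()].
#' @param ancestry ancestry label (e.g. `"EUR"`, `"AFR"`).
#' @return data.frame with columns `variant, locus, chrom, pos, a1, a2, maf`.
#' @export
variant_table <- function(config, ancestry = "EUR") {
  lay <- locus_layout(config)
  m <- config$n_variants
  vt <- do.call(rbind, lapply(seq_len(config$n_loci), function(l) {
    data.frame(locus = l, chrom = lay$chrom[l],
               pos = lay$base[l] + (seq_len(m) - 1L) * 2000 + 1)
  }))
  vt$variant <- variant_key(vt$chrom, vt$pos)
  # alleles: shared across ancestries, non-palindromic pairs only
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  vt[, c("a1", "a2")] <- with_seed(derive_seed(config$seed, "alleles"), {
    pairs[sample.int(4L, nrow(vt), replace = TRUE), , drop = FALSE]
  })
  vt$maf <- with_seed(derive_seed(config$seed, "maf", ancestry), {
    runif(nrow(vt), config$maf_range[1], config$maf_range[2])
  })
  vt[, c("variant", "locus", "chrom", "pos", "a1", "a2", "maf")]
}

#' Ground-truth table of simulated causal genes
#'
#' Assigns `n_loci * n_genes` cis genes to loci and cell types, gives every
#' gene a sparse cis-eQTL architecture, and marks `n_causal` of them causal
#' for disease.  With `stratum_specificity = 1` causal genes act in exactly
#' one APOE*4 stratum, alternating carrier / non-carrier.
#'
#' @param config a [sim_config()].
#' @param n_causal number of causal genes (one per locus, in the first
#'   `n_causal` loci, so loci are either causal or null).
#' @param eqtl_per_gene cis variants with nonzero weight per gene.
#' @return list of class `truth_table` with elements `genes` (data.frame:
#'   `gene, locus, chrom, tss, cell_type, causal_stratum, beta_liability`)
#'   and `eqtl` (data.frame: `gene, variant, weight`).
#' @export
make_truth_table <- function(config, n_causal = 10, eqtl_per_gene = 3) {
  stopifnot(n_causal <= config$n_loci)
  if (config$h2_cis == 0 && n_causal > 0)
    stopf("configuration error: h2_cis = 0 with causal genes leaves no detectable signal")
  lay <- locus_layout(config)
  vt <- variant_table(config, "EUR")  # positions/keys are ancestry-invariant
  genes <- expand.grid(gidx = seq_len(config$n_genes), locus = seq_len(config$n_loci))
  genes$gene <- sprintf("G%03d", seq_len(nrow(genes)))
  genes$chrom <- lay$chrom[genes$locus]
  # TSS inside the locus, genes of one locus within ~tens of kb of each other
  genes$tss <- lay$base[genes$locus] + config$n_variants * 1000 +
    (genes$gidx - 1L) * 25000
  genes$cell_type <- config$cell_types[
    ((seq_len(nrow(genes)) - 1L) %% length(config$cell_types)) + 1L]

  genes$causal_stratum <- "none"
  genes$beta_liability <- 0
  with_seed(derive_seed(config$seed, "truth"), {
    causal_rows <- which(genes$gidx == 1L & genes$locus <= n_causal)
    n_specific <- round(config$stratum_specificity * n_causal)
    strata <- c(rep(c("carrier", "non-carrier"), length.out = n_specific),
                rep("both", n_causal - n_specific))
    genes$causal_stratum[causal_rows] <- strata
    genes$beta_liability[causal_rows] <-
      config$beta_liability * sample(c(-1, 1), n_causal, replace = TRUE)
    eqtl <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      ## each gene is regulated by its own block of the locus, so co-located
      ## genes have (near-)independent cis architectures under AR(1) LD decay
      loc_vars <- vt$variant[vt$locus == genes$locus[i]]
      blocks <- split(loc_vars, cut(seq_along(loc_vars), config$n_genes,
                                    labels = FALSE))
      mine <- blocks[[genes$gidx[i]]]
      k <- min(eqtl_per_gene, length(mine))
      data.frame(gene = genes$gene[i],
                 variant = sort(sample(mine, k)),
                 weight = rnorm(k))
    }))
    structure(list(genes = genes[, c("gene", "locus", "chrom", "tss", "cell_type",
                                     "causal_stratum", "beta_liability")],
                   eqtl = eqtl),
              class = "truth_table")
  })
}

#' @exportS3Method base::print
print.truth_table <- function(x, ...) {
  cat("<truth_table>", nrow(x$genes), "genes (",
      sum(x$genes$causal_stratum != "none"), "causal ),",
      nrow(x$eqtl), "eQTL weights\n")
  invisible(x)
}
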