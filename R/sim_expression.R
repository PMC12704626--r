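#' Simulate expression, pseudobulk counts and disease phenotypes
#'
#' Latent expression of each cis gene is its genotype score (cis variants x
#' weights, rescaled so the genetic component has variance `h2_cis`) plus
#' Gaussian noise of variance `1 - h2_cis`.  Disease status is Bernoulli with
#' log-odds `intercept + sum(beta_liability * latent_g)` where each causal
#' gene's beta is applied only to subjects in its causal stratum.  Pseudobulk
#' counts per cell type are negative-binomial with mean
#' `exp(library offset + gene baseline + latent)`; background genes carry
#' pure-noise latents.  A quantitative pathology score (liability + noise) is
#' returned alongside the binary label.
#'
#' @param genotypes n x variants dosage matrix (columns named by variant key).
#' @param truth a [make_truth_table()] object.
#' @param config the [sim_config()].
#' @param stratum `NULL` for a mixed cohort (carrier status drawn with
#'   `carrier_prob`), or `"carrier"` / `"non-carrier"` to force one stratum.
#' @param counts if `FALSE`, skip count generation (GWAS cohorts only need
#'   phenotypes).
#' @param seed_tag extra label mixed into the random stream so distinct
#'   cohorts get distinct draws.
#' @param lib_log_mean mean of the per-sample log library-size offset;
#'   shifting it by `log(2)` doubles expected totals (same random stream).
#' @return list with `labels` (0/1 disease status), `pathology`
#'   (quantitative), `covariates` (sex, age, pmi, batch, apoe2, apoe4,
#'   stratum), `latent` (subjects x cis genes), `weights_used` (list of
#'   effective scaled weight vectors; at `h2_cis = 1` latent equals
#'   `genotypes %*% weights_used[[g]]` exactly), and `counts` (named list of
#'   gene x sample matrices per cell type, or `NULL`).
#' @export
simulate_expression_and_phenotype <- function(genotypes, truth, config,
                                              stratum = NULL, counts = TRUE,
                                              seed_tag = "cohort",
                                              lib_log_mean = log(200)) {
  validate_sim_config(config)
  genes <- truth$genes
  if (config$h2_cis == 0 && any(genes$causal_stratum != "none"))
    stopf("configuration error: h2_cis = 0 makes causal-gene signal undetectable")
  missing_v <- setdiff(truth$eqtl$variant, colnames(genotypes))
  if (length(missing_v))
    stopf("truth table references variants absent from genotypes: %s",
          paste(head(missing_v, 3), collapse = ", "))
  n <- nrow(genotypes)
  with_seed(derive_seed(config$seed, "expr", seed_tag, stratum %||% "mixed", n), {
    ## covariates
    apoe4 <- if (is.null(stratum)) {
      carrier <- rbinom(n, 1, config$carrier_prob)
      ifelse(carrier == 1, 1 + rbinom(n, 1, 0.2), 0)
    } else if (stratum == "carrier") 1 + rbinom(n, 1, 0.2) else rep(0L, n)
    covariates <- data.frame(
      sex = rbinom(n, 1, 0.5),
      age = rnorm(n, 75, 8),
      pmi = pmax(rnorm(n, 7, 2), 0.5),
      batch = sample(c("b1", "b2", "b3"), n, replace = TRUE),
      apoe2 = rbinom(n, 2, 0.07),
      apoe4 = apoe4)
    covariates$stratum <- ifelse(apoe4 > 0, "carrier", "non-carrier")

    ## latent expression per cis gene
    latent <- matrix(NA_real_, n, nrow(genes), dimnames = list(NULL, genes$gene))
    weights_used <- vector("list", nrow(genes))
    names(weights_used) <- genes$gene
    for (i in seq_len(nrow(genes))) {
      eq <- truth$eqtl[truth$eqtl$gene == genes$gene[i], ]
      Gsub <- genotypes[, eq$variant, drop = FALSE]
      if (anyNA(Gsub))  # dosages masked for genotyping-rate fixtures
        Gsub <- apply(Gsub, 2, function(g) { g[is.na(g)] <- mean(g, na.rm = TRUE); g })
      gscore <- as.vector(Gsub %*% eq$weight)
      s <- sd(gscore)
      w <- if (s > 0) eq$weight * sqrt(config$h2_cis) / s else eq$weight * 0
      names(w) <- eq$variant
      weights_used[[i]] <- w
      gpart <- if (s > 0) gscore * sqrt(config$h2_cis) / s else gscore * 0
      noise <- if (config$h2_cis < 1) rnorm(n, 0, sqrt(1 - config$h2_cis)) else 0
      latent[, i] <- gpart + noise
    }

    ## disease liability: causal betas act only in their causal stratum
    eta <- rep(config$prevalence_logit_intercept, n)
    lia <- numeric(n)
    for (i in which(genes$causal_stratum != "none")) {
      in_str <- switch(genes$causal_stratum[i],
                       both = rep(TRUE, n),
                       carrier = covariates$stratum == "carrier",
                       `non-carrier` = covariates$stratum == "non-carrier")
      lia <- lia + genes$beta_liability[i] * latent[, i] * in_str
    }
    eta <- eta + lia
    labels <- rbinom(n, 1, 1 / (1 + exp(-eta)))
    pathology <- as.vector(scale(lia + rnorm(n)))

    ## pseudobulk counts
    cts <- NULL
    if (counts) {
      log_lib <- rnorm(n, lib_log_mean, 0.3)
      cts <- lapply(config$cell_types, function(ct) {
        cis <- genes$gene[genes$cell_type == ct]
        bg <- sprintf("BG_%s_%02d", ct, seq_len(config$n_background_genes))
        gene_ids <- c(cis, bg)
        base <- rnorm(length(gene_ids), 0, 0.5)
        lat <- cbind(latent[, cis, drop = FALSE],
                     matrix(rnorm(n * length(bg)), n, length(bg),
                            dimnames = list(NULL, bg)))
        mu <- exp(outer(log_lib, base, "+") + lat)
        cm <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                     nrow = n)
        dimnames(cm) <- list(NULL, gene_ids)
        t(cm)  # genes x samples
      })
      names(cts) <- config$cell_types
    }
    list(labels = labels, pathology = pathology, covariates = covariates,
         latent = latent, weights_used = weights_used, counts = cts,
         library_offset = if (counts) log_lib else NULL)
  })
}
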