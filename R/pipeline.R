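#' Run the full stratified cTWAS discovery-and-prioritization pipeline
#'
#' Chains every stage against a fixture bundle: harmonization and
#' genotyping-rate filtering of cohort summary statistics against the anchor
#' set, fixed-effects meta-analysis of the primary-ancestry cohorts,
#' cell-type TWAS in both APOE*4 strata, FDR and heterogeneity filtering with
#' locus exclusion, then the six prioritization layers (cross-ancestry
#' consistency, colocalization, SMR+HEIDI, open-chromatin overlap, and
#' non-stratified / stratified differential expression), evidence profiles,
#' and drug-target enrichment per stratum.  Deterministic given the config
#' seed; every output table is written to `outdir` together with a run
#' manifest recording the config hash, seed and all thresholds applied.
#'
#' @param config a [sim_config()]; used to generate the bundle when
#'   `bundle_dir` is `NULL` and to derive all analysis random streams.
#' @param outdir results directory (created).
#' @param bundle_dir optional pre-built bundle (from
#'   [emit_fixture_bundle()]); default generates one under
#'   `file.path(outdir, "bundle")`.
#' @param n_causal causal genes when generating the bundle.
#' @param fdr_alpha FDR level for discovery and support rules.
#' @param pp4_tiers suggestive/strong PP4 thresholds.
#' @param r2_proxy LD r-squared threshold for open-chromatin proxies.
#' @param fc_ratio stratified differential-expression fold-change ratio.
#' @param min_overlap minimum prioritized-gene overlap for an enriched
#'   compound.
#' @return list with all stage tables (`ctwas`, `filtered`, `coloc`, `smr`,
#'   `deg`, `overlap`, `profiles`, `enrichment`, `recovery`, `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         bundle_dir = NULL,
                         n_causal = min(10L, config$n_loci %/% 2L),
                         fdr_alpha = 0.05,
                         pp4_tiers = c(suggestive = 0.4, strong = 0.7),
                         r2_proxy = 0.8, fc_ratio = 1.5, min_overlap = 2) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(bundle_dir)) {
    bundle_dir <- file.path(outdir, "bundle")
    message("pipeline: generating fixture bundle under ", bundle_dir)
    bundle <- emit_fixture_bundle(config, bundle_dir, n_causal = n_causal)
  } else {
    bundle <- read_bundle(bundle_dir)
  }
  needed <- c("sumstats", "anchor", "weights", "eqtl", "ld", "counts",
              "covariates", "peaks", "gmt", "druggable", "edges")
  for (nm in needed) if (is.null(bundle[[nm]]) || length(bundle[[nm]]) == 0)
    stopf("pipeline pre-flight: bundle is missing '%s'", nm)

  ## ---- stage 1: harmonize, intersect/rate-filter, meta-analyze EUR
  message("pipeline: harmonization and meta-analysis")
  harm <- lapply(bundle$sumstats, function(st) harmonize_stats(st, bundle$anchor)$stats)
  eur_names <- grep("^EUR", names(harm), value = TRUE)
  keys <- filter_variants(harm[eur_names], bundle$anchor, min_rate = 0.9)
  meta <- list(
    carrier = meta_stats_table(harm[grep("^EUR.*_carrier$", names(harm))], keys),
    `non-carrier` = meta_stats_table(harm[grep("^EUR.*_noncarrier$", names(harm))], keys))
  afr <- list(carrier = harm[["AFR_CC_carrier"]],
              `non-carrier` = harm[["AFR_CC_noncarrier"]])
  n_eff <- list(
    EUR = vapply(meta, function(m) median(m$n_eff), 0),
    AFR = vapply(afr, function(a)
      median(effective_n(a$n_cases, a$n_controls, a$is_proxy)), 0))

  ## ---- stage 2: cTWAS in both strata, FDR + heterogeneity + locus rule
  message("pipeline: cell-type TWAS and stratum filtering")
  ctwas <- run_ctwas(bundle$weights, meta, bundle$ld$EUR)
  ctwas <- add_heterogeneity(ctwas, alpha = fdr_alpha)
  sig <- !is.na(pmin(ctwas$q_carrier, ctwas$q_noncarrier)) &
    pmin(ctwas$q_carrier, ctwas$q_noncarrier) < fdr_alpha
  filtered <- ctwas[0, ]
  if (any(sig)) {
    cand <- ctwas[sig, , drop = FALSE]
    cand$locus <- cluster_loci(cand$chrom, cand$tss)
    filtered <- locus_exclusion(cand)
  }
  if (nrow(filtered) == 0) message("pipeline: no pairs pass the heterogeneity filter")

  ## ---- stage 3: six prioritization layers per retained pair
  message("pipeline: prioritization layers for ", nrow(filtered), " pairs")
  afr_ctwas <- run_ctwas(bundle$weights[unique(filtered$gene)], afr, bundle$ld$AFR)
  deg <- run_deg_stage(bundle, fdr_alpha, fc_ratio)
  layers <- with_seed(derive_seed(config$seed, "layers"),
                      lapply(seq_len(nrow(filtered)), function(i)
                        pair_layers(filtered[i, ], bundle, meta, afr_ctwas,
                                    n_eff, deg, fdr_alpha, r2_proxy)))
  coloc_tab <- do.call(rbind, lapply(layers, `[[`, "coloc_row"))
  smr_tab <- do.call(rbind, lapply(layers, `[[`, "smr_row"))
  overlap_tab <- do.call(rbind, lapply(layers, `[[`, "overlap_row"))
  if (!is.null(smr_tab) && nrow(smr_tab)) {
    smr_tab$p_smr_fdr <- bh_fdr(smr_tab$p_smr)
    smr_tab$support <- smr_support(smr_tab$p_smr_fdr, smr_tab$p_heidi, fdr_alpha)
  }

  profiles <- do.call(rbind, lapply(seq_len(nrow(filtered)), function(i) {
    pr <- filtered[i, ]
    ep <- evidence_profile(
      cross_ancestry = layers[[i]]$cross_ancestry,
      coloc = coloc_tab$tier[i] %in% c("suggestive", "strong"),
      smr = if (nrow(smr_tab)) smr_tab$support[i] else NA,
      atac = overlap_tab$hit[i],
      deg_nonstratified = layers[[i]]$deg_nonstrat,
      deg_stratified = layers[[i]]$deg_strat)
    data.frame(gene = pr$gene, cell_type = pr$cell_type,
               stratum = pr$heterogeneity_stratum,
               t(as.matrix(ep$flags * 1L)),
               support_count = ep$support_count, tier = ep$tier,
               stringsAsFactors = FALSE)
  }))

  ## ---- stage 4: druggable intersection, network expansion, enrichment
  message("pipeline: drug-target analyses")
  universe <- unique(c(bundle$truth$genes$gene,
                       unlist(lapply(bundle$counts, rownames))))
  enrichment <- list()
  for (s in c("carrier", "non-carrier")) {
    seeds <- unique(profiles$gene[profiles$stratum == s &
                                    profiles$tier == "more_than_half"])
    if (length(seeds) == 0) next
    tier1 <- druggable_intersect(seeds, bundle$druggable)
    expanded <- network_expand(seeds, bundle$edges, bundle$druggable)
    enr <- drug_enrichment(expanded, bundle$gmt, universe,
                           min_overlap = min_overlap, prioritized = seeds,
                           alpha = fdr_alpha)
    enrichment[[s]] <- list(seeds = seeds, tier1_druggable = tier1,
                            expanded = expanded, table = enr$table,
                            significant = enr$significant)
  }

  recovery <- evaluate_recovery(filtered, ctwas, bundle$truth)

  ## ---- outputs + manifest
  res <- list(ctwas = ctwas, filtered = filtered, coloc = coloc_tab,
              smr = smr_tab, deg = deg$table, overlap = overlap_tab,
              profiles = profiles, enrichment = enrichment,
              recovery = recovery)
  write_tsv(ctwas, file.path(outdir, "ctwas_pairs.tsv"))
  write_tsv(filtered, file.path(outdir, "filtered_pairs.tsv"))
  if (!is.null(coloc_tab)) write_tsv(coloc_tab, file.path(outdir, "coloc.tsv"))
  if (!is.null(smr_tab)) write_tsv(smr_tab, file.path(outdir, "smr.tsv"))
  if (!is.null(overlap_tab)) write_tsv(overlap_tab, file.path(outdir, "overlap.tsv"))
  write_tsv(deg$table, file.path(outdir, "deg.tsv"))
  if (!is.null(profiles)) write_tsv(profiles, file.path(outdir, "profiles.tsv"))
  for (s in names(enrichment))
    write_tsv(enrichment[[s]]$table,
              file.path(outdir, sprintf("enrichment_%s.tsv", sub("-", "", s))))
  cfg_json <- toJSON(unclass(config), auto_unbox = TRUE)
  manifest <- list(seed = config$seed, config_hash = fnv1a(cfg_json),
                   config = unclass(config),
                   thresholds = list(fdr_alpha = fdr_alpha,
                                     pp4_suggestive = unname(pp4_tiers["suggestive"]),
                                     pp4_strong = unname(pp4_tiers["strong"]),
                                     r2_proxy = r2_proxy, fc_ratio = fc_ratio,
                                     min_overlap = min_overlap,
                                     min_geno_rate = 0.9),
                   n_retained_variants = length(keys),
                   n_pairs_tested = nrow(ctwas),
                   n_pairs_filtered = nrow(filtered))
  write_json(manifest, file.path(outdir, "run_manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res
}

# Differential-expression stage: non-stratified plus per-stratum fits for
# both phenotypes (binary status and quantitative pathology), all cell types.
run_deg_stage <- function(bundle, fdr_alpha, fc_ratio) {
  cov <- bundle$covariates
  phenos <- list(ad_status = cov$ad_status, pathology = cov$pathology)
  covars <- cov[, c("sex", "pmi", "age", "apoe2", "apoe4", "batch")]
  scopes <- list(nonstratified = seq_len(nrow(cov)),
                 carrier = which(cov$stratum == "carrier"),
                 `non-carrier` = which(cov$stratum == "non-carrier"))
  rows <- list()
  for (ct in names(bundle$counts)) {
    counts <- bundle$counts[[ct]]
    for (sc in names(scopes)) {
      idx <- scopes[[sc]]
      lc <- cpm_log2(counts[, idx, drop = FALSE])
      for (ph in names(phenos)) {
        fit <- suppressMessages(
          fit_de(lc, phenos[[ph]][idx], covars[idx, , drop = FALSE]))
        fit$cell_type <- ct; fit$scope <- sc; fit$phenotype <- ph
        rows[[length(rows) + 1L]] <- fit
      }
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, fc_ratio = fc_ratio)
}

# Evaluate the six evidence layers for one retained pair.
pair_layers <- function(pair, bundle, meta, afr_ctwas, n_eff, deg,
                        fdr_alpha, r2_proxy) {
  s <- pair$heterogeneity_stratum
  o <- setdiff(c("carrier", "non-carrier"), s)
  ws <- bundle$weights[[pair$gene]]

  ## cross-ancestry consistency
  ar <- afr_ctwas[afr_ctwas$gene == pair$gene &
                    afr_ctwas$cell_type == pair$cell_type, ]
  cross <- if (nrow(ar) == 1) {
    zp <- c(carrier = pair$z_carrier, `non-carrier` = pair$z_noncarrier)
    zs <- c(carrier = ar$z_carrier, `non-carrier` = ar$z_noncarrier)
    cross_ancestry_consistent(zp, zs, n_eff$EUR, n_eff$AFR, respective = s)
  } else NA

  ## colocalization over the gene's cis window (two prior schemes)
  gslice <- meta[[s]]
  gslice <- gslice[match(ws$variants, gslice$variant), ]
  eslice <- bundle$eqtl[bundle$eqtl$GENE == pair$gene, ]
  eslice <- eslice[match(ws$variants, eslice$VARIANT), ]
  ok <- !is.na(gslice$beta) & !is.na(eslice$BETA)
  l1 <- wakefield_labf(gslice$beta[ok], gslice$se[ok], 0.2)
  l2 <- wakefield_labf(eslice$BETA[ok], eslice$SE[ok], 0.15)
  names(l1) <- names(l2) <- ws$variants[ok]
  schemes <- coloc_schemes()
  cres <- lapply(names(schemes), function(nm)
    coloc_abf(l1, l2, schemes[[nm]]["p1"], schemes[[nm]]["p2"],
              schemes[[nm]]["p12"], scheme_tag = nm))
  best <- best_pp4(cres)
  coloc_row <- data.frame(gene = pair$gene, cell_type = pair$cell_type,
                          stratum = s, pp4_best = best$pp4_best,
                          tier = best$tier, scheme = best$scheme_tag,
                          top_variant = best$top_variant,
                          stringsAsFactors = FALSE)

  ## SMR + HEIDI at the top cis eQTL
  gw <- data.frame(variant = ws$variants[ok], beta = gslice$beta[ok],
                   se = gslice$se[ok], z = gslice$z[ok])
  eq <- data.frame(variant = ws$variants[ok], beta = eslice$BETA[ok],
                   se = eslice$SE[ok], z = eslice$Z[ok])
  top <- which.max(abs(eq$z))
  smr <- smr_test(gw$beta[top], gw$se[top], eq$beta[top], eq$se[top])
  heidi <- suppressMessages(
    heidi_test(gw, eq, bundle$ld$EUR[gw$variant, gw$variant]))
  smr_row <- data.frame(gene = pair$gene, cell_type = pair$cell_type,
                        stratum = s, top_eqtl = heidi$top_variant,
                        b_xy = smr$b_xy, t_smr = smr$t_smr, p_smr = smr$p_smr,
                        p_heidi = heidi$p_heidi, n_heidi_snps = heidi$n_snps,
                        stringsAsFactors = FALSE)

  ## open-chromatin overlap of top coloc variant + LD proxies
  hit <- NA
  if (coloc_row$tier != "none") {
    prox <- ld_proxies(best$top_variant, bundle$ld$EUR, r2_min = r2_proxy)
    vv <- bundle$anchor[bundle$anchor$variant %in% prox, c("variant", "chrom", "pos")]
    hit <- tryCatch(peak_overlap(vv, bundle$peaks, pair$cell_type)$any,
                    warning = function(w) FALSE)
  }
  overlap_row <- data.frame(gene = pair$gene, cell_type = pair$cell_type,
                            stratum = s, hit = isTRUE(hit),
                            stringsAsFactors = FALSE)

  ## differential-expression support (any phenotype)
  dt <- deg$table
  dsel <- function(scope, ph) dt[dt$gene == pair$gene &
                                   dt$cell_type == pair$cell_type &
                                   dt$scope == scope & dt$phenotype == ph, ]
  deg_ns <- any(vapply(unique(dt$phenotype), function(ph)
    isTRUE(deg_support(dsel("nonstratified", ph)$p)), TRUE))
  deg_st <- any(vapply(unique(dt$phenotype), function(ph) {
    a <- dsel(s, ph); b <- dsel(o, ph)
    if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
    isTRUE(deg_support(a$p, a$logFC, b$logFC, fc_ratio = deg$fc_ratio))
  }, TRUE))

  list(cross_ancestry = cross, coloc_row = coloc_row, smr_row = smr_row,
       overlap_row = overlap_row, deg_nonstrat = deg_ns, deg_strat = deg_st)
}

#' Recovery of simulated causal genes by the heterogeneity filter
#'
#' @param filtered retained pairs (from the locus-exclusion stage).
#' @param ctwas the full tested pair table.
#' @param truth the simulation `truth_table`.
#' @return list: `causal_recovered / causal_total` (causal genes recovered in
#'   their correct stratum), `recovery_rate`, `null_retained / null_tested`,
#'   `null_rate`.
#' @export
evaluate_recovery <- function(filtered, ctwas, truth) {
  causal <- truth$genes[truth$genes$causal_stratum != "none", ]
  tested <- intersect(causal$gene, ctwas$gene)
  hit <- vapply(seq_len(nrow(causal)), function(i) {
    g <- causal$gene[i]; s <- causal$causal_stratum[i]
    any(filtered$gene == g &
          (filtered$heterogeneity_stratum == s | s == "both"))
  }, TRUE)
  null_genes <- truth$genes$gene[truth$genes$causal_stratum == "none"]
  null_tested <- sum(ctwas$gene %in% null_genes)
  null_retained <- sum(filtered$gene %in% null_genes)
  list(causal_recovered = sum(hit), causal_total = nrow(causal),
       causal_tested = length(tested),
       recovery_rate = sum(hit) / nrow(causal),
       null_retained = null_retained, null_tested = null_tested,
       null_rate = if (null_tested > 0) null_retained / null_tested else 0)
}
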