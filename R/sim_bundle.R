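#' Emit a complete synthetic fixture bundle
#'
#' Generates every input the downstream analysis consumes, end-to-end, with
#' no external data: per-stratum GWAS summary statistics for a primary
#' case-control cohort, a proxy-phenotype cohort and a secondary-ancestry
#' cohort; an anchor variant table; cell-type expression weights and marginal
#' eQTL statistics fitted on a reference panel; LD matrices for both
#' ancestries; pseudobulk count matrices with sample covariates; open
#' chromatin peaks placed over each gene's eQTL variants in its own cell
#' type; compound gene sets seeded with the causal genes; an interaction
#' edge list; a druggable-gene list; and the simulation truth table.  A
#' fixed config seed yields a bit-identical bundle.
#'
#' @param config a [sim_config()].
#' @param outdir writable output directory (created if needed).
#' @param n_causal causal genes in the truth table (default 10, capped at
#'   half the loci).
#' @return (invisibly) the bundle as a list (same content as
#'   [read_bundle()] returns).
#' @export
emit_fixture_bundle <- function(config, outdir,
                                n_causal = min(10L, config$n_loci %/% 2L)) {
  validate_sim_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_truth_table(config, n_causal = n_causal)
  vt_eur <- variant_table(config, "EUR")

  ## ---- GWAS cohorts -> per-stratum summary statistics
  cohorts <- list(
    EUR_CC = list(ancestry = "EUR", n = 2L * config$n_per_stratum, proxy = FALSE),
    EUR_PROXY = list(ancestry = "EUR", n = config$n_per_stratum, proxy = TRUE),
    AFR_CC = list(ancestry = "AFR", n = config$n_per_stratum %/% 2L, proxy = FALSE))
  stats_files <- character(0)
  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    gt <- simulate_genotypes(config, stratum = nm, ancestry = ch$ancestry, n = ch$n)
    G <- gt$genotypes
    if (ch$proxy) {
      # a few low-genotyping-rate variants to exercise the >=90% filter
      with_seed(derive_seed(config$seed, "missing", nm), {
        drop_v <- sample(colnames(G), 3)
        for (v in drop_v) G[sample.int(nrow(G), round(0.12 * nrow(G))), v] <- NA
      })
    }
    sim <- simulate_expression_and_phenotype(G, truth, config, counts = FALSE,
                                             seed_tag = nm)
    gw <- run_stratified_gwas(G, gt$variants, sim$labels,
                              sim$covariates[, c("sex", "age")],
                              sim$covariates$stratum, is_proxy = ch$proxy)
    for (s in names(gw)) {
      f <- file.path(outdir, sprintf("sumstats_%s_%s.tsv", nm,
                                     sub("-", "", s)))
      write_sumstats(gw[[s]], f)
      stats_files <- c(stats_files, basename(f))
    }
  }

  ## ---- anchor variant set (primary case-control cohort)
  write_tsv(data.frame(VARIANT = vt_eur$variant, CHR = vt_eur$chrom,
                       POS = vt_eur$pos, A1 = vt_eur$a1, A2 = vt_eur$a2,
                       MAF = vt_eur$maf),
            file.path(outdir, "anchor_variants.tsv"))

  ## ---- reference panel: expression, weights, eQTL stats, LD
  ref_gt <- simulate_genotypes(config, stratum = "reference", ancestry = "EUR",
                               n = config$n_reference)
  ref <- simulate_expression_and_phenotype(ref_gt$genotypes, truth, config,
                                           counts = TRUE, seed_tag = "REF")
  for (ct in config$cell_types)
    write_counts(ref$counts[[ct]], file.path(outdir, sprintf("counts_%s.tsv", ct)))
  cov_out <- ref$covariates
  cov_out$ad_status <- ref$labels
  cov_out$pathology <- ref$pathology
  write_covariates(cov_out, file.path(outdir, "covariates_ref.tsv"))

  logcpm <- lapply(ref$counts, function(cm) cpm_log2(cm))
  expr_by_gene <- list(); geno_by_gene <- list()
  for (i in seq_len(nrow(truth$genes))) {
    g <- truth$genes$gene[i]
    ct <- truth$genes$cell_type[i]
    expr_by_gene[[g]] <- logcpm[[ct]][g, ]
    cis <- vt_eur$variant[vt_eur$locus == truth$genes$locus[i]]
    geno_by_gene[[g]] <- ref_gt$genotypes[, cis, drop = FALSE]
  }
  ws <- with_seed(derive_seed(config$seed, "weights"),
                  build_weights(expr_by_gene, geno_by_gene, truth$genes))
  ws <- lapply(ws, function(w) {
    m <- match(w$variants, vt_eur$variant)
    w$a1 <- vt_eur$a1[m]; w$a2 <- vt_eur$a2[m]; w
  })
  write_weights(ws, file.path(outdir, "weights.tsv"))

  eqtl <- do.call(rbind, lapply(names(expr_by_gene), function(g) {
    st <- eqtl_marginal(expr_by_gene[[g]], geno_by_gene[[g]])
    ct <- truth$genes$cell_type[match(g, truth$genes$gene)]
    data.frame(GENE = g, CELL_TYPE = ct, VARIANT = st$variant, BETA = st$beta,
               SE = st$se, Z = st$z, P = st$p, stringsAsFactors = FALSE)
  }))
  write_tsv(eqtl, file.path(outdir, "eqtl_stats.tsv"))

  write_ld_matrix(cor(ref_gt$genotypes), file.path(outdir, "ld_EUR.tsv"))
  afr_gt <- simulate_genotypes(config, stratum = "reference", ancestry = "AFR",
                               n = 200L)
  write_ld_matrix(cor(afr_gt$genotypes), file.path(outdir, "ld_AFR.tsv"))

  ## ---- peaks over eQTL variants, matching cell type; plus decoys
  half <- config$peak_width %/% 2L
  eq <- merge(truth$eqtl, truth$genes[, c("gene", "cell_type")], by = "gene")
  m <- match(eq$variant, vt_eur$variant)
  peaks <- data.frame(chrom = vt_eur$chrom[m],
                      start = pmax(vt_eur$pos[m] - 1L - half, 0),
                      end = vt_eur$pos[m] - 1L - half + config$peak_width,
                      label = eq$cell_type)
  decoys <- with_seed(derive_seed(config$seed, "decoy-peaks"), {
    lay <- locus_layout(config)
    k <- 30L
    li <- sample.int(config$n_loci, k, replace = TRUE)
    st <- lay$base[li] + sample.int(config$n_variants * 2000L, k)
    data.frame(chrom = lay$chrom[li], start = st, end = st + config$peak_width,
               label = sample(config$cell_types, k, replace = TRUE))
  })
  peaks <- unique(rbind(peaks, decoys))
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  write_bed(peaks, file.path(outdir, "peaks.bed"))

  ## ---- compound sets, druggable list, interaction edges
  causal <- truth$genes[truth$genes$causal_stratum != "none", ]
  null_genes <- truth$genes$gene[truth$genes$causal_stratum == "none"]
  bg_genes <- unlist(lapply(config$cell_types, function(ct)
    sprintf("BG_%s_%02d", ct, seq_len(config$n_background_genes))))
  all_genes <- c(truth$genes$gene, bg_genes)
  gmt <- with_seed(derive_seed(config$seed, "gmt"), {
    sets <- list()
    for (s in c("carrier", "non-carrier")) {
      cg <- causal$gene[causal$causal_stratum %in% c(s, "both")]
      if (length(cg) == 0) next
      tag <- if (s == "carrier") "CAR" else "NON"
      for (k in 1:3)
        sets[[sprintf("CMPD_%s_%d", tag, k)]] <-
          c(cg, sample(bg_genes, 5))
    }
    for (k in 1:20)
      sets[[sprintf("CMPD_DECOY_%02d", k)]] <-
        sample(c(bg_genes, null_genes), 8)
    sets
  })
  write_gmt(gmt, file.path(outdir, "compounds.gmt"))
  druggable <- with_seed(derive_seed(config$seed, "druggable"), {
    unique(c(causal$gene, sample(bg_genes, length(bg_genes) %/% 2),
             sample(null_genes, length(null_genes) %/% 3)))
  })
  write_gene_list(druggable, file.path(outdir, "druggable.txt"))
  edges <- with_seed(derive_seed(config$seed, "edges"), {
    drug_bg <- intersect(bg_genes, druggable)
    seeded <- do.call(rbind, lapply(causal$gene, function(g)
      data.frame(gene_a = g, gene_b = sample(drug_bg, 2), source = "seeded")))
    noise <- data.frame(gene_a = sample(all_genes, 40, replace = TRUE),
                        gene_b = sample(all_genes, 40, replace = TRUE),
                        source = "noise")
    rbind(seeded, noise[noise$gene_a != noise$gene_b, ])
  })
  write_edges(edges, file.path(outdir, "edges.tsv"))
  write_truth_table(truth, file.path(outdir, "truth"))

  manifest <- list(config = unclass(config), n_causal = n_causal,
                   config_hash = fnv1a(toJSON(unclass(config), auto_unbox = TRUE)),
                   files = sort(list.files(outdir)))
  write_json(manifest, file.path(outdir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(read_bundle(outdir))
}

#' Load a fixture bundle from disk
#'
#' @param dir bundle directory written by [emit_fixture_bundle()].
#' @return list with `sumstats` (named list of cohort/stratum tables),
#'   `anchor`, `weights`, `eqtl`, `ld` (EUR/AFR), `counts`, `covariates`,
#'   `peaks`, `gmt`, `druggable`, `edges`, `truth`, `manifest`.
#' @export
read_bundle <- function(dir) {
  manifest <- read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  cts <- manifest$config$cell_types
  ss_files <- list.files(dir, pattern = "^sumstats_.*\\.tsv$")
  sumstats <- lapply(ss_files, function(f)
    suppressWarnings(read_sumstats(file.path(dir, f))))
  names(sumstats) <- sub("^sumstats_(.*)\\.tsv$", "\\1", ss_files)
  anchor_raw <- read_tsv_checked(file.path(dir, "anchor_variants.tsv"),
                                 c("VARIANT", "CHR", "POS", "A1", "A2", "MAF"),
                                 numeric_cols = c("POS", "MAF"))
  anchor <- data.frame(variant = anchor_raw$VARIANT, chrom = anchor_raw$CHR,
                       pos = anchor_raw$POS, a1 = anchor_raw$A1,
                       a2 = anchor_raw$A2, maf = anchor_raw$MAF,
                       stringsAsFactors = FALSE)
  counts <- lapply(cts, function(ct) read_counts(file.path(dir, sprintf("counts_%s.tsv", ct))))
  names(counts) <- cts
  eqtl_raw <- read_tsv_checked(file.path(dir, "eqtl_stats.tsv"),
                               c("GENE", "CELL_TYPE", "VARIANT", "BETA", "SE", "Z", "P"),
                               numeric_cols = c("BETA", "SE", "Z", "P"))
  list(sumstats = sumstats, anchor = anchor,
       weights = suppressWarnings(read_weights(file.path(dir, "weights.tsv"))),
       eqtl = eqtl_raw,
       ld = list(EUR = read_ld_matrix(file.path(dir, "ld_EUR.tsv")),
                 AFR = read_ld_matrix(file.path(dir, "ld_AFR.tsv"))),
       counts = counts,
       covariates = read_covariates(file.path(dir, "covariates_ref.tsv")),
       peaks = read_bed(file.path(dir, "peaks.bed")),
       gmt = read_gmt(file.path(dir, "compounds.gmt")),
       druggable = read_gene_list(file.path(dir, "druggable.txt")),
       edges = suppressWarnings(read_edges(file.path(dir, "edges.tsv"))),
       truth = read_truth_table(file.path(dir, "truth")),
       manifest = manifest)
}
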