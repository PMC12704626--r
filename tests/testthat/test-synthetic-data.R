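test_that("invalid configurations are rejected", {
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(h2_cis = 1.2), "h2_cis")
  expect_error(sim_config(n_loci = 0), "counts")
  cfg0 <- tiny_config(h2_cis = 0)
  expect_error(make_truth_table(cfg0, n_causal = 2), "undetectable|signal")
})

test_that("genotypes respect the configured LD structure", {
  cfg0 <- sim_config(n_per_stratum = 100, n_variants = 10, n_loci = 2,
                     ld_rho = 0, seed = 3)
  g0 <- simulate_genotypes(cfg0, n = 5000)$genotypes
  adj <- sapply(seq_len(9), function(j) cor(g0[, j], g0[, j + 1]))
  expect_lt(max(abs(adj)), 0.05)

  # Monte-Carlo oracle for one adjacent pair under the same copula
  cfg9 <- sim_config(n_per_stratum = 100, n_variants = 6, n_loci = 1,
                     ld_rho = 0.9, maf_range = c(0.3, 0.3001), seed = 3)
  g9 <- simulate_genotypes(cfg9, n = 5000)$genotypes
  r_emp <- cor(g9[, 1], g9[, 2])
  oracle <- local({
    set.seed(99)
    n <- 1e6
    thr <- qnorm(0.3)
    z1a <- rnorm(n); z2a <- 0.9 * z1a + sqrt(1 - 0.81) * rnorm(n)
    z1b <- rnorm(n); z2b <- 0.9 * z1b + sqrt(1 - 0.81) * rnorm(n)
    ga <- (z1a < thr) + (z1b < thr)
    gb <- (z2a < thr) + (z2b < thr)
    cor(ga, gb)
  })
  expect_lt(abs(r_emp - oracle), 0.1)
})

test_that("generation is deterministic and frequencies match the config", {
  cfg <- tiny_config()
  a <- simulate_genotypes(cfg, "carrier", "EUR", n = 400)
  b <- simulate_genotypes(cfg, "carrier", "EUR", n = 400)
  expect_identical(a, b)
  big <- simulate_genotypes(cfg, n = 4000)
  emp <- colMeans(big$genotypes) / 2
  tol <- 3 * sqrt(0.25 / (2 * 4000))
  expect_true(all(emp >= cfg$maf_range[1] - tol & emp <= cfg$maf_range[2] + tol))
  # positions strictly increasing within chromosome
  vt <- big$variants
  for (ch in unique(vt$chrom))
    expect_true(all(diff(vt$pos[vt$chrom == ch]) > 0))
})

test_that("phenotype model matches its stated structure", {
  cfg <- sim_config(n_per_stratum = 100, n_variants = 8, n_loci = 4,
                    beta_liability = 0, prevalence_logit_intercept = -0.8,
                    seed = 5)
  truth <- make_truth_table(cfg, n_causal = 0)
  gt <- simulate_genotypes(cfg, n = 10000)
  sim <- simulate_expression_and_phenotype(gt$genotypes, truth, cfg,
                                           counts = FALSE)
  p0 <- 1 / (1 + exp(0.8))
  ci <- p0 + c(-4, 4) * sqrt(p0 * (1 - p0) / 10000)
  expect_gt(mean(sim$labels), ci[1])
  expect_lt(mean(sim$labels), ci[2])

  # degenerate noise: latent expression is exactly genotype %*% weights
  cfg1 <- tiny_config(h2_cis = 1)
  truth1 <- make_truth_table(cfg1, n_causal = 2)
  gt1 <- simulate_genotypes(cfg1, n = 150)
  sim1 <- simulate_expression_and_phenotype(gt1$genotypes, truth1, cfg1,
                                            counts = FALSE)
  g <- truth1$genes$gene[1]
  w <- sim1$weights_used[[g]]
  expect_equal(unname(sim1$latent[, g]),
               unname(as.vector(gt1$genotypes[, names(w)] %*% w)))
})

test_that("library-size offset propagates into total counts", {
  cfg <- tiny_config()
  truth <- make_truth_table(cfg, n_causal = 2)
  gt <- simulate_genotypes(cfg, n = 200)
  s1 <- simulate_expression_and_phenotype(gt$genotypes, truth, cfg,
                                          lib_log_mean = log(200))
  s2 <- simulate_expression_and_phenotype(gt$genotypes, truth, cfg,
                                          lib_log_mean = log(400))
  d <- mean(log(colSums(s2$counts[[1]])) - log(colSums(s1$counts[[1]])))
  expect_lt(abs(d - log(2)), 0.1)
})

test_that("fixture bundle round-trips and is internally consistent", {
  cfg <- tiny_config()
  dir <- file.path(tempdir(), "bundle_rt")
  bundle <- suppressMessages(emit_fixture_bundle(cfg, dir))
  back <- suppressMessages(read_bundle(dir))
  expect_identical(bundle$anchor, back$anchor)
  expect_identical(bundle$sumstats, back$sumstats)
  expect_identical(bundle$gmt, back$gmt)
  expect_equal(bundle$ld$EUR, back$ld$EUR)

  # every eQTL variant lies inside >=1 peak of the gene's own cell type
  eq <- merge(bundle$truth$eqtl, bundle$truth$genes[, c("gene", "cell_type")],
              by = "gene")
  pos <- as.numeric(sub(".*:", "", eq$variant))
  chrom <- as.integer(sub(":.*", "", eq$variant))
  for (i in seq_len(nrow(eq))) {
    ov <- peak_overlap(data.frame(chrom = chrom[i], pos = pos[i]),
                       bundle$peaks, eq$cell_type[i])
    expect_true(ov$any, info = eq$variant[i])
  }
  # every compound set has at least 2 genes
  expect_true(all(lengths(bundle$gmt) >= 2))

  # fixed seed => bit-identical bundle files
  dir2 <- file.path(tempdir(), "bundle_rt2")
  suppressMessages(emit_fixture_bundle(cfg, dir2))
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
})
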