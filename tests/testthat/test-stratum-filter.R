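test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.031), 0.031)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("heterogeneity criterion reproduces its rule table", {
  # (1) significant in s, non-significant same-direction in other
  expect_true(heterogeneity_flag(q_s = 0.01, z_s = 2.5, p_other = 0.5, z_other = 0.3))
  # significant same-direction in both strata -> not heterogeneous
  expect_false(heterogeneity_flag(0.01, 2.5, 0.001, 3.3))
  # (2) opposite direction in other stratum, even if significant
  expect_true(heterogeneity_flag(0.01, 2.5, 0.001, -3.3))
  # not FDR-significant in s
  expect_false(heterogeneity_flag(0.2, 2.5, 0.5, 0.3))
  # zero z in other stratum counts as same-direction
  expect_true(heterogeneity_flag(0.01, 2.5, 0.5, 0))
  expect_false(heterogeneity_flag(0.01, 2.5, 0.001, 0))
  # missing other-stratum result -> FALSE
  expect_false(heterogeneity_flag(0.01, 2.5, NA, NA))
})

test_that("locus clustering is single linkage with 1 Mb reach", {
  expect_equal(cluster_loci(rep(1, 3), c(1.0e6, 1.8e6, 3.5e6)), c(1, 1, 2))
  expect_equal(cluster_loci(1, 5e6), 1L)
  # transitive chaining: 1.0, 1.9, 2.8 all linked
  expect_equal(cluster_loci(rep(1, 3), c(1.0e6, 1.9e6, 2.8e6)), c(1, 1, 1))
  # chromosomes never merge
  expect_equal(cluster_loci(c(1, 2), c(1e6, 1e6)), c(1, 2))
})

make_locus_pairs <- function(top_flagged) {
  # 3 genes at one locus; gene A is most significant
  df <- data.frame(
    gene = c("A", "B", "C"), cell_type = "Ast", chrom = 1,
    tss = c(1.0e6, 1.2e6, 1.4e6), n_variants = 5,
    z_carrier = c(6, 4, 3.5), p_carrier = c(1e-9, 1e-4, 5e-4),
    z_noncarrier = if (top_flagged) c(0.5, 0.4, 3.4) else c(4.5, 0.4, 3.4),
    p_noncarrier = if (top_flagged) c(0.6, 0.7, 6e-4) else c(1e-5, 0.7, 6e-4),
    stringsAsFactors = FALSE)
  df <- add_heterogeneity(df)
  df$locus <- cluster_loci(df$chrom, df$tss)
  df
}

test_that("locus exclusion retains flagged members only when the top gene is biased", {
  flagged <- make_locus_pairs(top_flagged = TRUE)
  kept <- locus_exclusion(flagged)
  # A and B are carrier-biased; C is significant same-direction in both
  expect_setequal(kept$gene, c("A", "B"))
  expect_false("C" %in% kept$gene)

  unflagged <- make_locus_pairs(top_flagged = FALSE)
  expect_false(unflagged$flag_carrier[1])   # top gene significant in both
  kept2 <- locus_exclusion(unflagged)
  expect_equal(nrow(kept2), 0)

  single <- flagged[1, ]
  single$locus <- 1
  expect_equal(nrow(locus_exclusion(single)), 1)
})

test_that("locus exclusion never retains a pair the heterogeneity flag rejects", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    df <- data.frame(
      gene = LETTERS[1:k], cell_type = "Exc", chrom = 1,
      tss = sort(runif(k, 1e6, 2.5e6)), n_variants = 5,
      z_carrier = rnorm(k, 0, 3), p_carrier = runif(k)^3,
      z_noncarrier = rnorm(k, 0, 3), p_noncarrier = runif(k)^3,
      stringsAsFactors = FALSE)
    df <- add_heterogeneity(df)
    df$locus <- cluster_loci(df$chrom, df$tss)
    kept <- suppressMessages(locus_exclusion(df))
    expect_true(all(kept$heterogeneity_stratum != "none"))
  }
})

test_that("cross-ancestry consistency follows the Stouffer arithmetic", {
  zp <- c(carrier = 4.2, `non-carrier` = 0.8)
  np <- c(carrier = 20000, `non-carrier` = 25000)
  ns <- c(carrier = 2000, `non-carrier` = 2500)
  # supportive secondary z, opposite stratum stays null
  expect_true(cross_ancestry_consistent(zp, c(carrier = 2.0, `non-carrier` = 0.1),
                                        np, ns, "carrier"))
  # zero secondary z shrinks |Z| -> p worsens -> inconsistent
  expect_false(cross_ancestry_consistent(zp, c(carrier = 0, `non-carrier` = 0.1),
                                         np, ns, "carrier"))
  # opposite stratum significant after meta -> inconsistent regardless
  expect_false(cross_ancestry_consistent(zp, c(carrier = 2.0, `non-carrier` = 30),
                                         np, ns, "carrier"))
  # missing secondary result -> FALSE
  expect_false(suppressMessages(
    cross_ancestry_consistent(zp, c(carrier = NA, `non-carrier` = 0.1),
                              np, ns, "carrier")))
})
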