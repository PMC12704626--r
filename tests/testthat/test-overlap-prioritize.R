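test_that("LD proxy expansion honors its threshold and matches brute force", {
  set.seed(25)
  n <- 400
  z <- rnorm(n)
  G <- cbind(a = rbinom(n, 2, 0.4))
  G <- cbind(G, b = G[, "a"],                        # perfect proxy
             c = ifelse(runif(n) < 0.9, G[, "a"], rbinom(n, 2, 0.4)),
             d = rbinom(n, 2, 0.4))                  # independent
  expect_setequal(ld_proxies("a", G, r2_min = 1.0), c("a", "b"))
  expect_true("b" %in% ld_proxies("a", G, r2_min = 0.5))
  expect_false("d" %in% ld_proxies("a", G, r2_min = 0.5))
  expect_error(ld_proxies("x", G), "not in panel")
  expect_error(ld_proxies("a", cbind(a = rep(1, n), G[, -1])), "monomorphic")

  # AR(1) panel: against a brute-force all-pairs scan
  cfg <- sim_config(n_per_stratum = 100, n_variants = 15, n_loci = 1,
                    ld_rho = 0.95, seed = 6)
  P <- simulate_genotypes(cfg, n = 2000)$genotypes
  idx <- colnames(P)[8]
  brute <- colnames(P)[cor(P[, idx], P)^2 >= 0.8]
  expect_setequal(ld_proxies(idx, P, 0.8), union(idx, brute))
  # LD-matrix input agrees with the dosage-panel route
  expect_setequal(ld_proxies(idx, cor(P), 0.8), ld_proxies(idx, P, 0.8))
})

test_that("peak overlap uses BED half-open coordinates exactly", {
  peaks <- data.frame(chrom = 1, start = 100, end = 101, label = "Ast")
  hit <- peak_overlap(data.frame(chrom = 1, pos = 101), peaks, "Ast")
  expect_true(hit$any)                        # p-1 = 100 in [100, 101)
  miss <- peak_overlap(data.frame(chrom = 1, pos = 100), peaks, "Ast")
  expect_false(miss$any)                      # p-1 = 99 outside
  expect_false(peak_overlap(data.frame(chrom = 1, pos = 101)[0, ], peaks, "Ast")$any)
  expect_warning(r <- peak_overlap(data.frame(chrom = 1, pos = 101), peaks, "Mic"),
                 "no peaks")
  expect_false(r$any)
  # splitting a peak into adjacent half-open intervals changes nothing
  split_pk <- data.frame(chrom = 1, start = c(100, 150), end = c(150, 200),
                         label = "Ast")
  whole_pk <- data.frame(chrom = 1, start = 100, end = 200, label = "Ast")
  for (p in c(101, 150, 151, 200))
    expect_equal(peak_overlap(data.frame(chrom = 1, pos = p), split_pk, "Ast")$any,
                 peak_overlap(data.frame(chrom = 1, pos = p), whole_pk, "Ast")$any)
  # peak file ordering is irrelevant
  expect_true(peak_overlap(data.frame(chrom = 1, pos = 151),
                           split_pk[2:1, ], "Ast")$any)
})

test_that("evidence profiles count layers and assign tiers", {
  all6 <- evidence_profile(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  expect_equal(all6$support_count, 6)
  expect_equal(all6$tier, "more_than_half")
  three <- evidence_profile(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(three$tier, "at_least_half")
  four <- evidence_profile(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(four$tier, "more_than_half")
  none <- evidence_profile(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(none$tier, "none")
  partial <- evidence_profile(NA, TRUE, TRUE, NA, TRUE, FALSE)
  expect_equal(partial$support_count, 3)
  expect_setequal(partial$missing, c("cross_ancestry", "atac"))
})

test_that("druggable intersection is case-insensitive set logic", {
  expect_equal(druggable_intersect(c("A", "B"), c("B", "C")), "B")
  expect_equal(druggable_intersect(c("abc1"), c("ABC1")), "abc1")
  expect_length(druggable_intersect(c("A"), c("B")), 0)
  expect_error(druggable_intersect("A", character(0)), "empty")
})

test_that("network expansion adds only druggable first-degree neighbors", {
  edges <- data.frame(gene_a = c("S", "S", "S", "X"),
                      gene_b = c("x", "y", "z", "w"))
  expect_setequal(network_expand("S", edges, c("x", "z")), c("S", "x", "z"))
  expect_equal(suppressMessages(network_expand("S", edges[0, ], c("x"))), "S")
  # neighbor-of-neighbor (w, via x? no: via X) is never included
  expect_false("w" %in% network_expand("S", edges, c("x", "z", "w")))
  # seeds kept even when absent from the network
  expect_true("Q" %in% suppressMessages(network_expand(c("S", "Q"), edges, "x")))
})

test_that("hypergeometric enrichment matches exact enumeration", {
  gmt <- list(SET1 = paste0("g", 1:5))
  universe <- paste0("g", 1:20)
  r <- drug_enrichment(paste0("g", 1:5), gmt, universe, min_overlap = 2)
  expect_equal(r$table$p[1], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$table$p[1], hyper_brute(5, 5, 20, 5), tolerance = 1e-12)
  # zero overlap: upper tail includes k = 0, so p = 1
  r0 <- drug_enrichment(paste0("g", 6:10), gmt, universe)
  expect_equal(r0$table$p[1], 1)
  # enumeration oracle across random small instances
  set.seed(26)
  for (i in 1:50) {
    N <- sample(8:25, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    uni <- paste0("u", 1:N)
    set <- sample(uni, K); qry <- sample(uni, n)
    k <- length(intersect(set, qry))
    r <- drug_enrichment(qry, list(S = set), uni)
    expect_equal(r$table$p, hyper_brute(k, K, N, n), tolerance = 1e-12)
  }
  # removing a query gene never decreases a set's p
  qry <- paste0("g", 1:5)
  p_full <- drug_enrichment(qry, gmt, universe)$table$p
  for (drop in qry) {
    p_less <- drug_enrichment(setdiff(qry, drop), gmt, universe)$table$p
    expect_gte(p_less, p_full - 1e-12)
  }
  expect_warning(r_empty <- drug_enrichment(character(0), gmt, universe), "empty")
  expect_equal(nrow(r_empty$table), 0)
})
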