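test_that("stratified GWAS flags monomorphic variants and matches a direct ML oracle", {
  set.seed(1)
  n <- 4000
  g <- rbinom(n, 2, 0.3)
  covars <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 70, 5))
  eta <- -0.2 + log(2) * g
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  G <- cbind(g, mono = rep(1L, n))
  colnames(G) <- c("1:100", "1:200")
  variants <- data.frame(variant = colnames(G), chrom = 1L, pos = c(100, 200),
                         a1 = "A", a2 = "C")
  stratum <- rep(c("carrier", "non-carrier"), length.out = n)
  res <- run_stratified_gwas(G, variants, y, covars, stratum)
  car <- res$carrier
  expect_equal(car$note[2], "monomorphic")
  expect_true(is.na(car$p[2]))

  idx <- stratum == "carrier"
  X <- cbind(1, covars$sex[idx], covars$age[idx], g[idx])
  oracle <- logistic_ml_oracle(X, y[idx])
  expect_equal(car$z[1], oracle$z[4], tolerance = 1e-3)
  expect_equal(car$beta[1], oracle$beta[4], tolerance = 1e-3)
})

test_that("effective sample size follows the balanced-design identity and proxy rule", {
  expect_equal(effective_n(100, 100), 200)
  expect_equal(effective_n(100, 100), 4 / (1 / 100 + 1 / 100))
  expect_equal(effective_n(100, 100, is_proxy = TRUE), 50)
  expect_equal(effective_n(2500, 2500), 5000)   # balanced: N_eff = N
  expect_equal(effective_n(100, 300), 4 * 400 * 0.25 * 0.75)
  expect_error(effective_n(0, 0), "zero total")
})

test_that("variant filtering enforces anchor intersection and genotyping rate", {
  mk <- function(pos, rate) {
    data.frame(variant = variant_key(1, pos), chrom = 1, pos = pos,
               a1 = "A", a2 = "C", freq_a1 = 0.3, beta = 0, se = 1, z = 0,
               p = 1, n_cases = 10, n_controls = 10, geno_rate = rate,
               is_proxy = FALSE, note = "")
  }
  coh1 <- mk(1:5 * 100, c(1, 1, 0.85, 1, 1))
  coh2 <- mk(1:5 * 100, 1)
  anchor <- data.frame(chrom = 1, pos = 1:5 * 100, a1 = "A", a2 = "C")
  kept <- filter_variants(list(coh1, coh2), anchor, min_rate = 0.9)
  expect_length(kept, 4)
  expect_false(variant_key(1, 300) %in% kept)
  # absent from anchor -> dropped regardless of rate
  anchor2 <- anchor[-1, ]
  expect_false(variant_key(1, 100) %in%
                 filter_variants(list(coh1, coh2), anchor2))
})

test_that("allele harmonization flips swapped alleles and is involutive", {
  anchor <- data.frame(chrom = 1, pos = c(100, 200, 300),
                       a1 = c("A", "C", "A"), a2 = c("C", "T", "T"))
  stats <- data.frame(variant = variant_key(1, c(100, 200, 300)), chrom = 1,
                      pos = c(100, 200, 300),
                      a1 = c("C", "C", "A"), a2 = c("A", "T", "T"),
                      freq_a1 = c(0.8, 0.4, 0.5), beta = c(0.5, 0.2, 0.1),
                      se = 0.1, z = c(5, 2, 1), p = 0.5, n_cases = 10,
                      n_controls = 10, geno_rate = 1, is_proxy = FALSE,
                      note = "")
  h <- harmonize_stats(stats, anchor)
  expect_equal(h$stats$beta[1], -0.5)           # swapped -> sign flip
  expect_equal(h$stats$freq_a1[1], 0.2)
  expect_equal(h$stats$a1[1], "A")
  expect_equal(h$stats$beta[2], 0.2)            # already aligned
  expect_equal(h$dropped$reason, "palindromic") # A/T dropped
  expect_equal(nrow(h$stats), 2)
  h2 <- harmonize_stats(h$stats, anchor)        # involutive
  expect_equal(h2$stats, h$stats, ignore_attr = TRUE)
  expect_equal(nrow(h2$dropped), 0)
})

test_that("fixed-effects meta-analysis matches hand arithmetic", {
  one <- meta_fixed_effects(0.3, 0.1)
  expect_equal(one$beta, 0.3)
  expect_equal(one$se, 0.1)
  sym <- meta_fixed_effects(c(0.4, -0.4), c(0.2, 0.2))
  expect_equal(sym$beta, 0)
  b <- c(0.2, 0.1, 0.3); s <- c(0.1, 0.2, 0.1)
  w <- 1 / s^2
  m <- meta_fixed_effects(b, s)
  expect_equal(m$beta, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(m$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  # pooled variance never exceeds the best single cohort
  for (i in 1:50) {
    bb <- rnorm(3); ss <- runif(3, 0.05, 0.5)
    expect_lte(meta_fixed_effects(bb, ss)$se, min(ss))
  }
})

test_that("Stouffer combination follows its formula and ignores ordering", {
  expect_equal(meta_stouffer(c(1.5, 1.5), c(200, 200))$z, 1.5 * sqrt(2))
  expect_equal(meta_stouffer(2.2, 500)$z, 2.2)
  expect_equal(meta_stouffer(c(1, 2), c(100, 400))$z,
               (10 * 1 + 20 * 2) / sqrt(500))
  set.seed(7)
  z <- rnorm(4); ne <- runif(4, 50, 500)
  o <- sample(4)
  expect_equal(meta_stouffer(z, ne)$z, meta_stouffer(z[o], ne[o])$z)
  expect_error(meta_stouffer(1, 0), "positive")
})
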