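test_that("heritability screen hits its floor on perfect signal and errors without variants", {
  set.seed(2)
  G <- matrix(rbinom(100 * 5, 2, 0.4), 100, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  expr <- G[, 3]                       # noise-free signal
  p <- with_seed(11, screen_heritability(expr, G, n_perm = 500))
  expect_equal(p, 1 / 501)
  expect_equal(screen_heritability(rep(1, 100), G), 1)
  expect_error(screen_heritability(rnorm(100), G[, 0]), "cis variants")
  expect_error(screen_heritability(rnorm(10), G[1:10, ]), "20 subjects")
})

test_that("weight fitting recovers a single-eQTL architecture with top1", {
  set.seed(3)
  n <- 200
  G <- matrix(rbinom(n * 8, 2, 0.3), n, 8,
              dimnames = list(NULL, paste0("v", 1:8)))
  expr <- G[, 5]
  ws <- with_seed(5, fit_weights(expr, G, gene = "g1"))
  expect_s3_class(ws, "weight_set")
  expect_equal(ws$model_tag, "top1")
  expect_equal(sum(ws$weights != 0), 1)
  expect_equal(names(which(ws$weights != 0)), "v5")
})

test_that("ridge wins over top1 for a polygenic architecture", {
  set.seed(4)
  n <- 300
  G <- matrix(rbinom(n * 10, 2, 0.4), n, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  expr <- rowSums(scale(G)) / sqrt(10) + rnorm(n, 0, 0.5)
  ws <- with_seed(6, fit_weights(expr, G, gene = "gpoly"))
  expect_equal(ws$model_tag, "ridge")
  expect_true(all(ws$weights != 0))
})

test_that("permuted expression is dropped as unpredictable", {
  # a permuted trait retains only chance correlation with the genotypes, so
  # the CV gate should reject it in the large majority of replicates
  dropped <- vapply(1:10, function(r) {
    set.seed(100 + r)
    n <- 150
    G <- matrix(rbinom(n * 6, 2, 0.3), n, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    expr <- sample(G[, 1])   # destroys the genotype-expression link
    is.null(suppressMessages(fit_weights(expr, G, gene = "gnull")))
  }, TRUE)
  expect_gte(sum(dropped), 8)
})

test_that("TWAS association obeys its algebra", {
  R <- ar1_mat(3, 0.5)
  dimnames(R) <- list(paste0("v", 1:3), paste0("v", 1:3))
  # unit weight on one variant with identity LD returns that variant's z
  I3 <- diag(3); dimnames(I3) <- dimnames(R)
  w1 <- c(v1 = 0, v2 = 1, v3 = 0)
  z <- c(v1 = 1.1, v2 = -2.3, v3 = 0.4)
  expect_equal(twas_associate(w1, z, I3)$z, -2.3)
  # z = R w c  =>  z_twas = c sqrt(w' R w)
  w <- c(v1 = 0.3, v2 = -0.7, v3 = 0.2)
  cc <- 2.5
  zrw <- setNames(as.vector(R %*% w) * cc, names(w))
  expect_equal(twas_associate(w, zrw, R)$z,
               cc * sqrt(as.numeric(t(w) %*% R %*% w)), tolerance = 1e-12)
  # all-zero z
  z0 <- setNames(numeric(3), names(w))
  r0 <- twas_associate(w, z0, R)
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  # degenerate quadratic form -> missing
  expect_true(is.na(twas_associate(c(v1 = 0, v2 = 0, v3 = 0), z, R)$z))
  # misaligned variants -> informative error
  expect_error(twas_associate(c(vX = 1), z, R), "vX")
})

test_that("TWAS z is invariant to variant permutation and allele flips", {
  set.seed(10)
  m <- 5
  R <- ar1_mat(m, 0.6)
  nm <- paste0("v", 1:m)
  dimnames(R) <- list(nm, nm)
  w <- setNames(rnorm(m), nm)
  z <- setNames(rnorm(m), nm)
  base <- twas_associate(w, z, R)$z
  o <- sample(m)
  expect_equal(twas_associate(w[o], z[o], R[o, o])$z, base, tolerance = 1e-12)
  # flip allele orientation of variant 2 in both weights and z (LD signs too)
  wf <- w; zf <- z; Rf <- R
  wf[2] <- -wf[2]; zf[2] <- -zf[2]
  Rf[2, ] <- -Rf[2, ]; Rf[, 2] <- -Rf[, 2]; Rf[2, 2] <- 1
  expect_equal(twas_associate(wf, zf, Rf)$z, base, tolerance = 1e-12)
})

test_that("run_ctwas keeps one row per overlapping weight set, symmetric across identical strata", {
  cfg <- tiny_config()
  dir <- file.path(tempdir(), "bundle_ctwas")
  bundle <- suppressMessages(emit_fixture_bundle(cfg, dir))
  harm <- harmonize_stats(bundle$sumstats$EUR_CC_carrier, bundle$anchor)$stats
  same <- list(carrier = harm, `non-carrier` = harm)
  tab <- run_ctwas(bundle$weights, same, bundle$ld$EUR)
  expect_equal(nrow(tab), length(bundle$weights))
  expect_equal(tab$z_carrier, tab$z_noncarrier)
})
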