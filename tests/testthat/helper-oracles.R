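# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (enumeration, brute force, quadrature,
# direct likelihood optimization) and never call the implementation they
# check.

# Brute-force Benjamini-Hochberg step-up: sort, scale by m/rank, cumulative
# minimum from the largest rank down.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exact hypergeometric upper tail P(X >= k) by enumeration over all
# achievable overlap counts.
hyper_brute <- function(k, K, N, n) {
  kk <- max(0, n + K - N):min(K, n)
  probs <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(probs[kk >= k])
}

# Logistic regression ML fit by direct likelihood optimization (oracle for
# the GWAS scan's glm-based Wald statistics).
logistic_ml_oracle <- function(X, y) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(fit$hessian)))
  list(beta = fit$par, se = se, z = fit$par / se)
}

# Wakefield ABF by numerical quadrature: marginal likelihood ratio of
# beta_hat under effect-prior N(0, W) versus the point null.
wakefield_quadrature <- function(beta, se, sd_prior) {
  num <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, sd_prior),
                   -Inf, Inf, rel.tol = 1e-12)$value
  log(num / dnorm(beta, 0, se))
}

# AR(1) correlation matrix.
ar1_mat <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

# Draw marginal summary statistics for a quantitative trait with a single
# causal variant, from the asymptotic sampling distribution on the
# standardized-genotype scale: beta_hat ~ MVN(R b, R / n), se = 1/sqrt(n).
sim_marginal_stats <- function(R, causal_beta, n) {
  m <- nrow(R)
  L <- chol(R)
  mu <- as.vector(R %*% causal_beta)
  bhat <- mu + as.vector(rnorm(m) %*% L) / sqrt(n)
  se <- rep(1 / sqrt(n), m)
  data.frame(variant = rownames(R) %||% paste0("v", seq_len(m)),
             beta = bhat, se = se, z = bhat / se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Marginal per-variant stats computed from raw data (used where tests
# simulate subjects rather than summary statistics).
marginal_stats_raw <- function(y, G) {
  eqtl_marginal(y, G)
}

# Small config used by several module tests (kept fast).
tiny_config <- function(seed = 42, ...) {
  sim_config(n_per_stratum = 300, n_variants = 10, n_loci = 4,
             n_reference = 120, n_background_genes = 8, seed = seed, ...)
}
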