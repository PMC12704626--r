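# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed and a stream label
#'
#' All stochastic stages draw their seeds through this function so that a
#' single integer seed determines the whole pipeline, while distinct stages
#' (genotypes, permutations, Monte-Carlo draws, ...) use distinct streams.
#'
#' @param seed base integer seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (k in utf8ToInt(lab)) h <- (h * 131 + k) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 1103515245 + h) %% 2147483629)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# log(sum(exp(x))) without overflow; -Inf for empty input.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
# or is non-positive (degenerate one-variant case).
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Variant key used to match rows across cohorts and panels.
variant_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

# FNV-1a hash of a string, hex-encoded; used for run-manifest config hashes.
fnv1a <- function(s) {
  h <- 2166136261
  for (k in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), k)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
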