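#' @import methods
#' @importFrom stats rnorm runif setNames approx sd
#' @importFrom utils head tail write.csv read.csv
NULL

## RNG discipline: every stochastic operation runs under an explicit seed
## through withSeed(), and sub-seeds are derived with deriveSeeds() so that
## a whole run is a pure function of one master seed.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## Stable 31-bit string hash (doubles stay < 2^53 throughout).
hashSalt <- function(salt) {
  h <- 0
  for (code in utf8ToInt(as.character(salt))) h <- (h * 31 + code) %% 2147483647
  h
}

## n reproducible sub-seeds for a named purpose, all < 2^31.
deriveSeeds <- function(seed, n, salt = "") {
  base <- (as.numeric(seed) %% 2147483647 + hashSalt(salt)) %% 2147483646 + 1
  withSeed(base, sample.int(2147483646L, n))
}

## Row-wise / column-wise L2 normalization with a guard for zero vectors.
l2NormalizeRows <- function(x, eps = 1e-12) {
  nrm <- sqrt(rowSums(x * x))
  if (any(nrm < eps)) stop("cannot L2-normalize a (near-)zero vector")
  x / nrm
}

l2NormalizeCols <- function(x, eps = 1e-12) {
  nrm <- sqrt(colSums(x * x))
  if (any(nrm < eps)) stop("cannot L2-normalize a (near-)zero column")
  sweep(x, 2, nrm, "/")
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
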