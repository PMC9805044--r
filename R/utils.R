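#' @import methods
#' @importFrom stats rnorm rbinom rlnorm runif predict cor sd
#'   quantile setNames aggregate cov as.formula coef fft acf mahalanobis
#'   model.matrix lm lm.fit glm binomial gaussian residuals fitted
#'   plogis complete.cases
#' @importFrom data.table as.data.table
NULL

## 32-bit FNV-1a over the bytes of a string; returned as a double in
## [0, 2^32).  Used only for deterministic seed derivation and content
## hashing -- not cryptographic.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor with a byte only touches the low 8 bits
    h <- h - low + bitwXor(as.integer(low), b)
    ## multiply mod 2^32 in two 16-bit halves to stay within double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 2^32
  }
  h
}

#' Derive a reproducible child seed
#'
#' Child seeds are derived from the experiment master seed and a string
#' key (module, ESM id, member id, ...) by a fixed hash, so that adding
#' or reordering one component of an experiment never perturbs the
#' random stream of another.
#'
#' @param master integer master seed.
#' @param ... character or numeric key components.
#' @return An integer seed in \[0, 2^31).
#' @export
childSeed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- fnv1a32(key) %% 1048573
  as.integer((as.numeric(master) %% 2^31 * 1048573 + h) %% 2147483629)
}

## Content hash of an arbitrary R object (FNV-1a over its serialization).
## Drives the stage memoization in runExperiment().
contentHash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 3)
  ## skip the serialization header (R version stamps) for stability
  raw <- raw[-seq_len(14)]
  h1 <- 2166136261
  h2 <- 40503
  n <- length(raw)
  v <- as.integer(raw)
  ## block-wise polynomial rolling hash, vectorized for speed
  chunk <- 65536L
  for (i in seq(1L, n, by = chunk)) {
    block <- v[i:min(n, i + chunk - 1L)]
    h1 <- (h1 * 31 + sum(block * seq_along(block))) %% 2147483629
    h2 <- (h2 * 37 + sum(block * block)) %% 2147483587
  }
  sprintf("%08x%08x%08x", h1, h2, n %% 4294967296)
}

## clamp to [lo, hi]
clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
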