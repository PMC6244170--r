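#' @keywords internal
"_PACKAGE"

# Deterministic fan-out of one global seed into per-stage sub-seeds.
# Stages are identified by label; the mapping is pure arithmetic so the same
# (seed, stage) pair always yields the same sub-seed, independent of call
# order, and stays below .Machine$integer.max.
sub_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% 1000000007
  }
  as.integer((abs(seed) * 48271 + h) %% 2147483647L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample moments used by score summaries: skew g1 and excess kurtosis g2,
# both without small-sample bias correction.
moment_skew <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
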