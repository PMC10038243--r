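# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

# Stable 31-bit hash of (seed, key...) used to derive independent RNG streams.
# Per-record streams mean insertion order never changes an individual image.
hash_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Largest-remainder (Hamilton) apportionment of n among weights p.
# Ties in the remainder are broken by position, keeping results deterministic.
largest_remainder <- function(p, n) {
  if (!is_count(n)) stopf("n must be a non-negative integer")
  if (any(p < 0) || sum(p) <= 0) stopf("weights must be non-negative with positive sum")
  q <- p / sum(p) * n
  base <- floor(q)
  short <- as.integer(round(n - sum(base)))
  if (short > 0L) {
    ord <- order(-(q - base), seq_along(p))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# round() half-away-from-zero for non-negative x (base round() is banker's).
round_half_up <- function(x) floor(x + 0.5)

# Numerically stable row-wise softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}
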