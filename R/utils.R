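# Internal numeric / bitmask helpers.  Node sets are stored as integer
# bitmasks (bit i-1 set <=> node i in the set); n never exceeds ~20 so
# masks fit comfortably in R's 32-bit integers.

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

mask_of <- function(idx) {
  if (!length(idx)) return(0L)
  as.integer(sum(bitwShiftL(1L, as.integer(idx) - 1L)))
}

bits_of <- function(mask, n) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
}

popcount <- function(mask) {
  out <- integer(length(mask))
  m <- as.integer(mask)
  while (any(m != 0L)) {
    out <- out + bitwAnd(m, 1L)
    m <- bitwShiftR(m, 1L)
  }
  out
}

# all subsets (as masks) of `universe` (node indices) with size <= cap,
# ordered by size then lexicographically; empty set first
subset_masks <- function(universe, cap) {
  out <- 0L
  k <- 1L
  while (k <= cap && k <= length(universe)) {
    cmb <- utils::combn(universe, k)
    out <- c(out, apply(cmb, 2L, mask_of))
    k <- k + 1L
  }
  as.integer(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
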