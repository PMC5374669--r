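# Internal numerical helpers. Everything tail-related works in log space;
# these are the few primitives that make that safe.

logSumExp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (m = -Inf) or contains +Inf
  m + log(sum(exp(x - m)))
}

## Add a vector along one dimension of an array (recycling over the rest).
## Used to fold per-variable messages into a factor's joint table.
addAlongDim <- function(arr, vec, dim) {
  d <- dim(arr)
  nd <- length(d)
  vec <- as.vector(vec)
  if (nd == 1L) return(arr + vec)
  perm <- c(dim, seq_len(nd)[-dim])
  out <- aperm(arr, perm) + vec
  aperm(out, order(perm))
}

## log-sum-exp over all dimensions of `arr` except `keep`; returns a vector
## indexed by the kept dimension.
logSumExpExcept <- function(arr, keep) {
  d <- dim(arr)
  if (length(d) == 1L) return(as.vector(arr))
  as.vector(apply(arr, keep, logSumExp))
}

## Strides for flattening joint states in R (column-major) order:
## linear = 1 + sum((state_i - 1) * stride_i).
colMajorStrides <- function(cards) {
  if (length(cards) == 0L) return(integer(0))
  cumprod(c(1L, cards[-length(cards)]))
}

## Convert an array to / from the interchange flat layout (row-major,
## last scope variable varying fastest).
flattenRowMajor <- function(arr) {
  d <- dim(arr)
  if (is.null(d) || length(d) == 1L) return(as.vector(arr))
  as.vector(aperm(arr, rev(seq_along(d))))
}

unflattenRowMajor <- function(flat, cards) {
  cards <- unname(cards)
  if (length(cards) == 1L) return(array(flat, dim = cards))
  aperm(array(flat, dim = rev(cards)), rev(seq_along(cards)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

relErr <- function(est, truth) abs(est - truth) / abs(truth)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
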