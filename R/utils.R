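# internal helpers shared across modules

# Squared Euclidean distances between the rows of `x` (n x d) and the rows of
# `centers` (k x d). Returns an n x k matrix. Clamps tiny negatives from
# floating-point cancellation.
.dist2 <- function(x, centers) {
  x <- as.matrix(x)
  centers <- matrix(centers, ncol = ncol(x))
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

# Split a vector into consecutive chunks of size `size` (last chunk may be
# shorter). Returns a list.
.chunk <- function(x, size) {
  if (length(x) == 0L) return(list())
  split(x, ceiling(seq_along(x) / size))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

.is_prop <- function(x, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x))) return(FALSE)
  a <- if (lo_open) x > lo else x >= lo
  b <- if (hi_open) x < hi else x <= hi
  a && b
}
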