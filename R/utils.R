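# Internal helpers shared across modules.

# Canonical key for an unordered pair; "\r" cannot occur in identifiers read
# from TSV, so the key is collision-free.
pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  paste(a, b, sep = "\r")
}

# Canonicalize a two-column pair table: order within pairs, drop duplicates.
# Self-pairs are the caller's responsibility (read_pairs warns, internal
# enumerators never produce them).
canonicalize_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  keep <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
}

# All unordered pairs among the elements of x (a character vector), as a
# canonical pair data frame.
all_pairs <- function(x) {
  x <- unique(x)
  if (length(x) < 2L) return(empty_pairs())
  idx <- utils::combn(length(x), 2L)
  canonicalize_pairs(x[idx[1L, ]], x[idx[2L, ]])
}

# Decode linear indices in 1..choose(n, 2) into unordered index pairs (i < j).
# Used to sample distinct pairs from a large universe without enumerating it.
decode_pair_index <- function(k, n) {
  # pairs ordered (1,2), (1,3), ..., (1,n), (2,3), ...
  k <- as.numeric(k)
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  offset <- (i - 1) * n - i * (i - 1) / 2
  j <- k - offset + i
  cbind(as.integer(i), as.integer(j))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
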