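# Independent brute-force oracles. These never call the implementation path
# they check.

# S-value of `anc` in the profile of `term`: max over all directed paths
# term -> ... -> anc of the product of edge weights, found by exhaustive
# path enumeration on the raw edge table.
oracle_s_value <- function(edges, weights, term, anc) {
  if (term == anc) return(1)
  best <- -Inf
  walk <- function(node, acc) {
    up <- which(edges$child == node)
    for (k in up) {
      w <- acc * weights[[edges$type[k]]]
      if (edges$parent[k] == anc) best <<- max(best, w)
      walk(edges$parent[k], w)
    }
  }
  walk(term, 1)
  if (is.finite(best)) best else NA_real_
}

# All ancestors of a term (including itself) by transitive closure.
oracle_ancestors <- function(edges, term) {
  anc <- term
  repeat {
    new <- unique(edges$parent[edges$child %in% anc])
    new <- setdiff(new, anc)
    if (length(new) == 0L) return(anc)
    anc <- c(anc, new)
  }
}

# Wang term similarity from oracle S-values.
oracle_term_sim <- function(edges, weights, a, b) {
  anc_a <- oracle_ancestors(edges, a)
  anc_b <- oracle_ancestors(edges, b)
  sa <- vapply(anc_a, function(t) oracle_s_value(edges, weights, a, t),
               numeric(1))
  sb <- vapply(anc_b, function(t) oracle_s_value(edges, weights, b, t),
               numeric(1))
  common <- intersect(anc_a, anc_b)
  if (length(common) == 0L) return(0)
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}

# Best-match average over an explicit all-pairs similarity table.
oracle_gene_sim <- function(edges, weights, t1, t2) {
  tab <- matrix(NA_real_, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      tab[i, j] <- oracle_term_sim(edges, weights, t1[i], t2[j])
    }
  }
  row_best <- numeric(length(t1))
  for (i in seq_along(t1)) row_best[i] <- max(tab[i, ])
  col_best <- numeric(length(t2))
  for (j in seq_along(t2)) col_best[j] <- max(tab[, j])
  (sum(row_best) / length(t1) + sum(col_best) / length(t2)) / 2
}

# Survival function of chi-square with even df = 2k, in closed form:
# exp(-x/2) * sum_{i<k} (x/2)^i / i!.
oracle_chisq_sf_even <- function(x, k) {
  h <- x / 2
  exp(-h) * sum(h^(0:(k - 1)) / factorial(0:(k - 1)))
}

# Upper-tail hypergeometric by full term-by-term enumeration.
oracle_hyper_tail <- function(N, K, n, t) {
  ks <- t:min(K, n)
  ks <- ks[(n - ks) <= (N - K) & ks >= 0]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# One-sided binomial upper tail P(X >= k) by direct summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# Brute-force evaluation metrics with explicit loops.
oracle_eval <- function(predicted, reference, omega) {
  aff <- function(p, b) length(intersect(p, b))^2 / (length(p) * length(b))
  n_cp <- 0L
  for (p in predicted) {
    if (any(vapply(reference, function(b) aff(p, b), numeric(1)) >= omega))
      n_cp <- n_cp + 1L
  }
  n_cb <- 0L
  for (b in reference) {
    if (any(vapply(predicted, function(p) aff(p, b), numeric(1)) >= omega))
      n_cb <- n_cb + 1L
  }
  precision <- n_cp / length(predicted)
  recall <- n_cb / length(reference)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  sn_num <- 0
  sn_den <- 0
  for (b in reference) {
    sn_num <- sn_num + max(vapply(predicted, function(p)
      length(intersect(b, p)), numeric(1)))
    sn_den <- sn_den + length(b)
  }
  ppv_num <- 0
  ppv_den <- 0
  for (p in predicted) {
    ov <- vapply(reference, function(b) length(intersect(b, p)), numeric(1))
    ppv_num <- ppv_num + max(ov)
    ppv_den <- ppv_den + sum(ov)
  }
  sn <- sn_num / sn_den
  ppv <- if (ppv_den == 0) 0 else ppv_num / ppv_den
  list(n_cp = n_cp, n_cb = n_cb, precision = precision, recall = recall,
       f_measure = f, sensitivity = sn,
       ppv = ppv, accuracy = if (ppv_den == 0) 0 else sqrt(sn * ppv))
}

# Random complex collections over a small alphabet, for parameterised cases.
random_complex_sets <- function(n_complexes, max_size, alphabet = LETTERS) {
  lapply(seq_len(n_complexes), function(i)
    sample(alphabet, sample(2:max_size, 1L)))
}
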