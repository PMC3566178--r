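# Semantic similarity over the GO biological-process DAG, following the
# contribution-propagation (S-value) scheme of Wang et al.: each ancestor of
# a term contributes to its semantics with a weight that decays
# multiplicatively along the path, is_a edges contributing more than part_of
# edges, and two terms are compared through the S-values of their shared
# ancestors.

#' Construct a GO DAG
#'
#' A directed acyclic graph of GO terms with typed child-to-parent edges.
#' Each edge type carries a semantic contribution weight in `(0, 1)`; the
#' defaults (0.8 for `is_a`, 0.6 for `part_of`) are the canonical constants
#' of the Wang similarity measure. Construction fails on cycles, on edges to
#' unknown terms, and on weights outside `(0, 1)`, so a `go_dag` that exists
#' is always valid.
#'
#' @param edges data frame with columns `child`, `parent`, `type`.
#' @param weights named numeric vector of per-type weights, strictly inside
#'   `(0, 1)`.
#' @param terms optional character vector of all term ids (to include
#'   isolated terms); defaults to the ids seen in `edges`.
#' @return An object of class `go_dag`.
#' @examples
#' dag <- go_dag(data.frame(child = c("B", "C"), parent = c("A", "B"),
#'                          type = "is_a"))
#' term_similarity(dag, "B", "C")
#' @export
go_dag <- function(edges, weights = c(is_a = 0.8, part_of = 0.6),
                   terms = NULL) {
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      type = as.character(edges$type),
                      stringsAsFactors = FALSE)
  if (any(weights <= 0 | weights >= 1)) {
    stop("edge weights must lie strictly between 0 and 1", call. = FALSE)
  }
  bad_type <- setdiff(unique(edges$type), names(weights))
  if (length(bad_type)) {
    stop("edge type(s) without a weight: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(terms)) {
    terms <- unique(c(edges$child, edges$parent))
  } else {
    terms <- unique(as.character(terms))
    unknown <- setdiff(unique(c(edges$child, edges$parent)), terms)
    if (length(unknown)) {
      stop("edge references unknown term(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (any(edges$child == edges$parent)) {
    stop("self-loop edge detected", call. = FALSE)
  }
  cyc <- find_cycle(edges, terms)
  if (!is.null(cyc)) {
    stop("cycle detected in ontology: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  edges$w <- unname(weights[edges$type])
  dag <- list(terms = terms, edges = edges, weights = weights,
              parent_index = split(edges[c("parent", "w")], edges$child),
              cache = new.env(parent = emptyenv()))
  class(dag) <- "go_dag"
  dag
}

# Kahn topological sort on child->parent edges; returns one cycle (as a term
# path) if the graph is cyclic, NULL otherwise.
find_cycle <- function(edges, terms) {
  out_deg <- table(factor(edges$child, levels = terms))
  incoming <- split(edges$child, edges$parent)  # parent -> children
  queue <- terms[out_deg == 0L]
  deg <- as.integer(out_deg)
  names(deg) <- terms
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in incoming[[t]] %||% character(0)) {
      deg[ch] <- deg[ch] - 1L
      if (deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(terms)) return(NULL)
  # walk parents within the residual (cyclic) subgraph until a repeat
  residual <- names(deg)[deg > 0L]
  par_of <- split(edges$parent, edges$child)
  path <- residual[[1L]]
  repeat {
    nxt <- intersect(par_of[[path[length(path)]]], residual)[1L]
    if (nxt %in% path) {
      return(c(path[which(path == nxt)[1L]:length(path)], nxt))
    }
    path <- c(path, nxt)
  }
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d edges (%s)\n", length(x$terms),
              nrow(x$edges),
              paste(sprintf("%s=%g", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Ancestor contribution profile of a term
#'
#' Computes the S-value of every ancestor of `term` (including the term
#' itself): the term scores 1, and each ancestor scores the maximum over its
#' children on paths toward the term of the edge weight times the child's
#' S-value. The semantic value `sv` is the sum of the profile.
#'
#' @param dag a [go_dag()].
#' @param term a term id present in the DAG.
#' @return A list with `term`, `s` (named numeric vector of S-values) and
#'   `sv` (their sum).
#' @export
ancestor_profile <- function(dag, term) {
  stopifnot(inherits(dag, "go_dag"))
  if (!term %in% dag$terms) {
    stop("unknown term: ", term, call. = FALSE)
  }
  key <- paste0("prof:", term)
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- stats::setNames(1.0, term)
  active <- term
  # worklist relaxation; terminates because the graph is acyclic and each
  # update strictly raises an S-value
  while (length(active)) {
    nxt <- character(0)
    for (ch in active) {
      pl <- dag$parent_index[[ch]]
      if (is.null(pl)) next
      cand <- pl$w * s[[ch]]
      for (k in seq_along(cand)) {
        p <- pl$parent[k]
        cur <- s[p]
        if (is.na(cur) || cand[k] > cur) {
          s[p] <- cand[k]
          nxt <- c(nxt, p)
        }
      }
    }
    active <- unique(nxt)
  }
  prof <- list(term = term, s = s, sv = sum(s))
  assign(key, prof, envir = dag$cache)
  prof
}

#' Wang semantic similarity between two GO terms
#'
#' The summed S-values of the common ancestors of `a` and `b` (each ancestor
#' contributing its S-value in both profiles), normalized by the two
#' semantic values: `sum(S_a(t) + S_b(t)) / (SV(a) + SV(b))` over common
#' ancestors `t`. Symmetric, in `[0, 1]`, and 1 exactly when the two
#' profiles coincide.
#'
#' @param dag a [go_dag()].
#' @param a,b term ids.
#' @return Numeric scalar in `[0, 1]`.
#' @export
term_similarity <- function(dag, a, b) {
  key <- paste0("tsim:", pair_key(a, b))
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  pa <- ancestor_profile(dag, a)
  pb <- ancestor_profile(dag, b)
  common <- intersect(names(pa$s), names(pb$s))
  sim <- if (length(common) == 0L) 0 else {
    (sum(pa$s[common]) + sum(pb$s[common])) / (pa$sv + pb$sv)
  }
  assign(key, sim, envir = dag$cache)
  sim
}

#' Semantic similarity between two annotated genes
#'
#' Best-match average over the two genes' term sets: for every term of the
#' first gene take its best [term_similarity()] against the second gene's
#' terms, and vice versa, then average the two directional means. Returns
#' `NA` when either gene has no annotation — such pairs are excluded from
#' complex significance averages rather than scored 0.
#'
#' @param annot named list gene -> term ids (see [read_annotations()]).
#' @param dag a [go_dag()].
#' @param g1,g2 gene symbols.
#' @return Numeric scalar in `[0, 1]`, or `NA_real_` if either gene is
#'   unannotated.
#' @export
gene_similarity <- function(annot, dag, g1, g2) {
  t1 <- annot[[g1]]
  t2 <- annot[[g2]]
  if (is.null(t1) || length(t1) == 0L || is.null(t2) || length(t2) == 0L) {
    return(NA_real_)
  }
  m <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      m[i, j] <- term_similarity(dag, t1[i], t2[j])
    }
  }
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}
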