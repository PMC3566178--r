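# Bipartite drug-complex network and its statistics: hub/target-usage
# tables with and without repeat removal, druggability enrichment among
# overlapping proteins, and a permutation test for whether known drug-drug
# interactions are enriched among co-complex drug pairs.

#' Build a bipartite drug-complex network
#'
#' A drug and a complex are connected when the complex contains at least one
#' target of the drug; the edge is annotated with that (non-empty) set of
#' supporting target proteins. Drugs and complexes without any edge are not
#' part of the network's node sets.
#'
#' @param catalogue a [complex_catalogue()].
#' @param targets named list drug id -> character vector of target symbols
#'   (see [read_drug_targets()]).
#' @return An object of class `drug_complex_network`: `edges` (data frame
#'   with columns `drug`, `complex` and list column `support`), `drugs`,
#'   `complexes` (connected node ids), `all_drugs` (the full drug universe
#'   of the target table, used as an alternative sampling universe).
#' @export
build_drug_complex_network <- function(catalogue, targets) {
  stopifnot(inherits(catalogue, "complex_catalogue"))
  rows <- list()
  for (d in names(targets)) {
    tg <- unique(targets[[d]])
    if (length(tg) == 0L) next
    hit <- vapply(catalogue$members, function(m) any(tg %in% m), logical(1))
    for (ci in which(hit)) {
      rows[[length(rows) + 1L]] <-
        list(drug = d, complex = catalogue$id[ci],
             support = intersect(tg, catalogue$members[[ci]]))
    }
  }
  edges <- data.frame(
    drug = vapply(rows, `[[`, character(1), "drug"),
    complex = vapply(rows, `[[`, character(1), "complex"),
    stringsAsFactors = FALSE)
  edges$support <- lapply(rows, `[[`, "support")
  structure(list(edges = edges,
                 drugs = unique(edges$drug),
                 complexes = unique(edges$complex),
                 all_drugs = names(targets)),
            class = "drug_complex_network")
}

#' @export
print.drug_complex_network <- function(x, ...) {
  cat(sprintf("drug_complex_network: %d drugs, %d complexes, %d edges\n",
              length(x$drugs), length(x$complexes), nrow(x$edges)))
  invisible(x)
}

#' Convert a drug-complex network to an igraph object
#'
#' Node type follows the bipartite convention: `FALSE` for drugs, `TRUE`
#' for complexes.
#'
#' @param net a [build_drug_complex_network()] result.
#' @return An [igraph::graph] with a logical `type` vertex attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "drug_complex_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[c("drug", "complex")], directed = FALSE,
    vertices = data.frame(name = c(net$drugs, net$complexes),
                          type = rep(c(FALSE, TRUE),
                                     c(length(net$drugs), length(net$complexes)))))
  g
}

#' Hub and target-usage statistics of a drug-complex network
#'
#' In raw mode, a drug's degree is its number of incident edges, a complex's
#' degree likewise, and a target's usage is the number of edges whose
#' support set contains it. A target shared by several complexes therefore
#' inflates both its own usage and its drugs' degrees. In de-duplicated mode
#' each (drug, target) relationship is counted once regardless of how many
#' complexes carry it: a drug's degree becomes its number of distinct
#' targets found in at least one complex, and a target's usage the number of
#' distinct drugs using it.
#'
#' @param net a [build_drug_complex_network()] result.
#' @param dedup logical; remove repeat counting (default `FALSE`).
#' @return A list of class `degree_report` with data frames `drugs`
#'   (`drug`, `degree`), `complexes` (`complex`, `degree`; raw mode only)
#'   and `targets` (`target`, `times_used`), each sorted by decreasing
#'   count.
#' @export
degree_report <- function(net, dedup = FALSE) {
  stopifnot(inherits(net, "drug_complex_network"))
  edges <- net$edges
  desc_df <- function(tab, names_col) {
    df <- data.frame(names(tab), as.integer(tab), stringsAsFactors = FALSE)
    names(df) <- names_col
    df[order(-df[[2L]], df[[1L]]), , drop = FALSE]
  }
  if (!dedup) {
    drug_tab <- table(edges$drug)
    cplx_tab <- table(edges$complex)
    tgt <- unlist(edges$support, use.names = FALSE)
    res <- list(drugs = desc_df(drug_tab, c("drug", "degree")),
                complexes = desc_df(cplx_tab, c("complex", "degree")),
                targets = desc_df(table(tgt), c("target", "times_used")))
  } else {
    dt <- unique(data.frame(
      drug = rep(edges$drug, lengths(edges$support)),
      target = unlist(edges$support, use.names = FALSE),
      stringsAsFactors = FALSE))
    res <- list(drugs = desc_df(table(dt$drug), c("drug", "degree")),
                complexes = NULL,
                targets = desc_df(table(dt$target), c("target", "times_used")))
  }
  structure(c(res, list(dedup = dedup)), class = "degree_report")
}

#' Co-complex drug pairs
#'
#' All unordered pairs of distinct drugs that share at least one complex
#' neighbor in the network.
#'
#' @param net a [build_drug_complex_network()] result.
#' @return Canonical pair data frame with columns `a`, `b`.
#' @export
cocomplex_drug_pairs <- function(net) {
  stopifnot(inherits(net, "drug_complex_network"))
  by_complex <- split(net$edges$drug, net$edges$complex)
  mats <- lapply(by_complex, function(d) {
    d <- unique(d)
    if (length(d) < 2L) return(NULL)
    idx <- utils::combn(length(d), 2L)
    cbind(d[idx[1L, ]], d[idx[2L, ]])
  })
  mat <- do.call(rbind, mats)
  if (is.null(mat)) return(empty_pairs())
  canonicalize_pairs(mat[, 1L], mat[, 2L])
}

#' Permutation test: are drug-drug interactions co-complex drug pairs?
#'
#' Counts how many known drug-drug interaction (DDI) pairs are co-complex
#' drug pairs, then compares against `reps` draws of the same number of
#' distinct random drug pairs from the sampling universe (by default, all
#' drugs with at least one network edge). The empirical p-value uses the
#' add-one convention `(1 + #[replicate >= observed]) / (reps + 1)`, so it
#' can never be exactly zero.
#'
#' @param net a [build_drug_complex_network()] result.
#' @param ddis canonical pair data frame of known interacting drug pairs;
#'   pairs involving drugs outside the universe are dropped with a message.
#' @param reps number of random replicates (>= 1).
#' @param seed optional integer seed for reproducible draws.
#' @param universe `"network"` (drugs with >= 1 edge, default) or `"all"`
#'   (every drug of the target table).
#' @return A list of class `ddi_permutation_result`: `n_ddi_pairs`,
#'   `observed`, `replicates` (integer vector of length `reps`),
#'   `null_mean`, `p_value`.
#' @export
ddi_permutation_test <- function(net, ddis, reps = 1000L, seed = NULL,
                                 universe = c("network", "all")) {
  stopifnot(inherits(net, "drug_complex_network"), reps >= 1L)
  universe <- match.arg(universe)
  drugs <- sort(if (universe == "network") net$drugs else net$all_drugs)
  nd <- length(drugs)
  in_univ <- ddis$a %in% drugs & ddis$b %in% drugs
  if (any(!in_univ)) {
    message(sprintf(
      "ddi_permutation_test: %d DDI pair(s) outside the sampling universe dropped",
      sum(!in_univ)))
    ddis <- ddis[in_univ, , drop = FALSE]
  }
  n_ddi <- nrow(ddis)
  cc_keys <- with(cocomplex_drug_pairs(net), pair_key(a, b))
  observed <- if (n_ddi) sum(pair_key(ddis$a, ddis$b) %in% cc_keys) else 0L
  n_univ_pairs <- choose(nd, 2)
  if (n_univ_pairs < n_ddi) {
    stop(sprintf("universe of %d drugs cannot yield %d distinct pairs",
                 nd, n_ddi), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  replicates <- integer(reps)
  if (n_ddi > 0L) {
    for (r in seq_len(reps)) {
      k <- sample.int(n_univ_pairs, n_ddi)
      ij <- decode_pair_index(k, nd)
      replicates[r] <- sum(pair_key(drugs[ij[, 1L]], drugs[ij[, 2L]]) %in% cc_keys)
    }
  }
  p <- if (n_ddi == 0L) 1 else (1 + sum(replicates >= observed)) / (reps + 1)
  structure(list(n_ddi_pairs = n_ddi, observed = observed,
                 replicates = replicates, null_mean = mean(replicates),
                 p_value = p),
            class = "ddi_permutation_result")
}

#' @export
print.ddi_permutation_result <- function(x, ...) {
  cat(sprintf(
    "ddi_permutation_result: %d/%d DDI pairs co-complex; null mean %.1f; p = %.4g\n",
    x$observed, x$n_ddi_pairs, x$null_mean, x$p_value))
  invisible(x)
}

#' Druggability enrichment of overlapping proteins
#'
#' Among the overlapping proteins of a catalogue (members of two or more
#' complexes), counts established drug targets and potential druggable
#' proteins, and tests with a one-sided binomial upper tail whether the
#' druggable fraction exceeds the genome-wide baseline `p0`. The default
#' baseline reflects roughly 2500 druggable proteins among about 20500
#' protein-coding genes.
#'
#' @param catalogue a [complex_catalogue()].
#' @param targets character vector of established drug-target symbols.
#' @param potential character vector of additional potentially druggable
#'   symbols (druggable-family members not yet targeted).
#' @param p0 baseline druggability probability in `(0, 1)`.
#' @return A list of class `druggability_report`: `n_targets`,
#'   `n_potential_targets`, `n_druggable`, `n_overlapping_nodes`, `ratio`,
#'   `p0`, `p_value`.
#' @export
druggability_test <- function(catalogue, targets, potential = character(0),
                              p0 = 2500 / 20500) {
  stopifnot(p0 > 0, p0 < 1)
  sets <- member_sets(catalogue)
  occ <- table(unlist(sets, use.names = FALSE))
  overlapping <- names(occ)[occ >= 2L]
  n_over <- length(overlapping)
  if (n_over == 0L) {
    stop("no overlapping proteins in the catalogue", call. = FALSE)
  }
  targets <- unique(targets)
  potential <- setdiff(unique(potential), targets)
  n_t <- sum(overlapping %in% targets)
  n_p <- sum(overlapping %in% potential)
  k <- n_t + n_p
  structure(list(n_targets = n_t, n_potential_targets = n_p,
                 n_druggable = k, n_overlapping_nodes = n_over,
                 ratio = k / n_over, p0 = p0,
                 p_value = stats::pbinom(k - 1L, n_over, p0,
                                         lower.tail = FALSE)),
            class = "druggability_report")
}

#' @export
print.druggability_report <- function(x, ...) {
  cat(sprintf(
    "druggability_report: %d/%d overlapping proteins druggable (%.3f); p = %.3g (p0 = %.3f)\n",
    x$n_druggable, x$n_overlapping_nodes, x$ratio, x$p_value, x$p0))
  invisible(x)
}
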