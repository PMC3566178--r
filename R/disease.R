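# Disease-gene evidence aggregation (Fisher's method), hypergeometric
# disease-complex association, disease-specific complex-drug subnetworks and
# drug-repositioning candidates.

#' Combine p-values with Fisher's method
#'
#' Refers `-2 * sum(log(p))` to a chi-square distribution with `2k` degrees
#' of freedom. A single p-value is returned unchanged.
#'
#' @param pvals numeric vector of p-values, each in `(0, 1]`.
#' @return Combined p-value in `(0, 1]`.
#' @export
fisher_meta <- function(pvals) {
  if (length(pvals) == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (length(pvals) == 1L) return(pvals)
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals),
                lower.tail = FALSE)
}

#' Aggregate per-study disease-gene p-values
#'
#' Collapses repeated (disease, gene) rows — the same association reported
#' by different studies — into one row with the Fisher meta p-value.
#'
#' @param evidence data frame with columns `disease`, `gene`, `p_value`
#'   (see [read_disease_genes()]).
#' @return Data frame with columns `disease`, `gene`, `n_studies`,
#'   `meta_p`.
#' @export
combine_gene_pvalues <- function(evidence) {
  key <- paste(evidence$disease, evidence$gene, sep = "\r")
  grp <- split(seq_len(nrow(evidence)), key)
  rows <- lapply(grp, function(ix) {
    data.frame(disease = evidence$disease[ix[1L]],
               gene = evidence$gene[ix[1L]],
               n_studies = length(ix),
               meta_p = fisher_meta(evidence$p_value[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$disease, out$gene), , drop = FALSE]
}

#' Filter disease-gene associations by meta p-value
#'
#' Keeps associations whose combined p-value falls below `cutoff` and
#' reports the retained gene sets per disease. The cutoff is a deliberate,
#' always-logged parameter of any genome-wide association extract.
#'
#' @param combined output of [combine_gene_pvalues()].
#' @param cutoff p-value cutoff (default `1e-5`).
#' @param quiet suppress the log message.
#' @return Named list: disease id -> character vector of associated genes.
#' @export
filter_disease_genes <- function(combined, cutoff = 1e-5, quiet = FALSE) {
  keep <- combined$meta_p < cutoff
  if (!quiet) {
    message(sprintf("filter_disease_genes: cutoff %g keeps %d/%d associations",
                    cutoff, sum(keep), length(keep)))
  }
  kept <- combined[keep, , drop = FALSE]
  lapply(split(kept$gene, kept$disease), unique)
}

#' Hypergeometric disease-complex association
#'
#' For each complex of size `n` in a universe of `N` proteins, of which `K`
#' are associated with the disease, computes the upper-tail hypergeometric
#' probability of observing at least the actual overlap `t`:
#' `p = sum_{k >= t} C(K, k) C(N - K, n - k) / C(N, n)` (the observed
#' overlap is included in the tail). Associations with `p < alpha` are
#' flagged significant.
#'
#' @param catalogue a [complex_catalogue()].
#' @param disease_genes character vector of disease-associated gene symbols;
#'   genes outside the universe are dropped with a warning.
#' @param universe protein universe; defaults to all proteins of the
#'   catalogue.
#' @param alpha significance level on the (by default unadjusted) p-values.
#' @param adjust `"none"` (default, a raw cut at `alpha`) or `"BH"` for a
#'   Benjamini-Hochberg adjustment before the cut.
#' @return Data frame with one row per complex: `complex`, `N`, `K`, `n`,
#'   `t`, `p_value`, `significant`, sorted by increasing p-value.
#' @export
disease_complex_enrichment <- function(catalogue, disease_genes,
                                       universe = NULL, alpha = 0.05,
                                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  sets <- member_sets(catalogue)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(universe)
  disease_genes <- unique(disease_genes)
  outside <- setdiff(disease_genes, universe)
  if (length(outside)) {
    warning(sprintf("%d disease gene(s) outside the universe dropped",
                    length(outside)))
    disease_genes <- intersect(disease_genes, universe)
  }
  N <- length(universe)
  K <- length(disease_genes)
  rows <- lapply(names(sets), function(id) {
    m <- intersect(sets[[id]], universe)
    n <- length(m)
    t <- sum(m %in% disease_genes)
    p <- if (t == 0L) 1 else
      stats::phyper(t - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(complex = id, N = N, K = K, n = n, t = t, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_for_cut <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else
    out$p_value
  out$significant <- p_for_cut < alpha
  out <- out[order(out$p_value, out$complex), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Disease-specific complex-drug subnetwork
#'
#' The induced bipartite subgraph over the complexes significantly
#' associated with a disease and every drug adjacent to one of them in the
#' drug-complex network. Significant complexes with no adjacent drug are
#' retained as isolated nodes — they mark disease biology not yet reached
#' by any drug.
#'
#' @param associations output of [disease_complex_enrichment()] for one
#'   disease.
#' @param net a [build_drug_complex_network()] result.
#' @param disease disease identifier carried through to the result.
#' @return A list of class `disease_subnetwork`: `disease`, `complexes`
#'   (all significant complex ids), `drugs`, `edges` (data frame `drug`,
#'   `complex`).
#' @export
disease_subnetwork <- function(associations, net, disease = NA_character_) {
  stopifnot(inherits(net, "drug_complex_network"))
  sig <- associations$complex[associations$significant]
  edges <- net$edges[net$edges$complex %in% sig, c("drug", "complex"),
                     drop = FALSE]
  rownames(edges) <- NULL
  structure(list(disease = disease, complexes = sig,
                 drugs = unique(edges$drug), edges = edges),
            class = "disease_subnetwork")
}

#' @export
print.disease_subnetwork <- function(x, ...) {
  cat(sprintf(
    "disease_subnetwork '%s': %d complexes (%d drug-free), %d drugs, %d edges\n",
    x$disease, length(x$complexes),
    length(setdiff(x$complexes, x$edges$complex)), length(x$drugs),
    nrow(x$edges)))
  invisible(x)
}

#' Enumerate drug-repositioning candidates
#'
#' Every drug adjacent to a significant disease complex is a repositioning
#' candidate for that disease; the supporting complexes are listed with the
#' candidate. One candidate is emitted per (disease, drug) pair.
#'
#' @param subnetworks a [disease_subnetwork()] or a list of them.
#' @return Data frame with columns `disease`, `drug`, `n_support`,
#'   `complexes` (supporting complex ids joined by `";"`).
#' @export
repositioning_candidates <- function(subnetworks) {
  if (inherits(subnetworks, "disease_subnetwork")) {
    subnetworks <- list(subnetworks)
  }
  rows <- lapply(subnetworks, function(sn) {
    if (nrow(sn$edges) == 0L) return(NULL)
    by_drug <- split(sn$edges$complex, sn$edges$drug)
    data.frame(disease = sn$disease, drug = names(by_drug),
               n_support = lengths(lapply(by_drug, unique)),
               complexes = vapply(by_drug, function(cc)
                 paste(sort(unique(cc)), collapse = ";"), character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(disease = character(0), drug = character(0),
                      n_support = integer(0), complexes = character(0),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[order(out$disease, out$drug), , drop = FALSE]
}
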