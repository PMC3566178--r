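# End-to-end driver: compile a catalogue from a (typically simulated) input
# bundle and run every downstream analysis. This is the programmatic
# equivalent of running the stages one by one and is what the reproduction
# script executes.

#' Run the full catalogue pipeline on an input bundle
#'
#' Scores and compiles the raw catalogue, derives co-complex pairs and
#' their PPI overlap, builds the drug-complex network with hub statistics,
#' runs the DDI permutation test, computes disease-complex enrichment and
#' repositioning candidates for every disease, and — when the bundle
#' carries planted ground truth — measures true-complex recovery and
#' evaluates the compiled catalogue against the true one.
#'
#' @param bundle a [simulate_bundle()] / [read_bundle()] result, or a
#'   directory path understood by [read_bundle()].
#' @param overlap_thres,merge_thres compilation thresholds, see
#'   [compile_catalogue()].
#' @param passes compilation passes.
#' @param gwas_cutoff disease-gene meta p-value cutoff.
#' @param alpha disease-complex significance level.
#' @param reps DDI permutation replicates.
#' @param seed seed for the permutation draws.
#' @param omega evaluation match threshold.
#' @return A list of class `pipeline_result` with elements `compilation`,
#'   `raw_stats`, `compiled_stats`, `ppi_overlap`, `network`, `degrees`,
#'   `degrees_dedup`, `ddi`, `enrichment` (per disease), `subnetworks`,
#'   `candidates`, and, with ground truth, `recovery` and `evaluation`.
#' @export
run_pipeline <- function(bundle, overlap_thres = 0.5, merge_thres = 0.8,
                         passes = 2L, gwas_cutoff = 1e-5, alpha = 0.05,
                         reps = 1000L, seed = 1L, omega = 0.2) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  raw <- score_catalogue(bundle$raw_catalogue, bundle$annot, bundle$dag,
                         quiet = TRUE)
  comp <- compile_catalogue(raw, overlap_thres = overlap_thres,
                            merge_thres = merge_thres, passes = passes,
                            annot = bundle$annot, dag = bundle$dag)
  catalogue <- comp$catalogue
  pairs <- cocomplex_pairs(catalogue)
  ppi_overlap <- overlap_report(pairs, list(PPI = bundle$ppi))
  net <- build_drug_complex_network(catalogue, bundle$targets)
  ddi <- ddi_permutation_test(net, bundle$ddis, reps = reps, seed = seed)
  combined <- combine_gene_pvalues(bundle$disease_evidence)
  disease_genes <- filter_disease_genes(combined, cutoff = gwas_cutoff,
                                        quiet = TRUE)
  enrichment <- lapply(disease_genes, function(gs)
    suppressWarnings(disease_complex_enrichment(catalogue, gs, alpha = alpha)))
  subnetworks <- lapply(names(enrichment), function(d)
    disease_subnetwork(enrichment[[d]], net, disease = d))
  names(subnetworks) <- names(enrichment)
  candidates <- repositioning_candidates(subnetworks)
  out <- list(compilation = comp,
              raw_stats = catalogue_stats(bundle$raw_catalogue),
              compiled_stats = catalogue_stats(catalogue),
              residual_redundancy = count_redundancy(catalogue, overlap_thres),
              ppi_overlap = ppi_overlap,
              network = net,
              degrees = degree_report(net, dedup = FALSE),
              degrees_dedup = degree_report(net, dedup = TRUE),
              ddi = ddi,
              enrichment = enrichment,
              subnetworks = subnetworks,
              candidates = candidates)
  if (!is.null(bundle$true_complexes)) {
    out$recovery <- true_complex_recovery(catalogue, bundle$true_complexes)
    out$evaluation <- evaluate_complexes(catalogue, bundle$true_complexes,
                                         omega = omega)
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  raw: %d complexes -> compiled: %d (residual redundancy %d)\n",
              x$raw_stats$n_complexes, x$compiled_stats$n_complexes,
              x$residual_redundancy))
  cat(sprintf("  co-complex pairs: %d (PPI overlap %.2f%%)\n",
              x$ppi_overlap$n_pairs, x$ppi_overlap$overlaps$ratio[1L]))
  cat(sprintf("  drug-complex network: %d drugs, %d complexes, %d edges\n",
              length(x$network$drugs), length(x$network$complexes),
              nrow(x$network$edges)))
  cat(sprintf("  DDI test: observed %d vs null mean %.1f (p = %.4g)\n",
              x$ddi$observed, x$ddi$null_mean, x$ddi$p_value))
  cat(sprintf("  repositioning candidates: %d (%d drugs, %d diseases)\n",
              nrow(x$candidates), length(unique(x$candidates$drug)),
              length(unique(x$candidates$disease))))
  if (!is.null(x$recovery)) {
    cat(sprintf("  true-complex recovery: %.1f%%; evaluation F = %.3f\n",
                100 * x$recovery, x$evaluation$f_measure))
  }
  invisible(x)
}
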