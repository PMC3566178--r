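# Seeded generators for every input the pipeline consumes: a GO-like DAG
# with gene annotations that make true complexes functionally coherent, a
# redundant raw catalogue with perturbed cross-"database" copies, a PPI
# network enriched for co-complex edges, a heavy-tailed drug-target table,
# drug-drug interactions enriched among co-complex drug pairs, and disease
# gene sets planted inside chosen complexes. Every planted answer is
# recorded in a manifest so downstream assertions never re-derive ground
# truth.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale study: a few hundred genes annotated over
#' a ~120-term biological-process-like DAG, 50 true complexes of 5-10
#' members copied redundantly across pseudo-sources with at most one member
#' edited per copy, a PPI network where half of all co-complex pairs are
#' observed against a 1% background, ~120 drugs with power-law target
#' counts, and drug-drug interactions four times as likely among co-complex
#' drug pairs as among random ones.
#'
#' @param seed integer; fixes every draw of the bundle.
#' @param n_terms number of GO-like terms (>= 2).
#' @param n_genes size of the gene universe.
#' @param n_true_complexes number of planted true complexes.
#' @param size_range inclusive range of complex sizes.
#' @param redundancy_rate fraction of true complexes emitted with redundant
#'   perturbed copies.
#' @param copies_range inclusive range of perturbed copies per selected
#'   complex.
#' @param perturb_ops number of member edits (add or remove one gene) per
#'   copy.
#' @param p_add probability that an edit adds a gene (otherwise removes
#'   one).
#' @param jaccard_floor minimum Jaccard between a copy and its original;
#'   edits that would cross it are skipped.
#' @param p_theme probability a member is annotated with each of its
#'   complex's theme terms.
#' @param p_noise_term probability of one extra random term per gene.
#' @param p_unannotated probability that a background gene carries no
#'   annotation.
#' @param ppi_p_in probability a co-complex pair appears in the PPI set.
#' @param ppi_p_bg probability for background pairs (must be `< ppi_p_in`).
#' @param n_drugs number of drugs.
#' @param target_alpha exponent of the truncated power law for
#'   targets-per-drug.
#' @param max_targets upper truncation of targets-per-drug.
#' @param target_complex_frac fraction of targets drawn from complex
#'   members (the rest from the whole universe).
#' @param n_ddis number of known drug-drug interaction pairs.
#' @param ddi_enrichment odds multiplier for drawing a DDI from the
#'   co-complex drug pairs (>= 1).
#' @param n_diseases number of diseases, each planted in one true complex.
#' @param leak_rate probability a planted complex member is dropped from
#'   its disease set.
#' @param disease_extra_genes random non-planted genes added per disease.
#' @param gwas_cutoff p-value cutoff the disease-gene file is built around:
#'   intended disease genes receive per-study p-values below it, decoys
#'   above.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_terms = 120L,
                             n_genes = 400L,
                             n_true_complexes = 50L,
                             size_range = c(5L, 10L),
                             redundancy_rate = 0.4,
                             copies_range = c(1L, 3L),
                             perturb_ops = 1L,
                             p_add = 0.5,
                             jaccard_floor = 0.6,
                             p_theme = 0.9,
                             p_noise_term = 0.3,
                             p_unannotated = 0.05,
                             ppi_p_in = 0.5,
                             ppi_p_bg = 0.01,
                             n_drugs = 120L,
                             target_alpha = 2.2,
                             max_targets = 8L,
                             target_complex_frac = 0.8,
                             n_ddis = 150L,
                             ddi_enrichment = 4,
                             n_diseases = 5L,
                             leak_rate = 0.1,
                             disease_extra_genes = 15L,
                             gwas_cutoff = 1e-5) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_terms >= 2L, cfg$size_range[1L] >= 2L,
            cfg$redundancy_rate >= 0, cfg$redundancy_rate <= 1,
            cfg$p_add >= 0, cfg$p_add <= 1,
            cfg$ppi_p_in > cfg$ppi_p_bg,
            cfg$ddi_enrichment >= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a GO-like DAG with complex-coherent gene annotations
#'
#' Builds a rooted random tree over `n_terms` terms plus extra typed edges
#' (all edges point from later to earlier terms, so acyclicity is
#' guaranteed), then annotates genes: every true complex owns a small
#' "theme" of terms that its members carry with high probability, so
#' within-complex semantic similarity separates true complexes from random
#' gene sets. Uses the current RNG state; seed via [simulate_bundle()] or
#' `set.seed()`.
#'
#' @param cfg a [synthetic_config()].
#' @param true_complexes a [complex_catalogue()] of the planted complexes.
#' @return List with `dag` (a [go_dag()]), `annot` (named list gene ->
#'   terms) and `themes` (list complex id -> theme terms).
#' @export
make_go_dag <- function(cfg, true_complexes) {
  terms <- sprintf("T%04d", seq_len(cfg$n_terms))
  if (cfg$n_terms == 1L) {
    dag <- go_dag(data.frame(child = character(0), parent = character(0),
                             type = character(0)), terms = terms)
  } else {
    parent_of <- vapply(2:cfg$n_terms, function(i)
      sample.int(i - 1L, 1L), integer(1))
    type <- sample(c("is_a", "part_of"), cfg$n_terms - 1L, replace = TRUE,
                   prob = c(0.8, 0.2))
    # extra cross edges, still child(later) -> parent(earlier)
    n_extra <- max(0L, round(0.3 * cfg$n_terms))
    extra_child <- sample(3:cfg$n_terms, n_extra, replace = TRUE)
    extra_parent <- vapply(extra_child, function(i)
      sample.int(i - 2L, 1L), integer(1))
    edges <- data.frame(
      child = terms[c(2:cfg$n_terms, extra_child)],
      parent = terms[c(parent_of, extra_parent)],
      type = c(type, sample(c("is_a", "part_of"), n_extra, replace = TRUE,
                            prob = c(0.8, 0.2))),
      stringsAsFactors = FALSE)
    edges <- edges[!duplicated(paste(edges$child, edges$parent)), ]
    dag <- go_dag(edges, terms = terms)
  }
  genes <- unique(unlist(true_complexes$members, use.names = FALSE))
  universe <- sprintf("G%04d", seq_len(cfg$n_genes))
  annot <- stats::setNames(vector("list", length(universe)), universe)
  themes <- stats::setNames(vector("list", nrow(true_complexes)),
                            true_complexes$id)
  for (i in seq_len(nrow(true_complexes))) {
    theme <- sample(terms, min(2L, length(terms)))
    themes[[i]] <- theme
    for (g in true_complexes$members[[i]]) {
      got <- theme[stats::runif(length(theme)) < cfg$p_theme]
      annot[[g]] <- union(annot[[g]], got)
    }
  }
  for (g in universe) {
    if (g %in% genes) {
      if (stats::runif(1) < cfg$p_noise_term) {
        annot[[g]] <- union(annot[[g]], sample(terms, 1L))
      }
      if (length(annot[[g]]) == 0L) annot[[g]] <- sample(terms, 1L)
    } else if (stats::runif(1) >= cfg$p_unannotated) {
      annot[[g]] <- sample(terms, sample(2:3, 1L))
    } else {
      annot[[g]] <- character(0)
    }
  }
  list(dag = dag, annot = annot, themes = themes)
}

# Sample the planted true complexes from the gene universe.
make_true_complexes <- function(cfg) {
  universe <- sprintf("G%04d", seq_len(cfg$n_genes))
  sizes <- sample(cfg$size_range[1L]:cfg$size_range[2L],
                  cfg$n_true_complexes, replace = TRUE)
  members <- lapply(sizes, function(s) sample(universe, s))
  complex_catalogue(sprintf("true%03d", seq_len(cfg$n_true_complexes)),
                    "TRUTH", members)
}

#' Generate a redundant raw catalogue from true complexes
#'
#' A fraction `redundancy_rate` of the true complexes is re-emitted as 1-3
#' perturbed copies under pseudo-source names (`DB1`, `DB2`, ...); each
#' copy differs from its original by `perturb_ops` single-member edits
#' (add or remove), never crossing `jaccard_floor`. Provenance records the
#' true origin of every emitted complex.
#'
#' @param cfg a [synthetic_config()].
#' @param true_complexes a [complex_catalogue()].
#' @return List with `catalogue` (raw redundant catalogue) and `provenance`
#'   (data frame `id`, `true_id`, `is_copy`, `jaccard_to_true`).
#' @export
make_redundant_catalogue <- function(cfg, true_complexes) {
  universe <- sprintf("G%04d", seq_len(cfg$n_genes))
  ids <- true_complexes$id
  sources <- rep("DB1", nrow(true_complexes))
  members <- true_complexes$members
  prov <- data.frame(id = ids, true_id = ids, is_copy = FALSE,
                     jaccard_to_true = 1, stringsAsFactors = FALSE)
  n_copy_sources <- 3L
  dup <- which(stats::runif(nrow(true_complexes)) < cfg$redundancy_rate)
  copy_n <- 0L
  for (i in dup) {
    n_copies <- sample(cfg$copies_range[1L]:cfg$copies_range[2L], 1L)
    for (k in seq_len(n_copies)) {
      m <- true_complexes$members[[i]]
      for (op in seq_len(cfg$perturb_ops)) {
        if (stats::runif(1) < cfg$p_add) {
          cand <- union(m, sample(setdiff(universe, m), 1L))
        } else if (length(m) > 2L) {
          cand <- m[-sample.int(length(m), 1L)]
        } else {
          cand <- m
        }
        if (jaccard(cand, true_complexes$members[[i]]) >= cfg$jaccard_floor) {
          m <- cand
        }
      }
      copy_n <- copy_n + 1L
      cid <- sprintf("copy%03d", copy_n)
      ids <- c(ids, cid)
      sources <- c(sources, sprintf("DB%d", 1L + (k %% n_copy_sources) + 1L))
      members <- c(members, list(m))
      prov <- rbind(prov, data.frame(
        id = cid, true_id = true_complexes$id[i], is_copy = TRUE,
        jaccard_to_true = jaccard(m, true_complexes$members[[i]]),
        stringsAsFactors = FALSE))
    }
  }
  list(catalogue = complex_catalogue(ids, sources, members),
       provenance = prov)
}

#' Generate a PPI pair set enriched for co-complex pairs
#'
#' Every co-complex pair of the true catalogue is included with probability
#' `ppi_p_in`; pairs of the remaining gene-universe background with
#' probability `ppi_p_bg`.
#'
#' @param cfg a [synthetic_config()] (requires `ppi_p_in > ppi_p_bg`).
#' @param true_complexes a [complex_catalogue()].
#' @return Canonical pair data frame with columns `a`, `b`.
#' @export
make_ppi <- function(cfg, true_complexes) {
  stopifnot(cfg$ppi_p_in > cfg$ppi_p_bg)
  cc <- cocomplex_pairs(true_complexes)
  keep <- stats::runif(nrow(cc)) < cfg$ppi_p_in
  inside <- cc[keep, , drop = FALSE]
  universe <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_all <- choose(length(universe), 2)
  n_bg <- stats::rbinom(1L, n_all, cfg$ppi_p_bg)
  ij <- decode_pair_index(sample.int(n_all, n_bg), length(universe))
  bg <- data.frame(a = universe[ij[, 1L]], b = universe[ij[, 2L]],
                   stringsAsFactors = FALSE)
  cc_keys <- pair_key(cc$a, cc$b)
  bg <- bg[!(pair_key(bg$a, bg$b) %in% cc_keys), , drop = FALSE]
  out <- canonicalize_pairs(c(inside$a, bg$a), c(inside$b, bg$b))
  out[order(out$a, out$b), , drop = FALSE]
}

#' Generate drug-target, drug-drug-interaction and disease-gene data
#'
#' Targets-per-drug follow a truncated discrete power law (`P(k)
#' proportional to k^-target_alpha`, `k <= max_targets`), with targets
#' drawn preferentially from catalogue members so the drug-complex network
#' is non-trivial. DDI pairs are sampled with odds `ddi_enrichment` in
#' favor of co-complex drug pairs. Each disease is planted in one true
#' complex: its gene set is the complex members minus `leak_rate` dropouts
#' plus random extra genes, encoded as per-study GWAS-like p-values below
#' `gwas_cutoff` (with above-cutoff decoy genes added).
#'
#' @param cfg a [synthetic_config()].
#' @param catalogue the catalogue the drug network will be built on
#'   (typically the true complexes).
#' @return List with `targets` (named list drug -> target symbols), `ddis`
#'   (canonical pair data frame), `disease_evidence` (data frame `disease`,
#'   `gene`, `p_value`), `disease_genes` (intended post-filter gene sets),
#'   `planted` (data frame `disease`, `complex`).
#' @export
make_pharmacology <- function(cfg, catalogue) {
  universe <- sprintf("G%04d", seq_len(cfg$n_genes))
  complex_proteins <- unique(unlist(catalogue$members, use.names = FALSE))
  # truncated discrete power law for targets per drug
  k_support <- seq_len(cfg$max_targets)
  k_prob <- k_support^(-cfg$target_alpha)
  drugs <- sprintf("drug%03d", seq_len(cfg$n_drugs))
  n_targets <- sample(k_support, cfg$n_drugs, replace = TRUE,
                      prob = k_prob / sum(k_prob))
  targets <- stats::setNames(lapply(seq_len(cfg$n_drugs), function(i) {
    pool_complex <- stats::runif(n_targets[i]) < cfg$target_complex_frac
    unique(c(sample(complex_proteins, sum(pool_complex), replace = TRUE),
             sample(universe, sum(!pool_complex), replace = TRUE)))
  }), drugs)
  net <- build_drug_complex_network(catalogue, targets)
  cc_drug <- cocomplex_drug_pairs(net)
  cc_keys <- pair_key(cc_drug$a, cc_drug$b)
  n_all <- choose(cfg$n_drugs, 2)
  ij <- decode_pair_index(seq_len(n_all), cfg$n_drugs)
  all_a <- drugs[ij[, 1L]]
  all_b <- drugs[ij[, 2L]]
  w <- ifelse(pair_key(all_a, all_b) %in% cc_keys, cfg$ddi_enrichment, 1)
  pick <- sample.int(n_all, min(cfg$n_ddis, n_all), prob = w)
  ddis <- canonicalize_pairs(all_a[pick], all_b[pick])
  # diseases planted in distinct true complexes
  planted_idx <- sample.int(nrow(catalogue),
                            min(cfg$n_diseases, nrow(catalogue)))
  diseases <- sprintf("disease%02d", seq_along(planted_idx))
  ev <- list()
  disease_genes <- stats::setNames(vector("list", length(diseases)), diseases)
  for (d in seq_along(planted_idx)) {
    m <- catalogue$members[[planted_idx[d]]]
    kept <- m[stats::runif(length(m)) >= cfg$leak_rate]
    if (length(kept) == 0L) kept <- m[1L]
    extra <- sample(setdiff(universe, m), cfg$disease_extra_genes)
    genes <- c(kept, extra)
    disease_genes[[d]] <- genes
    for (g in genes) {
      n_st <- sample(1:3, 1L)
      # per-study p-values that pass the GWAS cutoff after Fisher pooling
      ev[[length(ev) + 1L]] <- data.frame(
        disease = diseases[d], gene = g,
        p_value = 10^-stats::runif(n_st, 6.5, 10),
        stringsAsFactors = FALSE)
    }
    decoys <- sample(setdiff(universe, genes), cfg$disease_extra_genes)
    for (g in decoys) {
      ev[[length(ev) + 1L]] <- data.frame(
        disease = diseases[d], gene = g,
        p_value = 10^-stats::runif(1L, 0, 3),
        stringsAsFactors = FALSE)
    }
  }
  list(targets = targets, ddis = ddis,
       disease_evidence = do.call(rbind, ev),
       disease_genes = disease_genes,
       planted = data.frame(disease = diseases,
                            complex = catalogue$id[planted_idx],
                            stringsAsFactors = FALSE))
}

#' Simulate a complete input bundle
#'
#' Runs every generator under one seed and returns all pipeline inputs plus
#' a manifest of planted answers (redundant-copy provenance, planted
#' disease complexes, generator configuration).
#'
#' @param cfg a [synthetic_config()].
#' @param seed optional override of `cfg$seed`.
#' @return A list of class `synthetic_bundle`: `true_complexes`,
#'   `raw_catalogue`, `dag`, `annot`, `ppi`, `targets`, `ddis`,
#'   `disease_evidence`, `manifest` (with `provenance`, `planted_diseases`,
#'   `disease_genes`, `themes`, `config`).
#' @export
simulate_bundle <- function(cfg = synthetic_config(), seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed %||% cfg$seed)
  true_complexes <- make_true_complexes(cfg)
  onto <- make_go_dag(cfg, true_complexes)
  red <- make_redundant_catalogue(cfg, true_complexes)
  ppi <- make_ppi(cfg, true_complexes)
  pharma <- make_pharmacology(cfg, true_complexes)
  structure(list(true_complexes = true_complexes,
                 raw_catalogue = red$catalogue,
                 dag = onto$dag,
                 annot = onto$annot,
                 ppi = ppi,
                 targets = pharma$targets,
                 ddis = pharma$ddis,
                 disease_evidence = pharma$disease_evidence,
                 manifest = list(provenance = red$provenance,
                                 planted_diseases = pharma$planted,
                                 disease_genes = pharma$disease_genes,
                                 themes = onto$themes,
                                 config = cfg)),
            class = "synthetic_bundle")
}

#' Write a simulated bundle to disk
#'
#' Emits every component in exactly the formats the readers consume
#' (complex TSVs, OBO subset, annotation/target/pair/disease TSVs) plus a
#' JSON manifest, so end-to-end runs can start from files.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_complexes(bundle$true_complexes, fp("true_complexes.tsv"))
  write_complexes(bundle$raw_catalogue, fp("raw_catalogue.tsv"))
  write_obo_subset(bundle$dag, fp("ontology.obo"))
  write_annotations(bundle$annot, fp("annotations.tsv"))
  write_pairs(bundle$ppi, fp("ppi.tsv"))
  write_drug_targets(bundle$targets, fp("drug_targets.tsv"))
  write_pairs(bundle$ddis, fp("ddis.tsv"))
  write_disease_genes(bundle$disease_evidence, fp("disease_genes.tsv"))
  manifest <- bundle$manifest
  manifest$config <- unclass(manifest$config)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir directory containing the bundle files.
#' @return A list of class `synthetic_bundle` (manifest config is a plain
#'   list).
#' @export
read_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  dag <- read_obo_subset(fp("ontology.obo"))
  manifest <- jsonlite::read_json(fp("manifest.json"), simplifyVector = TRUE)
  manifest$disease_genes <- lapply(manifest$disease_genes, as.character)
  manifest$themes <- lapply(manifest$themes, as.character)
  structure(list(true_complexes = read_complexes(fp("true_complexes.tsv")),
                 raw_catalogue = read_complexes(fp("raw_catalogue.tsv")),
                 dag = dag,
                 annot = read_annotations(fp("annotations.tsv"), dag),
                 ppi = read_pairs(fp("ppi.tsv")),
                 targets = read_drug_targets(fp("drug_targets.tsv")),
                 ddis = read_pairs(fp("ddis.tsv")),
                 disease_evidence = read_disease_genes(fp("disease_genes.tsv")),
                 manifest = manifest),
            class = "synthetic_bundle")
}

#' Fraction of true complexes recovered by a compiled catalogue
#'
#' A true complex counts as recovered when some retained complex matches it
#' at Jaccard >= `threshold`, each retained complex matching at most one
#' true complex (greedy best-first assignment).
#'
#' @param compiled a [complex_catalogue()] (e.g.
#'   `compile_catalogue(...)$catalogue`).
#' @param true_complexes the planted [complex_catalogue()].
#' @param threshold Jaccard match threshold (default 0.8).
#' @return Fraction in `[0, 1]`.
#' @export
true_complex_recovery <- function(compiled, true_complexes, threshold = 0.8) {
  comp <- member_sets(compiled)
  truth <- member_sets(true_complexes)
  if (length(truth) == 0L) return(NA_real_)
  jmat <- outer(seq_along(truth), seq_along(comp),
                Vectorize(function(i, j) jaccard(truth[[i]], comp[[j]])))
  recovered <- 0L
  used_comp <- rep(FALSE, length(comp))
  done_truth <- rep(FALSE, length(truth))
  for (k in order(-jmat)) {
    if (jmat[k] < threshold) break
    i <- (k - 1L) %% length(truth) + 1L
    j <- (k - 1L) %/% length(truth) + 1L
    if (used_comp[j] || done_truth[i]) next
    used_comp[j] <- TRUE
    done_truth[i] <- TRUE
    recovered <- recovered + 1L
  }
  recovered / length(truth)
}
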