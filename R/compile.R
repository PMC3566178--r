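# Catalogue compilation: score every complex by the mean GO semantic
# similarity of its member pairs, rank by that score, then sweep the ranking
# once, absorbing (member union) near-identical lower-ranked complexes and
# discarding moderately overlapping ones.

#' Significance score of one complex
#'
#' The mean [gene_similarity()] over all unordered member pairs with a
#' defined similarity. Pairs involving unannotated genes are excluded from
#' the mean (their count is reported via the `n_excluded` attribute).
#' Singleton complexes, and complexes where no pair has a defined
#' similarity, score 0 so that they rank last and can never absorb an
#' annotated complex.
#'
#' @param members character vector of member gene symbols.
#' @param annot named list gene -> term ids.
#' @param dag a [go_dag()].
#' @return Numeric scalar in `[0, 1]` with attribute `n_excluded`.
#' @export
complex_significance <- function(members, annot, dag) {
  members <- unique(as.character(members))
  if (length(members) == 0L) {
    stop("complex has no members", call. = FALSE)
  }
  if (length(members) == 1L) {
    return(structure(0, n_excluded = 0L))
  }
  idx <- utils::combn(length(members), 2L)
  sims <- vapply(seq_len(ncol(idx)), function(k) {
    gene_similarity(annot, dag, members[idx[1L, k]], members[idx[2L, k]])
  }, numeric(1))
  n_excl <- sum(is.na(sims))
  defined <- sims[!is.na(sims)]
  score <- if (length(defined) == 0L) 0 else mean(defined)
  structure(score, n_excluded = n_excl)
}

#' Score every complex in a catalogue
#'
#' Adds (or replaces) the `score` column of a catalogue with
#' [complex_significance()] values. The number of member pairs excluded for
#' missing annotation is reported with a message.
#'
#' @param catalogue a [complex_catalogue()].
#' @param annot named list gene -> term ids.
#' @param dag a [go_dag()].
#' @param quiet suppress the exclusion message.
#' @return The catalogue with a `score` column.
#' @export
score_catalogue <- function(catalogue, annot, dag, quiet = FALSE) {
  stopifnot(inherits(catalogue, "complex_catalogue"))
  excl <- 0L
  scores <- vapply(catalogue$members, function(m) {
    s <- complex_significance(m, annot, dag)
    excl <<- excl + attr(s, "n_excluded")
    as.numeric(s)
  }, numeric(1))
  if (!quiet && excl > 0L) {
    message(sprintf("score_catalogue: %d member pair(s) excluded (unannotated gene)",
                    excl))
  }
  catalogue$score <- scores
  catalogue
}

# Rank: score desc, then size desc, then id asc — a stable, reproducible
# total order even under score ties.
rank_order <- function(catalogue) {
  order(-catalogue$score, -lengths(catalogue$members), catalogue$id,
        method = "radix")
}

#' Compile a non-redundant catalogue
#'
#' Implements the ranked redundancy sweep: complexes are ranked by
#' descending significance score and scanned in that order. For each
#' retained complex, every lower-ranked complex whose Jaccard coefficient
#' with it exceeds `overlap_thres` is removed — merged into the retained
#' complex (member union) when the coefficient also exceeds `merge_thres`
#' (the two are near-identical), discarded otherwise (keeping the
#' higher-scored of two moderately overlapping complexes). By default the
#' retained complex's grown member set is used for subsequent comparisons;
#' set `grow = FALSE` to always compare against its original members.
#'
#' A single pass can leave residual redundant pairs created by merging;
#' `passes > 1` repeats the sweep (re-scoring merged complexes when `annot`
#' and `dag` are supplied) until redundancy-free or the pass budget is
#' spent.
#'
#' @param catalogue a scored [complex_catalogue()] (see [score_catalogue()]).
#' @param overlap_thres overlapping threshold; pairs above it are redundant.
#' @param merge_thres merge threshold; redundant pairs above it are merged
#'   rather than discarded. Must satisfy
#'   `0 < overlap_thres < merge_thres < 1`.
#' @param passes maximum number of sweeps.
#' @param annot,dag optional; enable re-scoring of merged complexes between
#'   passes.
#' @param grow compare against the merged (growing) member set (default) or
#'   the original one.
#' @return A list of class `compilation_result`: `catalogue` (retained
#'   complexes in rank order), `merges` and `discards` (logs with the
#'   triggering Jaccard coefficients), `passes_run`.
#' @export
compile_catalogue <- function(catalogue, overlap_thres = 0.5,
                              merge_thres = 0.8, passes = 1L,
                              annot = NULL, dag = NULL, grow = TRUE) {
  stopifnot(inherits(catalogue, "complex_catalogue"))
  if (!("score" %in% names(catalogue)) || anyNA(catalogue$score)) {
    stop("catalogue must be scored before compilation (see score_catalogue)",
         call. = FALSE)
  }
  if (!(overlap_thres > 0 && overlap_thres < merge_thres && merge_thres < 1)) {
    stop("thresholds must satisfy 0 < overlap_thres < merge_thres < 1",
         call. = FALSE)
  }
  merges <- list()
  discards <- list()
  work <- catalogue
  passes_run <- 0L
  for (p in seq_len(passes)) {
    ord <- rank_order(work)
    ids <- work$id[ord]
    sets <- work$members[ord]
    orig <- sets  # frozen copies for grow = FALSE comparisons
    scores <- work$score[ord]
    sources <- work$source[ord]
    alive <- rep(TRUE, length(ids))
    removed_this_pass <- 0L
    for (i in seq_along(ids)) {
      if (!alive[i]) next
      for (j in seq_along(ids)) {
        if (j <= i || !alive[j]) next
        ref <- if (grow) sets[[i]] else orig[[i]]
        jac <- jaccard(ref, sets[[j]])
        if (jac > overlap_thres) {
          alive[j] <- FALSE
          removed_this_pass <- removed_this_pass + 1L
          if (jac > merge_thres) {
            sets[[i]] <- union(sets[[i]], sets[[j]])
            merges[[length(merges) + 1L]] <-
              data.frame(absorber = ids[i], absorbed = ids[j], jaccard = jac,
                         pass = p, stringsAsFactors = FALSE)
          } else {
            discards[[length(discards) + 1L]] <-
              data.frame(keeper = ids[i], discarded = ids[j], jaccard = jac,
                         pass = p, stringsAsFactors = FALSE)
          }
        }
      }
    }
    passes_run <- p
    work <- complex_catalogue(ids[alive], sources[alive], sets[alive],
                              score = scores[alive])
    if (!is.null(annot) && !is.null(dag) && p < passes) {
      work <- score_catalogue(work, annot, dag, quiet = TRUE)
    }
    if (removed_this_pass == 0L) break
  }
  structure(list(catalogue = work,
                 merges = do.call(rbind, merges) %||% data.frame(
                   absorber = character(0), absorbed = character(0),
                   jaccard = numeric(0), pass = integer(0)),
                 discards = do.call(rbind, discards) %||% data.frame(
                   keeper = character(0), discarded = character(0),
                   jaccard = numeric(0), pass = integer(0)),
                 passes_run = passes_run),
            class = "compilation_result")
}

#' @export
print.compilation_result <- function(x, ...) {
  cat(sprintf(
    "compilation_result: %d retained, %d merged, %d discarded (%d pass(es))\n",
    nrow(x$catalogue), nrow(x$merges), nrow(x$discards), x$passes_run))
  invisible(x)
}
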