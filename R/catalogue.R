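#' Construct a protein complex catalogue
#'
#' A catalogue is a data frame with one row per complex: a unique `id`, the
#' `source` database it came from, and a list column `members` holding the
#' member gene symbols of each complex. Member sets are de-duplicated on
#' construction; empty member sets and empty gene symbols are rejected. An
#' optional `score` column carries the significance score assigned by
#' [score_catalogue()].
#'
#' @param id character vector of complex identifiers (unique).
#' @param source character vector of source database labels (recycled if
#'   length 1).
#' @param members list of character vectors, one per complex; duplicates
#'   within a vector are collapsed.
#' @param score optional numeric vector of significance scores in `[0, 1]`.
#' @return An object of class `complex_catalogue` (a data frame).
#' @examples
#' cat <- complex_catalogue(c("c1", "c2"), "demo",
#'                          list(c("A", "B", "C"), c("B", "C", "D")))
#' catalogue_stats(cat)
#' @export
complex_catalogue <- function(id, source, members, score = NULL) {
  id <- as.character(id)
  if (length(source) == 1L) source <- rep(source, length(id))
  source <- as.character(source)
  stopifnot(length(id) == length(source), length(id) == length(members))
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicate complex id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  members <- lapply(members, function(m) unique(as.character(m)))
  sizes <- lengths(members)
  if (any(sizes == 0L)) {
    stop("complex(es) with empty member set: ",
         paste(id[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  if (any(vapply(members, function(m) any(!nzchar(m)), logical(1)))) {
    stop("empty gene symbol in member list", call. = FALSE)
  }
  out <- data.frame(id = id, source = source, stringsAsFactors = FALSE)
  out$members <- members
  if (!is.null(score)) {
    stopifnot(length(score) == length(id))
    out$score <- as.numeric(score)
  }
  class(out) <- c("complex_catalogue", "data.frame")
  out
}

#' @export
print.complex_catalogue <- function(x, ...) {
  cat(sprintf("complex_catalogue: %d complexes, %d proteins\n",
              nrow(x), length(unique(unlist(x$members)))))
  n <- min(nrow(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %s [%s]%s: %s\n", x$id[i], x$source[i],
                if ("score" %in% names(x)) sprintf(" score=%.3f", x$score[i]) else "",
                paste(sort(x$members[[i]]), collapse = ", ")))
  }
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}

# Extract member sets from a catalogue or a bare list of character vectors.
member_sets <- function(x) {
  if (inherits(x, "complex_catalogue")) {
    stats::setNames(x$members, x$id)
  } else if (is.list(x)) {
    lapply(x, function(m) unique(as.character(m)))
  } else {
    stop("expected a complex_catalogue or a list of member vectors",
         call. = FALSE)
  }
}

#' Jaccard coefficient between two member sets
#'
#' `|a intersect b| / |a union b|`, the set-overlap measure that drives all
#' redundancy decisions during catalogue compilation.
#'
#' @param a,b non-empty character vectors (treated as sets).
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("jaccard requires non-empty sets", call. = FALSE)
  }
  ni <- sum(a %in% b)
  ni / (length(a) + length(b) - ni)
}

#' Count redundant complex pairs in a catalogue
#'
#' Two complexes form a redundant pair when their Jaccard coefficient is
#' strictly greater than the overlapping threshold.
#'
#' @param catalogue a [complex_catalogue()] or list of member vectors.
#' @param overlap_thres overlapping threshold in `(0, 1)`.
#' @return Integer count of unordered redundant pairs.
#' @export
count_redundancy <- function(catalogue, overlap_thres = 0.5) {
  sets <- member_sets(catalogue)
  n <- length(sets)
  if (n < 2L) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (jaccard(sets[[i]], sets[[j]]) > overlap_thres) cnt <- cnt + 1L
    }
  }
  cnt
}

#' Summary statistics for a catalogue
#'
#' Reports the complex count, the number of distinct proteins, the number of
#' overlapping proteins (members of two or more complexes), and the mean
#' complex size.
#'
#' @param catalogue a [complex_catalogue()] or list of member vectors.
#' @return A list with elements `n_complexes`, `n_proteins`,
#'   `n_overlapping_proteins`, `avg_size`.
#' @export
catalogue_stats <- function(catalogue) {
  sets <- member_sets(catalogue)
  if (length(sets) == 0L) {
    warning("empty catalogue: average size undefined, reported as 0")
    return(list(n_complexes = 0L, n_proteins = 0L,
                n_overlapping_proteins = 0L, avg_size = 0))
  }
  all_members <- unlist(sets, use.names = FALSE)
  occ <- table(all_members)  # each set is de-duplicated, so occ = #complexes
  list(n_complexes = length(sets),
       n_proteins = length(occ),
       n_overlapping_proteins = sum(occ >= 2L),
       avg_size = mean(lengths(sets)))
}

#' Drop exact-duplicate member sets within each source
#'
#' Databases often carry literal duplicates of the same complex record. This
#' removes, within each source, every complex whose member set is identical
#' to an earlier one, and reports what was dropped.
#'
#' @param catalogue a [complex_catalogue()].
#' @return A list with `catalogue` (duplicates removed) and `dropped`, a data
#'   frame mapping each dropped id to the id it duplicated.
#' @export
dedup_exact <- function(catalogue) {
  stopifnot(inherits(catalogue, "complex_catalogue"))
  key <- paste(catalogue$source,
               vapply(catalogue$members,
                      function(m) paste(sort(m), collapse = "\r"), character(1)),
               sep = "\n")
  first <- !duplicated(key)
  dropped <- data.frame(
    id = catalogue$id[!first],
    duplicate_of = catalogue$id[match(key[!first], key)],
    stringsAsFactors = FALSE)
  if (nrow(dropped)) {
    message(sprintf("dedup_exact: dropped %d exact duplicate complex(es)",
                    nrow(dropped)))
  }
  list(catalogue = catalogue[first, , drop = FALSE], dropped = dropped)
}
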