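# Co-complex protein pairs and their overlap with reference PPI sets. The
# fraction of co-complex pairs that are also observed binary interactions is
# a quality proxy for a catalogue: a cleaner catalogue yields a higher
# overlap ratio.

#' Co-complex protein pairs of a catalogue
#'
#' The union, over all complexes, of every unordered pair of members of the
#' same complex. A pair occurring in several complexes is counted once.
#'
#' @param catalogue a [complex_catalogue()] or list of member vectors.
#' @return Canonical pair data frame with columns `a`, `b`.
#' @export
cocomplex_pairs <- function(catalogue) {
  sets <- member_sets(catalogue)
  per_complex <- lapply(sets, function(m) {
    if (length(m) < 2L) return(NULL)
    idx <- utils::combn(length(m), 2L)
    cbind(m[idx[1L, ]], m[idx[2L, ]])
  })
  mat <- do.call(rbind, per_complex)
  if (is.null(mat)) return(empty_pairs())
  canonicalize_pairs(mat[, 1L], mat[, 2L])
}

#' Overlap of a pair set with reference pair sets
#'
#' For each named reference (typically a PPI database extract), counts how
#' many of `pairs` occur in the reference and reports the percentage ratio.
#' Ratios are additionally rounded to two decimals in the `ratio_rounded`
#' column, the precision at which such tables are conventionally printed.
#'
#' @param pairs canonical pair data frame (e.g. from [cocomplex_pairs()]);
#'   must be non-empty, otherwise the ratio is undefined.
#' @param references named list of canonical pair data frames.
#' @return A list of class `pair_overlap_report` with `n_pairs` and a data
#'   frame `overlaps` (columns `reference`, `n_overlap`, `ratio`,
#'   `ratio_rounded`; `ratio` is a percentage).
#' @export
overlap_report <- function(pairs, references) {
  if (nrow(pairs) == 0L) {
    stop("empty co-complex pair set: overlap ratio undefined", call. = FALSE)
  }
  stopifnot(is.list(references), !is.null(names(references)))
  keys <- pair_key(pairs$a, pairs$b)
  rows <- lapply(names(references), function(nm) {
    ref <- references[[nm]]
    n_ov <- sum(keys %in% pair_key(ref$a, ref$b))
    data.frame(reference = nm, n_overlap = n_ov,
               ratio = 100 * n_ov / nrow(pairs),
               ratio_rounded = round(100 * n_ov / nrow(pairs), 2L),
               stringsAsFactors = FALSE)
  })
  structure(list(n_pairs = nrow(pairs), overlaps = do.call(rbind, rows)),
            class = "pair_overlap_report")
}

#' @export
print.pair_overlap_report <- function(x, ...) {
  cat(sprintf("pair_overlap_report: %d co-complex pairs\n", x$n_pairs))
  for (i in seq_len(nrow(x$overlaps))) {
    cat(sprintf("  %s: %d (%.2f%%)\n", x$overlaps$reference[i],
                x$overlaps$n_overlap[i], x$overlaps$ratio[i]))
  }
  invisible(x)
}
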