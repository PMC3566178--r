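# Readers and writers for the plain-text formats the pipeline exchanges:
# complex membership TSV, unordered pair TSV (PPIs, drug-drug interactions),
# gene->GO annotation TSV, drug->target TSV, disease-gene TSV with per-study
# p-values, and an OBO subset for the GO biological-process DAG.

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[!grepl("^#", lines) & nzchar(trimws(lines))]
}

#' Read a complex membership file
#'
#' One complex per line, tab-separated: complex id, source database, member
#' list joined by `member_sep`. Lines starting with `#` are comments.
#' Duplicate member symbols within a complex collapse to one; a duplicate
#' complex id or an empty member set is an error.
#'
#' @param path file path.
#' @param member_sep delimiter between member symbols (default `";"`).
#' @return A [complex_catalogue()] in file order.
#' @export
read_complexes <- function(path, member_sep = ";") {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) {
    return(complex_catalogue(character(0), character(0), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                 path, bad[1L]), call. = FALSE)
  }
  id <- vapply(fields, `[[`, character(1), 1L)
  source <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) {
    m <- strsplit(f[[3L]], member_sep, fixed = TRUE)[[1L]]
    m[nzchar(m)]
  })
  empty <- which(lengths(lapply(members, unique)) == 0L)
  if (length(empty)) {
    stop(sprintf("%s: empty member set at line %d (complex '%s')",
                 path, empty[1L], id[empty[1L]]), call. = FALSE)
  }
  complex_catalogue(id, source, members)
}

#' Write a complex membership file
#'
#' Inverse of [read_complexes()]. Members are written sorted so that a
#' read/write round trip is the identity on canonicalized catalogues.
#'
#' @param catalogue a [complex_catalogue()].
#' @param path file path.
#' @param member_sep delimiter between member symbols.
#' @export
write_complexes <- function(catalogue, path, member_sep = ";") {
  stopifnot(inherits(catalogue, "complex_catalogue"))
  header <- sprintf("# complex_id\tsource_db\tmembers (sep='%s')\t[complexcat %s]",
                    member_sep, as.character(utils::packageVersion("complexcat")))
  body <- sprintf("%s\t%s\t%s", catalogue$id, catalogue$source,
                  vapply(catalogue$members,
                         function(m) paste(sort(m), collapse = member_sep),
                         character(1)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an unordered pair list
#'
#' Two-column TSV of identifiers, interpreted as unordered pairs: `(a, b)`
#' and `(b, a)` are the same record and duplicates collapse. Self-pairs are
#' dropped with a warning (a self-interaction carries no co-complex meaning).
#'
#' @param path file path.
#' @return A data frame with columns `a`, `b`, canonically ordered
#'   (`a < b`) and de-duplicated.
#' @export
read_pairs <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) return(empty_pairs())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop(sprintf("%s: line %d has fewer than 2 fields", path, bad[1L]),
         call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  self <- a == b
  if (any(self)) {
    warning(sprintf("%s: dropped %d self-pair(s)", path, sum(self)))
    a <- a[!self]
    b <- b[!self]
  }
  canonicalize_pairs(a, b)
}

#' Write an unordered pair list
#' @param pairs data frame with columns `a`, `b`.
#' @param path file path.
#' @export
write_pairs <- function(pairs, path) {
  writeLines(c("# a\tb", sprintf("%s\t%s", pairs$a, pairs$b)), path)
  invisible(path)
}

#' Read gene annotations
#'
#' Two-column TSV mapping gene symbols to GO term ids; a gene may appear on
#' several lines. Genes listed with no valid term are recorded as unannotated
#' (an entry with an empty term vector).
#'
#' @param path file path.
#' @param dag optional [go_dag()]; when given, every term id must exist in it.
#' @return Named list: gene symbol -> character vector of term ids.
#' @export
read_annotations <- function(path, dag = NULL) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(fields, `[[`, character(1), 1L)
  term <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "",
                 character(1))
  annot <- lapply(split(term, gene), function(t) unique(t[nzchar(t)]))
  if (!is.null(dag)) {
    unknown <- setdiff(unique(unlist(annot)), dag$terms)
    if (length(unknown)) {
      stop("annotation references unknown GO term(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
  }
  annot
}

#' Write gene annotations
#' @param annot named list gene -> term ids.
#' @param path file path.
#' @export
write_annotations <- function(annot, path) {
  genes <- rep(names(annot), lengths(annot))
  terms <- unlist(annot, use.names = FALSE)
  # keep unannotated genes visible as a gene with an empty term field
  empty <- names(annot)[lengths(annot) == 0L]
  writeLines(c("# gene\tgo_term",
               sprintf("%s\t%s", c(genes, empty), c(terms, rep("", length(empty))))),
             path)
  invisible(path)
}

#' Read a drug-target table
#'
#' Two-column TSV: drug id, target gene symbol (one target per line).
#'
#' @param path file path.
#' @return Named list: drug id -> character vector of target symbols.
#' @export
read_drug_targets <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  drug <- vapply(fields, `[[`, character(1), 1L)
  target <- vapply(fields, `[[`, character(1), 2L)
  lapply(split(target, drug), unique)
}

#' Write a drug-target table
#' @param targets named list drug -> target symbols.
#' @param path file path.
#' @export
write_drug_targets <- function(targets, path) {
  writeLines(c("# drug\ttarget",
               sprintf("%s\t%s", rep(names(targets), lengths(targets)),
                       unlist(targets, use.names = FALSE))), path)
  invisible(path)
}

#' Read disease-gene evidence
#'
#' Three-column TSV: disease id, gene symbol, per-study association p-value.
#' The same (disease, gene) pair may appear once per study; combine the rows
#' with [combine_gene_pvalues()].
#'
#' @param path file path.
#' @return Data frame with columns `disease`, `gene`, `p_value`.
#' @export
read_disease_genes <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) {
    return(data.frame(disease = character(0), gene = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(disease = vapply(fields, `[[`, character(1), 1L),
             gene = vapply(fields, `[[`, character(1), 2L),
             p_value = as.numeric(vapply(fields, `[[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Write disease-gene evidence
#' @param evidence data frame with columns `disease`, `gene`, `p_value`.
#' @param path file path.
#' @export
write_disease_genes <- function(evidence, path) {
  writeLines(c("# disease\tgene\tp_value",
               sprintf("%s\t%s\t%.6g", evidence$disease, evidence$gene,
                       evidence$p_value)), path)
  invisible(path)
}

#' Read a GO DAG from an OBO subset
#'
#' Consumes only `[Term]` stanzas and, within them, the `id`, `name`,
#' `is_a`, `relationship: part_of` and `is_obsolete` fields. Obsolete terms
#' and their edges are skipped. The resulting graph is validated: every edge
#' endpoint must be a known term and the graph must be acyclic.
#'
#' @param path file path.
#' @param weights named edge-type contribution weights, see [go_dag()].
#' @return A [go_dag()].
#' @export
read_obo_subset <- function(path, weights = c(is_a = 0.8, part_of = 0.6)) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0)
  child <- character(0)
  parent <- character(0)
  type <- character(0)
  cur_id <- NA_character_
  cur_obsolete <- FALSE
  cur_child <- character(0)
  cur_parent <- character(0)
  cur_type <- character(0)
  in_term <- FALSE
  flush <- function() {
    if (in_term && !is.na(cur_id) && !cur_obsolete) {
      terms <<- c(terms, cur_id)
      child <<- c(child, cur_child)
      parent <<- c(parent, cur_parent)
      type <<- c(type, cur_type)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur_id <- NA_character_
      cur_obsolete <- FALSE
      cur_child <- character(0)
      cur_parent <- character(0)
      cur_type <- character(0)
    } else if (grepl("^\\[", ln)) {  # [Typedef] etc.
      flush()
      in_term <- FALSE
    } else if (in_term) {
      if (grepl("^id:", ln)) {
        cur_id <- trimws(sub("^id:", "", ln))
      } else if (grepl("^is_obsolete:\\s*true", ln)) {
        cur_obsolete <- TRUE
      } else if (grepl("^is_a:", ln)) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        cur_child <- c(cur_child, cur_id)
        cur_parent <- c(cur_parent, tgt)
        cur_type <- c(cur_type, "is_a")
      } else if (grepl("^relationship:\\s*part_of", ln)) {
        tgt <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
        cur_child <- c(cur_child, cur_id)
        cur_parent <- c(cur_parent, tgt)
        cur_type <- c(cur_type, "part_of")
      }
    }
  }
  flush()
  edges <- data.frame(child = child, parent = parent, type = type,
                      stringsAsFactors = FALSE)
  go_dag(edges, weights = weights, terms = terms)
}

#' Write a GO DAG as an OBO subset
#' @param dag a [go_dag()].
#' @param path file path.
#' @export
write_obo_subset <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    out <- c(out, "[Term]", paste0("id: ", t))
    e <- dag$edges[dag$edges$child == t, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      out <- c(out, if (e$type[k] == "is_a") paste0("is_a: ", e$parent[k])
                    else paste0("relationship: part_of ", e$parent[k]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
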