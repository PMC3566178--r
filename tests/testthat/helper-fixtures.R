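# Small fixtures built in code.

W_DEFAULT <- c(is_a = 0.8, part_of = 0.6)

# Single chain T is_a P is_a R.
chain_edges <- function() {
  data.frame(child = c("T", "P"), parent = c("P", "R"), type = "is_a",
             stringsAsFactors = FALSE)
}

# Diamond: T -> P1 -> R and T -> P2 -> R, all is_a.
diamond_edges <- function() {
  data.frame(child = c("T", "T", "P1", "P2"),
             parent = c("P1", "P2", "R", "R"),
             type = "is_a", stringsAsFactors = FALSE)
}

# Random rooted DAG: every term beyond the first gets >= 1 parent among the
# earlier terms, mixed edge types.
random_dag_edges <- function(n_terms, extra = ceiling(n_terms / 3)) {
  terms <- paste0("t", seq_len(n_terms))
  child <- terms[2:n_terms]
  parent <- terms[vapply(2:n_terms, function(i) sample.int(i - 1L, 1L),
                         integer(1))]
  if (extra > 0L && n_terms >= 3L) {
    ec <- sample(3:n_terms, extra, replace = TRUE)
    ep <- vapply(ec, function(i) sample.int(i - 2L, 1L), integer(1))
    child <- c(child, terms[ec])
    parent <- c(parent, terms[ep])
  }
  e <- data.frame(child = child, parent = parent,
                  type = sample(c("is_a", "part_of"), length(child),
                                replace = TRUE),
                  stringsAsFactors = FALSE)
  e[!duplicated(paste(e$child, e$parent)), , drop = FALSE]
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_obo <- function() {
  write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0001", "name: root", "",
    "[Term]", "id: GO:0002", "is_a: GO:0001 ! root", "",
    "[Term]", "id: GO:0003", "relationship: part_of GO:0002", "",
    "[Term]", "id: GO:0009", "is_a: GO:0001", "is_obsolete: true", ""),
    ext = ".obo")
}
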