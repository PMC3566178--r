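test_that("jaccard follows the set definition", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard(c("A", "B"), c("B", "A")), 1)  # order-free
  expect_error(jaccard(character(0), "A"), "non-empty")
})

test_that("catalogue construction enforces its invariants", {
  expect_error(complex_catalogue(c("c1", "c1"), "S", list("A", "B")),
               "duplicate")
  expect_error(complex_catalogue("c1", "S", list(character(0))), "empty")
  cat <- complex_catalogue("c1", "S", list(c("A", "A", "B")))
  expect_setequal(cat$members[[1]], c("A", "B"))
})

test_that("significance is the mean of defined pairwise similarities", {
  set.seed(5)
  edges <- random_dag_edges(12)
  dag <- go_dag(edges)
  annot <- list(gA = c("t2", "t4"), gB = c("t2", "t4"), gC = "t9",
                gD = character(0))
  # singleton: no pairs
  expect_equal(as.numeric(complex_significance("gA", annot, dag)), 0)
  # identical annotations
  expect_equal(as.numeric(complex_significance(c("gA", "gB"), annot, dag)), 1)
  # 3-member: mean of 3 pairwise values from the exhaustive oracle
  sims <- c(oracle_gene_sim(edges, W_DEFAULT, annot$gA, annot$gB),
            oracle_gene_sim(edges, W_DEFAULT, annot$gA, annot$gC),
            oracle_gene_sim(edges, W_DEFAULT, annot$gB, annot$gC))
  expect_equal(as.numeric(complex_significance(c("gA", "gB", "gC"), annot, dag)),
               mean(sims), tolerance = 1e-12)
  # unannotated member: its pairs excluded, not scored 0
  s <- complex_significance(c("gA", "gB", "gD"), annot, dag)
  expect_equal(as.numeric(s), 1)
  expect_equal(attr(s, "n_excluded"), 2L)
  # all pairs undefined -> 0
  expect_equal(as.numeric(complex_significance(c("gD", "gX"), annot, dag)), 0)
})

make_scored <- function(ids, members, scores, source = "S") {
  complex_catalogue(ids, source, members, score = scores)
}

test_that("compilation discards moderate overlaps and merges near-identical ones", {
  # J = 4/6 in (0.5, 0.8]: second discarded, first unchanged
  cat1 <- make_scored(c("hi", "lo"),
                      list(c("A", "B", "C", "D", "E"),
                           c("A", "B", "C", "D", "F")), c(0.9, 0.5))
  r1 <- compile_catalogue(cat1)
  expect_equal(r1$catalogue$id, "hi")
  expect_setequal(r1$catalogue$members[[1]], c("A", "B", "C", "D", "E"))
  expect_equal(r1$discards$discarded, "lo")
  expect_equal(r1$discards$jaccard, 4 / 6)
  expect_equal(nrow(r1$merges), 0L)

  # J = 5/6 > 0.8: merged to the union
  cat2 <- make_scored(c("hi", "lo"),
                      list(c("A", "B", "C", "D", "E"),
                           c("A", "B", "C", "D", "E", "F")), c(0.9, 0.5))
  r2 <- compile_catalogue(cat2)
  expect_equal(r2$catalogue$id, "hi")
  expect_setequal(r2$catalogue$members[[1]], c("A", "B", "C", "D", "E", "F"))
  expect_equal(r2$merges$absorbed, "lo")
  expect_equal(r2$merges$jaccard, 5 / 6)

  # identical duplicates: one retained, one absorbed at J = 1
  cat3 <- make_scored(c("x", "y"), list(c("A", "B"), c("A", "B")), c(0.7, 0.7))
  r3 <- compile_catalogue(cat3)
  expect_equal(nrow(r3$catalogue), 1L)
  expect_equal(r3$merges$jaccard, 1)

  # nothing above the overlap threshold: output equals input
  cat4 <- make_scored(c("p", "q"), list(c("A", "B", "C"), c("D", "E", "F")),
                      c(0.8, 0.6))
  r4 <- compile_catalogue(cat4)
  expect_equal(nrow(r4$catalogue), 2L)
  expect_equal(nrow(r4$merges) + nrow(r4$discards), 0L)
})

test_that("every input complex lands in exactly one of retained/merged/discarded", {
  set.seed(21)
  for (rep in 1:10) {
    sets <- random_complex_sets(12, 6, LETTERS[1:12])
    cat <- make_scored(sprintf("c%02d", 1:12), sets, runif(12))
    r <- compile_catalogue(cat)
    accounted <- c(r$catalogue$id, r$merges$absorbed, r$discards$discarded)
    expect_setequal(accounted, cat$id)
    expect_equal(length(accounted), 12L)
    expect_true(all(c(r$merges$jaccard, r$discards$jaccard) > 0.5))
    # retained sets contain their absorbed complexes' members
    for (k in seq_len(nrow(r$merges))) {
      keeper <- r$catalogue$members[[
        match(r$merges$absorber[k], r$catalogue$id)]]
      absorbed <- sets[[match(r$merges$absorbed[k], cat$id)]]
      expect_true(all(absorbed %in% keeper))
    }
  }
})

test_that("compilation is invariant to input order for distinct scores", {
  set.seed(31)
  sets <- random_complex_sets(10, 6, LETTERS[1:10])
  scores <- sample(seq(0.1, 0.95, length.out = 10))
  cat <- make_scored(sprintf("c%02d", 1:10), sets, scores)
  r_fwd <- compile_catalogue(cat)
  perm <- sample(10)
  r_perm <- compile_catalogue(cat[perm, , drop = FALSE])
  expect_equal(r_fwd$catalogue$id, r_perm$catalogue$id)
  expect_equal(lapply(r_fwd$catalogue$members, sort),
               lapply(r_perm$catalogue$members, sort))
})

test_that("repeated compilation reaches a redundancy-free fixpoint", {
  set.seed(41)
  for (rep in 1:5) {
    sets <- random_complex_sets(15, 7, LETTERS[1:9])  # heavy overlap
    cat <- make_scored(sprintf("c%02d", 1:15), sets, runif(15))
    r <- compile_catalogue(cat, passes = 10L)
    expect_equal(count_redundancy(r$catalogue, 0.5), 0L)
    expect_lte(r$passes_run, 10L)
  }
})

test_that("redundancy counting uses strict inequality", {
  disjoint <- list(c("A", "B"), c("C", "D"), c("E", "F"))
  expect_equal(count_redundancy(disjoint, 0.5), 0L)
  triple <- list(c("A", "B"), c("A", "B"), c("A", "B"))
  expect_equal(count_redundancy(triple, 0.5), 3L)  # C(3,2) identical pairs
  at_thres <- list(c("A", "B", "C", "D"), c("A", "B", "E", "F"))  # J = 1/3
  expect_equal(count_redundancy(at_thres, 1 / 3), 0L)
  expect_equal(count_redundancy(at_thres, 0.33), 1L)
})

test_that("catalogue statistics count complexes, proteins and overlaps", {
  s <- catalogue_stats(list(c("A", "B"), c("B", "C")))
  expect_equal(s$n_complexes, 2L)
  expect_equal(s$n_proteins, 3L)
  expect_equal(s$n_overlapping_proteins, 1L)
  expect_equal(s$avg_size, 2)

  s1 <- catalogue_stats(list(c("A", "B", "C")))
  expect_equal(unlist(s1[c("n_complexes", "n_proteins",
                           "n_overlapping_proteins")]),
               c(n_complexes = 1L, n_proteins = 3L,
                 n_overlapping_proteins = 0L))
  expect_equal(s1$avg_size, 3)

  sdup <- catalogue_stats(list(c("A", "B"), c("A", "B")))
  expect_equal(sdup$n_overlapping_proteins, 2L)

  expect_warning(s0 <- catalogue_stats(list()), "average size")
  expect_equal(s0$avg_size, 0)
})

test_that("exact duplicates within a source are dropped and logged", {
  cat <- complex_catalogue(c("c1", "c2", "c3"), c("S1", "S1", "S2"),
                           list(c("A", "B"), c("B", "A"), c("A", "B")))
  expect_message(r <- dedup_exact(cat), "1 exact duplicate")
  expect_equal(r$catalogue$id, c("c1", "c3"))  # same members, other source kept
  expect_equal(r$dropped$id, "c2")
  expect_equal(r$dropped$duplicate_of, "c1")
})
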