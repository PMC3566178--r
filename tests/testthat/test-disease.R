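test_that("Fisher's method matches the closed-form chi-square tail", {
  expect_equal(fisher_meta(0.03), 0.03)        # single value unchanged
  expect_equal(fisher_meta(c(1, 1)), 1)        # X^2 = 0
  expect_equal(fisher_meta(c(0.05, 0.05)),
               oracle_chisq_sf_even(-2 * sum(log(c(0.05, 0.05))), 2),
               tolerance = 1e-12)
  expect_equal(round(fisher_meta(c(0.05, 0.05)), 4), 0.0175)
  expect_error(fisher_meta(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_meta(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("Fisher's method is permutation-invariant and monotone", {
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(2:6, 1))
    expect_equal(fisher_meta(p), fisher_meta(sample(p)))
    lowered <- p
    i <- sample(length(p), 1)
    lowered[i] <- lowered[i] / 2
    expect_lt(fisher_meta(lowered), fisher_meta(p))
  }
})

test_that("per-study evidence collapses to one meta p per association", {
  ev <- data.frame(disease = c("d1", "d1", "d1", "d2"),
                   gene = c("A", "A", "B", "A"),
                   p_value = c(0.05, 0.05, 0.01, 0.2))
  comb <- combine_gene_pvalues(ev)
  expect_equal(nrow(comb), 3L)
  row_aa <- comb[comb$disease == "d1" & comb$gene == "A", ]
  expect_equal(row_aa$n_studies, 2L)
  expect_equal(row_aa$meta_p, fisher_meta(c(0.05, 0.05)))
  expect_equal(comb$meta_p[comb$disease == "d2"], 0.2)

  genes <- filter_disease_genes(comb, cutoff = 0.05, quiet = TRUE)
  expect_equal(genes$d1, c("A", "B"))
  expect_null(genes$d2)
})

test_that("hypergeometric enrichment matches full enumeration", {
  # worked example: N=10, K=3, n=4, t=2 -> 70/210 = 1/3
  expect_equal(oracle_hyper_tail(10, 3, 4, 2), 1 / 3)
  cat <- complex_catalogue("c1", "S", list(c("g1", "g2", "g3", "g4")))
  univ <- paste0("g", 1:10)
  res <- disease_complex_enrichment(cat, c("g1", "g2", "g10"),
                                    universe = univ)
  expect_equal(res$t, 2L)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  # complex entirely inside the disease set: p = 1 / C(N, n)
  res_all <- disease_complex_enrichment(cat, paste0("g", 1:4),
                                        universe = univ)
  expect_equal(res_all$p_value, 1 / choose(10, 4), tolerance = 1e-12)
  # t = 0 -> the whole tail, p = 1
  res0 <- disease_complex_enrichment(cat, c("g9", "g10"), universe = univ)
  expect_equal(res0$p_value, 1)
  expect_false(res0$significant)
})

test_that("enrichment p is monotonically non-increasing in the overlap t", {
  for (N in c(8, 10, 12)) {
    for (K in c(2, 4)) {
      for (n in c(3, 5)) {
        ps <- vapply(0:min(K, n), function(t) oracle_hyper_tail(N, K, n, t),
                     numeric(1))
        expect_true(all(diff(ps) <= 1e-12))
      }
    }
  }
})

test_that("disease genes outside the universe are dropped with a warning", {
  cat <- complex_catalogue("c1", "S", list(c("a", "b")))
  expect_warning(res <- disease_complex_enrichment(cat, c("a", "zzz")),
                 "outside the universe")
  expect_equal(res$K, 1L)
})

test_that("disease subnetworks induce the significant complex-drug subgraph", {
  cat <- complex_catalogue(c("c1", "c2", "c3"), "S",
                           list(c("a", "b"), c("c", "d"), c("e", "f")))
  net <- build_drug_complex_network(
    cat, list(d1 = "a", d2 = c("a", "c"), d3 = "x"))
  assoc <- data.frame(complex = c("c1", "c2", "c3"),
                      significant = c(TRUE, TRUE, FALSE))
  sn <- disease_subnetwork(assoc, net, disease = "dis")
  expect_setequal(sn$complexes, c("c1", "c2"))
  expect_setequal(sn$drugs, c("d1", "d2"))
  expect_equal(nrow(sn$edges), 3L)
  # no significant complexes -> only the disease node
  sn0 <- disease_subnetwork(data.frame(complex = "c1", significant = FALSE),
                            net, "dis")
  expect_equal(length(sn0$complexes), 0L)
  expect_equal(nrow(sn0$edges), 0L)
  # drug-free significant complex stays as an isolated node
  assoc3 <- data.frame(complex = "c3", significant = TRUE)
  sn3 <- disease_subnetwork(assoc3, net, "dis")
  expect_equal(sn3$complexes, "c3")
  expect_equal(length(sn3$drugs), 0L)
})

test_that("repositioning candidates are the (disease, drug) adjacencies", {
  cat <- complex_catalogue(c("c1", "c2"), "S",
                           list(c("a", "b"), c("c", "d")))
  net <- build_drug_complex_network(cat, list(d1 = c("a", "c"), d2 = "c"))
  assoc <- data.frame(complex = c("c1", "c2"), significant = TRUE)
  sn <- disease_subnetwork(assoc, net, "dis")
  cand <- repositioning_candidates(sn)
  # d1 supported by both complexes -> one candidate with 2 supports
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$n_support[cand$drug == "d1"], 2L)
  expect_equal(cand$complexes[cand$drug == "d1"], "c1;c2")
  # brute-force adjacency scan on a random system
  set.seed(19)
  sets <- random_complex_sets(6, 5, letters[1:12])
  cat2 <- complex_catalogue(sprintf("k%d", 1:6), "S", sets)
  tg <- setNames(lapply(1:8, function(i) sample(letters[1:12], 2)),
                 sprintf("dr%d", 1:8))
  net2 <- build_drug_complex_network(cat2, tg)
  assoc2 <- data.frame(complex = cat2$id,
                       significant = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  sn2 <- disease_subnetwork(assoc2, net2, "dz")
  cand2 <- repositioning_candidates(sn2)
  sig <- assoc2$complex[assoc2$significant]
  brute <- unique(net2$edges$drug[net2$edges$complex %in% sig])
  expect_setequal(cand2$drug, brute)
  # empty subnetwork -> no candidates
  empty <- repositioning_candidates(
    disease_subnetwork(data.frame(complex = "k1", significant = FALSE),
                       net2, "dz"))
  expect_equal(nrow(empty), 0L)
})
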