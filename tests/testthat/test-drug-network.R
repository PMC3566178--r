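toy_net <- function() {
  # complexes A..C around shared protein D, plus an unrelated complex
  cat <- complex_catalogue(
    c("A", "B", "C", "Z"), "S",
    list(c("D", "P1"), c("D", "P2"), c("D", "P3"), c("Q1", "Q2")))
  targets <- list(E = "D",              # the worked over-counting example
                  F = c("D", "P1"),     # two targets in complex A
                  G = "Q1",
                  H = "nowhere")        # isolated drug
  build_drug_complex_network(cat, targets)
}

test_that("network edges require a shared protein and carry support sets", {
  net <- toy_net()
  expect_false("H" %in% net$drugs)      # isolated drug excluded
  expect_true("H" %in% net$all_drugs)
  eF_A <- net$edges[net$edges$drug == "F" & net$edges$complex == "A", ]
  expect_equal(nrow(eF_A), 1L)          # one edge, not per-target edges
  expect_setequal(eF_A$support[[1]], c("D", "P1"))
  expect_true(all(lengths(net$edges$support) >= 1L))
  empty <- build_drug_complex_network(
    complex_catalogue("c", "S", list("A")), list())
  expect_equal(nrow(empty$edges), 0L)
})

test_that("raw and de-duplicated degrees follow the over-counting rule", {
  net <- toy_net()
  raw <- degree_report(net, dedup = FALSE)
  # drug E targets D, present in complexes A, B, C: raw degree 3
  expect_equal(raw$drugs$degree[raw$drugs$drug == "E"], 3L)
  expect_equal(raw$targets$times_used[raw$targets$target == "D"], 6L)  # E:3 + F:3
  dd <- degree_report(net, dedup = TRUE)
  expect_equal(dd$drugs$degree[dd$drugs$drug == "E"], 1L)
  expect_equal(dd$targets$times_used[dd$targets$target == "D"], 2L)  # E and F once each
  # drug with 2 targets inside one complex: raw degree counts edges,
  # dedup degree counts targets
  cat1 <- complex_catalogue("c1", "S", list(c("X", "Y", "Z")))
  net1 <- build_drug_complex_network(cat1, list(d = c("X", "Y")))
  expect_equal(degree_report(net1)$drugs$degree, 1L)
  expect_equal(degree_report(net1, dedup = TRUE)$drugs$degree, 2L)
  # dedup degree is bounded by the drug's distinct target count (raw degree
  # can fall on either side: shared targets inflate it, multi-target
  # complexes deflate it)
  expect_lte(dd$drugs$degree[dd$drugs$drug == "F"], 2L)
  # total raw target usage equals total support size over edges
  expect_equal(sum(raw$targets$times_used), sum(lengths(net$edges$support)))
})

test_that("co-complex drug pairs are pairs sharing a complex neighbor", {
  net <- toy_net()
  ccd <- cocomplex_drug_pairs(net)
  expect_equal(nrow(ccd), 1L)           # E and F share complexes A-C; G apart
  expect_equal(sort(c(ccd$a, ccd$b)), c("E", "F"))
  # k drugs on one complex -> C(k,2) pairs
  cat1 <- complex_catalogue("c1", "S", list("X"))
  tg <- setNames(rep(list("X"), 5), paste0("d", 1:5))
  expect_equal(nrow(cocomplex_drug_pairs(build_drug_complex_network(cat1, tg))),
               choose(5, 2))
})

test_that("DDI permutation test handles extremes and matches pair density", {
  # designed toy: the only DDI is the only co-complex pair
  net <- toy_net()
  ddis <- data.frame(a = "E", b = "F")
  res <- ddi_permutation_test(net, ddis, reps = 99, seed = 1)
  expect_equal(res$observed, 1L)
  expect_gte(res$p_value, 1 / 100)
  expect_equal(length(res$replicates), 99L)
  # empty DDI set
  res0 <- ddi_permutation_test(net, data.frame(a = character(0),
                                               b = character(0)),
                               reps = 9, seed = 1)
  expect_equal(res0$observed, 0L)
  expect_equal(res0$p_value, 1)
  # null mean approximates universe co-complex density * n_ddis
  cat2 <- complex_catalogue(c("c1", "c2"), "S", list(c("X"), c("Y")))
  tg2 <- c(setNames(rep(list("X"), 4), paste0("x", 1:4)),
           setNames(rep(list("Y"), 4), paste0("y", 1:4)))
  net2 <- build_drug_complex_network(cat2, tg2)
  dens <- (2 * choose(4, 2)) / choose(8, 2)  # exhaustive enumeration
  n_dd <- 6L
  ddis2 <- data.frame(a = paste0("x", 1:3), b = c("x4", "y1", "y2"))
  ddis2 <- rbind(ddis2, data.frame(a = c("y3", "x1", "x2"),
                                   b = c("y4", "x3", "y1")))
  res2 <- ddi_permutation_test(net2, ddis2, reps = 400, seed = 5)
  se <- sqrt(n_dd * dens * (1 - dens) / 400)
  expect_lt(abs(res2$null_mean - n_dd * dens), 3 * se + 0.3)
  # reproducible under seed
  res2b <- ddi_permutation_test(net2, ddis2, reps = 400, seed = 5)
  expect_identical(res2$replicates, res2b$replicates)
  # universe too small for the requested number of distinct pairs
  # (universe has 3 drugs -> 3 possible pairs; ask for 4 draws)
  expect_error(ddi_permutation_test(net, data.frame(a = c("E", "E", "E", "F"),
                                                    b = c("F", "G", "F", "G")),
                                    reps = 2),
               "distinct pairs")
})

test_that("empirical p-values live in [1/(reps+1), 1]", {
  net <- toy_net()
  res <- ddi_permutation_test(net, data.frame(a = "E", b = "F"),
                              reps = 19, seed = 2)
  expect_gte(res$p_value, 1 / 20)
  expect_lte(res$p_value, 1)
})

test_that("druggability enrichment counts overlapping proteins and tails", {
  # D overlaps A,B,C; P's and Q's occur once each
  cat <- complex_catalogue(
    c("A", "B", "C"), "S",
    list(c("D", "P1", "S1"), c("D", "P2", "S1"), c("D", "P3")))
  rep <- druggability_test(cat, targets = c("D"), potential = c("S1", "P9"),
                           p0 = 0.1)
  expect_equal(rep$n_overlapping_nodes, 2L)  # D and S1
  expect_equal(rep$n_targets, 1L)
  expect_equal(rep$n_potential_targets, 1L)
  expect_equal(rep$ratio, 1)
  # tail oracle: n = 10, k = 3, p0 = 0.1
  expect_equal(stats::pbinom(2, 10, 0.1, lower.tail = FALSE),
               oracle_binom_tail(3, 10, 0.1), tolerance = 1e-12)
  expect_equal(round(oracle_binom_tail(3, 10, 0.1), 4), 0.0702)
  # extremes: k = 0 -> p = 1; k = n -> p = p0^n
  cat0 <- complex_catalogue(c("a", "b"), "S", list(c("U", "V"), c("U", "W")))
  r0 <- druggability_test(cat0, targets = "ZZZ", p0 = 0.3)
  expect_equal(r0$p_value, 1)
  rall <- druggability_test(cat0, targets = "U", p0 = 0.3)
  expect_equal(rall$p_value, 0.3)  # 1 overlapping node, k = 1
  expect_error(druggability_test(
    complex_catalogue("a", "S", list(c("U", "V"))), "U"), "overlapping")
})
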