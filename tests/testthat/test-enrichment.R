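test_that("hypergeom_pvalue matches the combinatorial tail", {
  expect_equal(hypergeom_pvalue(0, 5, 4, 10), 1)
  expect_equal(hypergeom_pvalue(4, 4, 4, 4), 1)        # certain event
  expect_equal(hypergeom_pvalue(4, 5, 4, 10), 5 / 210) # C(5,4)C(5,0)/C(10,4)
  for (i in 1:20) {
    N <- sample(8:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_pvalue(k, K, n, N), oracle_hyper_tail(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_pvalue(5, 4, 4, 10), "inconsistent")
})

test_that("bh_adjust matches the step-up oracle and is rank-monotone", {
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(1)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("binomial_improvement_test is the exact one-sided tail", {
  expect_equal(binomial_improvement_test(1, 1), 0.5)
  expect_equal(binomial_improvement_test(8, 10), 56 / 1024)
  for (i in 1:15) {
    n <- sample(1:30, 1); k <- sample(0:n, 1)
    expect_equal(binomial_improvement_test(k, n), oracle_binom_tail(k, n),
                 tolerance = 1e-12)
  }
  expect_error(binomial_improvement_test(1, 0), "n_compared")
  expect_error(binomial_improvement_test(5, 3), "n_improved")
})

test_that("binomial tail agrees with the normal approximation at large n", {
  for (n in c(200, 500)) for (z in c(1, 3, 5)) {
    k <- ceiling(n / 2 + z * sqrt(n) / 2)
    exact <- binomial_improvement_test(k, n)
    approx <- pnorm((k - 0.5 - n / 2) / (sqrt(n) / 2), lower.tail = FALSE)
    expect_lt(abs(log10(exact) - log10(approx)), 1)
  }
})

test_that("classify_de_genes partitions by sign at the alpha cutoff", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    log2FoldChange = c(2, -1, 0.5, -0.2),
                    padj = c(0.005, 0.05, 0.001, NA))
  expect_warning(p <- classify_de_genes(tab, alpha = 0.01), "NA")
  expect_equal(p$positive, c("g1", "g3"))
  expect_equal(p$negative, character(0))
  expect_equal(p$all, c("g1", "g3"))
  bad <- data.frame(gene = "g", log2FoldChange = 0, padj = 0.001)
  expect_error(classify_de_genes(bad), "zero log2 fold change")
})

test_that("classify_de_genes recovers the DE generator's planted truth", {
  spec <- small_spec(171)
  de <- generate_de_table(spec)
  p <- classify_de_genes(de$tables[[1]], alpha = spec$de_alpha)
  truth <- de$truth
  expect_equal(p$positive, sort(names(truth)[truth == "positive"]))
  expect_equal(p$negative, sort(names(truth)[truth == "negative"]))
})

test_that("time-series classes follow the two-interval rules", {
  t1 <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   log2FoldChange = c(2, 0.1, 1.5, -2, 1),
                   padj = c(0.001, 0.5, 0.002, 0.003, 0.004))
  t2 <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   log2FoldChange = c(0.1, -2, -1.2, -1, 2),
                   padj = c(0.4, 0.001, 0.005, 0.002, 0.001))
  p <- classify_time_series(t1, t2, alpha = 0.01)
  expect_equal(p$early_positive, "a")        # sig up then flat
  expect_equal(p$late_negative, "b")         # flat then sig down
  expect_equal(p$transient_positive, "c")    # up then down, interval-1 sign
  expect_equal(p$consistent_negative, "d")
  expect_equal(p$consistent_positive, "e")
  expect_warning(classify_time_series(t1, t2[-1, ], alpha = 0.01), "excluded")
})

test_that("time-series classification matches the generator's ledger", {
  spec <- small_spec(181)
  de <- generate_de_table(spec, contrasts = 2L)
  p <- classify_time_series(de$tables[[1]], de$tables[[2]],
                            alpha = spec$de_alpha)
  truth <- de$truth
  for (cl in c("early_positive", "early_negative", "late_positive",
               "late_negative", "transient_positive", "transient_negative",
               "consistent_positive", "consistent_negative"))
    expect_equal(p[[cl]], sort(names(truth)[truth == cl]), info = cl)
})

test_that("enrich computes hypergeometric rows with BH adjustment", {
  ann <- structure(list(g1 = c("T1", "T2"), g2 = "T1", g3 = "T1", g4 = "T3"),
                   class = "annotation_set", expanded = TRUE,
                   provenance = "test")
  res <- enrich(c("g1", "g2"), c("g1", "g2", "g3", "g4"), ann, alpha = 0.05)
  t1 <- res[res$term == "T1", ]
  expect_equal(t1$k, 2L); expect_equal(t1$K, 3L)
  expect_equal(t1$n, 2L); expect_equal(t1$N, 4L)
  expect_equal(t1$pvalue, oracle_hyper_tail(2, 3, 2, 4))
  expect_equal(res$padj, bh_adjust(res$pvalue))  # BH is permutation-equivariant
  # a term annotated to the whole universe has p = 1
  ann2 <- structure(list(g1 = "T", g2 = "T"), class = "annotation_set",
                    expanded = TRUE, provenance = "test")
  res2 <- enrich("g1", c("g1", "g2"), ann2)
  expect_equal(res2$pvalue, 1)
  expect_error(enrich(character(0), "g1", ann2), "empty gene set")
  expect_error(enrich("zz", "g1", ann2), "subset")
})

test_that("enrichment p-values are invariant under gene relabeling", {
  spec <- small_spec(191)
  f <- generate_ontology(spec)
  gaf <- generate_gaf(spec, f$ledger)
  ann <- annotation_set(read_gaf(gaf$gaf))
  map <- build_ancestor_map(f$graph, policy_preset("gocats"))
  ex <- expand_annotations(ann, map)
  genes <- gaf$ledger$signal_genes
  res1 <- suppressWarnings(enrich(genes, gaf$ledger$genes, ex))
  relabel <- stats::setNames(paste0("X", seq_along(gaf$ledger$genes)),
                             gaf$ledger$genes)
  ex2 <- structure(stats::setNames(unclass(ex), relabel[names(ex)]),
                   class = "annotation_set", expanded = TRUE, provenance = "t")
  res2 <- suppressWarnings(enrich(unname(relabel[genes]),
                                  unname(relabel[gaf$ledger$genes]), ex2))
  expect_equal(stats::setNames(res1$pvalue, res1$term),
               stats::setNames(res2$pvalue, res2$term))
})

test_that("compare_enrichments tallies improvements and excludes ties", {
  mk <- function(terms, padj) data.frame(term = terms, padj = padj,
                                         stringsAsFactors = FALSE)
  ref <- mk(c("T1", "T2", "T3", "T4"), c(0.001, 0.002, 0.005, 0.5))
  alt <- mk(c("T1", "T2", "T3", "T5"), c(0.0005, 0.002, 0.02, 0.001))
  cmp <- compare_enrichments(ref, alt, alpha = 0.01)
  expect_equal(cmp$n_significant_reference, 3L)
  expect_equal(cmp$n_ties, 1L)           # T2 identical
  expect_equal(cmp$n_compared, 2L)
  expect_equal(cmp$n_improved, 1L)       # T1 improved, T3 worsened
  expect_equal(cmp$binomial_p, binomial_improvement_test(1, 2))
  expect_equal(cmp$unique_alternate, "T5")
  expect_equal(cmp$unique_reference, "T3")
  # conservation: improved + not improved + ties = reference significant
  not_improved <- cmp$n_compared - cmp$n_improved
  expect_equal(cmp$n_improved + not_improved + cmp$n_ties,
               cmp$n_significant_reference)
  # all ties -> undefined test surfaces
  expect_error(compare_enrichments(ref, ref, alpha = 0.01), "ties")
})

test_that("terms untested in the alternate count as not improved", {
  ref <- data.frame(term = c("T1", "T2"), padj = c(0.001, 0.002))
  alt <- data.frame(term = "T1", padj = 0.0001)
  cmp <- suppressWarnings(compare_enrichments(ref, alt, alpha = 0.01))
  expect_equal(cmp$n_compared, 2L)
  expect_equal(cmp$n_improved, 1L)
})

test_that("time-series term-set algebra follows the set definitions", {
  sets <- time_series_term_sets(
    interval1_gocats = c("A", "B", "C"), interval1_no_hp = "B",
    interval2_gocats = c("D", "E"), interval2_no_hp = character(0),
    transient_no_hp = "C", consistent_no_hp = c("A", "Z", "E"))
  expect_equal(sets$early_unique, "A")            # {A,B,C} - {B} - {C}
  expect_equal(sets$early_supported, "A")         # {A} intersect {A,Z,E}
  expect_equal(sets$late_unique, c("D", "E"))
  expect_equal(sets$late_supported, "E")
  expect_equal(sets$early_supported_full, "A")
  # transient empty: plain two-set difference
  s2 <- time_series_term_sets(c("A", "B"), "B", character(0), character(0),
                              character(0), character(0))
  expect_equal(s2$early_unique, "A")
  # supported sets are contained in their unique sets
  expect_true(all(sets$early_supported %in% sets$early_unique))
  expect_true(all(sets$late_supported %in% sets$late_unique))
})
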