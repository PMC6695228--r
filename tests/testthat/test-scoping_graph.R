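test_that("scoped_parents applies the part_of_some reinterpretation", {
  g <- ontology_graph(
    data.frame(id = c("nucleus", "chromosome")),
    data.frame(subject = "nucleus", relation = "has_part",
               object = "chromosome"))
  pol <- policy_preset("gocats")
  # the part climbs to its whole ...
  expect_equal(scoped_parents(g, pol, "chromosome"), "nucleus")
  # ... and the native downward step is gone
  expect_equal(scoped_parents(g, pol, "nucleus"), character(0))
  # excluding has_part removes the edge entirely
  expect_equal(scoped_parents(g, policy_preset("no_hp"), "chromosome"),
               character(0))
  expect_error(scoped_parents(g, pol, "ribosome"), "unknown term")
})

test_that("ancestors follows is_a chains transitively and excludes self", {
  g <- chain_graph(c("GO:0061448", "GO:0009888", "GO:0048856", "GO:0032502"))
  pol <- policy_preset("gocats")
  expect_equal(ancestors(g, pol, "GO:0061448"),
               sort(c("GO:0009888", "GO:0048856", "GO:0032502")))
  expect_equal(ancestors(g, pol, "GO:0032502"), character(0))  # root
})

test_that("ancestors equals the brute-force reachability oracle on fixtures", {
  for (seed in c(41, 42)) {
    f <- generate_ontology(small_spec(seed))
    g <- f$graph
    pol <- policy_preset("gocats")
    terms <- sample(term_ids(g), 10)
    for (t in terms)
      expect_equal(ancestors(g, pol, t), oracle_ancestors(g$edges, t), info = t)
  }
})

test_that("build_ancestor_map is transitively closed and matches per-term ancestors", {
  g <- chain_graph()
  map <- build_ancestor_map(g, policy_preset("gocats"))
  expect_equal(unclass(map), list(A = c("B", "C"), B = "C", C = character(0)),
               ignore_attr = TRUE)
  # single reinterpreted edge
  g2 <- ontology_graph(data.frame(id = c("W", "P")),
                       data.frame(subject = "W", relation = "has_part",
                                  object = "P"))
  map2 <- build_ancestor_map(g2, policy_preset("gocats"))
  expect_equal(map2$P, "W")
  expect_equal(map2$W, character(0))
  # closure property on a fixture: anc(anc(x)) subseteq anc(x), no self
  f <- generate_ontology(small_spec(43))
  m <- build_ancestor_map(f$graph, policy_preset("gocats"))
  for (t in names(m)) {
    expect_false(t %in% m[[t]])
    for (a in m[[t]]) expect_true(all(m[[a]] %in% m[[t]]))
  }
})

test_that("ancestor maps match the generator's independent ground truth", {
  f <- generate_ontology(small_spec(44))
  m_g <- build_ancestor_map(f$graph, policy_preset("gocats"))
  m_n <- build_ancestor_map(f$graph, policy_preset("no_hp"))
  expect_equal(unclass(m_g)[order(names(m_g))],
               f$ledger$ancestors_gocats[order(names(f$ledger$ancestors_gocats))],
               ignore_attr = TRUE)
  expect_equal(unclass(m_n)[order(names(m_n))],
               f$ledger$ancestors_no_hp[order(names(f$ledger$ancestors_no_hp))],
               ignore_attr = TRUE)
})

test_that("adding has_part to the scoping set only ever adds ancestors", {
  for (seed in 51:55) {
    f <- generate_ontology(small_spec(seed))
    m_nohp <- build_ancestor_map(f$graph, policy_preset("no_hp"))
    m_gocats <- build_ancestor_map(f$graph, policy_preset("gocats"))
    expect_equal(names(m_nohp), names(m_gocats))
    for (t in names(m_nohp))
      expect_true(all(m_nohp[[t]] %in% m_gocats[[t]]), info = paste(seed, t))
  }
})

test_that("reinterpretation equals flipping has_part edges and relabeling", {
  f <- generate_ontology(small_spec(61))
  g <- f$graph
  hp <- g$edges$relation == "has_part"
  flipped <- g$edges
  flipped[hp, c("subject", "object")] <- flipped[hp, c("object", "subject")]
  flipped$relation[hp] <- "part_of_some"
  g2 <- ontology_graph(g$nodes, flipped)
  pol2 <- scoping_policy(c("is_a", "part_of", "part_of_some"))
  m1 <- build_ancestor_map(g, policy_preset("gocats"))
  m2 <- build_ancestor_map(g2, pol2)
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
})

test_that("check_acyclic detects cycles and restores acyclicity after reinterpretation", {
  expect_true(check_acyclic(chain_graph(), policy_preset("gocats"))$acyclic)
  g2 <- ontology_graph(data.frame(id = c("A", "B")),
                       data.frame(subject = c("A", "B"), relation = "is_a",
                                  object = c("B", "A")))
  res <- check_acyclic(g2, policy_preset("gocats"))
  expect_false(res$acyclic)
  expect_true(all(c("A", "B") %in% res$cycle))
  expect_error(ancestors(g2, policy_preset("gocats"), "A"), "cycl")
  # native has_part direction creates a cycle; reinterpretation removes it
  g3 <- ontology_graph(
    data.frame(id = c("cell", "nucleus")),
    data.frame(subject = c("nucleus", "cell"),
               relation = c("part_of", "has_part"),
               object = c("cell", "nucleus")))
  native <- scoping_policy(c("is_a", "part_of", "has_part"),
                           reinterpret_has_part = FALSE)
  expect_false(check_acyclic(g3, native)$acyclic)
  expect_true(check_acyclic(g3, policy_preset("gocats"))$acyclic)
})

test_that("category_map assigns terms to every root above them, roots included", {
  g <- chain_graph()
  cm <- category_map(g, policy_preset("gocats"), "C")
  expect_equal(cm, list(A = "C", B = "C", C = "C"))
  # term reachable from two roots maps to both; terms under no root map to none
  g2 <- ontology_graph(
    data.frame(id = c("X", "R1", "R2", "Z")),
    data.frame(subject = c("X", "X"), relation = "is_a",
               object = c("R1", "R2")))
  cm2 <- category_map(g2, policy_preset("gocats"), c("R1", "R2"))
  expect_equal(cm2$X, c("R1", "R2"))
  expect_equal(cm2$Z, character(0))
  expect_error(category_map(g, policy_preset("gocats"), "nope"), "unknown root")
})

test_that("category_map matches the ledger's planted membership", {
  f <- generate_ontology(small_spec(71))
  cm <- category_map(f$graph, policy_preset("gocats"), f$ledger$category_root)
  members <- sort(names(cm)[lengths(cm) > 0])
  expect_equal(members, f$ledger$category_members)
})

test_that("namespace restriction drops cross-namespace terms from the map", {
  f <- generate_ontology(small_spec(81))
  m <- build_ancestor_map(f$graph, policy_preset("gocats"),
                          namespace = "biological_process")
  expect_equal(sort(names(m)),
               sort(term_ids(f$graph, "biological_process")))
})
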