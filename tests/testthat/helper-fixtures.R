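# Shared in-code fixtures for the test suite.

# the 6-node hand-enumerable toy: W is_a R; Q is_a R; P is_a Q; D1 is_a W;
# (W, has_part, P). Under the corrected reading: PA = {P, Q}, PD = {W, D1},
# per-edge false pairs 4, true mappings 7, is_a/part_of-only mappings 6.
toy_graph <- function() {
  ontology_graph(
    nodes = data.frame(id = c("R", "W", "Q", "P", "D1"),
                       namespace = "cellular_component",
                       stringsAsFactors = FALSE),
    edges = data.frame(
      subject = c("W", "Q", "P", "D1", "W"),
      relation = c("is_a", "is_a", "is_a", "is_a", "has_part"),
      object = c("R", "R", "Q", "W", "P"),
      stringsAsFactors = FALSE))
}

chain_graph <- function(ids = c("A", "B", "C")) {
  n <- length(ids)
  ontology_graph(
    nodes = data.frame(id = ids, namespace = "biological_process",
                       stringsAsFactors = FALSE),
    edges = data.frame(subject = ids[-n], relation = "is_a", object = ids[-1],
                       stringsAsFactors = FALSE))
}

write_mini_obo <- function(lines, path = tempfile(fileext = ".obo")) {
  writeLines(c("format-version: 1.2", lines), path)
  path
}

# a standard small fixture spec used across property tests
small_spec <- function(seed, ...) {
  fixture_spec(seed = seed,
               nodes_per_namespace = c(cellular_component = 25L,
                                       biological_process = 35L,
                                       molecular_function = 15L),
               ...)
}
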