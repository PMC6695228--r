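# Policy-driven traversal: scoped parents, transitive ancestors/descendants,
# acyclicity checking and category mapping.

# Child->parent edge table for the scoped subgraph. For subject_narrower
# relations the stored edge already points child->parent; for subject_broader
# relations (reinterpreted has_part) it is flipped.
scoped_parent_edges <- function(graph, policy) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(policy, "scoping_policy"))
  e <- graph$edges[graph$edges$relation %in% policy$scoping_relations, , drop = FALSE]
  if (!nrow(e))
    return(data.frame(child = character(0), parent = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  broad <- policy$direction[e$relation] == "subject_broader"
  data.frame(child = ifelse(broad, e$object, e$subject),
             parent = ifelse(broad, e$subject, e$object),
             relation = ifelse(broad, paste0(e$relation, "_reinterpreted"),
                               e$relation),
             stringsAsFactors = FALSE)
}

scoped_igraph <- function(graph, policy) {
  pe <- scoped_parent_edges(graph, policy)
  verts <- term_ids(graph)
  igraph::graph_from_data_frame(pe[, c("child", "parent")],
                                directed = TRUE,
                                vertices = data.frame(name = verts))
}

#' Broader-scope neighbours of a term under a policy
#'
#' The direct scoped parents of `term`: objects of its `is_a`/`part_of`
#' edges, plus subjects of `has_part` edges whose object is `term` when the
#' policy reinterprets `has_part` as `part_of_some`. Non-scoping relations
#' contribute nothing.
#'
#' @param graph An `ontology_graph`.
#' @param policy A [scoping_policy()].
#' @param term A term id present in the graph.
#' @return Sorted character vector of parent term ids.
#' @export
scoped_parents <- function(graph, policy, term) {
  if (!(term %in% graph$nodes$id)) stop("unknown term: ", term)
  pe <- scoped_parent_edges(graph, policy)
  sort(unique(pe$parent[pe$child == term]))
}

#' Transitive ancestors of a term under a policy
#'
#' All terms reachable from `term` by repeatedly stepping to scoped parents;
#' the term itself is excluded. Errors if the scoped subgraph contains a
#' directed cycle through the searched region.
#'
#' @inheritParams scoped_parents
#' @return Sorted character vector of ancestor ids (possibly empty).
#' @export
ancestors <- function(graph, policy, term) {
  if (!(term %in% graph$nodes$id)) stop("unknown term: ", term)
  cyc <- check_acyclic(graph, policy)
  if (!cyc$acyclic)
    stop("scoped subgraph is cyclic; cycle: ", paste(cyc$cycle, collapse = " -> "))
  g <- scoped_igraph(graph, policy)
  reach <- names(igraph::subcomponent(g, term, mode = "out"))
  sort(setdiff(reach, term))
}

#' Transitive descendants of a term under a policy
#'
#' Mirror image of [ancestors()]: all terms from which `term` is reachable
#' along scoped parent edges.
#'
#' @inheritParams scoped_parents
#' @return Sorted character vector of descendant ids.
#' @export
descendants <- function(graph, policy, term) {
  if (!(term %in% graph$nodes$id)) stop("unknown term: ", term)
  g <- scoped_igraph(graph, policy)
  reach <- names(igraph::subcomponent(g, term, mode = "in"))
  sort(setdiff(reach, term))
}

#' Build the full term-to-ancestors map under a policy
#'
#' One entry per non-obsolete term, each the transitive closure of its scoped
#' parents (term itself excluded). The map built with the `"no_hp"` policy is
#' the traditional map; the map built with the `"gocats"` policy additionally
#' traverses reinterpreted `has_part` edges, so it is always an entrywise
#' superset of the former.
#'
#' @inheritParams scoped_parents
#' @param namespace Optional namespace; restricts both the terms mapped and
#'   the edges traversed to that sub-ontology.
#' @return An object of class `ancestor_map`: a named list of sorted
#'   character vectors, with the policy stored in attribute `"policy"`.
#' @export
build_ancestor_map <- function(graph, policy, namespace = NULL) {
  if (!is.null(namespace)) {
    keep <- term_ids(graph, namespace)
    nodes <- graph$nodes[graph$nodes$id %in% keep, , drop = FALSE]
    e <- graph$edges[graph$edges$subject %in% keep & graph$edges$object %in% keep, , drop = FALSE]
    graph <- ontology_graph(nodes, e)
  }
  cyc <- check_acyclic(graph, policy)
  if (!cyc$acyclic)
    stop("scoped subgraph is cyclic; cycle: ", paste(cyc$cycle, collapse = " -> "))
  g <- scoped_igraph(graph, policy)
  ord <- names(igraph::topo_sort(g, mode = "out"))  # parents after children
  pe <- scoped_parent_edges(graph, policy)
  parents_of <- split(pe$parent, pe$child)
  anc <- vector("list", length(ord)); names(anc) <- ord
  for (v in rev(ord)) {  # parents first
    ps <- unique(parents_of[[v]])
    if (is.null(ps)) anc[[v]] <- character(0)
    else anc[[v]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  anc <- anc[sort(names(anc))]
  structure(anc, class = "ancestor_map", policy = policy)
}

#' Check that the scoped subgraph is acyclic
#'
#' A cycle is returned as a value, not thrown: the whole point of the
#' `part_of_some` reinterpretation is that flipping `has_part` restores
#' acyclicity on go-core style graphs, and this is the check that verifies it.
#'
#' @inheritParams scoped_parents
#' @return List with `acyclic` (logical) and `cycle` (character vector of
#'   term ids forming one directed cycle, `NULL` when acyclic).
#' @export
check_acyclic <- function(graph, policy) {
  g <- scoped_igraph(graph, policy)
  if (igraph::is_dag(g)) return(list(acyclic = TRUE, cycle = NULL))
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1L)[1L]
  members <- names(comp$membership)[comp$membership == big]
  sub <- igraph::induced_subgraph(g, members)
  # any vertex in a nontrivial SCC lies on a cycle back to itself
  v <- igraph::V(sub)[1L]
  nbr <- igraph::neighbors(sub, v, mode = "out")[1L]
  path <- igraph::shortest_paths(sub, from = nbr, to = v, mode = "out")$vpath[[1L]]
  list(acyclic = FALSE, cycle = c(names(v), names(path)))
}

#' Map every term to the category roots it falls under
#'
#' Term `t` maps to root `r` iff `r` is an ancestor of `t` under the policy
#' or `t` is `r` itself (so genes annotated directly to a category root still
#' count for the category).
#'
#' @inheritParams scoped_parents
#' @param roots Character vector of category root term ids.
#' @return Named list, one entry per non-obsolete term: sorted character
#'   vector of the roots it maps to (empty when under none).
#' @export
category_map <- function(graph, policy, roots) {
  missing <- setdiff(roots, graph$nodes$id)
  if (length(missing)) stop("unknown root term(s): ", paste(missing, collapse = ", "))
  amap <- build_ancestor_map(graph, policy)
  out <- lapply(names(amap), function(t) sort(intersect(roots, c(t, amap[[t]]))))
  names(out) <- names(amap)
  out
}
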