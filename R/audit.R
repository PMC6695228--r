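# Mapping audit: hypothetical false mappings from native has_part
# directionality, true scoping mappings, mappings lost when has_part is
# omitted, and the error fraction of a non-discriminating slim mapper.

# Ordered (descendant, ancestor) pair sets are represented as character
# vectors of "d<TAB>a" keys inside a small S3 container.

#' Construct a set of ordered (descendant, ancestor) mapping pairs
#' @param d,a Equal-length character vectors of descendant and ancestor ids.
#' @param label Provenance label (e.g. `"M_T"`, `"epM_F"`, `"naive"`).
#' @return Object of class `mapping_pairs`: list with `keys` (sorted unique
#'   `"d\ta"` strings, self-pairs removed) and `label`.
#' @export
mapping_pairs <- function(d = character(0), a = character(0), label = "") {
  stopifnot(length(d) == length(a))
  keep <- d != a  # self-mappings are ignored everywhere
  structure(list(keys = sort(unique(paste(d[keep], a[keep], sep = "\t"))),
                 label = label),
            class = "mapping_pairs")
}

#' @export
print.mapping_pairs <- function(x, ...) {
  cat("<mapping_pairs>", if (nzchar(x$label)) x$label else "(unlabelled)",
      "-", length(x$keys), "ordered pairs\n")
  invisible(x)
}

#' Number of pairs in a `mapping_pairs` set
#' @param x A `mapping_pairs` object.
#' @return Integer count.
#' @export
pair_count <- function(x) length(x$keys)

#' Convert a `mapping_pairs` set to a two-column data.frame
#' @param x A `mapping_pairs` object.
#' @return data.frame with columns `descendant`, `ancestor`.
#' @export
pairs_to_df <- function(x) {
  if (!length(x$keys))
    return(data.frame(descendant = character(0), ancestor = character(0),
                      stringsAsFactors = FALSE))
  m <- matrix(unlist(strsplit(x$keys, "\t", fixed = TRUE)), ncol = 2L, byrow = TRUE)
  data.frame(descendant = m[, 1L], ancestor = m[, 2L], stringsAsFactors = FALSE)
}

pairs_from_keys <- function(keys, label = "") {
  structure(list(keys = sort(unique(keys)), label = label), class = "mapping_pairs")
}

# restrict a pair set to pairs with both endpoints in `ids`
pairs_in_scope <- function(x, ids) {
  df <- pairs_to_df(x)
  keep <- df$descendant %in% ids & df$ancestor %in% ids
  pairs_from_keys(x$keys[keep], x$label)
}

scope_ids <- function(graph, scope) {
  if (identical(scope, "all") || is.null(scope)) term_ids(graph)
  else term_ids(graph, scope)
}

# full descendant map derived by inverting an ancestor map
invert_ancestor_map <- function(amap) {
  if (!length(amap)) return(list())
  n <- lengths(amap)
  child <- rep(names(amap), n)
  parent <- unlist(amap, use.names = FALSE)
  desc <- split(child, parent)
  out <- stats::setNames(vector("list", length(amap)), names(amap))
  for (t in names(amap)) out[[t]] <- sort(unique(desc[[t]]))
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Problematic ancestors and descendants of one has_part edge
#'
#' For a `has_part` edge stored whole-to-part, the native (uncorrected)
#' traversal direction lets every descendant of the whole map onto every
#' ancestor of the part. The problematic ancestor set is
#' `PA = (ancestors(part) + part) - (ancestors(whole) + whole)` and the
#' problematic descendant set is
#' `PD = (descendants(whole) + whole) - (descendants(part) + part)`, with all
#' ancestor/descendant sets computed over the corrected scoping graph (the
#' policy with `has_part` reinterpreted) unless another policy is passed.
#'
#' @param graph An `ontology_graph`.
#' @param policy Policy defining the ancestor/descendant sets used inside the
#'   formula; default the corrected `"gocats"` policy.
#' @param whole,part Subject (whole) and object (part) ids of the `has_part`
#'   edge.
#' @param amap,dmap Optional precomputed ancestor and descendant maps (as
#'   returned by [build_ancestor_map()] and its inversion) to avoid repeated
#'   closure computation over many edges.
#' @return List with `whole`, `part`, `PA`, `PD`.
#' @export
edge_problem_sets <- function(graph, policy = policy_preset("gocats"),
                              whole, part, amap = NULL, dmap = NULL) {
  hp <- graph$edges$relation == "has_part" &
    graph$edges$subject == whole & graph$edges$object == part
  if (!any(hp)) stop("no has_part edge ", whole, " -> ", part, " in graph")
  if (is.null(amap)) amap <- build_ancestor_map(graph, policy)
  if (is.null(dmap)) dmap <- invert_ancestor_map(amap)
  PA <- setdiff(union(amap[[part]], part), union(amap[[whole]], whole))
  PD <- setdiff(union(dmap[[whole]], whole), union(dmap[[part]], part))
  list(whole = whole, part = part, PA = sort(PA), PD = sort(PD))
}

#' False mapping pairs induced by one edge's problem sets
#'
#' The Cartesian product `PD x PA` with self-pairs removed: every pairing of
#' a problematic descendant with a problematic ancestor is a mapping the
#' native `has_part` direction would wrongly license.
#'
#' @param eps Result of [edge_problem_sets()].
#' @return A `mapping_pairs` set.
#' @export
edge_false_pairs <- function(eps) {
  if (!length(eps$PA) || !length(eps$PD))
    return(mapping_pairs(label = "pM_F,e"))
  grid <- expand.grid(d = eps$PD, a = eps$PA, stringsAsFactors = FALSE)
  mapping_pairs(grid$d, grid$a, label = "pM_F,e")
}

#' Estimated potential false mappings of a relation (epM_F)
#'
#' Union over every edge of the given relation (within scope) of its
#' per-edge false pair set.
#'
#' @inheritParams edge_problem_sets
#' @param relation Relation label audited (the study case is `"has_part"`).
#' @param scope `"all"` or a namespace name; an edge is in scope when both of
#'   its endpoints carry the namespace.
#' @return A `mapping_pairs` set labelled `"epM_F"`.
#' @export
estimated_false_mappings <- function(graph, policy = policy_preset("gocats"),
                                     relation = "has_part", scope = "all") {
  ids <- scope_ids(graph, scope)
  e <- graph$edges[graph$edges$relation == relation &
                     graph$edges$subject %in% ids &
                     graph$edges$object %in% ids, , drop = FALSE]
  sub <- restrict_graph(graph, ids)
  amap <- build_ancestor_map(sub, policy)
  dmap <- invert_ancestor_map(amap)
  keys <- character(0)
  for (i in seq_len(nrow(e))) {
    eps <- edge_problem_sets(sub, policy, e$subject[i], e$object[i],
                             amap = amap, dmap = dmap)
    keys <- c(keys, edge_false_pairs(eps)$keys)
  }
  pairs_from_keys(keys, "epM_F")
}

# induced subgraph on a set of term ids (keeps only internal edges)
restrict_graph <- function(graph, ids) {
  nodes <- graph$nodes[graph$nodes$id %in% ids, , drop = FALSE]
  e <- graph$edges[graph$edges$subject %in% ids & graph$edges$object %in% ids, , drop = FALSE]
  ontology_graph(nodes, e)
}

#' True mapping pairs under a policy (M_T)
#'
#' All ordered pairs (descendant, ancestor) with the ancestor in the
#' descendant's transitive scoped ancestor set, endpoints within scope,
#' self-pairs excluded.
#'
#' @inheritParams estimated_false_mappings
#' @return A `mapping_pairs` set labelled by the policy.
#' @export
true_mappings <- function(graph, policy = policy_preset("gocats"), scope = "all") {
  ids <- scope_ids(graph, scope)
  sub <- restrict_graph(graph, ids)
  amap <- build_ancestor_map(sub, policy)
  n <- lengths(amap)
  mapping_pairs(rep(names(amap), n), unlist(amap, use.names = FALSE),
                label = paste0("M_T(", policy$label, ")"))
}

#' Audit the false/lost mapping burden of a relation
#'
#' Assembles, for one relation and scope: the estimated potential false
#' mappings `epM_F` from the relation's native direction, the true mappings
#' `M_T` of the corrected scoping graph, their intersection, the potential
#' false mappings `pM_F = epM_F - |M_T ∩ epM_F|`, the true mappings of
#' the `is_a`/`part_of`-only graph (`IA_PO_M_T`), and the mappings lost when
#' the relation is simply dropped (`lost = M_T - IA_PO_M_T`).
#'
#' @inheritParams estimated_false_mappings
#' @return Object of class `audit_report`: list of the counts above plus the
#'   ratios `pMF_over_MT` and `lost_over_MT` and the underlying pair sets.
#' @export
audit_relation <- function(graph, relation = "has_part", scope = "all",
                           policy = policy_preset("gocats")) {
  epMF <- estimated_false_mappings(graph, policy, relation, scope)
  MT <- true_mappings(graph, policy, scope)
  nohp <- true_mappings(graph, policy_preset("no_hp"), scope)
  inter <- length(intersect(epMF$keys, MT$keys))
  pMF <- pair_count(epMF) - inter
  lost <- pair_count(MT) - pair_count(nohp)
  structure(list(
    relation = relation, scope = scope,
    epM_F = pair_count(epMF), M_T = pair_count(MT),
    intersection = inter, pM_F = pMF,
    IA_PO_M_T = pair_count(nohp), lost = lost,
    pMF_over_MT = if (pair_count(MT) > 0) pMF / pair_count(MT) else NA_real_,
    lost_over_MT = if (pair_count(MT) > 0) lost / pair_count(MT) else NA_real_,
    pairs = list(epM_F = epMF, M_T = MT, IA_PO_M_T = nohp)),
    class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report> relation=", x$relation, " scope=", x$scope, "\n", sep = "")
  cat(sprintf("  epM_F=%d  M_T=%d  intersection=%d  pM_F=%d\n",
              x$epM_F, x$M_T, x$intersection, x$pM_F))
  cat(sprintf("  IA_PO_M_T=%d  lost=%d  pM_F/M_T=%.3f  lost/M_T=%.3f\n",
              x$IA_PO_M_T, x$lost, x$pMF_over_MT, x$lost_over_MT))
  invisible(x)
}

#' Mapping pairs of a non-discriminating mapper
#'
#' Emulates a slim mapper that follows every relationship edge in its stored
#' subject-to-object direction regardless of label: for every term, its
#' "ancestors" are all terms reachable that way (cycles are tolerated via
#' visited-set reachability), and the result is the set of (term, reachable
#' term) pairs with self-mappings ignored.
#'
#' @param graph An `ontology_graph`.
#' @param scope `"all"` or a namespace; both pair endpoints must lie in scope.
#'   Reachability is always computed on the full graph, then pairs filtered.
#' @return A `mapping_pairs` set labelled `"naive"`.
#' @export
naive_mapping_pairs <- function(graph, scope = "all") {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("subject", "object")], directed = TRUE,
    vertices = data.frame(name = term_ids(graph)))
  d <- character(0); a <- character(0)
  for (v in term_ids(graph)) {
    reach <- setdiff(names(igraph::subcomponent(g, v, mode = "out")), v)
    if (length(reach)) { d <- c(d, rep(v, length(reach))); a <- c(a, reach) }
  }
  out <- mapping_pairs(d, a, label = "naive")
  if (!identical(scope, "all")) out <- pairs_in_scope(out, scope_ids(graph, scope))
  out
}

#' Error report for the non-discriminating mapper
#'
#' For each scope (all terms plus each namespace present): the naive pair
#' count, the corrected scoping pair count, the potentially-false naive pairs
#' (naive pairs absent from the whole-graph corrected pair set), the correct
#' naive pairs (the complement), and the error fraction
#' `potentially_false / naive` (the primary convention, which matches the
#' published all-ontology error of false/naive); the alternative ratio with
#' the corrected pair count as denominator is reported as
#' `error_fraction_alt`.
#'
#' @param graph An `ontology_graph`.
#' @param policy Corrected policy used for the reference pair set.
#' @return data.frame of class `naive_error_report`, one row per scope, with
#'   columns `scope`, `naive`, `gocats_scoping`, `potentially_false`,
#'   `correct`, `error_fraction`, `error_fraction_alt`.
#' @export
naive_error_report <- function(graph, policy = policy_preset("gocats")) {
  naive_all <- naive_mapping_pairs(graph, "all")
  gocats_all <- true_mappings(graph, policy, "all")
  scopes <- c("all", sort(unique(stats::na.omit(graph$nodes$namespace))))
  rows <- lapply(scopes, function(sc) {
    ids <- scope_ids(graph, sc)
    naive_sc <- if (identical(sc, "all")) naive_all else pairs_in_scope(naive_all, ids)
    gocats_sc <- if (identical(sc, "all")) gocats_all
      else true_mappings(graph, policy, sc)
    correct <- length(intersect(naive_sc$keys, gocats_all$keys))
    false_ <- pair_count(naive_sc) - correct
    data.frame(scope = sc, naive = pair_count(naive_sc),
               gocats_scoping = pair_count(gocats_sc),
               potentially_false = false_, correct = correct,
               error_fraction = if (pair_count(naive_sc) > 0)
                 false_ / pair_count(naive_sc) else NA_real_,
               error_fraction_alt = if (pair_count(gocats_sc) > 0)
                 false_ / pair_count(gocats_sc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("naive_error_report", "data.frame")
  out
}
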