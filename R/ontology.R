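#' Parse an OBO 1.2 flat file into a relation-typed ontology graph
#'
#' Reads `[Term]` stanzas from a go/go-core style OBO file. Recognized stanza
#' keys are `id`, `name`, `namespace`, `alt_id`, `is_a`, `relationship` and
#' `is_obsolete`; all other keys are ignored. `is_a` lines and `relationship`
#' lines become typed edges stored verbatim in their asserted
#' subject-to-object direction (for `has_part` that is whole-to-part).
#' Obsolete terms are retained as nodes but excluded from edge attachment.
#' `alt_id` lines populate an alias table used to resolve edge endpoints.
#' Edges whose target resolves to no known term are dropped and recorded in
#' the `dangling` attribute; duplicate (subject, relation, object) triples are
#' deduplicated with a warning.
#'
#' @param path Path to an OBO 1.2 flat file. The file must begin with an OBO
#'   header (a `format-version:` line before the first stanza).
#' @param restrict_namespace Optional namespace (`"cellular_component"`,
#'   `"biological_process"` or `"molecular_function"`); if given, only edges
#'   with both endpoints in that namespace are kept.
#' @return An object of class `ontology_graph`: a list with
#'   * `nodes`: data.frame (`id`, `name`, `namespace`, `obsolete`),
#'   * `edges`: data.frame (`subject`, `relation`, `object`),
#'   * `alt`: named character vector mapping alt_id to primary id,
#'   * `dangling`: data.frame of dropped unresolved edges,
#'   * `typedefs`: character vector of relation labels declared in
#'     `[Typedef]` stanzas.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0009888", "name: tissue development",
#'   "namespace: biological_process", "",
#'   "[Term]", "id: GO:0061448", "name: connective tissue development",
#'   "namespace: biological_process", "is_a: GO:0009888"), obo)
#' g <- parse_obo(obo)
#' g$edges
#' @export
parse_obo <- function(path, restrict_namespace = NULL) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header_end <- match(TRUE, startsWith(lines, "["), nomatch = length(lines) + 1L)
  if (!any(grepl("^format-version:", lines[seq_len(header_end - 1L)])))
    stop("not an OBO file (no format-version header line): ", path)

  stanza_starts <- which(startsWith(lines, "["))
  stanza_types <- sub("^\\[(.*)\\]\\s*$", "\\1", lines[stanza_starts])
  stanza_ends <- c(stanza_starts[-1L] - 1L, length(lines))

  ids <- character(0); names_ <- character(0); namespaces <- character(0)
  obsolete <- logical(0)
  alt_from <- character(0); alt_to <- character(0)
  e_subj <- character(0); e_rel <- character(0); e_obj <- character(0)
  typedefs <- character(0)

  strip_comment <- function(x) sub("\\s*!.*$", "", x)

  for (s in seq_along(stanza_starts)) {
    type <- stanza_types[s]
    body <- lines[seq(stanza_starts[s] + 1L, stanza_ends[s])]
    body <- body[nzchar(body)]
    if (type == "Typedef") {
      idl <- grep("^id:", body, value = TRUE)
      if (length(idl)) typedefs <- c(typedefs, trimws(sub("^id:", "", strip_comment(idl[1L]))))
      next
    }
    if (type != "Term") next
    idl <- grep("^id:", body, value = TRUE)
    if (!length(idl))
      stop("malformed [Term] stanza without id at line ", stanza_starts[s])
    id <- trimws(sub("^id:", "", strip_comment(idl[1L])))
    nm <- grep("^name:", body, value = TRUE)
    ns <- grep("^namespace:", body, value = TRUE)
    obs <- any(grepl("^is_obsolete:\\s*true", body))
    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm)) trimws(sub("^name:", "", nm[1L])) else NA_character_)
    namespaces <- c(namespaces, if (length(ns)) trimws(sub("^namespace:", "", ns[1L])) else NA_character_)
    obsolete <- c(obsolete, obs)
    for (al in grep("^alt_id:", body, value = TRUE)) {
      alt_from <- c(alt_from, trimws(sub("^alt_id:", "", strip_comment(al))))
      alt_to <- c(alt_to, id)
    }
    if (obs) next  # obsolete nodes contribute no edges
    for (ia in grep("^is_a:", body, value = TRUE)) {
      e_subj <- c(e_subj, id); e_rel <- c(e_rel, "is_a")
      e_obj <- c(e_obj, trimws(strip_comment(sub("^is_a:", "", ia))))
    }
    for (rl in grep("^relationship:", body, value = TRUE)) {
      parts <- strsplit(trimws(strip_comment(sub("^relationship:", "", rl))), "\\s+")[[1L]]
      if (length(parts) < 2L) next
      e_subj <- c(e_subj, id); e_rel <- c(e_rel, parts[1L]); e_obj <- c(e_obj, parts[2L])
    }
  }

  nodes <- data.frame(id = ids, name = names_, namespace = namespaces,
                      obsolete = obsolete, stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id))
    nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  alt <- stats::setNames(alt_to, alt_from)

  resolve <- function(x) {
    hit <- !(x %in% nodes$id) & x %in% names(alt)
    x[hit] <- unname(alt[x[hit]])
    x
  }
  e_subj <- resolve(e_subj); e_obj <- resolve(e_obj)

  edges <- data.frame(subject = e_subj, relation = e_rel, object = e_obj,
                      stringsAsFactors = FALSE)
  # self-edges can only arise through alias collapse; they are meaningless
  edges <- edges[edges$subject != edges$object, , drop = FALSE]

  known <- nodes$id
  obsolete_ids <- nodes$id[nodes$obsolete]
  dangling <- edges[!(edges$object %in% known) | !(edges$subject %in% known), , drop = FALSE]
  edges <- edges[edges$object %in% known & edges$subject %in% known, , drop = FALSE]
  edges <- edges[!(edges$object %in% obsolete_ids) &
                   !(edges$subject %in% obsolete_ids), , drop = FALSE]

  key <- paste(edges$subject, edges$relation, edges$object)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate relation triple(s) deduplicated")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }

  if (!is.null(restrict_namespace)) {
    ns_of <- stats::setNames(nodes$namespace, nodes$id)
    keep <- ns_of[edges$subject] == restrict_namespace &
      ns_of[edges$object] == restrict_namespace
    keep[is.na(keep)] <- FALSE
    edges <- edges[keep, , drop = FALSE]
  }
  rownames(edges) <- NULL
  rownames(nodes) <- NULL

  structure(list(nodes = nodes, edges = edges, alt = alt,
                 dangling = dangling, typedefs = unique(typedefs)),
            class = "ontology_graph")
}

#' Construct an ontology graph directly from node and edge tables
#'
#' Programmatic counterpart of [parse_obo()], used by the fixture generators
#' and in tests. Applies the same hygiene rules: endpoints must resolve to
#' known node ids, edges touching obsolete nodes are dropped, and duplicate
#' triples are removed.
#'
#' @param nodes data.frame with columns `id` and optionally `name`,
#'   `namespace`, `obsolete`.
#' @param edges data.frame with columns `subject`, `relation`, `object`.
#' @return An `ontology_graph`.
#' @export
ontology_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!("name" %in% names(nodes))) nodes[["name"]] <- NA_character_
  if (!("namespace" %in% names(nodes))) nodes[["namespace"]] <- NA_character_
  if (!("obsolete" %in% names(nodes))) nodes[["obsolete"]] <- FALSE
  nodes <- nodes[, c("id", "name", "namespace", "obsolete")]
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    edges <- data.frame(subject = character(0), relation = character(0),
                        object = character(0), stringsAsFactors = FALSE)
  edges <- edges[, c("subject", "relation", "object")]
  stopifnot(all(edges$subject != edges$object))
  bad <- !(edges$subject %in% nodes$id) | !(edges$object %in% nodes$id)
  dangling <- edges[bad, , drop = FALSE]
  edges <- edges[!bad, , drop = FALSE]
  obs <- nodes$id[nodes$obsolete]
  edges <- edges[!(edges$subject %in% obs) & !(edges$object %in% obs), , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$subject, edges$relation, edges$object)), , drop = FALSE]
  rownames(edges) <- NULL; rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 alt = stats::setNames(character(0), character(0)),
                 dangling = dangling, typedefs = character(0)),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$nodes), " terms (",
      sum(x$nodes$obsolete), " obsolete), ", nrow(x$edges), " edges\n", sep = "")
  ns <- table(x$nodes$namespace, useNA = "ifany")
  if (length(ns)) cat("  namespaces:",
                      paste(names(ns), ns, sep = "=", collapse = ", "), "\n")
  rel <- sort(table(x$edges$relation), decreasing = TRUE)
  if (length(rel)) cat("  relations:",
                       paste(names(rel), rel, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Census of relation frequencies, overall and per sub-ontology
#'
#' Counts edges by relation label. Each edge is tallied once per namespace
#' column under its subject's namespace, so the per-namespace columns always
#' sum (with cross-namespace or namespace-less edges) to the total.
#'
#' @param graph An `ontology_graph`.
#' @param watch Optional character vector of relation labels to report even
#'   when absent (as zero rows).
#' @return data.frame with columns `relation`, `total`, `cellular_component`,
#'   `biological_process`, `molecular_function`, sorted by decreasing total.
#' @export
relation_census <- function(graph, watch = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  ns_levels <- c("cellular_component", "biological_process", "molecular_function")
  rels <- sort(unique(c(graph$edges$relation, watch)))
  if (!length(rels))
    return(data.frame(relation = character(0), total = integer(0),
                      cellular_component = integer(0),
                      biological_process = integer(0),
                      molecular_function = integer(0),
                      stringsAsFactors = FALSE))
  ns_of <- stats::setNames(graph$nodes$namespace, graph$nodes$id)
  out <- data.frame(relation = rels, total = 0L,
                    cellular_component = 0L, biological_process = 0L,
                    molecular_function = 0L, stringsAsFactors = FALSE)
  if (nrow(graph$edges)) {
    subj_ns <- ns_of[graph$edges$subject]
    for (i in seq_along(rels)) {
      sel <- graph$edges$relation == rels[i]
      out$total[i] <- sum(sel)
      for (ns in ns_levels) {
        cnt <- sum(sel & !is.na(subj_ns) & subj_ns == ns)
        out[[ns]][i] <- cnt
      }
    }
    out <- out[order(-out$total, out$relation), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Ids of non-obsolete terms, optionally restricted to one namespace
#' @param graph An `ontology_graph`.
#' @param namespace Optional namespace name.
#' @return Character vector of term ids.
#' @export
term_ids <- function(graph, namespace = NULL) {
  n <- graph$nodes[!graph$nodes$obsolete, , drop = FALSE]
  if (!is.null(namespace)) n <- n[!is.na(n$namespace) & n$namespace == namespace, , drop = FALSE]
  n$id
}
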