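#' Define a scoping policy for ontology traversal
#'
#' A scoping policy says which relation labels order terms by generality and,
#' for each, whether the edge subject is the narrower or the broader term.
#' With the defaults, `is_a` and `part_of` subjects are narrower (the edge
#' already points toward the broader term) while `has_part` subjects are
#' broader: a `has_part` edge is stored whole-to-part, and reinterpreting it
#' as `part_of_some` means traversing it from its object (the part) up to its
#' subject (the whole). Setting `reinterpret_has_part = FALSE` keeps the
#' native whole-to-part direction, which is the erroneous reading the mapping
#' audit quantifies.
#'
#' @param scoping_relations Character vector of relation labels that count as
#'   scoping. Default `c("is_a", "part_of", "has_part")`.
#' @param reinterpret_has_part Logical; reinterpret `has_part` as
#'   `part_of_some` (default `TRUE`).
#' @param label Optional provenance label for the policy.
#' @return An object of class `scoping_policy`: list with
#'   `scoping_relations`, `direction` (named vector, `"subject_narrower"` or
#'   `"subject_broader"` per label), `reinterpret_has_part`, `label`, and
#'   `correspondence` metadata classing each known relation label.
#' @seealso [policy_preset()] for the named policies used throughout.
#' @export
scoping_policy <- function(scoping_relations = c("is_a", "part_of", "has_part"),
                           reinterpret_has_part = TRUE,
                           label = "custom") {
  stopifnot(is.character(scoping_relations), !anyDuplicated(scoping_relations))
  direction <- stats::setNames(rep("subject_narrower", length(scoping_relations)),
                               scoping_relations)
  if ("has_part" %in% scoping_relations)
    direction[["has_part"]] <-
      if (reinterpret_has_part) "subject_broader" else "subject_narrower"
  correspondence <- c(
    is_a = "scoping", part_of = "mereological", has_part = "mereological",
    happens_during = "spatiotemporal", ends_during = "spatiotemporal",
    occurs_in = "spatiotemporal", regulates = "active",
    positively_regulates = "active", negatively_regulates = "active")
  structure(list(scoping_relations = scoping_relations,
                 direction = direction,
                 reinterpret_has_part = reinterpret_has_part,
                 label = label,
                 correspondence = correspondence),
            class = "scoping_policy")
}

#' Named traversal policies
#'
#' * `"gocats"`: `{is_a, part_of, has_part}` with `has_part` reinterpreted as
#'   `part_of_some` — the corrected scoping traversal.
#' * `"no_hp"`: `{is_a, part_of}` — the traditional traversal that omits
#'   `has_part` entirely.
#' * `"go-basic-scoping"`: identical relation set to `"no_hp"`; kept as a
#'   separate label because it denotes emulating a go-basic style graph from a
#'   go-core file rather than deliberately dropping `has_part`.
#'
#' @param name One of `"gocats"`, `"no_hp"`, `"go-basic-scoping"`.
#' @return A [scoping_policy()].
#' @export
policy_preset <- function(name = c("gocats", "no_hp", "go-basic-scoping")) {
  name <- match.arg(name)
  switch(name,
    "gocats" = scoping_policy(c("is_a", "part_of", "has_part"),
                              reinterpret_has_part = TRUE, label = "gocats"),
    "no_hp" = scoping_policy(c("is_a", "part_of"), label = "no_hp"),
    "go-basic-scoping" = scoping_policy(c("is_a", "part_of"),
                                        label = "go-basic-scoping"))
}

#' @export
print.scoping_policy <- function(x, ...) {
  cat("<scoping_policy> ", x$label, ": {",
      paste(x$scoping_relations, collapse = ", "), "}",
      if (isTRUE(x$reinterpret_has_part) && "has_part" %in% x$scoping_relations)
        " (has_part reinterpreted as part_of_some)" else "",
      "\n", sep = "")
  invisible(x)
}
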