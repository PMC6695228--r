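# GAF 2.x gene-association file handling and annotation expansion.

gaf_columns <- c("db", "object_id", "symbol", "qualifier", "go_id",
                 "reference", "evidence", "with_from", "aspect", "name",
                 "synonym", "type", "taxon", "date", "assigned_by",
                 "extension", "gene_product_form_id")

#' Read a GAF 2.x gene-association file
#'
#' Comment lines (starting `!`) are skipped; every record line must have 17
#' tab-separated columns. Records are returned verbatim, including
#' NOT-qualified ones — exclusion of NOT annotations happens when an
#' [annotation_set()] is built.
#'
#' @param path Path to a GAF 2.0/2.1 file.
#' @return data.frame with the 17 standard GAF columns (named `db`,
#'   `object_id`, `symbol`, `qualifier`, `go_id`, `reference`, `evidence`,
#'   `with_from`, `aspect`, `name`, `synonym`, `type`, `taxon`, `date`,
#'   `assigned_by`, `extension`, `gene_product_form_id`).
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!startsWith(lines, "!") & nzchar(trimws(lines)))
  empty <- as.data.frame(stats::setNames(
    replicate(17, character(0), simplify = FALSE), gaf_columns),
    stringsAsFactors = FALSE)
  if (!length(data_idx)) return(empty)
  # sentinel keeps trailing empty fields that strsplit would drop
  parts <- strsplit(paste0(lines[data_idx], "\tEND"), "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) p[-length(p)])
  nf <- lengths(parts)
  if (any(nf != 17L))
    stop("GAF format error: line ", data_idx[which(nf != 17L)[1L]],
         " has ", nf[nf != 17L][1L], " columns (expected 17)")
  m <- matrix(unlist(parts), ncol = 17L, byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- gaf_columns
  out
}

#' Build a gene-to-terms annotation set from GAF records
#'
#' NOT-qualified records are excluded; gene identity is the GAF column-2
#' object id. Optional evidence-code filtering is available but off by
#' default (the enrichment analyses here use all annotations).
#'
#' @param records data.frame from [read_gaf()].
#' @param exclude_evidence Optional character vector of evidence codes to
#'   drop (e.g. `"IEA"`).
#' @return Object of class `annotation_set`: named list gene id -> sorted
#'   character vector of GO ids, with attributes `expanded` (logical) and
#'   `provenance`.
#' @export
annotation_set <- function(records, exclude_evidence = NULL) {
  keep <- !grepl("(^|\\|)NOT($|\\|)", records$qualifier)
  if (!is.null(exclude_evidence)) keep <- keep & !(records$evidence %in% exclude_evidence)
  r <- records[keep, , drop = FALSE]
  ann <- lapply(split(r$go_id, r$object_id), function(x) sort(unique(x)))
  structure(ann[sort(names(ann))], class = "annotation_set",
            expanded = FALSE, provenance = "gaf")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", length(x), " genes, ",
      length(unique(unlist(x, use.names = FALSE))), " distinct terms",
      if (isTRUE(attr(x, "expanded"))) " (ancestor-expanded)" else " (raw)",
      "\n", sep = "")
  invisible(x)
}

#' Expand an annotation set through an ancestor map
#'
#' Each gene's term set is replaced by its union with the ancestors of each
#' of its terms. Terms absent from the map (unknown or obsolete) contribute
#' no ancestors; their count is attached as attribute `"unknown_terms"`.
#' Because ancestor maps are transitively closed, expansion is idempotent.
#'
#' @param ann An `annotation_set`.
#' @param map An `ancestor_map` (named list term -> ancestors).
#' @return The expanded `annotation_set`.
#' @export
expand_annotations <- function(ann, map) {
  unknown <- 0L
  out <- lapply(ann, function(terms) {
    unknown <<- unknown + sum(!(terms %in% names(map)))
    anc <- unlist(map[intersect(terms, names(map))], use.names = FALSE)
    sort(unique(c(terms, anc)))
  })
  lbl <- attr(map, "policy")$label %||% "map"
  structure(out, class = "annotation_set", expanded = TRUE,
            provenance = paste0(attr(ann, "provenance"), "+", lbl),
            unknown_terms = unknown)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a term-as-gene identity GAF
#'
#' Emits one GAF 2.1 line per non-obsolete term in the namespace with both
#' the gene id column and the GO id column set to the term id. Mapping such a
#' file with any gene-level slim mapper turns it into a term-level mapper,
#' which is how a black-box mapper's term-to-term pairs can be extracted.
#'
#' @param graph An `ontology_graph`.
#' @param namespace Namespace to emit (`NULL` for all).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
identity_gaf <- function(graph, namespace = NULL, path) {
  ids <- term_ids(graph, namespace)
  ns_of <- stats::setNames(graph$nodes$namespace, graph$nodes$id)
  aspect <- c(cellular_component = "C", biological_process = "P",
              molecular_function = "F")[ns_of[ids]]
  aspect[is.na(aspect)] <- "P"
  con <- file(path, "w"); on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  for (i in seq_along(ids))
    writeLines(paste(c("GOSCOPE", ids[i], ids[i], "", ids[i], "GO_REF:0000000",
                       "IEA", "", aspect[i], "", "", "gene_product",
                       "taxon:0000", "20160112", "goscope", "", ""),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write an annotation set as a two-column gene/term TSV
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# gene\tterm", con)
  for (g in names(ann))
    if (length(ann[[g]])) writeLines(paste(g, ann[[g]], sep = "\t"), con)
  invisible(path)
}
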