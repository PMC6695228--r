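# Serialization of term -> ancestor maps (TSV and JSON), round-trip safe.

#' Write an ancestor map to disk
#'
#' TSV output is two columns (`term`, `ancestor`), one pair per line, sorted
#' lexicographically by term then ancestor, preceded by a `#` header comment;
#' terms with empty ancestor sets are recorded with an empty second field so
#' the map round-trips exactly. JSON output is an object mapping each term to
#' an array of ancestors.
#'
#' @param map An `ancestor_map` (or plain named list of character vectors).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_mapping_table()]
#' @export
write_mapping_table <- function(map, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(!is.null(map))
  map <- lapply(map, function(x) sort(unique(as.character(x))))
  map <- map[sort(names(map))]
  if (format == "json") {
    jsonlite::write_json(lapply(map, as.character), path, auto_unbox = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# term\tancestor", con)
  for (t in names(map)) {
    anc <- map[[t]]
    if (!length(anc)) writeLines(paste0(t, "\t"), con)
    else writeLines(paste(t, anc, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an ancestor map written by [write_mapping_table()]
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return Named list of sorted character vectors.
#' @export
read_mapping_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(raw, function(x) sort(unique(as.character(x)))))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  term <- vapply(parts, `[`, "", 1L)
  anc <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")
  out <- lapply(split(anc, term), function(x) sort(unique(x[nzchar(x)])))
  out[sort(names(out))]
}

#' Write a relation census as TSV
#' @param census Result of [relation_census()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  utils::write.table(census, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
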