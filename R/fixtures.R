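# Seeded synthetic fixtures: toy ontologies, GAF annotation files and DE
# tables, each with a ground-truth ledger so downstream computations can be
# checked without external data.

#' Specification for a synthetic fixture family
#'
#' One seed governs all randomness; identical spec + seed yields byte
#' identical artifacts. The generators draw from separate streams derived
#' from the seed (`seed` for the ontology, `seed + 1` for the GAF,
#' `seed + 2` for DE tables) so regenerating one artifact never perturbs
#' another.
#'
#' @param seed Integer seed.
#' @param nodes_per_namespace Named integer vector of term counts, names from
#'   `cellular_component`/`biological_process`/`molecular_function`.
#' @param relation_mix Named numeric proportions over
#'   `is_a`, `part_of`, `has_part`, `regulates`; must sum to 1.
#' @param max_out_degree Maximum scoping out-degree per term.
#' @param n_genes Number of genes in the annotation universe.
#' @param n_signal Number of signal genes carrying the planted enrichment.
#' @param odds_ratio Planted gene-level odds ratio of being annotated inside
#'   the planted category (signal vs background genes).
#' @param annotations_per_gene Direct annotations drawn per gene.
#' @param de_sig_fraction Fraction of genes planted as significant in a DE
#'   table.
#' @param de_alpha Adjusted p-value threshold the DE generator plants
#'   significance against.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         nodes_per_namespace = c(cellular_component = 30L,
                                                 biological_process = 40L,
                                                 molecular_function = 20L),
                         relation_mix = c(is_a = 0.70, part_of = 0.15,
                                          has_part = 0.10, regulates = 0.05),
                         max_out_degree = 2L,
                         n_genes = 300L,
                         n_signal = 30L,
                         odds_ratio = 8,
                         annotations_per_gene = 3L,
                         de_sig_fraction = 0.2,
                         de_alpha = 0.01) {
  stopifnot(abs(sum(relation_mix) - 1) < 1e-9, all(relation_mix >= 0),
            all(nodes_per_namespace >= 0), max_out_degree >= 1,
            n_signal <= n_genes, odds_ratio > 0,
            de_sig_fraction >= 0, de_sig_fraction <= 1)
  if (sum(nodes_per_namespace) > 0 && max(nodes_per_namespace) < 2 &&
      sum(nodes_per_namespace > 0) > 0 && any(nodes_per_namespace == 1))
    stop("infeasible spec: a namespace needs at least 2 terms to carry edges")
  structure(as.list(environment()), class = "fixture_spec")
}

go_id <- function(i) sprintf("GO:%07d", i)

# memoized transitive closure over a child->parent edge list; this is the
# generator's own ground truth, independent of the igraph-based traversal
closure_from_edges <- function(child, parent, ids) {
  parents_of <- split(parent, child)
  anc <- stats::setNames(vector("list", length(ids)), ids)
  done <- stats::setNames(logical(length(ids)), ids)
  visit <- function(v) {
    if (done[[v]]) return(anc[[v]])
    ps <- unique(parents_of[[v]])
    res <- ps
    for (p in ps) res <- union(res, visit(p))
    anc[[v]] <<- sort(res %||% character(0))
    done[[v]] <<- TRUE
    anc[[v]]
  }
  for (v in ids) visit(v)
  anc
}

#' Generate a synthetic OBO ontology with a ground-truth ledger
#'
#' Terms are created in sequence; every scoping edge is drawn from a
#' later-created term to an earlier-created one within the same namespace, so
#' the scoped subgraph is acyclic by construction. `has_part` edges are
#' stored in the GO convention (whole to part, i.e. from the earlier, broader
#' term to the later, narrower one) so the `part_of_some` reinterpretation is
#' genuinely exercised. A planted category root is chosen as the term whose
#' scoped descendant set is closest to 15% of its namespace.
#'
#' @param spec A [fixture_spec()].
#' @param path Output OBO path (default a tempfile).
#' @return List with `obo` (the file path), `graph` (the parsed
#'   [ontology_graph()]) and `ledger`: nodes, edges (by relation, as
#'   generated), ground-truth ancestor sets under the corrected and
#'   traditional policies, the planted `category_root` and its
#'   `category_members` (root plus scoped descendants).
#' @export
generate_ontology <- function(spec, path = tempfile(fileext = ".obo")) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  ns_names <- names(spec$nodes_per_namespace)
  ids <- character(0); ns <- character(0)
  counter <- 0L
  e_subj <- character(0); e_rel <- character(0); e_obj <- character(0)
  for (nsi in seq_along(ns_names)) {
    n <- spec$nodes_per_namespace[[nsi]]
    if (n == 0L) next
    local_ids <- go_id(counter + seq_len(n)); counter <- counter + n
    ids <- c(ids, local_ids); ns <- c(ns, rep(ns_names[nsi], n))
    for (i in seq_len(n)[-1]) {
      d <- sample.int(min(spec$max_out_degree, i - 1L), 1L)
      parents <- sample(local_ids[seq_len(i - 1L)], d)
      rels <- sample(names(spec$relation_mix), d, replace = TRUE,
                     prob = spec$relation_mix)
      for (j in seq_len(d)) {
        if (rels[j] == "has_part") {   # stored whole -> part
          e_subj <- c(e_subj, parents[j]); e_obj <- c(e_obj, local_ids[i])
        } else {
          e_subj <- c(e_subj, local_ids[i]); e_obj <- c(e_obj, parents[j])
        }
        e_rel <- c(e_rel, rels[j])
      }
    }
  }
  edges <- data.frame(subject = e_subj, relation = e_rel, object = e_obj,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$subject, edges$relation, edges$object)), ,
                 drop = FALSE]
  nodes <- data.frame(id = ids, name = paste("synthetic term", ids),
                      namespace = ns, obsolete = FALSE, stringsAsFactors = FALSE)
  write_obo(nodes, edges, path)
  graph <- parse_obo(path)

  # ground truth closures (generator-side recursion, not the igraph path)
  scoping <- edges$relation %in% c("is_a", "part_of", "has_part")
  hp <- edges$relation == "has_part"
  child <- ifelse(hp, edges$object, edges$subject)[scoping]
  parent <- ifelse(hp, edges$subject, edges$object)[scoping]
  anc_gocats <- closure_from_edges(child, parent, ids)
  nohp <- edges$relation %in% c("is_a", "part_of")
  anc_nohp <- closure_from_edges(edges$subject[nohp], edges$object[nohp], ids)

  desc_count <- table(factor(unlist(anc_gocats, use.names = FALSE), levels = ids))
  ns_size <- stats::setNames(as.integer(table(ns)[ns]), ids)
  target <- pmax(2, round(0.15 * ns_size))
  root <- ids[which.min(abs(as.integer(desc_count) - target))]
  members <- sort(c(root, ids[vapply(anc_gocats, function(a) root %in% a, TRUE)]))

  ledger <- list(nodes = nodes, edges = edges,
                 ancestors_gocats = anc_gocats, ancestors_no_hp = anc_nohp,
                 category_root = root, category_members = members)
  list(obo = path, graph = graph, ledger = ledger)
}

#' Write an ontology as an OBO 1.2 flat file
#' @param nodes data.frame with `id`, `name`, `namespace`, `obsolete`.
#' @param edges data.frame with `subject`, `relation`, `object`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(nodes, edges, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2",
               "ontology: goscope-synthetic-fixture"), con)
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", nodes$name[i]),
                 paste0("namespace: ", nodes$namespace[i])), con)
    if (isTRUE(nodes$obsolete[i])) writeLines("is_obsolete: true", con)
    mine <- edges[edges$subject == id, , drop = FALSE]
    for (j in seq_len(nrow(mine))) {
      if (mine$relation[j] == "is_a")
        writeLines(paste0("is_a: ", mine$object[j]), con)
      else
        writeLines(paste0("relationship: ", mine$relation[j], " ",
                          mine$object[j]), con)
    }
  }
  invisible(path)
}

#' Generate a synthetic GAF with a planted category enrichment
#'
#' Background genes draw their direct annotations uniformly from all terms,
#' so each background draw lands inside the planted category with probability
#' `f`, the category's share of terms. Each draw of a signal gene lands
#' inside the category with probability `q` such that
#' `odds(q) = odds_ratio * odds(f)`: the planted odds ratio acts per
#' annotation. The implied gene-level category-touch probabilities
#' (`1 - (1 - f)^a` and `1 - (1 - q)^a` for `a` annotations per gene) are
#' recorded in the ledger as `p_background` and `p_signal`.
#'
#' @param spec A [fixture_spec()].
#' @param ledger Ledger from [generate_ontology()].
#' @param path Output GAF path (default a tempfile).
#' @return List with `gaf` (path) and `ledger` additions: `genes`,
#'   `signal_genes`, `gene_terms` (the planted gene-to-terms truth) and
#'   `p_background`/`p_signal`.
#' @export
generate_gaf <- function(spec, ledger, path = tempfile(fileext = ".gaf")) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  ids <- ledger$nodes$id[!ledger$nodes$obsolete]
  members <- intersect(ledger$category_members, ids)
  outside <- setdiff(ids, members)
  genes <- sprintf("gene%04d", seq_len(spec$n_genes))
  signal <- if (spec$n_signal > 0) genes[seq_len(spec$n_signal)] else character(0)
  f <- length(members) / length(ids)
  q <- spec$odds_ratio * f / (1 - f) / (1 + spec$odds_ratio * f / (1 - f))
  a <- spec$annotations_per_gene
  p_bg <- 1 - (1 - f)^a
  p_sig <- 1 - (1 - q)^a
  gene_terms <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    if (g %in% signal && spec$n_signal > 0) {
      inside <- stats::runif(a) < q
      terms <- character(a)
      if (any(inside)) terms[inside] <- sample(members, sum(inside), replace = TRUE)
      if (any(!inside)) terms[!inside] <- sample(outside, sum(!inside), replace = TRUE)
    } else {
      terms <- sample(ids, a, replace = TRUE)
    }
    gene_terms[[g]] <- sort(unique(terms))
  }
  ns_of <- stats::setNames(ledger$nodes$namespace, ledger$nodes$id)
  aspect_of <- c(cellular_component = "C", biological_process = "P",
                 molecular_function = "F")
  con <- file(path, "w")
  writeLines("!gaf-version: 2.1", con)
  for (g in genes) for (t in gene_terms[[g]])
    writeLines(paste(c("GOSCOPE", g, g, "", t, "GO_REF:0000000", "IEA", "",
                       aspect_of[[ns_of[[t]]]], "", "", "gene_product",
                       "taxon:0000", "20160112", "goscope", "", ""),
                     collapse = "\t"), con)
  close(con)
  ledger$genes <- genes; ledger$signal_genes <- signal
  ledger$gene_terms <- gene_terms
  ledger$p_background <- p_bg; ledger$p_signal <- p_sig
  list(gaf = path, ledger = ledger)
}

#' Generate synthetic differential-expression tables with planted truth
#'
#' With `contrasts = 1`, plants `de_sig_fraction` of the genes as significant
#' (balanced signs) and records each gene's truth (`"positive"`, `"negative"`
#' or `"ns"`). With `contrasts = 2`, assigns each gene a time-series class
#' (`early`/`late`/`transient`/`consistent`, signed, or `"null"`) and builds
#' the two interval tables to match; the class assignment is the ledger
#' truth for [classify_time_series()].
#'
#' @param spec A [fixture_spec()].
#' @param ledger Ledger holding `genes` (from [generate_gaf()]); if absent,
#'   genes are created from the spec.
#' @param contrasts 1 or 2.
#' @return List with `tables` (list of data.frames with `gene`,
#'   `log2FoldChange`, `padj`) and `truth` (per-gene class vector).
#' @export
generate_de_table <- function(spec, ledger = NULL, contrasts = 1L) {
  stopifnot(inherits(spec, "fixture_spec"), contrasts %in% c(1L, 2L))
  set.seed(spec$seed + 2L)
  genes <- ledger$genes %||% sprintf("gene%04d", seq_len(spec$n_genes))
  n <- length(genes)
  alpha <- spec$de_alpha
  sig_p <- function(m) stats::runif(m, 0, alpha * 0.9)
  ns_p <- function(m) stats::runif(m, alpha * 1.5, 1)
  lfc <- function(m, sgn) sgn * (abs(stats::rnorm(m, 2, 0.5)) + 0.25)
  if (contrasts == 1L) {
    n_sig <- round(spec$de_sig_fraction * n)
    sig_idx <- if (n_sig > 0) sample.int(n, n_sig) else integer(0)
    sgn <- rep(0, n)
    if (n_sig > 0) sgn[sig_idx] <- sample(c(-1, 1), n_sig, replace = TRUE)
    tab <- data.frame(gene = genes,
                      log2FoldChange = ifelse(sgn != 0, lfc(n, sgn),
                                              stats::rnorm(n, 0, 0.3)),
                      padj = ifelse(sgn != 0, sig_p(n), ns_p(n)),
                      stringsAsFactors = FALSE)
    truth <- ifelse(sgn > 0, "positive", ifelse(sgn < 0, "negative", "ns"))
    return(list(tables = list(tab), truth = stats::setNames(truth, genes)))
  }
  classes <- c("early_positive", "early_negative", "late_positive",
               "late_negative", "transient_positive", "transient_negative",
               "consistent_positive", "consistent_negative", "null")
  probs <- c(rep(spec$de_sig_fraction / 8, 8), 1 - spec$de_sig_fraction)
  cls <- sample(classes, n, replace = TRUE, prob = probs)
  sgn1 <- rep(0, n); sgn2 <- rep(0, n)
  first_sign <- ifelse(grepl("positive$", cls), 1, -1)
  sel <- function(p) grepl(p, cls)
  sgn1[sel("^early|^transient|^consistent")] <- first_sign[sel("^early|^transient|^consistent")]
  sgn2[sel("^late")] <- first_sign[sel("^late")]
  sgn2[sel("^consistent")] <- first_sign[sel("^consistent")]
  sgn2[sel("^transient")] <- -first_sign[sel("^transient")]
  mk <- function(sgn) data.frame(
    gene = genes,
    log2FoldChange = ifelse(sgn != 0, lfc(n, sgn), stats::rnorm(n, 0, 0.3)),
    padj = ifelse(sgn != 0, sig_p(n), ns_p(n)),
    stringsAsFactors = FALSE)
  list(tables = list(mk(sgn1), mk(sgn2)), truth = stats::setNames(cls, genes))
}

#' A fixture whose planted category is reachable only through has_part
#'
#' Builds a small ontology in which the signal terms' only path to the
#' category root runs through a single `has_part` edge (stored root-to-hub,
#' i.e. the root has_part the hub), plus distractor terms under the namespace
#' root. Signal genes are annotated to the signal terms and background genes
#' to distractors. Under the corrected policy the category root is an
#' ancestor of every signal term; under the traditional policy it is an
#' ancestor of none, so enrichment of the signal gene set flags the root only
#' when `has_part` is reinterpreted.
#'
#' @param seed Integer seed.
#' @param n_signal_terms,n_distractor_terms Term counts.
#' @param n_genes,n_signal Gene universe size and signal gene count.
#' @return List with `graph`, `category_root`, `genes`, `signal_genes`, and
#'   `ann` (the raw `annotation_set`).
#' @export
haspart_sensitivity_fixture <- function(seed = 1L, n_signal_terms = 6L,
                                        n_distractor_terms = 20L,
                                        n_genes = 200L, n_signal = 30L) {
  set.seed(seed)
  ns_root <- "GO:0008150"; cat_root <- "GO:0001000"; hub <- "GO:0002000"
  sig_terms <- go_id(3000 + seq_len(n_signal_terms))
  dis_terms <- go_id(4000 + seq_len(n_distractor_terms))
  nodes <- data.frame(
    id = c(ns_root, cat_root, hub, sig_terms, dis_terms),
    name = "synthetic term", namespace = "biological_process",
    obsolete = FALSE, stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(subject = cat_root, relation = "is_a", object = ns_root,
               stringsAsFactors = FALSE),
    data.frame(subject = cat_root, relation = "has_part", object = hub,
               stringsAsFactors = FALSE),
    data.frame(subject = sig_terms, relation = "is_a", object = hub,
               stringsAsFactors = FALSE),
    data.frame(subject = dis_terms, relation = "is_a", object = ns_root,
               stringsAsFactors = FALSE))
  graph <- ontology_graph(nodes, edges)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  signal <- genes[seq_len(n_signal)]
  gene_terms <- lapply(genes, function(g)
    if (g %in% signal) sort(unique(sample(sig_terms, 2L, replace = TRUE)))
    else sort(unique(sample(dis_terms, 2L, replace = TRUE))))
  names(gene_terms) <- genes
  ann <- structure(gene_terms, class = "annotation_set", expanded = FALSE,
                   provenance = "haspart_sensitivity_fixture")
  list(graph = graph, category_root = cat_root, genes = genes,
       signal_genes = signal, ann = ann)
}
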