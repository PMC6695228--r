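# Hypergeometric annotation enrichment, DE-gene classification, the paired
# policy comparison with an exact one-sided binomial test, and the
# time-series term-set algebra.

#' One-sided hypergeometric over-representation p-value
#'
#' Upper tail `P(X >= k)` for `X` hypergeometric: a draw of `n` genes from a
#' universe of `N` in which `K` carry the annotation.
#'
#' @param k Annotated genes in the drawn set.
#' @param K Annotated genes in the universe.
#' @param n Drawn set size.
#' @param N Universe size.
#' @return The tail probability.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts: k=", k, " K=", K, " n=", n, " N=", N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving and capped at 1.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Exact one-sided binomial improvement test
#'
#' Tail probability `P(X >= n_improved)` for `X ~ Binomial(n_compared, 1/2)`:
#' the coin-toss test of whether more paired p-values improved than chance
#' would allow.
#'
#' @param n_improved Number of comparisons that improved.
#' @param n_compared Total comparisons (after excluding ties).
#' @param two_sided If `TRUE`, return the symmetric two-sided p-value
#'   (exactly twice the smaller tail at p = 1/2); default one-sided.
#' @return The p-value.
#' @export
binomial_improvement_test <- function(n_improved, n_compared, two_sided = FALSE) {
  if (n_compared < 1) stop("undefined binomial test: n_compared = 0")
  if (n_improved < 0 || n_improved > n_compared)
    stop("n_improved must lie in [0, n_compared]")
  p <- stats::pbinom(n_improved - 1, n_compared, 0.5, lower.tail = FALSE)
  if (two_sided) min(1, 2 * min(p, stats::pbinom(n_improved, n_compared, 0.5))) else p
}

#' Classify differentially expressed genes by sign
#'
#' @param table data.frame with columns `gene`, `log2FoldChange`, `padj`.
#' @param alpha Adjusted p-value threshold in (0, 1); default 0.01.
#' @return Object of class `gene_set_partition`: list with `positive`,
#'   `negative` and `all` gene id vectors. Rows with `NA` adjusted p are
#'   skipped with a warning; a significant row with fold change exactly zero
#'   is an error (its sign class is undefined).
#' @export
classify_de_genes <- function(table, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1,
            all(c("gene", "log2FoldChange", "padj") %in% names(table)))
  nas <- is.na(table$padj)
  if (any(nas)) {
    warning(sum(nas), " row(s) with NA adjusted p-value skipped")
    table <- table[!nas, , drop = FALSE]
  }
  sig <- table$padj <= alpha
  if (any(sig & table$log2FoldChange == 0))
    stop("significant gene(s) with zero log2 fold change cannot be classified: ",
         paste(table$gene[sig & table$log2FoldChange == 0], collapse = ", "))
  pos <- sort(table$gene[sig & table$log2FoldChange > 0])
  neg <- sort(table$gene[sig & table$log2FoldChange < 0])
  structure(list(positive = pos, negative = neg, all = sort(c(pos, neg))),
            class = "gene_set_partition", alpha = alpha)
}

#' Classify genes across a two-interval time series
#'
#' Each gene significant in at least one interval is assigned to exactly one
#' class: `early` (significant in interval 1 only), `late` (interval 2 only),
#' `transient` (both, opposite signs) or `consistent` (both, same sign). The
#' sign suffix for `early`, `transient` and `consistent` is the interval-1
#' fold-change sign; for `late` it is the interval-2 sign.
#'
#' @param interval1,interval2 DE tables (`gene`, `log2FoldChange`, `padj`)
#'   for the first and second time-point comparisons.
#' @param alpha Adjusted p-value threshold; default 0.01.
#' @return Object of class `gene_set_partition` with elements
#'   `early_positive`, `early_negative`, `late_positive`, `late_negative`,
#'   `transient_positive`, `transient_negative`, `consistent_positive`,
#'   `consistent_negative`, plus unsigned unions `early`, `late`,
#'   `transient`, `consistent`. Genes present in only one table are excluded
#'   with a warning.
#' @export
classify_time_series <- function(interval1, interval2, alpha = 0.01) {
  common <- intersect(interval1$gene, interval2$gene)
  dropped <- length(union(interval1$gene, interval2$gene)) - length(common)
  if (dropped > 0)
    warning(dropped, " gene(s) present in only one interval excluded")
  t1 <- interval1[match(common, interval1$gene), , drop = FALSE]
  t2 <- interval2[match(common, interval2$gene), , drop = FALSE]
  s1 <- !is.na(t1$padj) & t1$padj <= alpha
  s2 <- !is.na(t2$padj) & t2$padj <= alpha
  sign1 <- sign(t1$log2FoldChange); sign2 <- sign(t2$log2FoldChange)
  cls <- function(sel, sgn, want) sort(common[sel & sgn == want])
  out <- list(
    early_positive = cls(s1 & !s2, sign1, 1),
    early_negative = cls(s1 & !s2, sign1, -1),
    late_positive = cls(!s1 & s2, sign2, 1),
    late_negative = cls(!s1 & s2, sign2, -1),
    transient_positive = cls(s1 & s2 & sign1 != sign2, sign1, 1),
    transient_negative = cls(s1 & s2 & sign1 != sign2, sign1, -1),
    consistent_positive = cls(s1 & s2 & sign1 == sign2, sign1, 1),
    consistent_negative = cls(s1 & s2 & sign1 == sign2, sign1, -1))
  out$early <- sort(c(out$early_positive, out$early_negative))
  out$late <- sort(c(out$late_positive, out$late_negative))
  out$transient <- sort(c(out$transient_positive, out$transient_negative))
  out$consistent <- sort(c(out$consistent_positive, out$consistent_negative))
  structure(out, class = "gene_set_partition", alpha = alpha)
}

#' Hypergeometric annotation enrichment of a gene set
#'
#' For every term annotated to at least one universe gene in the (typically
#' ancestor-expanded) annotation set, computes the one-sided
#' over-representation p-value and adjusts across all tested terms with
#' Benjamini-Hochberg.
#'
#' @param genes Character vector, the gene set of interest (must be a subset
#'   of `universe`).
#' @param universe Character vector of universe gene ids; genes without any
#'   annotation are dropped from the universe with a warning.
#' @param ann An `annotation_set` (expanded for ancestor-aware enrichment).
#' @param alpha Significance threshold applied to adjusted p-values
#'   (default 0.01).
#' @return Object of class `enrichment_result`: data.frame with columns
#'   `term`, `k`, `K`, `n`, `N`, `pvalue`, `padj`, `significant`, sorted by
#'   `padj` then term; attributes `alpha`, `n_genes`, `n_universe`.
#' @export
enrich <- function(genes, universe, ann, alpha = 0.01) {
  if (!length(genes)) stop("empty gene set")
  if (!all(genes %in% universe)) stop("gene set is not a subset of the universe")
  annotated <- intersect(universe, names(ann)[lengths(ann) > 0])
  if (length(annotated) < length(universe))
    warning(length(universe) - length(annotated),
            " universe gene(s) without annotation dropped")
  genes <- intersect(genes, annotated)
  if (!length(genes)) stop("no annotated genes left in the gene set")
  N <- length(annotated); n <- length(genes)
  term_genes <- split(rep(annotated, lengths(ann[annotated])),
                      unlist(ann[annotated], use.names = FALSE))
  terms <- sort(names(term_genes))
  K <- vapply(term_genes[terms], length, 0L)
  k <- vapply(term_genes[terms], function(g) sum(g %in% genes), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  padj <- bh_adjust(p)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                    pvalue = p, padj = padj, significant = padj <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$padj, out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            alpha = alpha, n_genes = n, n_universe = N)
}

#' Paired comparison of two enrichment results
#'
#' Restricted to terms significant in the reference result (adjusted p <=
#' `alpha`): terms whose adjusted p-values are exactly equal in both results
#' are excluded as ties; `n_improved` counts terms whose alternate adjusted
#' p-value is strictly lower (terms untested in the alternate count as not
#' improved); the exact one-sided binomial test is applied to
#' `(n_improved, n_significant - n_ties)`. Unique significant terms on each
#' side are also reported.
#'
#' @param reference `enrichment_result` from the baseline policy (e.g.
#'   `no_hp`).
#' @param alternate `enrichment_result` from the corrected policy (e.g.
#'   `gocats`).
#' @param alpha Significance threshold on adjusted p-values; default 0.01.
#' @return Object of class `enrichment_comparison`: list with
#'   `n_significant_reference`, `n_ties`, `n_compared`, `n_improved`,
#'   `binomial_p`, `unique_reference`, `unique_alternate`.
#' @export
compare_enrichments <- function(reference, alternate, alpha = 0.01) {
  if (!length(intersect(reference$term, alternate$term)))
    warning("reference and alternate share no tested terms")
  ref_sig <- reference[reference$padj <= alpha, , drop = FALSE]
  alt_padj <- stats::setNames(alternate$padj, alternate$term)
  a <- alt_padj[ref_sig$term]            # NA when untested in alternate
  ties <- !is.na(a) & a == ref_sig$padj
  improved <- !is.na(a) & a < ref_sig$padj
  n_sig <- nrow(ref_sig); n_ties <- sum(ties)
  n_compared <- n_sig - n_ties; n_improved <- sum(improved)
  if (n_compared == 0)
    stop("undefined binomial test: all ", n_sig,
         " reference-significant terms are ties")
  structure(list(
    n_significant_reference = n_sig, n_ties = n_ties,
    n_compared = n_compared, n_improved = n_improved,
    binomial_p = binomial_improvement_test(n_improved, n_compared),
    unique_reference = sort(setdiff(reference$term[reference$padj <= alpha],
                                    alternate$term[alternate$padj <= alpha])),
    unique_alternate = sort(setdiff(alternate$term[alternate$padj <= alpha],
                                    reference$term[reference$padj <= alpha])),
    alpha = alpha), class = "enrichment_comparison")
}

#' @export
print.enrichment_comparison <- function(x, ...) {
  cat("<enrichment_comparison> alpha =", x$alpha, "\n")
  cat(sprintf("  reference-significant: %d (ties excluded: %d)\n",
              x$n_significant_reference, x$n_ties))
  cat(sprintf("  improved by alternate: %d / %d  (one-sided binomial p = %.3g)\n",
              x$n_improved, x$n_compared, x$binomial_p))
  cat(sprintf("  unique significant terms: reference %d, alternate %d\n",
              length(x$unique_reference), length(x$unique_alternate)))
  invisible(x)
}

#' Time-series enriched-term set algebra
#'
#' Given the six input term sets of a two-interval time-series analysis —
#' corrected-policy and traditional enrichments of each interval plus the
#' traditional transient and consistent enrichments — derives
#' `early_unique = interval1_gocats - interval1_no_hp - transient_no_hp`,
#' `late_unique = interval2_gocats - interval2_no_hp - transient_no_hp`, and
#' the supported subsets `early_supported = early_unique ∩ consistent_no_hp`
#' and `late_supported = late_unique ∩ consistent_no_hp`. Because the
#' definition of the supported sets can also be read with the full
#' corrected-policy interval set as the left operand, that variant is
#' returned as `*_supported_full`.
#'
#' @param interval1_gocats,interval1_no_hp Character vectors: significantly
#'   enriched terms in the first interval under each policy.
#' @param interval2_gocats,interval2_no_hp Same for the second interval.
#' @param transient_no_hp,consistent_no_hp Enriched terms of the transient
#'   and consistent gene sets under the traditional policy.
#' @return List of sorted character vectors: `early_unique`,
#'   `early_supported`, `early_supported_full`, `late_unique`,
#'   `late_supported`, `late_supported_full`.
#' @export
time_series_term_sets <- function(interval1_gocats, interval1_no_hp,
                                  interval2_gocats, interval2_no_hp,
                                  transient_no_hp, consistent_no_hp) {
  early_unique <- sort(setdiff(setdiff(interval1_gocats, interval1_no_hp),
                               transient_no_hp))
  late_unique <- sort(setdiff(setdiff(interval2_gocats, interval2_no_hp),
                              transient_no_hp))
  list(early_unique = early_unique,
       early_supported = sort(intersect(early_unique, consistent_no_hp)),
       early_supported_full = sort(intersect(interval1_gocats, consistent_no_hp)),
       late_unique = late_unique,
       late_supported = sort(intersect(late_unique, consistent_no_hp)),
       late_supported_full = sort(intersect(interval2_gocats, consistent_no_hp)))
}
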