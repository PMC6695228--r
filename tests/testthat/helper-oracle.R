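# Independent brute-force oracles. These never call the package's traversal
# or statistics code paths: reachability is a plain while-loop BFS over edge
# tables, the BH step-up and the combinatorial tails are written out from
# their definitions.

# child -> parent pairs under a scoping relation set, with has_part
# optionally flipped (part_of_some reading)
oracle_parent_pairs <- function(edges, relations = c("is_a", "part_of", "has_part"),
                                reinterpret_has_part = TRUE) {
  e <- edges[edges$relation %in% relations, , drop = FALSE]
  flip <- reinterpret_has_part & e$relation == "has_part"
  data.frame(child = ifelse(flip, e$object, e$subject),
             parent = ifelse(flip, e$subject, e$object),
             stringsAsFactors = FALSE)
}

# all nodes reachable from `start` over child->parent pairs (visited-set BFS)
oracle_reach <- function(pairs, start) {
  seen <- character(0)
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(pairs$parent[pairs$child %in% frontier])
    nxt <- setdiff(nxt, c(seen, start))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

oracle_ancestors <- function(edges, term, relations = c("is_a", "part_of", "has_part"),
                             reinterpret_has_part = TRUE) {
  oracle_reach(oracle_parent_pairs(edges, relations, reinterpret_has_part), term)
}

oracle_descendants <- function(edges, term, relations = c("is_a", "part_of", "has_part"),
                               reinterpret_has_part = TRUE) {
  p <- oracle_parent_pairs(edges, relations, reinterpret_has_part)
  oracle_reach(data.frame(child = p$parent, parent = p$child,
                          stringsAsFactors = FALSE), term)
}

# ordered (descendant, ancestor) "d\ta" keys of all true mappings
oracle_true_pair_keys <- function(edges, ids,
                                  relations = c("is_a", "part_of", "has_part"),
                                  reinterpret_has_part = TRUE) {
  keys <- character(0)
  for (t in ids) {
    anc <- oracle_ancestors(edges, t, relations, reinterpret_has_part)
    anc <- setdiff(anc, t)
    if (length(anc)) keys <- c(keys, paste(t, anc, sep = "\t"))
  }
  sort(unique(keys))
}

# naive mapper: follow every stored edge subject->object regardless of label
oracle_naive_pair_keys <- function(edges, ids) {
  pairs <- data.frame(child = edges$subject, parent = edges$object,
                      stringsAsFactors = FALSE)
  keys <- character(0)
  for (t in ids) {
    reach <- setdiff(oracle_reach(pairs, t), t)
    if (length(reach)) keys <- c(keys, paste(t, reach, sep = "\t"))
  }
  sort(unique(keys))
}

# per-edge problem sets and false pairs, straight from the set definitions
oracle_edge_false_keys <- function(edges, ids, whole, part) {
  anc <- function(t) oracle_ancestors(edges, t)
  desc <- function(t) oracle_descendants(edges, t)
  PA <- setdiff(union(anc(part), part), union(anc(whole), whole))
  PD <- setdiff(union(desc(whole), whole), union(desc(part), part))
  if (!length(PA) || !length(PD)) return(character(0))
  g <- expand.grid(d = PD, a = PA, stringsAsFactors = FALSE)
  g <- g[g$d != g$a, , drop = FALSE]
  sort(unique(paste(g$d, g$a, sep = "\t")))
}

oracle_epMF_keys <- function(edges, ids) {
  hp <- edges[edges$relation == "has_part", , drop = FALSE]
  keys <- character(0)
  for (i in seq_len(nrow(hp)))
    keys <- c(keys, oracle_edge_false_keys(edges, ids, hp$subject[i], hp$object[i]))
  sort(unique(keys))
}

# BH step-up written out from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# exact combinatorial tails (small n only)
oracle_binom_tail <- function(k, n) sum(choose(n, k:n)) / 2^n
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
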