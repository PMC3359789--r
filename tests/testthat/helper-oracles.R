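# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: connectivity via igraph, tail probabilities via
# direct choose() summation, Holm via the literal step-down formula,
# isomorphism grouping via brute-force label permutation.

# weak connectivity of a labeled edge set, via igraph
oracle_connected <- function(vertices, edge_mat) {
  if (nrow(edge_mat) == 0L) return(length(vertices) <= 1L)
  g <- igraph::graph_from_data_frame(
    as.data.frame(edge_mat, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = vertices))
  igraph::is_connected(g, mode = "weak")
}

# brute-force enumeration of connected induced subnetworks of one network:
# for every vertex subset, read off the induced edges from the adjacency
# matrix and test connectivity with igraph
oracle_enumerate <- function(network, size) {
  lab <- network$labels
  a <- network$adjacency
  keys <- character(0)
  for (subset in utils::combn(lab, size, simplify = FALSE)) {
    e <- which(a[subset, subset, drop = FALSE] == 1L, arr.ind = TRUE)
    if (!nrow(e)) next
    em <- cbind(subset[e[, 1L]], subset[e[, 2L]])
    if (!oracle_connected(subset, em)) next
    es <- paste0(em[, 1L], ">", em[, 2L])
    o <- order(em[, 1L], em[, 2L], method = "radix")
    keys <- c(keys, paste(es[o], collapse = ";"))
  }
  sort(keys, method = "radix")
}

# P(X >= count) for X ~ Binomial(n, p), by direct summation
oracle_binom_tail <- function(count, n, p) {
  if (count <= 0) return(1)
  i <- count:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# literal Holm step-down adjustment with family size m
oracle_holm <- function(p, m) {
  o <- order(p)
  adj <- numeric(length(p))
  running <- 0
  for (k in seq_along(p)) {
    running <- max(running, min(1, (m - k + 1) * p[o[k]]))
    adj[o[k]] <- running
  }
  adj
}

# canonical form of a key under vertex relabeling: the lexicographically
# smallest serialization over all permutations of its label set onto
# placeholder labels; equal canonical forms <=> isomorphic patterns
oracle_iso_class <- function(key_string) {
  e <- do.call(rbind, strsplit(strsplit(key_string, ";", fixed = TRUE)[[1L]],
                               ">", fixed = TRUE))
  verts <- sort(unique(c(e)))
  k <- length(verts)
  placeholders <- paste0("x", seq_len(k))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL
  for (p in perms(seq_len(k))) {
    map <- stats::setNames(placeholders[p], verts)
    es <- paste0(map[e[, 1L]], ">", map[e[, 2L]])
    s <- paste(sort(es), collapse = ";")
    if (is.null(best) || s < best) best <- s
  }
  best
}

# product-measure probability of an exact edge pattern on a fixed label set:
# every listed edge present (prob q), every other ordered pair absent
oracle_pattern_prob <- function(key_string, labels, q) {
  e <- strsplit(strsplit(key_string, ";", fixed = TRUE)[[1L]], ">",
                fixed = TRUE)
  present <- vapply(e, paste, character(1), collapse = ">")
  all_pairs <- c(outer(labels, labels,
                       function(a, b) ifelse(a == b, NA, paste0(a, ">", b))))
  all_pairs <- all_pairs[!is.na(all_pairs)]
  prod(ifelse(all_pairs %in% present, q, 1 - q))
}
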