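#' Edges induced by a vertex subset
#'
#' Induced-subgraph semantics: the result contains exactly those edges of the
#' network whose tail and head both lie in the subset — absent edges among the
#' subset stay absent, which is what the null model's occurrence probability
#' assumes.
#'
#' @param network a [labeled_digraph()].
#' @param vertex_subset character vector of labels, a subset of the network's
#'   labels.
#' @return character matrix of induced edges (columns `tail`, `head`),
#'   canonically ordered; zero rows if the subset spans no edges.
#' @export
induced_edges <- function(network, vertex_subset) {
  stopifnot(inherits(network, "labeled_digraph"))
  vertex_subset <- unique(as.character(vertex_subset))
  if (!all(vertex_subset %in% network$labels))
    stop("vertex subset is not contained in the network's label set (label error)",
         call. = FALSE)
  idx <- match(sort(vertex_subset, method = "radix"), network$labels)
  sub <- network$adjacency[idx, idx, drop = FALSE]
  w <- which(sub == 1L, arr.ind = TRUE)
  lab <- network$labels[idx]
  e <- cbind(tail = lab[w[, 1L]], head = lab[w[, 2L]])
  e[order(e[, 1L], e[, 2L], method = "radix"), , drop = FALSE]
}

#' Enumerate the connected induced subnetworks of one network
#'
#' Examines every combination of `size` vertices of the network and emits the
#' canonical key of each vertex subset whose induced edge set is weakly
#' connected. Distinct subsets of one network yield distinct keys (a connected
#' induced subnetwork determines its vertex set), so the result has no
#' duplicates.
#'
#' @param network a [labeled_digraph()].
#' @param size the subnetwork order `nu_S`, between 2 and the number of
#'   vertices.
#' @return character vector of canonical key strings, sorted; possibly empty.
#' @examples
#' g <- digraph_from_edges(c("F3>Fz"), labels = ecn_labels())
#' enumerate_connected_subnetworks(g, 2)  # "F3>Fz"
#' @export
enumerate_connected_subnetworks <- function(network, size) {
  stopifnot(inherits(network, "labeled_digraph"))
  nu <- length(network$labels)
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 2L || size > nu)
    stop("subnetwork size must be between 2 and the number of vertices (parameter error)",
         call. = FALSE)
  a <- network$adjacency
  lab <- network$labels
  subsets <- utils::combn(nu, size)
  keys <- character(0)
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    sub <- a[idx, idx, drop = FALSE]
    if (sum(sub) == 0L) next
    if (!.connected_sym((sub + t(sub)) > 0L)) next
    w <- which(sub == 1L)
    r <- ((w - 1L) %% size) + 1L
    cc <- ((w - 1L) %/% size) + 1L
    tails <- lab[idx[r]]
    heads <- lab[idx[cc]]
    o <- order(tails, heads, method = "radix")
    keys[[length(keys) + 1L]] <-
      paste(paste0(tails[o], ">", heads[o]), collapse = ";")
  }
  sort(keys, method = "radix")
}

#' Count each connected induced subnetwork across a sample
#'
#' For every sample member, all connected induced subnetworks of order `size`
#' are enumerated; the census maps each distinct labeled subnetwork (by
#' canonical key) to the number of sample members that contain it. Each
#' subnetwork can occur at most once per member — identity is by labeled edge
#' set — so every count lies in `1..n`. Keys occurring in no member are not
#' stored.
#'
#' @param sample a [network_sample()].
#' @param size subnetwork order `nu_S`.
#' @return an object of class `subnetwork_census`: list with `counts` (named
#'   integer vector, names are canonical keys in sorted order), `size` and
#'   `n`.
#' @export
subnetwork_census <- function(sample, size) {
  stopifnot(inherits(sample, "network_sample"))
  per <- lapply(sample$networks, enumerate_connected_subnetworks, size = size)
  all_keys <- unlist(per, use.names = FALSE)
  if (length(all_keys)) {
    tab <- table(all_keys)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts <- counts[order(names(counts), method = "radix")]
  } else {
    counts <- integer(0)
  }
  structure(list(size = as.integer(size), counts = counts, n = sample$n),
            class = "subnetwork_census")
}

#' @export
print.subnetwork_census <- function(x, ...) {
  cat(sprintf("subnetwork census: %d distinct connected %d-subnetworks over n = %d networks\n",
              length(x$counts), x$size, x$n))
  invisible(x)
}

#' Number of weakly connected digraphs on k labeled vertices
#'
#' Computed by the standard inclusion-exclusion recurrence over the component
#' containing the first vertex: with `D(m) = 2^(m(m-1))` the number of all
#' digraphs on `m` labeled vertices,
#' `W(m) = D(m) - sum_{j=1}^{m-1} C(m-1, j-1) W(j) D(m-j)`.
#' `W(1) = 1`, `W(2) = 3`, `W(3) = 54`.
#'
#' @param k number of labeled vertices, `k >= 1`.
#' @return a number (double; grows super-exponentially).
#' @export
count_weak_digraphs <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a positive integer (parameter error)", call. = FALSE)
  d <- function(m) 2^(m * (m - 1))
  w <- numeric(k)
  w[1L] <- 1
  for (m in seq_len(k)[-1L]) {
    tot <- d(m)
    for (j in seq_len(m - 1L))
      tot <- tot - choose(m - 1L, j - 1L) * w[j] * d(m - j)
    w[m] <- tot
  }
  w[k]
}

#' Size of the multiple-testing family
#'
#' The number of distinct weakly connected labeled subnetworks of order
#' `size` on `num_labels` vertex labels:
#' `C(num_labels, size) * W(size)`, where `W` is [count_weak_digraphs()].
#' This is the family over which the Holm correction is applied in the
#' default ("all-possible") mode — every connected labeled pattern of the
#' given order is a hypothesis, whether observed in the sample or not.
#'
#' @param num_labels total number of vertex labels `nu`.
#' @param size subnetwork order `nu_S`, between 2 and `num_labels`.
#' @return a number.
#' @examples
#' family_size(9, 2)  # 108
#' family_size(9, 3)  # 4536
#' @export
family_size <- function(num_labels, size) {
  num_labels <- as.integer(num_labels)
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 2L || size > num_labels)
    stop("size must be between 2 and num_labels (parameter error)",
         call. = FALSE)
  choose(num_labels, size) * count_weak_digraphs(size)
}

#' Exhaustively generate all connected labeled patterns on a label set
#'
#' Enumerates every subset of the `k(k-1)` possible directed edges on the
#' given labels and keeps those that are weakly connected and span all the
#' labels. For 3 labels this yields the 54 connected labeled 3-subnetworks.
#' Exhaustive generation is supported for 2 to 4 labels (at most 4096 edge
#' patterns); use [count_weak_digraphs()] to count larger orders.
#'
#' @param labels character vector of 2 to 4 distinct labels.
#' @return character vector of canonical key strings, sorted.
#' @examples
#' length(all_connected_keys(c("a", "b", "c")))  # 54
#' @export
all_connected_keys <- function(labels) {
  labels <- sort(as.character(labels), method = "radix")
  .check_labels(labels)
  k <- length(labels)
  if (k < 2L || k > 4L)
    stop("exhaustive generation supports 2 to 4 labels (parameter error)",
         call. = FALSE)
  # all ordered pairs, already in canonical (tail, head) order
  tails <- rep(labels, each = k)
  heads <- rep(labels, times = k)
  keep <- tails != heads
  tails <- tails[keep]
  heads <- heads[keep]
  m <- k * (k - 1L)
  out <- character(0)
  for (code in seq_len(2^m) - 1L) {
    sel <- bitwAnd(code, bitwShiftL(1L, seq_len(m) - 1L)) > 0L
    if (!any(sel)) next
    vs <- unique(c(tails[sel], heads[sel]))
    if (length(vs) < k) next
    e <- cbind(tails[sel], heads[sel])
    if (!is_weakly_connected(labels, e)) next
    out[[length(out) + 1L]] <- paste(paste0(e[, 1L], ">", e[, 2L]),
                                     collapse = ";")
  }
  sort(out, method = "radix")
}
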