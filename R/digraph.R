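#' Construct a vertex-labeled directed graph
#'
#' A `labeled_digraph` is one member of a network sample: a simple directed
#' graph (no loops, no multi-edges) on a set of pairwise-distinct vertex
#' labels. Vertex identity is by label string; internally labels are kept in
#' sorted order so that graphs built from differently ordered inputs compare
#' equal. A mutual connection `u <-> v` is encoded as the two directed edges
#' `(u, v)` and `(v, u)`; the adjacency matrix is therefore binary with a zero
#' diagonal but is not required to be asymmetric.
#'
#' @param adjacency square binary matrix; entry `[i, j] == 1` means a directed
#'   edge from the i-th label (tail) to the j-th label (head). Row = tail,
#'   column = head.
#' @param labels character vector of distinct vertex labels, one per matrix
#'   row. Defaults to `rownames(adjacency)`. Labels may not contain the key
#'   separator characters `">"` or `";"`, commas, or whitespace.
#' @return an object of class `labeled_digraph` with components `labels`
#'   (sorted), `adjacency` (integer matrix in sorted label order, with
#'   dimnames) and `n_edges`.
#' @seealso [digraph_from_edges()], [digraph_edges()], [network_sample()]
#' @examples
#' a <- matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' a["a", "b"] <- a["b", "a"] <- 1L
#' g <- labeled_digraph(a)
#' g$n_edges  # 2: the mutual pair counts as two directed edges
#' @export
labeled_digraph <- function(adjacency, labels = rownames(adjacency)) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix (shape error)", call. = FALSE)
  if (is.null(labels))
    stop("vertex labels are required (pass `labels` or set rownames)",
         call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(adjacency))
    stop("number of labels does not match matrix dimension (shape error)",
         call. = FALSE)
  .check_labels(labels)
  if (anyNA(adjacency) || !all(adjacency == 0L | adjacency == 1L))
    stop("adjacency entries must all be 0 or 1 (value error)", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("self-loops are not allowed: nonzero diagonal entry (loop error)",
         call. = FALSE)
  ord <- order(labels, method = "radix")
  labels <- labels[ord]
  a <- adjacency[ord, ord, drop = FALSE]
  storage.mode(a) <- "integer"
  dimnames(a) <- list(labels, labels)
  structure(list(labels = labels, adjacency = a, n_edges = sum(a)),
            class = "labeled_digraph")
}

#' Build a labeled digraph from a directed edge list
#'
#' @param edges directed edges: a two-column matrix or data frame
#'   (tail, head), a character vector of `"tail>head"` strings, or `NULL` /
#'   empty for an edgeless graph.
#' @param labels the full vertex label set (required, so that isolated
#'   vertices are representable).
#' @return a [labeled_digraph()].
#' @examples
#' digraph_from_edges(c("F3>Fz", "Fz>F3"), labels = ecn_labels())
#' @export
digraph_from_edges <- function(edges, labels) {
  labels <- as.character(labels)
  .check_labels(labels)
  e <- .as_edge_matrix(edges)
  nu <- length(labels)
  a <- matrix(0L, nu, nu, dimnames = list(sort(labels, method = "radix"),
                                          sort(labels, method = "radix")))
  if (nrow(e)) {
    unknown <- setdiff(c(e), labels)
    if (length(unknown))
      stop("edge endpoint(s) not in the label set (label error): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(e[, 1L] == e[, 2L]))
      stop("self-loops are not allowed (loop error)", call. = FALSE)
    if (anyDuplicated(paste(e[, 1L], e[, 2L])))
      stop("duplicate directed edge: multi-edges are not allowed (multi-edge error)",
           call. = FALSE)
    a[cbind(e[, 1L], e[, 2L])] <- 1L
  }
  labeled_digraph(a)
}

#' Extract the directed edge list of a labeled digraph
#'
#' @param network a [labeled_digraph()].
#' @return a character matrix with columns `tail` and `head`, rows in
#'   canonical (tail, head) order; zero rows for an edgeless graph.
#' @export
digraph_edges <- function(network) {
  stopifnot(inherits(network, "labeled_digraph"))
  w <- which(network$adjacency == 1L, arr.ind = TRUE)
  e <- cbind(tail = network$labels[w[, 1L]], head = network$labels[w[, 2L]])
  e[order(e[, 1L], e[, 2L], method = "radix"), , drop = FALSE]
}

#' @export
print.labeled_digraph <- function(x, ...) {
  cat(sprintf("labeled digraph: %d vertices, %d directed edges\n",
              length(x$labels), x$n_edges))
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a sample of labeled directed networks
#'
#' All members must share one identical vertex-label set; the order in which
#' labels were supplied per member is irrelevant (each member is normalized to
#' sorted label order on construction).
#'
#' @param networks a list of [labeled_digraph()] objects, length >= 1.
#' @return an object of class `network_sample` with components `networks`,
#'   `labels` (the shared sorted label set) and `n`.
#' @export
network_sample <- function(networks) {
  if (!is.list(networks) || length(networks) < 1L)
    stop("a sample needs at least one network (sample error)", call. = FALSE)
  ok <- vapply(networks, inherits, logical(1), what = "labeled_digraph")
  if (!all(ok))
    stop("all sample members must be labeled_digraph objects", call. = FALSE)
  labels <- networks[[1L]]$labels
  for (i in seq_along(networks)) {
    if (!identical(networks[[i]]$labels, labels))
      stop(sprintf("network %d has a different vertex-label set (label error)", i),
           call. = FALSE)
  }
  structure(list(networks = networks, labels = labels, n = length(networks)),
            class = "network_sample")
}

#' @export
print.network_sample <- function(x, ...) {
  k <- vapply(x$networks, function(g) g$n_edges, numeric(1))
  cat(sprintf("network sample: n = %d networks on %d shared labels\n",
              x$n, length(x$labels)))
  cat(sprintf("  edge counts: mean %.2f of %d possible (range %d-%d)\n",
              mean(k), length(x$labels) * (length(x$labels) - 1L),
              min(k), max(k)))
  invisible(x)
}

# labels must be nonempty, distinct, and free of the characters used by the
# canonical key serialization and the CSV/edge-list formats
.check_labels <- function(labels) {
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("labels must be nonempty strings (label error)", call. = FALSE)
  if (anyDuplicated(labels))
    stop("vertex labels must be pairwise distinct (label error)", call. = FALSE)
  if (any(grepl("[>;,[:space:]]", labels)))
    stop("labels may not contain '>', ';', ',' or whitespace (label error)",
         call. = FALSE)
  invisible(labels)
}

# normalize edge input to a 2-column character matrix (tail, head)
.as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.character(edges) && length(edges) == 0L))
    return(matrix(character(0), 0L, 2L,
                  dimnames = list(NULL, c("tail", "head"))))
  if (inherits(edges, "subnetwork_key")) return(edges$edges)
  if (is.data.frame(edges) || is.matrix(edges)) {
    if (ncol(edges) != 2L)
      stop("edge table must have two columns (tail, head)", call. = FALSE)
    m <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  } else if (is.character(edges)) {
    # allow one "a>b;c>d" string or a vector of "a>b" strings
    parts <- unlist(strsplit(edges, ";", fixed = TRUE), use.names = FALSE)
    sp <- strsplit(parts, ">", fixed = TRUE)
    if (any(lengths(sp) != 2L))
      stop("edge strings must have the form \"tail>head\"", call. = FALSE)
    m <- do.call(rbind, sp)
  } else {
    stop("unsupported edge representation", call. = FALSE)
  }
  dimnames(m) <- list(NULL, c("tail", "head"))
  m
}
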