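#' Canonical key for a labeled subnetwork
#'
#' Because all vertices carry pairwise-distinct labels, two subnetworks are
#' identical exactly when they have the same set of directed labeled edges.
#' A `subnetwork_key` is the canonical representation of such an edge set:
#' edges sorted by (tail, head) and serialized as `"tail>head"` joined by
#' `";"`, e.g. `"C3>Cz;Cz>C3"`. The same edge set supplied in any order yields
#' the same key. Only weakly connected edge sets are admissible: every vertex
#' of the subnetwork must be reachable from every other when edge directions
#' are ignored (a candidate motif is a *connected* pattern).
#'
#' @param edges directed edges in any form accepted by
#'   [digraph_from_edges()]: a two-column (tail, head) matrix or data frame,
#'   a character vector of `"tail>head"` strings, or a single serialized key
#'   string.
#' @return an object of class `subnetwork_key` with components `key` (the
#'   canonical string), `edges` (canonical 2-column matrix), `vertices`
#'   (sorted endpoint set), `size` (number of vertices), `eta` (number of
#'   edges) and `eta_max` (`size * (size - 1)`, the maximum possible number
#'   of directed edges on that many vertices).
#' @examples
#' k <- subnetwork_key(c("Fz>F4", "F4>Fz"))
#' k$key      # "F4>Fz;Fz>F4"
#' k$eta_max  # 2
#' @export
subnetwork_key <- function(edges) {
  e <- .as_edge_matrix(edges)
  if (nrow(e) == 0L)
    stop("a subnetwork key needs at least one edge (key error)", call. = FALSE)
  if (any(e[, 1L] == e[, 2L]))
    stop("self-loops are not allowed (loop error)", call. = FALSE)
  e <- unique(e)
  verts <- sort(unique(c(e)), method = "radix")
  .check_labels(verts)
  if (!is_weakly_connected(verts, e))
    stop("edge set is not weakly connected (key error)", call. = FALSE)
  e <- e[order(e[, 1L], e[, 2L], method = "radix"), , drop = FALSE]
  size <- length(verts)
  structure(list(key = paste(paste0(e[, 1L], ">", e[, 2L]), collapse = ";"),
                 edges = e, vertices = verts, size = size,
                 eta = nrow(e), eta_max = size * (size - 1L)),
            class = "subnetwork_key")
}

#' Parse a serialized subnetwork key
#'
#' Inverse of the serialization in [subnetwork_key()]: `"C3>Cz;Cz>C3"` is
#' split on `";"` into `"tail>head"` edges. Serializing the result again
#' reproduces the canonical string.
#'
#' @param key_string a key string such as `"F3>Fz;Fz>F3"`.
#' @return a [subnetwork_key()].
#' @export
parse_subnetwork_key <- function(key_string) {
  stopifnot(is.character(key_string), length(key_string) == 1L)
  subnetwork_key(key_string)
}

#' @export
print.subnetwork_key <- function(x, ...) {
  cat(sprintf("subnetwork key: %s  (%d vertices, %d of %d possible edges)\n",
              x$key, x$size, x$eta, x$eta_max))
  invisible(x)
}

#' @export
format.subnetwork_key <- function(x, ...) x$key

#' Test weak connectivity of a labeled edge set
#'
#' A vertex set with directed edges is weakly connected when the underlying
#' undirected graph is connected, i.e. every vertex is reachable from every
#' other when edge directions are ignored. Vertices of the set without any
#' incident edge make the set disconnected.
#'
#' @param vertices character vector of vertex labels (the subset under test).
#' @param edges directed edges with endpoints drawn from `vertices`, in any
#'   form accepted by [subnetwork_key()]; may be empty.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_weakly_connected(c("a", "b", "c"), c("a>b", "b>c"))  # TRUE
#' is_weakly_connected(c("a", "b", "c"), "a>b")            # FALSE: c isolated
#' @export
is_weakly_connected <- function(vertices, edges) {
  v <- unique(as.character(vertices))
  k <- length(v)
  e <- .as_edge_matrix(edges)
  if (nrow(e) && !all(c(e) %in% v))
    stop("edge endpoints must lie within the vertex set (label error)",
         call. = FALSE)
  if (k <= 1L) return(k == 1L)
  if (nrow(e) == 0L) return(FALSE)
  ti <- match(e[, 1L], v)
  hi <- match(e[, 2L], v)
  reach <- logical(k)
  reach[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- unique(c(hi[ti %in% frontier], ti[hi %in% frontier]))
    nb <- nb[!reach[nb]]
    reach[nb] <- TRUE
    frontier <- nb
  }
  all(reach)
}

# fast connectivity check used in the enumeration inner loop:
# u is a small logical matrix, the undirected (symmetrized) adjacency of an
# induced subnetwork; BFS from vertex 1
.connected_sym <- function(u) {
  k <- nrow(u)
  reach <- logical(k)
  reach[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which((colSums(u[frontier, , drop = FALSE]) > 0L) & !reach)
    reach[nb] <- TRUE
    frontier <- nb
  }
  all(reach)
}
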