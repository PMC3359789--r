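#' Read a directed network from a plain-text edge list
#'
#' One directed edge per line, `tail head`, whitespace-separated. Lines
#' starting with `#` are comments, except a header of the form
#' `#labels: F3,Fz,F4,...` which declares the full vertex-label set (needed
#' so that isolated vertices are representable). The label set may instead be
#' passed via `labels`; an explicit argument overrides the header.
#'
#' @param path file path.
#' @param labels optional character vector declaring the label set.
#' @return a [labeled_digraph()].
#' @export
read_edgelist <- function(path, labels = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#[[:space:]]*labels:", lines, value = TRUE)
  if (is.null(labels)) {
    if (!length(hdr))
      stop("no label declaration: add a '#labels: ...' header or pass `labels` (format error)",
           call. = FALSE)
    labels <- trimws(strsplit(sub("^#[[:space:]]*labels:", "", hdr[1L]),
                              ",", fixed = TRUE)[[1L]])
  }
  body <- trimws(lines[!grepl("^#", lines)])
  body <- body[nzchar(body)]
  if (!length(body)) return(digraph_from_edges(NULL, labels))
  parts <- strsplit(body, "[[:space:]]+")
  if (any(lengths(parts) != 2L))
    stop("each edge line must contain exactly 'tail head' (format error)",
         call. = FALSE)
  digraph_from_edges(do.call(rbind, parts), labels)
}

#' Write a directed network as a plain-text edge list
#'
#' @param network a [labeled_digraph()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "labeled_digraph"))
  e <- digraph_edges(network)
  writeLines(c(paste0("#labels: ", paste(network$labels, collapse = ",")),
               if (nrow(e)) paste(e[, 1L], e[, 2L])),
             path)
  invisible(path)
}

#' Read a directed network from a labeled adjacency-matrix CSV
#'
#' The CSV must have the vertex labels as header row and as first column,
#' with binary entries. Orientation is row = tail, column = head: entry
#' `[u, v] == 1` means the directed edge `u -> v`. Transposing the matrix
#' silently reverses every edge, so files written by other tools should be
#' checked against this convention.
#'
#' @param path file path.
#' @return a [labeled_digraph()].
#' @export
read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  rl <- rownames(df)
  cl <- colnames(df)
  if (length(rl) != length(cl) || !setequal(rl, cl) || anyDuplicated(cl))
    stop("row labels and column labels must be the same set (format error)",
         call. = FALSE)
  m <- as.matrix(df)[, rl, drop = FALSE]
  labeled_digraph(m, labels = rl)
}

#' Write a directed network as a labeled adjacency-matrix CSV
#'
#' Row = tail, column = head (see [read_adjacency_csv()]).
#'
#' @param network a [labeled_digraph()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(network, path) {
  stopifnot(inherits(network, "labeled_digraph"))
  utils::write.csv(as.data.frame(network$adjacency), path)
  invisible(path)
}

#' Read a sample of networks from files
#'
#' Reads every file of a directory (or an explicit vector of paths) as one
#' sample member and validates, before returning, that all members share one
#' identical vertex-label set.
#'
#' @param input a directory (all regular files in it, sorted by name) or a
#'   character vector of file paths.
#' @param format `"edgelist"` (see [read_edgelist()]) or `"adjacency"` (see
#'   [read_adjacency_csv()]).
#' @param labels optional shared label set passed to the edge-list reader.
#' @return a [network_sample()].
#' @export
read_network_sample <- function(input, format = c("edgelist", "adjacency"),
                                labels = NULL) {
  format <- match.arg(format)
  paths <- input
  if (length(input) == 1L && dir.exists(input))
    paths <- sort(list.files(input, full.names = TRUE))
  if (!length(paths))
    stop("no input files found (I/O error)", call. = FALSE)
  nets <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    nets[[i]] <- switch(format,
                        edgelist = read_edgelist(paths[i], labels = labels),
                        adjacency = read_adjacency_csv(paths[i]))
    if (i > 1L && !identical(nets[[i]]$labels, nets[[1L]]$labels))
      stop(sprintf("label set of '%s' differs from '%s' (label error)",
                   paths[i], paths[1L]), call. = FALSE)
  }
  network_sample(nets)
}

# 6 significant digits, "g" format: round-trips through as.numeric, never
# flushes a small p-value to 0
.fmt_num <- function(x) formatC(x, digits = 6L, format = "g")

#' Write a motif table as tab-separated text
#'
#' Columns: `subnetwork`, `size`, `eta`, `count`, `mean_count`, `p_null`,
#' `p_value`, `p_holm`, `is_motif`; rows sorted by ascending p-value then
#' canonical key. Header comment lines record the sample dimensions, the
#' fitted density, the test configuration and the package version. Floating
#' point values are printed at 6 significant digits; tiny p-values appear in
#' scientific notation, never as a bare 0. Writing, re-reading with
#' [read_motif_table()] and re-writing is byte-identical.
#'
#' @param fit a [motif_detect()] fit (or a table re-read by
#'   [read_motif_table()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(fit, path) {
  stopifnot(inherits(fit, "motif_fit"))
  tab <- fit$table
  hdr <- c("# labmotif motif table",
           paste0("# version: ", as.character(utils::packageVersion("labmotif"))),
           paste0("# n: ", fit$n),
           paste0("# nu: ", fit$num_labels),
           paste0("# q: ", .fmt_num(fit$q)),
           paste0("# size: ", fit$size),
           paste0("# alpha: ", .fmt_num(fit$alpha)),
           paste0("# family_mode: ", fit$family_mode),
           paste0("# m: ", format(fit$m, scientific = FALSE)))
  cols <- c("subnetwork", "size", "eta", "count", "mean_count",
            "p_null", "p_value", "p_holm", "is_motif")
  rows <- character(0)
  if (nrow(tab)) {
    rows <- paste(tab$subnetwork, tab$size, tab$eta, tab$count,
                  .fmt_num(tab$mean_count), .fmt_num(tab$p_null),
                  .fmt_num(tab$p_value), .fmt_num(tab$p_holm),
                  tab$is_motif, sep = "\t")
  }
  con <- file(path, open = "wb")  # binary mode: LF line endings on any OS
  on.exit(close(con))
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), con)
  invisible(path)
}

#' Read a motif table written by [write_motif_table()]
#'
#' @param path file path.
#' @return an object of class `motif_fit` reconstructed from the file
#'   (without the original sample's label set).
#' @export
read_motif_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(field) {
    ln <- grep(paste0("^# ", field, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^# ", field, ":"), "", ln[1L]))
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    tab <- data.frame(subnetwork = character(0), size = integer(0),
                      eta = integer(0), count = integer(0),
                      mean_count = numeric(0), p_null = numeric(0),
                      p_value = numeric(0), p_holm = numeric(0),
                      is_motif = logical(0), stringsAsFactors = FALSE)
  } else {
    tab$subnetwork <- as.character(tab$subnetwork)
    tab$is_motif <- as.logical(tab$is_motif)
  }
  structure(list(table = tab,
                 q = as.numeric(meta("q")),
                 n = as.integer(meta("n")),
                 num_labels = as.integer(meta("nu")),
                 labels = NULL,
                 size = as.integer(meta("size")),
                 alpha = as.numeric(meta("alpha")),
                 family_mode = meta("family_mode"),
                 m = as.numeric(meta("m")),
                 call = NULL),
            class = "motif_fit")
}
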