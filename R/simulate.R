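#' The nine-electrode label set
#'
#' The standard vertex labels of the effective connectivity networks this
#' package was dimensioned for: frontal, central and parietal electrodes of
#' a 9-channel EEG montage.
#'
#' @return character vector of 9 labels.
#' @export
ecn_labels <- function() c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4")

# deterministic per-network substream seed derived from one root seed, so a
# sample can grow without reshuffling earlier members' draws; Lehmer-style
# mixing keeps the result a valid 32-bit seed
.substream_seed <- function(root, i, salt = 0L) {
  x <- as.double(root) %% 2147483647
  x <- (x * 48271 + as.double(i) * 69621 + as.double(salt) * 16807) %% 2147483647
  as.integer(x)
}

#' Generate a null sample of independent-edge random digraphs
#'
#' Each member network is drawn independently; within a member every ordered
#' pair of distinct vertices carries a directed edge independently with
#' probability `q`. This is exactly the null model against which motifs are
#' tested, so samples from this generator calibrate the familywise error
#' rate. Defaults mirror the effective-connectivity setting: 16 networks on
#' the 9 electrode labels at density 36.79/72.
#'
#' @param n sample size (number of member networks). Default 16.
#' @param q edge probability in `[0, 1]`. Default `36.79 / 72` (approx 0.511).
#' @param labels explicit vertex labels; if `NULL`, the 9 electrode labels
#'   when `num_labels == 9`, else `v1..v<num_labels>`.
#' @param num_labels number of vertices when `labels` is `NULL`. Default 9.
#' @param seed integer root seed; each member uses a substream derived from
#'   it, so the draw is fully reproducible.
#' @return a [network_sample()].
#' @examples
#' s <- generate_null_sample(n = 16, q = 36.79 / 72, seed = 1)
#' fit_null(s)$q
#' @export
generate_null_sample <- function(n = 16, q = 36.79 / 72, labels = NULL,
                                 num_labels = 9, seed) {
  if (missing(seed)) stop("a seed is required (parameter error)", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("n must be a positive integer (parameter error)", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("q must be a probability in [0, 1] (parameter error)", call. = FALSE)
  if (is.null(labels)) {
    num_labels <- as.integer(num_labels)
    labels <- if (num_labels == 9L) ecn_labels()
              else paste0("v", seq_len(num_labels))
  }
  labels <- sort(as.character(labels), method = "radix")
  .check_labels(labels)
  nu <- length(labels)
  if (nu < 2L)
    stop("at least two vertex labels are required (parameter error)",
         call. = FALSE)
  off <- which(diag(nu) == 0)
  nets <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.substream_seed(seed, i))
    a <- matrix(0L, nu, nu, dimnames = list(labels, labels))
    a[off] <- as.integer(stats::runif(length(off)) < q)
    nets[[i]] <- labeled_digraph(a)
  }
  network_sample(nets)
}

#' Plant a subnetwork into sample members
#'
#' Independently for each member, with probability `penetrance`, the induced
#' subnetwork on the planted key's vertex set is forced to equal the key
#' exactly: the key's edges are made present *and* the remaining ordered
#' pairs among its vertices are made absent. Forcing absence matters because
#' counting is by induced subnetwork — planting only the edges would produce
#' a different induced pattern whenever background edges fall inside the
#' vertex set. Edges outside the key's vertex set are untouched.
#'
#' @param sample a [network_sample()].
#' @param key the subnetwork to plant: a [subnetwork_key()] or key string;
#'   its vertices must be sample labels.
#' @param penetrance probability in `[0, 1]` with which each member receives
#'   the plant. Default 1.
#' @param seed integer seed for the per-member penetrance draws.
#' @return a new [network_sample()] of the same dimensions.
#' @export
plant_subnetwork <- function(sample, key, penetrance = 1, seed) {
  stopifnot(inherits(sample, "network_sample"))
  if (missing(seed)) stop("a seed is required (parameter error)", call. = FALSE)
  if (is.character(key)) key <- subnetwork_key(key)
  stopifnot(inherits(key, "subnetwork_key"))
  if (!is.numeric(penetrance) || length(penetrance) != 1L ||
      is.na(penetrance) || penetrance < 0 || penetrance > 1)
    stop("penetrance must be a probability in [0, 1] (parameter error)",
         call. = FALSE)
  if (!all(key$vertices %in% sample$labels))
    stop("planted key uses labels outside the sample's label set (label error)",
         call. = FALSE)
  p <- length(key$vertices)
  pattern <- matrix(0L, p, p, dimnames = list(key$vertices, key$vertices))
  pattern[key$edges] <- 1L
  nets <- sample$networks
  for (i in seq_along(nets)) {
    set.seed(.substream_seed(seed, i, salt = 1L))
    if (stats::runif(1) < penetrance) {
      a <- nets[[i]]$adjacency
      a[key$vertices, key$vertices] <- pattern
      nets[[i]] <- labeled_digraph(a)
    }
  }
  network_sample(nets)
}

#' Generate an ECN-like sample
#'
#' Convenience wrapper dimensioned like an effective-connectivity study
#' sample: 16 networks on the 9 electrode labels with edge density
#' `36.79 / 72`, optionally with a planted subnetwork.
#'
#' @param seed integer root seed.
#' @param n sample size. Default 16.
#' @param plant optional subnetwork to plant (key string or
#'   [subnetwork_key()]).
#' @param penetrance planting probability per member when `plant` is given.
#'   Default 1.
#' @return a [network_sample()].
#' @examples
#' s <- generate_ecn_like_sample(seed = 42, plant = "C3>Cz;Cz>C3",
#'                               penetrance = 1)
#' @export
generate_ecn_like_sample <- function(seed, n = 16, plant = NULL,
                                     penetrance = 1) {
  if (missing(seed)) stop("a seed is required (parameter error)", call. = FALSE)
  s <- generate_null_sample(n = n, q = 36.79 / 72, labels = ecn_labels(),
                            seed = seed)
  if (!is.null(plant))
    s <- plant_subnetwork(s, plant, penetrance = penetrance,
                          seed = .substream_seed(seed, 0L, salt = 2L))
  s
}
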