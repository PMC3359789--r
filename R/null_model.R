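#' Fit the independent-edge null model to a sample
#'
#' The null model is an Erdos-Renyi random digraph on the shared label set in
#' which every ordered pair of distinct vertices carries an edge independently
#' with probability `q`, the normalized mean edge count of the sample:
#' `q = (1 / (n * nu * (nu - 1))) * sum_i k_i`, where `k_i` is the number of
#' edges of member `i`. A null network then has `q * nu * (nu - 1)` edges in
#' expectation.
#'
#' @param sample a [network_sample()].
#' @return an object of class `null_model`: list with `q`, `num_labels`, `n`
#'   and `labels`.
#' @examples
#' s <- generate_ecn_like_sample(seed = 1)
#' fit_null(s)$q  # close to 36.79 / 72
#' @export
fit_null <- function(sample) {
  stopifnot(inherits(sample, "network_sample"))
  nu <- length(sample$labels)
  k <- vapply(sample$networks, function(g) g$n_edges, numeric(1))
  q <- sum(k) / (sample$n * nu * (nu - 1))
  structure(list(q = q, num_labels = nu, n = sample$n, labels = sample$labels),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("independent-edge null model: q = %.6g on %d labels (n = %d networks)\n",
              x$q, x$num_labels, x$n))
  invisible(x)
}

#' Occurrence probability of a subnetwork under the null model
#'
#' The probability that a given labeled subnetwork `S` occurs as a connected
#' *induced* subnetwork of a null network: each of its `eta` edges must be
#' present and each of the `eta_max - eta` remaining ordered pairs among its
#' vertices must be absent, giving `q^eta * (1 - q)^(eta_max - eta)`.
#' Evaluated in log space for `q` strictly between 0 and 1 so that small
#' probabilities do not underflow prematurely; the conventions `0^0 = 1`
#' handle the degenerate densities `q = 0` and `q = 1`.
#'
#' @param key a [subnetwork_key()] or a serialized key string.
#' @param null a fitted [fit_null()] model, or a bare numeric density `q`.
#' @return the occurrence probability, in `[0, 1]`.
#' @examples
#' occurrence_probability("F3>Fz;Fz>F3", 0.5)  # 0.25
#' @export
occurrence_probability <- function(key, null) {
  if (is.character(key)) key <- subnetwork_key(key)
  stopifnot(inherits(key, "subnetwork_key"))
  q <- if (inherits(null, "null_model")) null$q else as.numeric(null)
  if (length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("q must be a probability in [0, 1] (parameter error)", call. = FALSE)
  .occ_prob(key$eta, key$eta_max, q)
}

# vectorized over eta for fixed eta_max and q
.occ_prob <- function(eta, eta_max, q) {
  if (q == 0) return(as.numeric(eta == 0))
  if (q == 1) return(as.numeric(eta == eta_max))
  exp(eta * log(q) + (eta_max - eta) * log1p(-q))
}

#' Exact upper-tail probability of the binomial count law
#'
#' Under the null model the number of sample members containing a given
#' subnetwork is `Binomial(n, p)` with `p` its occurrence probability; the
#' one-sided p-value of an observed count is `P(X >= count)`, evaluated
#' exactly via the binomial survival function (no normal approximation).
#'
#' @param count observed occurrence count, `0 <= count <= n` (vectorized).
#' @param n sample size.
#' @param p occurrence probability under the null (vectorized).
#' @return `P(X >= count)` for `X ~ Binomial(n, p)`.
#' @examples
#' binomial_upper_tail(12, 16, 0.5)  # 2517/65536
#' @export
binomial_upper_tail <- function(count, n, p) {
  if (any(is.na(count)) || any(count < 0) || any(count > n))
    stop("count must lie in 0..n (parameter error)", call. = FALSE)
  if (any(p < 0) || any(p > 1))
    stop("p must be a probability (parameter error)", call. = FALSE)
  stats::pbinom(count - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Holm step-down adjustment with an explicit family size
#'
#' Standard Holm (step-down Bonferroni) adjustment generalized to a family of
#' `family` hypotheses of which only `length(p_values)` were materialized;
#' the remaining hypotheses implicitly have p-value 1 (they can never be
#' rejected but they enlarge the correction factors). With
#' `family = length(p_values)` this is the classical Holm adjustment, i.e.
#' `stats::p.adjust(p, "holm")`. Rejections at level `alpha` are
#' `adjusted <= alpha`; this controls the familywise error rate at `alpha`
#' in the strong sense.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param family family size `m >= length(p_values)`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.001, 0.01, 0.03), family = 3)  # 0.003 0.020 0.030
#' @export
holm_adjust <- function(p_values, family = length(p_values)) {
  if (any(p_values < 0) || any(p_values > 1) || anyNA(p_values))
    stop("p-values must lie in [0, 1] (parameter error)", call. = FALSE)
  m <- as.numeric(family)
  if (length(m) != 1L || is.na(m) || m < length(p_values))
    stop("family size must be at least the number of p-values (parameter error)",
         call. = FALSE)
  if (length(p_values) == 0L) return(numeric(0))
  stats::p.adjust(p_values, method = "holm", n = m)
}
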