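#' Detect network motifs in a sample of labeled directed networks
#'
#' The central estimator of the package. Given a sample of directed simple
#' graphs on one shared set of pairwise-distinct vertex labels, it
#' \enumerate{
#'   \item enumerates all connected induced subnetworks of order `size` in
#'     every member and counts each distinct labeled subnetwork across the
#'     sample ([subnetwork_census()]);
#'   \item fits the independent-edge null density `q` to the sample's mean
#'     edge count ([fit_null()]);
#'   \item assigns each observed subnetwork its null occurrence probability
#'     `q^eta * (1-q)^(eta_max - eta)` and the exact one-sided binomial
#'     p-value of its count ([binomial_upper_tail()]);
#'   \item applies the Holm step-down correction over the full family of
#'     connected labeled patterns of that order ([holm_adjust()]).
#' }
#' A subnetwork whose Holm-adjusted p-value is at most `alpha` is declared a
#' motif: it occurs significantly more often across the sample than the
#' sample's overall edge density explains. Only overrepresentation is tested
#' (the p-value is one-sided, upper tail).
#'
#' @param sample a [network_sample()].
#' @param size subnetwork order `nu_S` (number of vertices), between 2 and
#'   the number of labels. Default 3.
#' @param alpha multiple significance level for the familywise error rate,
#'   strictly between 0 and 1. Default 0.05.
#' @param family_mode `"all-possible"` (default): the Holm family consists of
#'   all `C(nu, size) * W(size)` connected labeled patterns of the given
#'   order, whether observed or not (the conservative reading of "all
#'   subnetworks of a certain order are tested"); `"observed-only"`: only
#'   patterns actually occurring in the sample form the family (for
#'   sensitivity analysis).
#' @return an object of class `motif_fit` with components:
#'   \describe{
#'     \item{table}{data frame, one row per observed subnetwork, ordered by
#'       ascending p-value then canonical key, with columns `subnetwork`
#'       (canonical key string), `size`, `eta`, `count`, `mean_count`
#'       (`count / n`), `p_null`, `p_value`, `p_holm`, `is_motif`.}
#'     \item{q, n, num_labels, labels}{the fitted null density and sample
#'       dimensions.}
#'     \item{size, alpha, family_mode, m}{test configuration; `m` is the
#'       family size used by the Holm correction.}
#'   }
#' @seealso [summary.motif_fit()], [simulate.motif_fit()],
#'   [residuals.motif_fit()], [write_motif_table()]
#' @examples
#' s <- generate_ecn_like_sample(seed = 7, plant = "C3>Cz;Cz>C3;Cz>C4",
#'                               penetrance = 1)
#' fit <- motif_detect(s, size = 3)
#' summary(fit)
#' @export
motif_detect <- function(sample, size = 3, alpha = 0.05,
                         family_mode = c("all-possible", "observed-only")) {
  family_mode <- match.arg(family_mode)
  stopifnot(inherits(sample, "network_sample"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1 (parameter error)",
         call. = FALSE)
  cen <- subnetwork_census(sample, size)
  null <- fit_null(sample)
  size <- cen$size
  keys <- names(cen$counts)
  counts <- as.integer(cen$counts)
  if (null$q == 0 && length(keys) > 0L)
    stop("inconsistent input: zero edge density but non-empty census",
         call. = FALSE)
  eta <- if (length(keys)) {
    lengths(strsplit(keys, ";", fixed = TRUE))
  } else integer(0)
  eta_max <- size * (size - 1L)
  p_null <- .occ_prob(eta, eta_max, null$q)
  if (any(p_null == 0 & counts > 0))
    stop("consistency error: observed subnetwork has null occurrence probability 0",
         call. = FALSE)
  p_value <- binomial_upper_tail(counts, null$n, p_null)
  m <- switch(family_mode,
              "all-possible" = family_size(null$num_labels, size),
              "observed-only" = length(keys))
  p_holm <- holm_adjust(p_value, family = max(m, length(keys)))
  tab <- data.frame(subnetwork = if (length(keys)) keys else character(0),
                    size = rep(size, length(keys)),
                    eta = eta,
                    count = counts,
                    mean_count = counts / null$n,
                    p_null = p_null,
                    p_value = p_value,
                    p_holm = p_holm,
                    is_motif = p_holm <= alpha,
                    stringsAsFactors = FALSE)
  if (nrow(tab)) {
    tab <- tab[order(tab$p_value, tab$subnetwork, method = "radix"), ,
               drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, q = null$q, n = null$n,
                 num_labels = null$num_labels, labels = sample$labels,
                 size = size, alpha = alpha, family_mode = family_mode,
                 m = m, call = match.call()),
            class = "motif_fit")
}

#' @export
print.motif_fit <- function(x, ...) {
  cat("Labeled-network motif detection\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat(sprintf("  sample:  n = %d networks on %d labels\n", x$n, x$num_labels))
  cat(sprintf("  null:    independent-edge density q = %.6g\n", x$q))
  cat(sprintf("  test:    order %d, alpha = %g, Holm family m = %s (%s)\n",
              x$size, x$alpha, format(x$m, scientific = FALSE),
              x$family_mode))
  nm <- sum(x$table$is_motif)
  cat(sprintf("  result:  %d observed subnetworks, %d motif%s\n",
              nrow(x$table), nm, if (nm == 1L) "" else "s"))
  if (nrow(x$table)) {
    k <- min(10L, nrow(x$table))
    cat(sprintf("\nTop %d subnetworks by p-value:\n", k))
    print(x$table[seq_len(k), ], digits = 4)
  }
  invisible(x)
}

#' Summarize a motif fit
#'
#' @param object a [motif_detect()] fit.
#' @param ... unused.
#' @return an object of class `summary.motif_fit` carrying the fit metadata
#'   and the subset of the result table flagged as motifs.
#' @export
summary.motif_fit <- function(object, ...) {
  structure(list(n = object$n, num_labels = object$num_labels, q = object$q,
                 size = object$size, alpha = object$alpha,
                 family_mode = object$family_mode, m = object$m,
                 n_observed = nrow(object$table),
                 motifs = object$table[object$table$is_motif, , drop = FALSE]),
            class = "summary.motif_fit")
}

#' @export
print.summary.motif_fit <- function(x, ...) {
  cat(sprintf("Motif detection on n = %d networks (%d labels), order %d\n",
              x$n, x$num_labels, x$size))
  cat(sprintf("Null density q = %.6g; Holm at alpha = %g over m = %s %s patterns\n",
              x$q, x$alpha, format(x$m, scientific = FALSE), x$family_mode))
  cat(sprintf("%d subnetworks observed, %d declared motifs\n",
              x$n_observed, nrow(x$motifs)))
  if (nrow(x$motifs)) {
    cat("\nMotifs:\n")
    print(x$motifs, digits = 4)
  }
  invisible(x)
}

#' @export
coef.motif_fit <- function(object, ...) c(q = object$q)

#' Simulate samples from a fitted null model
#'
#' Draws new network samples of the same dimensions as the fitted data
#' (same label set, same number of members) with every directed edge present
#' independently at the fitted density `q` — the parametric bootstrap of the
#' null hypothesis.
#'
#' @param object a [motif_detect()] fit.
#' @param nsim number of samples to draw.
#' @param seed integer root seed; if `NULL`, one is drawn from the session
#'   RNG.
#' @param ... unused.
#' @return a list of `nsim` [network_sample()] objects, with the root seed
#'   attached as attribute `"seed"`.
#' @export
simulate.motif_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  out <- lapply(seq_len(nsim), function(i) {
    generate_null_sample(n = object$n, q = object$q, labels = object$labels,
                         seed = .substream_seed(seed, i, salt = 7L))
  })
  attr(out, "seed") <- seed
  out
}

#' Residuals of a motif fit
#'
#' Raw residuals are observed minus expected counts, `count - n * p_null`;
#' Pearson residuals divide by the binomial standard deviation
#' `sqrt(n * p_null * (1 - p_null))`. One value per observed subnetwork,
#' named by canonical key.
#'
#' @param object a [motif_detect()] fit.
#' @param type `"pearson"` (default) or `"response"`.
#' @param ... unused.
#' @return named numeric vector in the order of the fit's table.
#' @export
residuals.motif_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  tab <- object$table
  expected <- object$n * tab$p_null
  r <- tab$count - expected
  if (type == "pearson")
    r <- r / sqrt(object$n * tab$p_null * (1 - tab$p_null))
  stats::setNames(r, tab$subnetwork)
}

#' Plot observed against expected subnetwork counts
#'
#' Each point is one observed subnetwork; the x-axis is its expected count
#' under the fitted null (`n * p_null`), the y-axis its observed count.
#' Points above the identity line are overrepresented; motifs are filled red.
#'
#' @param x a [motif_detect()] fit.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.motif_fit <- function(x, ...) {
  tab <- x$table
  if (!nrow(tab)) {
    warning("empty motif table: nothing to plot")
    return(invisible(x))
  }
  expected <- x$n * tab$p_null
  graphics::plot(expected, tab$count,
                 xlab = "expected count under null",
                 ylab = "observed count",
                 pch = ifelse(tab$is_motif, 19L, 1L),
                 col = ifelse(tab$is_motif, "red3", "grey30"),
                 ylim = c(0, x$n), ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  if (any(tab$is_motif))
    graphics::legend("topleft", legend = c("motif", "not significant"),
                     pch = c(19L, 1L), col = c("red3", "grey30"), bty = "n")
  invisible(x)
}
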