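test_that("fitted null density is the normalized mean edge count", {
  g36 <- local({
    a <- matrix(0L, 9, 9, dimnames = list(ecn_labels(), ecn_labels()))
    a[which(diag(9) == 0)[1:36]] <- 1L
    labeled_digraph(a)
  })
  expect_equal(fit_null(network_sample(list(g36)))$q, 0.5)

  # a sample whose mean edge count is 36.79 of 72
  counts <- c(rep(37, 79), rep(36, 21))  # mean 36.79
  nets <- lapply(counts, function(k) {
    a <- matrix(0L, 9, 9, dimnames = list(ecn_labels(), ecn_labels()))
    a[which(diag(9) == 0)[seq_len(k)]] <- 1L
    labeled_digraph(a)
  })
  expect_equal(fit_null(network_sample(nets))$q, 36.79 / 72)

  empty <- digraph_from_edges(NULL, labels = ecn_labels())
  expect_equal(fit_null(network_sample(list(empty, empty)))$q, 0)
})

test_that("occurrence probability follows the product form, with degenerate q handled", {
  # q = 1/2: every 3-vertex pattern has probability 2^-6 regardless of eta
  for (key in c("a>b;b>c", "a>b;a>c;b>a;b>c;c>a;c>b", "a>b;b>a;b>c")) {
    expect_equal(occurrence_probability(key, 0.5), 2^-6)
  }
  expect_equal(occurrence_probability("a>b;b>a", 0.5), 0.25)
  expect_equal(occurrence_probability(subnetwork_key("a>b;b>c"), 0.51097),
               0.51097^2 * (1 - 0.51097)^4, tolerance = 1e-12)
  # degenerate densities: 0^0 = 1 convention
  expect_equal(occurrence_probability("a>b", 0), 0)
  expect_equal(occurrence_probability("a>b", 1), 0)
  expect_equal(occurrence_probability("a>b;b>a", 1), 1)
  expect_error(occurrence_probability("a>b", 1.5), "parameter")
})

test_that("pattern probabilities on a fixed vertex subset sum to one", {
  keys <- all_connected_keys(c("a", "b", "c"))
  for (q in c(0.2, 0.5, 0.51097, 0.8)) {
    p_conn <- sum(vapply(keys, function(k) occurrence_probability(k, q),
                         numeric(1)))
    # the 10 disconnected patterns: the empty one, and those whose edges all
    # lie within a single vertex pair (3 pairs, each ->, <- or <->)
    p_disc <- (1 - q)^6 +
      3 * (2 * q * (1 - q)^5 + q^2 * (1 - q)^4)
    expect_equal(p_conn + p_disc, 1, tolerance = 1e-12)
  }
})

test_that("binomial upper tail is exact and monotone", {
  expect_equal(binomial_upper_tail(12, 16, 0.5), 2517 / 65536,
               tolerance = 1e-14)
  expect_equal(binomial_upper_tail(0, 16, 0.3), 1)
  expect_equal(binomial_upper_tail(16, 16, 0.2), 0.2^16, tolerance = 1e-12)
  expect_error(binomial_upper_tail(17, 16, 0.5), "parameter")
  expect_error(binomial_upper_tail(-1, 16, 0.5), "parameter")

  # agreement with direct summation over a grid, n <= 32
  for (n in c(5, 16, 32)) {
    for (p in c(0.01, 0.25, 0.5, 0.9)) {
      for (count in 0:n) {
        got <- binomial_upper_tail(count, n, p)
        want <- oracle_binom_tail(count, n, p)
        expect_equal(got, want, tolerance = 1e-12)
      }
      tails <- binomial_upper_tail(0:n, n, p)
      expect_true(all(diff(tails) <= 1e-15))
    }
  }
})

test_that("Holm adjustment matches the literal step-down formula", {
  expect_equal(holm_adjust(c(0.001, 0.01, 0.03), family = 3),
               c(0.003, 0.02, 0.03))
  expect_equal(holm_adjust(c(0.03, 0.04), family = 2), c(0.06, 0.06))
  expect_equal(holm_adjust(0.2, family = 1), 0.2)
  expect_error(holm_adjust(c(0.1, 0.2), family = 1), "parameter")
  expect_error(holm_adjust(c(-0.1, 0.2)), "parameter")

  # family larger than the number of materialized hypotheses
  expect_equal(holm_adjust(c(0.001, 0.01), family = 10),
               oracle_holm(c(0.001, 0.01), 10))

  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(1:12, 1))^2
    m <- length(p) + sample(0:50, 1)
    expect_equal(holm_adjust(p, family = m), oracle_holm(p, m))
  }

  # with m = length it reduces to classical Holm
  p <- runif(8)
  expect_equal(holm_adjust(p), p.adjust(p, "holm"))
  # all p equal: smallest adjusted value is the Bonferroni bound
  expect_equal(min(holm_adjust(rep(0.004, 5), family = 5)), 0.02)
})

test_that("adjusted p-values dominate raw p-values and rejections respect alpha", {
  set.seed(13)
  for (rep in 1:10) {
    p <- runif(20)^3
    m <- 40
    adj <- holm_adjust(p, family = m)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # step-down rejection set at 0.05 equals {adjusted <= 0.05}
    srt <- sort(p)
    k <- 0
    while (k < length(srt) && (m - k) * srt[k + 1] <= 0.05) k <- k + 1
    expect_equal(sum(adj <= 0.05), k)
  }
})
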