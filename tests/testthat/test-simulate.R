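test_that("null generator honors its density, dimensions and seed", {
  s0 <- generate_null_sample(n = 5, q = 0, seed = 1)
  expect_true(all(vapply(s0$networks, function(g) g$n_edges, numeric(1)) == 0))

  s1 <- generate_null_sample(n = 3, q = 1, seed = 1)
  expect_true(all(vapply(s1$networks, function(g) g$n_edges, numeric(1)) == 72))

  a <- generate_null_sample(n = 4, q = 0.5, seed = 7)
  b <- generate_null_sample(n = 4, q = 0.5, seed = 7)
  expect_identical(lapply(a$networks, `[[`, "adjacency"),
                   lapply(b$networks, `[[`, "adjacency"))
  d <- generate_null_sample(n = 4, q = 0.5, seed = 8)
  expect_false(identical(lapply(a$networks, `[[`, "adjacency"),
                         lapply(d$networks, `[[`, "adjacency")))

  # growing n keeps earlier members' draws (substream property)
  small <- generate_null_sample(n = 3, q = 0.5, seed = 7)
  expect_identical(small$networks[[2]]$adjacency, a$networks[[2]]$adjacency)

  expect_error(generate_null_sample(n = 4, q = 2, seed = 1), "parameter")
  expect_error(generate_null_sample(n = 0, q = 0.5, seed = 1), "parameter")
  expect_error(generate_null_sample(n = 4, q = 0.5), "seed")
})

test_that("generated edge counts match the binomial edge law", {
  q <- 36.79 / 72
  s <- generate_null_sample(n = 2000, q = q, seed = 314)
  k <- vapply(s$networks, function(g) g$n_edges, numeric(1))
  # mean within 3 standard errors of 72 q = 36.79
  se <- sqrt(72 * q * (1 - q) / length(k))
  expect_lt(abs(mean(k) - 36.79), 3 * se)
  # variance consistent with independent edges
  expect_lt(abs(var(k) - 72 * q * (1 - q)), 0.15 * 72 * q * (1 - q))
  # chi-squared goodness of fit against Binomial(72, q), pooled tails
  br <- c(-Inf, 30, 33, 35, 37, 39, 42, Inf)
  obs <- table(cut(k, br))
  pr <- diff(pbinom(c(-Inf, 30, 33, 35, 37, 39, 42, Inf), 72, q))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 1e-4)
})

test_that("planting forces the induced pattern exactly", {
  key <- "C3>Cz;Cz>C3;Cz>C4"
  s <- generate_null_sample(n = 16, q = 0.5, seed = 10)
  planted <- plant_subnetwork(s, key, penetrance = 1, seed = 11)
  for (g in planted$networks) {
    e <- induced_edges(g, c("C3", "Cz", "C4"))
    expect_identical(paste(paste0(e[, 1], ">", e[, 2]), collapse = ";"), key)
  }
  expect_equal(as.integer(subnetwork_census(planted, 3)$counts[key]), 16)

  # penetrance 0 leaves the sample untouched
  same <- plant_subnetwork(s, key, penetrance = 0, seed = 11)
  expect_identical(lapply(same$networks, `[[`, "adjacency"),
                   lapply(s$networks, `[[`, "adjacency"))

  expect_error(plant_subnetwork(s, "C3>XX", penetrance = 1, seed = 1), "label")
})

test_that("partial penetrance yields the analytically expected census count", {
  key <- "C3>Cz;Cz>C3;Cz>C4"
  q <- 0.5
  n <- 1000
  s <- generate_null_sample(n = n, q = q, seed = 20)
  planted <- plant_subnetwork(s, key, penetrance = 0.5, seed = 21)
  count <- as.integer(subnetwork_census(planted, 3)$counts[key])
  # a member shows the key if planted (prob 1/2) or, if not planted,
  # by background chance q^3 (1-q)^3
  p_bg <- q^3 * (1 - q)^3
  p_exp <- 0.5 + 0.5 * p_bg
  se <- sqrt(n * p_exp * (1 - p_exp))
  expect_lt(abs(count - n * p_exp), 3 * se)
  # planting can only increase the count relative to the unplanted sample
  bare <- subnetwork_census(s, 3)$counts[key]
  bare <- if (is.na(bare)) 0L else as.integer(bare)
  expect_gte(count, bare)
})

test_that("the ECN-like wrapper has the study dimensions and is reproducible", {
  s <- generate_ecn_like_sample(seed = 5)
  expect_equal(s$n, 16)
  expect_identical(s$labels, sort(ecn_labels(), method = "radix"))
  s2 <- generate_ecn_like_sample(seed = 5)
  expect_identical(lapply(s$networks, `[[`, "adjacency"),
                   lapply(s2$networks, `[[`, "adjacency"))

  # grand mean edge count over many samples approaches 36.79
  k <- unlist(lapply(1:60, function(i) {
    vapply(generate_ecn_like_sample(seed = 1000 + i)$networks,
           function(g) g$n_edges, numeric(1))
  }))
  se <- sqrt(72 * (36.79 / 72) * (1 - 36.79 / 72) / length(k))
  expect_lt(abs(mean(k) - 36.79), 3 * se)
})
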