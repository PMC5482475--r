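test_that("ising_model enforces symmetry, zero diagonal and finiteness", {
  W <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  m <- ising_model(c(0.1, -0.1), W)
  expect_s3_class(m, "ising_model")
  expect_identical(m$node_count, 2L)

  Wbad <- W; Wbad[1, 2] <- 0.3
  expect_error(ising_model(c(0, 0), Wbad), "symmetric")
  Wdiag <- W; diag(Wdiag) <- 1
  expect_error(ising_model(c(0, 0), Wdiag), "diagonal")
  expect_error(ising_model(c(0, Inf), W), "finite")
  expect_error(ising_model(c(0, 0), matrix(0, 3, 3)), "matrix")
})

test_that("make_curie_weiss builds the uniform fully connected model", {
  m <- make_curie_weiss(3, 0.2, 0)
  expect_equal(upper_vec(m$weights), rep(0.2, 3))
  expect_equal(m$thresholds, rep(0, 3))
  expect_equal(diag(m$weights), rep(0, 3))

  # single node: no edges, only the threshold
  m1 <- make_curie_weiss(1, 0.2, 0.5)
  expect_identical(dim(m1$weights), c(1L, 1L))
  expect_equal(m1$thresholds, 0.5)

  expect_error(make_curie_weiss(0), "node_count")
})

test_that("make_random_sparse places the right number of edges, fixed by seed", {
  m <- make_random_sparse(10, density = 0.2, edge_weight = 0.2, seed = 1)
  w <- upper_vec(m$weights)
  expect_equal(sum(w != 0), 9)  # round(0.2 * 45)
  expect_true(all(w[w != 0] == 0.2))

  # deterministic given seed, different across seeds
  expect_identical(m, make_random_sparse(10, 0.2, 0.2, seed = 1))
  m2 <- make_random_sparse(10, 0.2, 0.2, seed = 2)
  expect_false(identical(m$weights, m2$weights))

  # boundary densities
  expect_equal(make_random_sparse(10, 0, seed = 1)$weights, matrix(0, 10, 10))
  expect_equal(make_random_sparse(10, 1, 0.2, seed = 1),
               make_curie_weiss(10, 0.2, 0))
  expect_error(make_random_sparse(10, 1.2, seed = 1), "density")
})

test_that("pattern_distribution matches hand enumeration", {
  # all-zero parameters: uniform over the 4 patterns
  m0 <- ising_model(c(0, 0), matrix(0, 2, 2))
  expect_equal(pattern_distribution(m0)$probabilities, rep(0.25, 4))

  # P = 2 with one interaction: Pr(1,1) = e^0.2 / (3 + e^0.2)
  m <- ising_model(c(0, 0), matrix(c(0, 0.2, 0.2, 0), 2, 2))
  pd <- pattern_distribution(m)
  expect_equal(pd$probabilities[4], exp(0.2) / (3 + exp(0.2)), tolerance = 1e-12)
  expect_equal(pd$probabilities[1], 1 / (3 + exp(0.2)), tolerance = 1e-12)

  # P = 1 logistic threshold
  m1 <- ising_model(log(3), matrix(0, 1, 1))
  expect_equal(pattern_distribution(m1)$probabilities[2], 0.75,
               tolerance = 1e-12)

  big <- make_curie_weiss(21, 0.1)
  expect_error(pattern_distribution(big), "20")
})

test_that("pattern probabilities sum to one for random models", {
  for (P in c(2, 5, 9, 12)) {
    pd <- pattern_distribution(random_model(P, seed = P))
    expect_true(all(pd$probabilities >= 0))
    expect_lt(abs(sum(pd$probabilities) - 1), 1e-12)
  }
})

test_that("Curie-Weiss pattern probabilities are exchangeable", {
  for (P in c(4, 8)) {
    pd <- pattern_distribution(make_curie_weiss(P, 0.2, 0.3))
    s <- rowSums(isingbet:::pattern_matrix(P))
    for (k in 0:P) {
      p_k <- pd$probabilities[s == k]
      expect_lt(diff(range(p_k)), 1e-15)
    }
  }
})

test_that("exact sampling draws i.i.d. patterns from the enumeration", {
  # independence model: fair coins
  m0 <- ising_model(rep(0, 4), matrix(0, 4, 4))
  x <- sample_ising(m0, 50000, seed = 1)
  expect_true(all(x %in% c(0L, 1L)))
  expect_true(all(abs(colMeans(x) - 0.5) < 3 * sqrt(0.25 / 50000)))

  # empirical pattern frequencies converge in total variation
  m <- random_model(4, seed = 3)
  pd <- pattern_distribution(m)
  x <- sample_ising(m, 100000, seed = 2)
  idx <- as.integer(x %*% 2^(0:3))
  freq <- tabulate(idx + 1L, 16) / nrow(x)
  expect_lt(0.5 * sum(abs(freq - pd$probabilities)), 0.02)

  # degenerate sizes and determinism
  x0 <- sample_ising(m, 0, seed = 1)
  expect_identical(dim(x0), c(0L, 4L))
  expect_identical(sample_ising(m, 100, seed = 9),
                   sample_ising(m, 100, seed = 9))
  expect_error(sample_ising(m, -1, seed = 1), "nonnegative")
  expect_error(sample_ising(make_curie_weiss(21, 0.1), 10, seed = 1), "20")
})

test_that("Gibbs and exact samplers agree on first and second moments", {
  m <- make_curie_weiss(8, 0.2, 0)
  n <- 20000
  th <- pattern_moments(pattern_distribution(m))
  for (method in c("exact", "gibbs")) {
    emp <- sample_moments(sample_ising(m, n, seed = 17, method = method))
    se1 <- sqrt(th$means * (1 - th$means) / n)
    expect_true(all(abs(emp$means - th$means) < 3.5 * se1))
    ut <- upper.tri(th$cross)
    se2 <- sqrt(th$cross[ut] * (1 - th$cross[ut]) / n)
    expect_true(all(abs(emp$cross[ut] - th$cross[ut]) < 3.5 * se2))
  }
})

test_that("seed_stream derives distinct, valid, reproducible sub-seeds", {
  s1 <- seed_stream(1, "truth")
  expect_identical(s1, seed_stream(1, "truth"))
  expect_false(s1 == seed_stream(1, "rep1/data"))
  expect_false(s1 == seed_stream(2, "truth"))
  labels <- c("a", "b", "truth", "rep1/data", "rep2/data", "cv-folds")
  seeds <- vapply(labels, function(l) seed_stream(123, l), integer(1))
  expect_true(all(seeds >= 1 & seeds < 2^31 - 1))
  expect_identical(length(unique(seeds)), length(labels))
})
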