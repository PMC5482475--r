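test_that("symmetrize implements the AND, OR and average rules", {
  m <- matrix(c(0, 0.3, 0.1, 0), 2, 2, byrow = TRUE)
  expect_equal(symmetrize(m, "AND")[1, 2], 0.2)
  expect_equal(symmetrize(m, "OR")[1, 2], 0.2)
  expect_equal(symmetrize(m, "average")[1, 2], 0.2)

  m2 <- matrix(c(0, 0.3, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(symmetrize(m2, "AND")[1, 2], 0)
  expect_equal(symmetrize(m2, "OR")[1, 2], 0.15)
  expect_equal(symmetrize(m2, "average")[1, 2], 0.15)

  # any input: symmetric with zero diagonal
  set.seed(4)
  r <- matrix(rnorm(25), 5, 5); diag(r) <- 0
  for (rule in c("AND", "OR", "average")) {
    s <- symmetrize(r, rule)
    expect_equal(s, t(s))
    expect_equal(diag(s), rep(0, 5))
  }
  expect_error(symmetrize(matrix(0, 2, 3)), "square")
})

test_that("ebic_score matches the closed form and reduces to BIC at gamma 0", {
  expect_equal(ebic_score(-100, 3, 1000, 10, 0.25),
               200 + 3 * log(1000) + 1.5 * log(9), tolerance = 1e-12)
  expect_equal(ebic_score(-100, 3, 1000, 10, 0),
               200 + 3 * log(1000), tolerance = 1e-12)
  expect_equal(ebic_score(-57.3, 0, 500, 6, 0.25), 114.6)
  # gamma = 0 is the classical BIC for any inputs
  for (k in 0:4)
    expect_equal(ebic_score(-80, k, 250, 8, 0), 160 + k * log(250))
})

test_that("fit_nodewise recovers a Curie-Weiss model at large n", {
  truth <- make_curie_weiss(6, 0.2, 0)
  x <- sample_ising(truth, 50000, seed = 41)
  fit <- fit_nodewise(x)
  W <- fit$model$weights
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(0, 6))
  expect_lt(max(abs(upper_vec(W) - 0.2)), 0.1)
  expect_lt(max(abs(fit$model$thresholds)), 0.1)
})

test_that("fit_nodewise rejects degenerate inputs", {
  x <- sample_ising(make_curie_weiss(4, 0.2), 100, seed = 2)
  x[, 3] <- 1
  expect_error(fit_nodewise(x), "node 3")
  x2 <- sample_ising(make_curie_weiss(5, 0.2), 4, seed = 2)
  expect_error(fit_nodewise(x2), "at least as many rows")
})

test_that("l1_logistic_path satisfies its path contracts", {
  x <- sample_ising(make_curie_weiss(6, 0.3, 0), 500, seed = 11)
  p <- l1_logistic_path(x[, 1], x[, -1], n_lambdas = 60)
  expect_identical(length(p$penalties), 60L)
  expect_true(all(diff(p$penalties) < 0))
  expect_true(all(p$coefficients[, 1] == 0))   # all-zero at lambda_max
  expect_true(all(is.finite(p$ebic_scores)))
  # l1 norm weakly increases as the penalty decreases
  l1 <- colSums(abs(p$coefficients))
  expect_true(all(diff(l1) > -1e-6))
  # near-unregularized at a tiny penalty
  p2 <- l1_logistic_path(x[, 1], x[, -1], lambda_min_ratio = 1e-4)
  mle <- glm.fit(cbind(1, x[, -1]), x[, 1], family = binomial())
  expect_lt(max(abs(p2$coefficients[, 100] - mle$coefficients[-1])), 0.02)

  expect_error(l1_logistic_path(rep(1, 100), x[1:100, -1]), "constant")
})

test_that("fit_elasso selects the per-node EBIC optimum and AND-symmetrizes", {
  truth <- make_random_sparse(10, 0.2, 0.2, seed = 5)
  x <- sample_ising(truth, 1000, seed = 12)
  fit <- fit_elasso(x)
  expect_identical(fit$gamma, 0.25)
  expect_identical(fit$rule, "AND")
  expect_true(all(fit$selected_penalties >= 0))
  W <- fit$model$weights
  expect_equal(W, t(W))

  # selection is internally optimal: refitting one node's path finds no
  # better EBIC than the selected penalty
  p1 <- l1_logistic_path(x[, 1], x[, -1], gamma = 0.25)
  best <- which.min(p1$ebic_scores)
  expect_equal(p1$penalties[best], fit$selected_penalties[1])
  expect_equal(min(p1$ebic_scores), p1$ebic_scores[best])

  # AND rule: an edge supported by only one direction is zeroed
  B <- matrix(c(0, 0.4, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(symmetrize(B, "AND"), matrix(0, 3, 3))
})

test_that("eLasso is specific on sparse truths and sparse on dense truths", {
  truth <- make_random_sparse(10, 0.2, 0.2, seed = 5)
  spec <- replicate(5, NA_real_)
  for (r in 1:5) {
    x <- sample_ising(truth, 1000, seed = 300 + r)
    m <- recovery_metrics(truth, fit_elasso(x)$model)
    spec[r] <- m$specificity
  }
  expect_gte(mean(spec), 0.9)

  # dense truth at small n: some edges are still exactly zero
  xd <- sample_ising(make_curie_weiss(10, 0.2, 0), 250, seed = 13)
  expect_lt(network_density(fit_elasso(xd)$model), 1)
})

test_that("fit_loglinear matches the saturated 2x2 closed form", {
  counts <- c(40, 20, 20, 20)  # (00, 01, 10, 11) as (x1, x2)
  x <- rbind(matrix(0, 40, 2),
             matrix(c(0, 1), 20, 2, byrow = TRUE),
             matrix(c(1, 0), 20, 2, byrow = TRUE),
             matrix(1, 20, 2))
  fit <- fit_loglinear(x)
  expect_equal(fit$model$weights[1, 2], log(2), tolerance = 1e-9)
  expect_equal(fit$model$thresholds, c(-log(2), -log(2)), tolerance = 1e-9)

  # a zero cell makes the MLE infinite
  xz <- x[1:80, ]  # no (1,1) pattern
  expect_error(fit_loglinear(xz), "zero")
  # ... unless smoothing is requested explicitly
  expect_s3_class(fit_loglinear(xz, smooth = 0.5), "ising_fit")

  expect_error(fit_loglinear(matrix(0:1, 4, 16)), "15")
})

test_that("log-linear and nodewise estimates agree at large n", {
  truth <- random_model(4, density = 0.8, seed = 9)
  x <- sample_ising(truth, 200000, seed = 14)
  f_ll <- fit_loglinear(x)
  f_nw <- fit_nodewise(x)
  expect_lt(max(abs(f_ll$model$weights - f_nw$model$weights)), 0.02)
  expect_lt(max(abs(f_ll$model$thresholds - f_nw$model$thresholds)), 0.02)
  # both near the truth
  expect_lt(max(abs(f_ll$model$weights - truth$weights)), 0.1)
})

test_that("rank-P low-rank fit matches the unconstrained optimum", {
  x <- sample_ising(make_curie_weiss(5, 0.2, 0), 500, seed = 7)
  P <- ncol(x)
  fit <- fit_low_rank(x, rank = P, tol = 1e-12, max_iter = 20000)
  # independent oracle: BFGS on the raw pseudolikelihood
  obj <- function(par) {
    tau <- par[1:P]
    W <- matrix(0, P, P); W[upper.tri(W)] <- par[-(1:P)]; W <- W + t(W)
    -isingbet:::pseudolikelihood(x, tau, W)
  }
  opt <- optim(rep(0, P + choose(P, 2)), obj, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  Wo <- matrix(0, P, P); Wo[upper.tri(Wo)] <- opt$par[-(1:P)]; Wo <- Wo + t(Wo)
  expect_lt(max(abs(fit$model$weights - Wo)), 1e-3)
  expect_lt(abs(fit$pseudolikelihood - (-opt$value)), 1e-6)
})

test_that("rank-2 fits are dense and smoother than unregularized fits", {
  x <- sample_ising(make_curie_weiss(10, 0.2, 0), 1000, seed = 8)
  f2 <- fit_low_rank(x, rank = 2)
  expect_identical(f2$rank, 2L)
  expect_equal(network_density(f2$model, 1e-8), 1)
  cv <- function(w) sd(w) / abs(mean(w))
  expect_lt(cv(upper_vec(f2$model$weights)),
            cv(upper_vec(fit_nodewise(x)$model$weights)))

  expect_error(fit_low_rank(x, rank = 0), "rank")
  expect_error(fit_low_rank(x, rank = 11), "rank")
  # non-convergence is flagged, not thrown
  f_stop <- fit_low_rank(x, rank = 2, max_iter = 2)
  expect_false(f_stop$converged)
})

test_that("elastic-net mixing limits behave as LASSO and ridge", {
  x <- sample_ising(make_curie_weiss(5, 0.2, 0), 300, seed = 2)
  f1 <- fit_elasticnet_cv(x, mixing_grid = 1, seed = 3)
  expect_true(all(f1$mixing == 1))
  expect_lt(network_density(f1$model), 1)  # L1 produces exact zeros here
  f0 <- fit_elasticnet_cv(x, mixing_grid = 0, seed = 3)
  expect_true(all(f0$mixing == 0))
  expect_equal(network_density(f0$model), 1)  # ridge never zeroes exactly
  # determinism under the fold seed
  f1b <- fit_elasticnet_cv(x, mixing_grid = 1, seed = 3)
  expect_identical(f1$model, f1b$model)
  expect_error(fit_elasticnet_cv(x, folds = 1), "folds")
})

test_that("elastic-net prefers a dense network on latent-variable data", {
  x <- sample_mirt(build_comorbidity_mirt(), 1000, seed = 31)
  f <- fit_elasticnet_cv(x, seed = 1)
  expect_gt(network_density(f$model), 0.75)
})

test_that("all estimators return exactly symmetric zero-diagonal weights", {
  x <- sample_ising(make_random_sparse(6, 0.3, 0.25, seed = 3), 400, seed = 15)
  fits <- list(fit_nodewise(x), fit_elasso(x), fit_loglinear(x),
               fit_low_rank(x, rank = 2),
               fit_elasticnet_cv(x, mixing_grid = c(0, 1), folds = 5, seed = 1))
  for (f in fits) {
    W <- f$model$weights
    expect_identical(W, t(W))
    expect_identical(diag(W), rep(0, 6))
    expect_identical(f$model$node_count, 6L)
  }
})
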