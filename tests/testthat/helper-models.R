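# A random Ising model with N(0, 0.3) weights on a random edge set.
random_model <- function(P, density = 0.5, seed = 1) {
  with_seed(seed, {
    W <- matrix(0, P, P)
    ut <- which(upper.tri(W))
    on <- ut[runif(length(ut)) < density]
    W[on] <- rnorm(length(on), sd = 0.3)
    W <- W + t(W)
    ising_model(rnorm(P, sd = 0.5), W)
  })
}

upper_vec <- function(m) m[upper.tri(m)]

# First and second moments implied by a pattern distribution.
pattern_moments <- function(pd) {
  X <- isingbet:::pattern_matrix(pd$node_count)
  m1 <- colSums(X * pd$probabilities)
  m2 <- crossprod(X, X * pd$probabilities)
  list(means = m1, cross = m2)
}

# Empirical first and second moments of a 0/1 matrix.
sample_moments <- function(x) {
  list(means = colMeans(x), cross = crossprod(x) / nrow(x))
}
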