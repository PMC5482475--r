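# Joint pseudolikelihood of an Ising model on 0/1 data:
# sum_j sum_i log Pr(x_ij | x_i,-j) with eta = X W + 1 tau'.
pseudolikelihood <- function(data, thresholds, weights) {
  eta <- data %*% weights +
    matrix(thresholds, nrow(data), length(thresholds), byrow = TRUE)
  sum(data * eta - log1p(exp(eta)))
}

# Projects a symmetric matrix onto rank <= k by keeping the k eigen
# components of largest magnitude.
project_rank <- function(M, rank) {
  P <- nrow(M)
  if (rank >= P) return(M)
  ed <- eigen(M, symmetric = TRUE)
  keep <- order(abs(ed$values), decreasing = TRUE)[seq_len(rank)]
  Mk <- ed$vectors[, keep, drop = FALSE] %*%
    (ed$values[keep] * t(ed$vectors[, keep, drop = FALSE]))
  (Mk + t(Mk)) / 2
}

# The optimizer state is (tau_base, M) with M symmetric rank <= k and a
# free diagonal; the Ising model it represents zeroes diag(M) and absorbs
# it into the thresholds (exact for 0/1 data, where x^2 = x).
lowrank_as_model <- function(tau_base, M) {
  W <- M
  diag(W) <- 0
  list(thresholds = tau_base + diag(M), weights = W)
}

# Marginal pairwise log odds ratios (0.5 continuity correction). A cheap
# moment-based surrogate of the weight matrix whose sign pattern puts the
# non-convex rank-constrained ascent in the right basin.
pairwise_log_or <- function(data) {
  n <- nrow(data)
  n11 <- crossprod(data)
  cs <- colSums(data)
  n10 <- outer(cs, rep(1, ncol(data))) - n11
  n01 <- t(n10)
  n00 <- n - n11 - n10 - n01
  lor <- log((n11 + 0.5) * (n00 + 0.5) / ((n10 + 0.5) * (n01 + 0.5)))
  diag(lor) <- 0
  (lor + t(lor)) / 2
}

#' Low-rank pseudolikelihood approximation of an Ising network
#'
#' The density-assuming estimator: maximizes the joint pseudolikelihood
#' \eqn{\sum_j \sum_i \log \Pr(x_{ij} \mid x_{i,-j})} over the thresholds
#' and a symmetric weight matrix constrained to rank at most \code{rank},
#' by projected gradient ascent. After every gradient step the weight
#' matrix is projected onto the symmetric rank-\eqn{\le k} matrices by
#' truncated eigendecomposition (largest-magnitude eigenvalues kept); the
#' diagonal the projection induces is absorbed into the thresholds, which
#' is exact for 0/1 data because \eqn{x^2 = x}. A backtracking line search
#' keeps the objective monotone; the rank constraint makes the problem
#' non-convex, so the best of \code{n_restarts} randomly perturbed starts
#' is returned. A rank-\eqn{k} weight matrix is the network counterpart of
#' a \eqn{k}-factor latent variable model: the estimate is dense (no edge
#' exactly zero) but highly constrained, with many near-equal weights.
#'
#' @param data 0/1 matrix, observations in rows; no constant columns.
#' @param rank Target rank \eqn{1 \le k \le P} (default 2).
#' @param max_iter Maximum gradient iterations per restart (default 1000).
#' @param tol Relative pseudolikelihood change declaring convergence
#'   (default 1e-8).
#' @param n_restarts Number of random restarts (default 3).
#' @param seed Integer seed for the restart perturbations.
#' @return An [ising_fit()] with method \code{"lowrank"}; \code{converged}
#'   reports whether the best restart met \code{tol} (non-convergence is
#'   flagged, not an error) and \code{iterations} its iteration count.
#' @export
fit_low_rank <- function(data, rank = 2L, max_iter = 1000L, tol = 1e-8,
                         n_restarts = 3L, seed = 1) {
  data <- check_estimation_input(data)
  P <- ncol(data)
  n <- nrow(data)
  if (rank < 1 || rank > P)
    stop("'rank' must be between 1 and P = ", P)
  tau0 <- stats::qlogis(pmin(pmax(colMeans(data), 1e-3), 1 - 1e-3))
  M0 <- pairwise_log_or(data)  # data-driven start (sign-correct basin)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    M <- with_seed(seed_stream(seed, paste0("lowrank-restart-", r)), {
      Z <- matrix(stats::rnorm(P * P, sd = 0.05), P, P)
      switch(1L + (r - 1L) %% 3L,
             M0,                     # log-odds-ratio start
             (Z + t(Z)) / 2,         # near-zero random start
             M0 + (Z + t(Z)) / 2)    # perturbed data-driven start
    })
    M <- project_rank(M, rank)
    tau <- tau0
    mod <- lowrank_as_model(tau, M)
    pl <- pseudolikelihood(data, mod$thresholds, mod$weights)
    step <- 1 / n
    it <- 0L
    converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      eta <- data %*% mod$weights +
        matrix(mod$thresholds, n, P, byrow = TRUE)
      R <- data - stats::plogis(eta)
      g_tau <- colSums(R)
      G <- crossprod(data, R)
      G <- G + t(G)
      diag(G) <- g_tau  # diag(M) acts as a threshold shift on 0/1 data
      improved <- FALSE
      step <- step * 2  # try growing first; backtrack as needed
      for (bt in 1:50) {
        M_new <- project_rank(M + step * G, rank)
        tau_new <- tau + step * g_tau
        cand <- lowrank_as_model(tau_new, M_new)
        pl_new <- pseudolikelihood(data, cand$thresholds, cand$weights)
        if (is.finite(pl_new) && pl_new > pl) { improved <- TRUE; break }
        step <- step / 2
      }
      if (!improved) { converged <- TRUE; break }  # projected stationary point
      rel <- (pl_new - pl) / (abs(pl) + 1e-12)
      M <- M_new; tau <- tau_new; mod <- lowrank_as_model(tau, M); pl <- pl_new
      if (rel < tol) { converged <- TRUE; break }
    }
    if (is.null(best) || pl > best$pl)
      best <- list(pl = pl, tau = mod$thresholds, W = mod$weights,
                   converged = converged, iterations = it)
  }
  ising_fit(ising_model(best$tau, best$W), "lowrank", rank = as.integer(rank),
            converged = best$converged, iterations = best$iterations,
            pseudolikelihood = best$pl)
}
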