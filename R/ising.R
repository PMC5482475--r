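#' Construct an Ising model
#'
#' An Ising model over \eqn{P} binary variables coded \{0, 1\} is the pairwise
#' Markov random field
#' \deqn{\Pr(X = x) \propto \exp\Big(\sum_i \tau_i x_i +
#'   \sum_{i<j} \omega_{ij} x_i x_j\Big),}
#' parameterized by node thresholds \eqn{\tau} (log-odds units) and a
#' symmetric, zero-diagonal weight matrix \eqn{\omega} holding the
#' \eqn{P(P-1)/2} pairwise interactions. The \{0, 1\} coding matters: the
#' same dependence structure has different parameter values under \eqn{\pm 1}
#' coding, and all estimators in this package use the \{0, 1\} convention of
#' logistic regression and eLasso.
#'
#' @param thresholds Numeric vector of node thresholds \eqn{\tau}.
#' @param weights Symmetric numeric matrix with zero diagonal; entry
#'   \code{[i, j]} is the pairwise interaction \eqn{\omega_{ij}}.
#' @return An object of class \code{"ising_model"}: a list with elements
#'   \code{node_count}, \code{thresholds} and \code{weights}.
#' @examples
#' m <- ising_model(c(0, 0), matrix(c(0, 0.2, 0.2, 0), 2, 2))
#' m$node_count
#' @export
ising_model <- function(thresholds, weights) {
  thresholds <- as.numeric(thresholds)
  weights <- as.matrix(weights)
  P <- length(thresholds)
  if (P < 1L) stop("an Ising model needs at least one node")
  if (!is.numeric(weights) || nrow(weights) != P || ncol(weights) != P)
    stop("'weights' must be a ", P, "x", P, " numeric matrix")
  if (!all(is.finite(thresholds)) || !all(is.finite(weights)))
    stop("all Ising parameters must be finite")
  if (!identical(dim(weights), as.integer(c(P, P))) ||
      !isTRUE(all(weights == t(weights))))
    stop("'weights' must be exactly symmetric")
  if (any(diag(weights) != 0))
    stop("'weights' must have a zero diagonal")
  dimnames(weights) <- NULL
  structure(
    list(node_count = P, thresholds = thresholds, weights = weights),
    class = "ising_model"
  )
}

#' @export
print.ising_model <- function(x, ...) {
  cat("Ising model:", x$node_count, "nodes,",
      sum(x$weights[upper.tri(x$weights)] != 0), "of",
      choose(x$node_count, 2), "edges nonzero\n")
  invisible(x)
}

#' Curie-Weiss (fully connected, exchangeable) Ising model
#'
#' Every pair of nodes gets the same interaction weight and every node the
#' same threshold. The weight matrix has rank 1 (up to its zeroed diagonal),
#' which makes this model the network counterpart of a unidimensional Rasch
#' model; see [rasch_representation()].
#'
#' @param node_count Number of nodes \eqn{P \ge 1}.
#' @param edge_weight Common pairwise interaction (default 0.2).
#' @param threshold Common node threshold (default 0).
#' @return An [ising_model()].
#' @examples
#' make_curie_weiss(3, edge_weight = 0.2)
#' @export
make_curie_weiss <- function(node_count, edge_weight = 0.2, threshold = 0) {
  node_count <- as.integer(node_count)
  if (length(node_count) != 1L || is.na(node_count) || node_count < 1L)
    stop("'node_count' must be a single integer >= 1")
  W <- matrix(edge_weight, node_count, node_count)
  diag(W) <- 0
  ising_model(rep(threshold, node_count), W)
}

#' Random sparse Ising model
#'
#' A fixed fraction of the \eqn{P(P-1)/2} node pairs, chosen uniformly at
#' random without replacement, receives a common weight; all other pairs get
#' weight zero. The edge set is fully determined by \code{seed}.
#'
#' @param node_count Number of nodes.
#' @param density Fraction of pairs that receive an edge, in \[0, 1\]. The
#'   number of edges is \code{round(density * choose(P, 2))}.
#' @param edge_weight Weight given to the selected pairs (default 0.2).
#' @param threshold Common node threshold (default 0).
#' @param seed Integer seed fixing the edge set.
#' @return An [ising_model()].
#' @examples
#' m <- make_random_sparse(10, density = 0.2, seed = 1)
#' sum(m$weights[upper.tri(m$weights)] != 0)  # 9 of 45 pairs
#' @export
make_random_sparse <- function(node_count, density, edge_weight = 0.2,
                               threshold = 0, seed = 1) {
  node_count <- as.integer(node_count)
  if (length(node_count) != 1L || is.na(node_count) || node_count < 1L)
    stop("'node_count' must be a single integer >= 1")
  if (!is.numeric(density) || length(density) != 1L ||
      is.na(density) || density < 0 || density > 1)
    stop("'density' must be a single number in [0, 1]")
  n_pairs <- choose(node_count, 2)
  n_edges <- round(density * n_pairs)
  W <- matrix(0, node_count, node_count)
  if (n_edges > 0) {
    pairs <- which(upper.tri(W))
    chosen <- with_seed(seed, sample(pairs, n_edges))
    W[chosen] <- edge_weight
    W <- W + t(W)
  }
  ising_model(rep(threshold, node_count), W)
}

# Hard cap on exact enumeration: 2^P patterns.
.enumeration_limit <- 20L

# All 2^P binary patterns as a (2^P x P) matrix; row r is the pattern whose
# integer index is r - 1, with node j stored in bit j - 1 (node 1 = least
# significant bit).
pattern_matrix <- function(node_count) {
  idx <- 0:(2^node_count - 1)
  vapply(seq_len(node_count),
         function(j) as.numeric(bitwAnd(idx, bitwShiftL(1L, j - 1L)) != 0L),
         numeric(length(idx)))
}

#' Exact pattern distribution of an Ising model
#'
#' Evaluates the probability of each of the \eqn{2^P} response patterns by
#' explicit enumeration, normalizing exactly. Patterns are indexed by the
#' integer whose bit \eqn{j - 1} is the value of node \eqn{j} (node 1 =
#' least significant bit), so \code{probabilities[1]} is the all-zero
#' pattern and \code{probabilities[2^P]} the all-one pattern.
#'
#' @param model An [ising_model()] with at most 20 nodes.
#' @return An object of class \code{"pattern_distribution"}: a list with
#'   \code{node_count} and the length-\eqn{2^P} vector \code{probabilities}.
#' @examples
#' pd <- pattern_distribution(make_curie_weiss(2, 0.2))
#' pd$probabilities  # Pr(0,0), Pr(1,0), Pr(0,1), Pr(1,1)
#' @export
pattern_distribution <- function(model) {
  stopifnot(inherits(model, "ising_model"))
  P <- model$node_count
  if (P > .enumeration_limit)
    stop("exact enumeration is limited to ", .enumeration_limit,
         " nodes; got ", P)
  X <- pattern_matrix(P)
  energy <- drop(X %*% model$thresholds) +
    rowSums((X %*% model$weights) * X) / 2
  logp <- energy - max(energy)
  p <- exp(logp)
  p <- p / sum(p)
  structure(list(node_count = P, probabilities = p),
            class = "pattern_distribution")
}

#' Simulate binary responses from an Ising model
#'
#' Two samplers are available. \code{"exact"} enumerates the pattern
#' distribution (so \eqn{P \le 20}) and draws i.i.d. patterns by
#' inverse-CDF lookup on the pattern index. \code{"gibbs"} runs one
#' independent single-site Gibbs chain per observation, all chains updated
#' in lock-step; each chain starts from independent Bernoulli(0.5) states,
#' performs \code{burnin} full sweeps plus \code{thin - 1} extra sweeps, and
#' its final state is the draw, so rows are independent by construction.
#'
#' @param model An [ising_model()].
#' @param n_obs Number of observations (rows) to draw.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param method \code{"exact"} (default for \eqn{P \le 20}) or
#'   \code{"gibbs"}.
#' @param burnin Gibbs burn-in sweeps per chain (default 200).
#' @param thin Gibbs thinning interval (default 1); with independent
#'   per-observation chains this adds \code{thin - 1} sweeps after burn-in.
#' @return An integer matrix of 0/1 values with \code{n_obs} rows and one
#'   column per node, with column names \code{V1..VP} (or the model's own
#'   labels when present).
#' @examples
#' x <- sample_ising(make_curie_weiss(4, 0.2), 100, seed = 1)
#' colMeans(x)
#' @export
sample_ising <- function(model, n_obs, seed,
                         method = c("exact", "gibbs"),
                         burnin = 200L, thin = 1L) {
  stopifnot(inherits(model, "ising_model"))
  method <- match.arg(method)
  if (length(n_obs) != 1L || is.na(n_obs) || n_obs < 0)
    stop("'n_obs' must be a single nonnegative integer")
  n_obs <- as.integer(n_obs)
  P <- model$node_count
  if (method == "exact") {
    if (P > .enumeration_limit)
      stop("exact sampling enumerates all patterns and is limited to ",
           .enumeration_limit, " nodes; got ", P, " (use method = \"gibbs\")")
    if (n_obs == 0L) {
      out <- matrix(integer(0), 0L, P)
    } else {
      pd <- pattern_distribution(model)
      cdf <- cumsum(pd$probabilities)
      cdf[length(cdf)] <- 1
      u <- with_seed(seed, stats::runif(n_obs))
      idx <- findInterval(u, cdf, left.open = TRUE) + 1L
      Xp <- pattern_matrix(P)
      out <- matrix(as.integer(Xp[idx, , drop = FALSE]), n_obs, P)
    }
  } else {
    if (burnin < 0) stop("'burnin' must be >= 0")
    if (thin < 1) stop("'thin' must be >= 1")
    out <- with_seed(seed, {
      X <- matrix(as.numeric(stats::runif(n_obs * P) < 0.5), n_obs, P)
      n_sweeps <- burnin + thin - 1L
      if (n_obs > 0L) {
        for (sweep in seq_len(n_sweeps)) {
          for (j in seq_len(P)) {
            eta <- model$thresholds[j] + X %*% model$weights[, j]
            X[, j] <- as.numeric(stats::runif(n_obs) < stats::plogis(eta))
          }
        }
      }
      matrix(as.integer(X), n_obs, P)
    })
  }
  colnames(out) <- paste0("V", seq_len(P))
  out
}

# Checks a dataset is a 0/1 matrix; returns it as numeric.
check_binary_matrix <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || !all(data %in% c(0, 1)))
    stop("'data' must be a matrix of 0/1 values without missing entries")
  storage.mode(data) <- "double"
  data
}
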