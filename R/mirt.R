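#' Construct a multidimensional item response (MIRT) model
#'
#' A compensatory logistic MIRT model for \eqn{P} binary items and \eqn{K}
#' latent traits: given latent vector \eqn{\theta \sim N(0, \Sigma)}, item
#' \eqn{j} is Bernoulli with success probability
#' \eqn{\mathrm{logit}^{-1}(a_j^\top \theta + b_j)}, where row \eqn{a_j} of
#' the loading matrix holds the item discriminations (logit units per latent
#' SD) and \eqn{b_j} is the intercept (\eqn{b = -}difficulty under the 2PL
#' convention). No 1.7 scaling constant is used: the logistic link is the
#' one under which the Ising/latent-trait correspondence holds.
#'
#' @param loadings \eqn{P \times K} numeric matrix of discriminations.
#' @param intercepts Length-\eqn{P} numeric vector of intercepts.
#' @param latent_cov \eqn{K \times K} symmetric positive-semidefinite
#'   latent covariance with unit diagonal (latent traits have SD 1).
#' @return An object of class \code{"mirt_model"}.
#' @export
mirt_model <- function(loadings, intercepts, latent_cov) {
  loadings <- as.matrix(loadings)
  latent_cov <- as.matrix(latent_cov)
  intercepts <- as.numeric(intercepts)
  P <- nrow(loadings); K <- ncol(loadings)
  if (length(intercepts) != P)
    stop("'intercepts' must have one entry per item")
  if (!identical(dim(latent_cov), as.integer(c(K, K))))
    stop("'latent_cov' must be ", K, "x", K)
  if (!isTRUE(all.equal(latent_cov, t(latent_cov), tolerance = 1e-12)))
    stop("'latent_cov' must be symmetric")
  if (max(abs(diag(latent_cov) - 1)) > 1e-12)
    stop("'latent_cov' must have unit diagonal (latents are standardized)")
  ev <- eigen(latent_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("'latent_cov' must be positive semidefinite")
  structure(
    list(n_items = P, n_latents = K, loadings = loadings,
         intercepts = intercepts, latent_cov = latent_cov),
    class = "mirt_model"
  )
}

#' The two-disorder comorbidity MIRT generator
#'
#' Builds the 19-symptom generating model for two comorbid disorders,
#' dysthymia (items D1-D10) and generalized anxiety disorder (items G1-G9),
#' with 8 latent variables:
#' \itemize{
#'   \item Traits 1-2: the two disorder traits, correlation 0.55, every
#'     item loading 1 on its own trait (interchangeable symptoms) and all
#'     difficulties 0.
#'   \item Factors 3-4: mutual-exclusivity contrasts, loading +1.1 and
#'     -1.1 on the mutually exclusive symptom pairs (D2, D3) and (G6, G7).
#'   \item Factors 5-8: bridge factors loading 0.75 on each of the shared
#'     symptom pairs (D7, G6), (D8, G7), (D9, G8), (D10, G9).
#' }
#' Factors 3-8 are orthogonal to each other and to the traits; all latents
#' have SD 1. No skip structure is imposed. The Ising network this model
#' induces is dense, with two disorder clusters, negative edges inside the
#' exclusive pairs and positive bridge edges between the shared pairs.
#'
#' @return A [mirt_model()] with 19 items, 8 latents and 31 nonzero
#'   loadings.
#' @examples
#' m <- build_comorbidity_mirt()
#' m$loadings["D2", 3]  #  1.1
#' m$loadings["D3", 3]  # -1.1
#' @export
build_comorbidity_mirt <- function() {
  items <- c(paste0("D", 1:10), paste0("G", 1:9))
  A <- matrix(0, 19, 8, dimnames = list(items, NULL))
  A[1:10, 1] <- 1            # dysthymia trait
  A[11:19, 2] <- 1           # GAD trait
  A["D2", 3] <- 1.1; A["D3", 3] <- -1.1   # exclusivity, dysthymia
  A["G6", 4] <- 1.1; A["G7", 4] <- -1.1   # exclusivity, GAD
  bridges <- list(c("D7", "G6"), c("D8", "G7"), c("D9", "G8"), c("D10", "G9"))
  for (k in seq_along(bridges)) A[bridges[[k]], 4 + k] <- 0.75
  S <- diag(8)
  S[1, 2] <- S[2, 1] <- 0.55
  mirt_model(A, rep(0, 19), S)
}

#' Simulate binary responses from a MIRT model
#'
#' Per row, draws \eqn{\theta} from a zero-mean multivariate normal with the
#' model's latent covariance, then each item independently from
#' Bernoulli(\eqn{\mathrm{logit}^{-1}(a_j^\top\theta + b_j)}).
#'
#' @param model A [mirt_model()].
#' @param n_obs Number of observations.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A 0/1 integer matrix with item names as column names.
#' @export
sample_mirt <- function(model, n_obs, seed) {
  stopifnot(inherits(model, "mirt_model"))
  if (length(n_obs) != 1L || is.na(n_obs) || n_obs < 0)
    stop("'n_obs' must be a single nonnegative integer")
  n_obs <- as.integer(n_obs)
  P <- model$n_items; K <- model$n_latents
  if (n_obs == 0L) {
    out <- matrix(integer(0), 0L, P)
    colnames(out) <- rownames(model$loadings) %||% paste0("V", seq_len(P))
    return(out)
  }
  ed <- eigen(model$latent_cov, symmetric = TRUE)
  if (min(ed$values) < -1e-10) stop("latent covariance is not PSD")
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), K)
  out <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n_obs * K), n_obs, K)
    theta <- Z %*% t(L)
    eta <- theta %*% t(model$loadings) +
      matrix(model$intercepts, n_obs, P, byrow = TRUE)
    matrix(as.integer(stats::runif(n_obs * P) < stats::plogis(eta)), n_obs, P)
  })
  colnames(out) <- rownames(model$loadings) %||% paste0("V", seq_len(P))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasch representation of a Curie-Weiss model
#'
#' A Curie-Weiss model with common nonnegative weight \eqn{w} and common
#' threshold \eqn{\tau} is exactly a unidimensional Rasch model marginalized
#' over a latent variable. Writing \eqn{s = \sum_i x_i}, the pairwise term
#' is \eqn{\sum_{i<j} w x_i x_j = (w/2)(s^2 - s)}, and the Gaussian identity
#' \eqn{\int N(t; 0, w)\, e^{ts}\,dt = e^{w s^2/2}} linearizes the
#' quadratic: the model is a Rasch model with common item easiness
#' \eqn{b = \tau - w/2} and a latent variable of variance \eqn{w}. The
#' latent density under which the equivalence is exact is not the plain
#' normal but the tilted density
#' \eqn{g(t) \propto (1 + e^{b+t})^P\, N(t; 0, w)}; see
#' [rasch_pattern_distribution()].
#'
#' @param model A Curie-Weiss [ising_model()] (uniform weights
#'   \eqn{w \ge 0}, uniform thresholds).
#' @return An object of class \code{"rasch_representation"} with elements
#'   \code{node_count}, \code{easiness} and \code{latent_variance}.
#' @examples
#' rasch_representation(make_curie_weiss(8, 0.2))
#' @export
rasch_representation <- function(model) {
  stopifnot(inherits(model, "ising_model"))
  P <- model$node_count
  off <- model$weights[upper.tri(model$weights)]
  w <- if (length(off)) off[1] else 0
  if (length(off) && max(abs(off - w)) > 1e-12)
    stop("model is not Curie-Weiss: edge weights are not uniform")
  tau <- model$thresholds[1]
  if (max(abs(model$thresholds - tau)) > 1e-12)
    stop("model is not Curie-Weiss: thresholds are not uniform")
  if (w < 0)
    stop("the Rasch representation needs a nonnegative common weight ",
         "(latent variance w = ", format(w), " would be negative)")
  structure(
    list(node_count = P, easiness = tau - w / 2, latent_variance = w),
    class = "rasch_representation"
  )
}

#' Pattern distribution of a Rasch representation
#'
#' Evaluates the marginal probability of every response pattern under the
#' Rasch representation of a Curie-Weiss model,
#' \deqn{\Pr(x) = \int \prod_j \mathrm{Bern}\big(x_j;\,
#'   \mathrm{logit}^{-1}(b + t)\big)\, g(t)\, dt,}
#' with the exact mixing density
#' \eqn{g(t) \propto (1 + e^{b+t})^P\, N(t; 0, w)} that the
#' Gaussian-linearization construction induces. The integral is evaluated by
#' Gauss-Hermite quadrature and the result normalized; with the tilted
#' density it reproduces [pattern_distribution()] of the originating
#' Curie-Weiss model to machine precision. (Integrating against the plain
#' normal \eqn{N(0, w)} instead gives a genuinely different distribution --
#' that is the marginal-vs-posterior distinction between the two model
#' families.)
#'
#' @param rep A [rasch_representation()].
#' @param quad_points Number of Gauss-Hermite nodes (default 61, minimum 11).
#' @return A \code{"pattern_distribution"}, indexed like
#'   [pattern_distribution()].
#' @export
rasch_pattern_distribution <- function(rep, quad_points = 61L) {
  stopifnot(inherits(rep, "rasch_representation"))
  if (quad_points < 11L) stop("'quad_points' must be at least 11")
  P <- rep$node_count
  if (P > .enumeration_limit)
    stop("pattern enumeration is limited to ", .enumeration_limit, " nodes")
  s <- rowSums(pattern_matrix(P))
  b <- rep$easiness
  v <- rep$latent_variance
  if (v == 0) {
    pr <- stats::plogis(b)
    p <- pr^s * (1 - pr)^(P - s)
  } else {
    gh <- pracma::gaussHermite(as.integer(quad_points))
    t_nodes <- sqrt(2 * v) * gh$x
    # tilt N(0, v) by (1 + e^(b+t))^P, in logs for stability
    log_wt <- log(gh$w / sqrt(pi)) + P * log1p(exp(b + t_nodes))
    wt <- exp(log_wt - max(log_wt))
    wt <- wt / sum(wt)
    # pattern prob per node: logistic(b + t)^s (1 - logistic)^(P - s)
    p <- vapply(seq_along(t_nodes), function(k) {
      pr <- stats::plogis(b + t_nodes[k])
      pr^s * (1 - pr)^(P - s)
    }, numeric(length(s))) %*% wt
    p <- drop(p)
  }
  p <- p / sum(p)
  structure(list(node_count = P, probabilities = p),
            class = "pattern_distribution")
}
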