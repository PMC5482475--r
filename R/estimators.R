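#' Estimated Ising network with method metadata
#'
#' Container returned by every estimator in the package: the estimated
#' [ising_model()] together with the method label and whatever tuning
#' metadata the method produces (symmetrization rule, EBIC \eqn{\gamma},
#' rank, selected per-node penalties, elastic-net mixing, convergence
#' flags).
#'
#' @param model The estimated [ising_model()].
#' @param method One of \code{"nodewise"}, \code{"elasso"},
#'   \code{"loglinear"}, \code{"lowrank"}, \code{"elasticnet"}.
#' @param ... Method metadata stored alongside (e.g. \code{rule},
#'   \code{gamma}, \code{rank}, \code{selected_penalties}, \code{mixing},
#'   \code{converged}, \code{iterations}).
#' @return An object of class \code{"ising_fit"}.
#' @export
ising_fit <- function(model, method, ...) {
  stopifnot(inherits(model, "ising_model"))
  method <- match.arg(method,
    c("nodewise", "elasso", "loglinear", "lowrank", "elasticnet"))
  meta <- list(...)
  if (!is.null(meta$selected_penalties) &&
      any(meta$selected_penalties < 0, na.rm = TRUE))
    stop("selected penalties must be nonnegative")
  structure(c(list(model = model, method = method), meta),
            class = "ising_fit")
}

#' @export
print.ising_fit <- function(x, ...) {
  cat("Ising fit [", x$method, "]: ", sep = "")
  print(x$model)
  invisible(x)
}

#' Symmetrize a matrix of directed nodewise coefficients
#'
#' Nodewise logistic regression yields two coefficients per node pair (node
#' i regressed on j, and j on i); a single undirected edge weight is formed
#' by one of three rules:
#' \describe{
#'   \item{AND}{mean of the two coefficients if \emph{both} are nonzero,
#'     else 0 -- the conservative rule used with LASSO selection.}
#'   \item{OR}{mean of the two coefficients (zeros included in the mean) if
#'     \emph{either} is nonzero, else 0.}
#'   \item{average}{unconditional mean -- appropriate for unregularized
#'     fits, where coefficients are never exactly zero.}
#' }
#'
#' @param in_weights Square numeric matrix with zero diagonal; entry
#'   \code{[j, l]} is the coefficient of node \code{l} in the regression of
#'   node \code{j}.
#' @param rule \code{"AND"}, \code{"OR"} or \code{"average"}.
#' @return A symmetric matrix with zero diagonal.
#' @examples
#' m <- matrix(c(0, 0.3, 0.1, 0), 2, 2, byrow = TRUE)
#' symmetrize(m, "AND")      # both nonzero: mean 0.2
#' @export
symmetrize <- function(in_weights, rule = c("AND", "OR", "average")) {
  rule <- match.arg(rule)
  in_weights <- as.matrix(in_weights)
  if (nrow(in_weights) != ncol(in_weights))
    stop("'in_weights' must be square")
  if (any(diag(in_weights) != 0))
    stop("'in_weights' must have a zero diagonal")
  avg <- (in_weights + t(in_weights)) / 2
  out <- switch(rule,
    AND     = avg * ((in_weights != 0) & (t(in_weights) != 0)),
    OR      = avg * ((in_weights != 0) | (t(in_weights) != 0)),
    average = avg)
  diag(out) <- 0
  out
}

# Shared input checks for the nodewise estimators. Errors name the
# offending column since a constant symptom makes its regressions
# ill-posed.
check_estimation_input <- function(data, need_n_ge_p = FALSE) {
  data <- check_binary_matrix(data)
  P <- ncol(data)
  if (P < 2L) stop("need at least 2 nodes to estimate a network")
  cm <- colMeans(data)
  if (any(cm == 0 | cm == 1)) {
    bad <- which(cm == 0 | cm == 1)[1]
    stop("column ", colnames(data)[bad] %||% bad,
         " (node ", bad, ") is constant; its parameters are inestimable")
  }
  if (need_n_ge_p && nrow(data) < P)
    stop("unregularized estimation needs at least as many rows as nodes (n = ",
         nrow(data), ", P = ", P, ")")
  data
}

# |coefficient| beyond this on the logit scale is treated as (quasi-)perfect
# separation / an infinite MLE.
.separation_limit <- 30

#' Unregularized nodewise (pseudolikelihood) estimation
#'
#' Fits, for each node, a maximum-likelihood logistic regression of that
#' node on all remaining nodes. The intercepts become the thresholds and
#' the two directed coefficients per pair are combined by [symmetrize()]
#' (default \code{"average"}, since ML coefficients are never exactly
#' zero). This is the consistent but high-variance baseline: with
#' \eqn{P(P-1)/2} free edge parameters it shows strong spurious variation
#' at small samples.
#'
#' @param data 0/1 matrix, observations in rows; needs \eqn{n \ge P} and no
#'   constant columns.
#' @param rule Symmetrization rule, default \code{"average"}.
#' @return An [ising_fit()] with method \code{"nodewise"}.
#' @export
fit_nodewise <- function(data, rule = "average") {
  data <- check_estimation_input(data, need_n_ge_p = TRUE)
  P <- ncol(data)
  B <- matrix(0, P, P)
  thresholds <- numeric(P)
  for (j in seq_len(P)) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, data[, -j, drop = FALSE]), data[, j],
                     family = stats::binomial()))
    co <- fit$coefficients
    if (anyNA(co) || !fit$converged ||
        max(abs(co[-1])) > .separation_limit)
      stop("logistic regression for node ", j,
           " did not yield a finite estimate (perfect separation?)")
    thresholds[j] <- co[1]
    B[j, -j] <- co[-1]
  }
  W <- symmetrize(B, rule)
  ising_fit(ising_model(thresholds, W), "nodewise", rule = rule,
            converged = TRUE)
}

#' Extended Bayesian Information Criterion for a nodewise fit
#'
#' \deqn{\mathrm{EBIC}_\gamma = -2\,\ell + k \ln n + 2\gamma\, k \ln(P-1),}
#' where \eqn{\ell} is the logistic log-likelihood of one node's
#' regression, \eqn{k} the number of active (nonzero) edge coefficients in
#' it, \eqn{n} the sample size and \eqn{P - 1} the number of candidate
#' predictors. The intercept is not counted in \eqn{k} (the eLasso
#' convention). \eqn{\gamma = 0} recovers the ordinary BIC; the eLasso
#' default is \eqn{\gamma = 0.25}.
#'
#' @param loglik Log-likelihood \eqn{\ell} at the fit.
#' @param n_active_edges Number of nonzero edge coefficients \eqn{k}.
#' @param n_obs Sample size \eqn{n \ge 1}.
#' @param n_nodes Number of nodes \eqn{P \ge 2} in the network.
#' @param gamma EBIC hyperparameter \eqn{\gamma \ge 0}.
#' @return The EBIC value (smaller is better).
#' @examples
#' ebic_score(-100, 3, 1000, 10, 0.25)  # 200 + 3 log 1000 + 1.5 log 9
#' @export
ebic_score <- function(loglik, n_active_edges, n_obs, n_nodes, gamma) {
  stopifnot(n_obs >= 1, n_nodes >= 2, n_active_edges >= 0)
  -2 * loglik + n_active_edges * log(n_obs) +
    2 * gamma * n_active_edges * log(n_nodes - 1)
}

#' Unregularized estimation via a Poisson log-linear model
#'
#' Cross-classifies the observations into the full \eqn{2^P} contingency
#' table and fits a Poisson log-linear model containing all main effects
#' and all two-way interactions under \{0, 1\} dummy coding. This is the
#' Ising model written as a log-linear model: the two-way interaction
#' coefficients are the edge weights and the main effects the thresholds,
#' estimated by full-information maximum likelihood (no symmetrization
#' needed).
#'
#' @param data 0/1 matrix with at most 15 columns (the table has \eqn{2^P}
#'   cells).
#' @param smooth Optional constant added to every cell count (default 0 --
#'   no silent smoothing). Structural zero margins make some parameters
#'   infinite; with \code{smooth = 0} that is reported as an error.
#' @return An [ising_fit()] with method \code{"loglinear"}.
#' @examples
#' # saturated 2x2: the edge weight is the log odds ratio
#' x <- rbind(matrix(0, 40, 2),
#'            matrix(c(0, 1), 20, 2, byrow = TRUE),
#'            matrix(c(1, 0), 20, 2, byrow = TRUE),
#'            matrix(1, 20, 2))
#' fit_loglinear(x)$model$weights[1, 2]  # log((40 * 20) / (20 * 20)) = log 2
#' @export
fit_loglinear <- function(data, smooth = 0) {
  data <- check_binary_matrix(data)
  P <- ncol(data)
  if (P > 15L)
    stop("the log-linear route enumerates 2^P cells and is limited to 15 ",
         "nodes; got ", P)
  if (P < 2L) stop("need at least 2 nodes")
  idx <- as.integer(data %*% 2^(seq_len(P) - 1))
  counts <- tabulate(idx + 1L, nbins = 2L^P) + smooth
  Xp <- pattern_matrix(P)
  pairs <- which(upper.tri(diag(P)), arr.ind = TRUE)
  Xint <- Xp[, pairs[, 1], drop = FALSE] * Xp[, pairs[, 2], drop = FALSE]
  design <- cbind(1, Xp, Xint)
  fit <- suppressWarnings(
    stats::glm.fit(design, counts, family = stats::poisson(),
                   control = stats::glm.control(maxit = 100)))
  co <- fit$coefficients
  # Poisson IRLS walks a diverging coefficient to -Inf only slowly; a
  # magnitude this large on the log scale already signals a zero margin.
  if (anyNA(co) || !fit$converged || max(abs(co[-1])) > 20)
    stop("log-linear MLE is not finite: some margin of the contingency ",
         "table is zero (set 'smooth' to a positive constant to regularize)")
  thresholds <- co[2:(P + 1)]
  W <- matrix(0, P, P)
  W[upper.tri(W)] <- co[-(1:(P + 1))]
  W <- W + t(W)
  ising_fit(ising_model(thresholds, W), "loglinear", converged = TRUE,
            smooth = smooth)
}
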