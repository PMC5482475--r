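# glmnet needs >= 2 predictor columns; for P = 2 networks a node has only
# one candidate predictor, so a zero column is appended and excluded from
# the model.
glmnet_binomial <- function(X, y, ...) {
  if (ncol(X) >= 2L) {
    glmnet::glmnet(X, y, family = "binomial", ...)
  } else {
    fit <- glmnet::glmnet(cbind(X, pad__ = 0), y, family = "binomial",
                          exclude = 2L, ...)
    fit$beta <- fit$beta[1, , drop = FALSE]
    fit
  }
}

binomial_loglik <- function(y, eta) sum(y * eta - log1p(exp(eta)))

#' L1-penalized logistic regularization path for one node
#'
#' Computes the LASSO path for the logistic regression of a binary response
#' on binary predictors, over a log-spaced penalty grid running from
#' \eqn{\lambda_{\max}} -- the smallest penalty at which every edge
#' coefficient is exactly zero, \eqn{\max_j |x_j'(y - \bar y)| / n} for an
#' unpenalized intercept -- down to
#' \eqn{\lambda_{\max} \cdot} \code{lambda_min_ratio}. The log-likelihood
#' and the EBIC are recorded at every path point. Predictors are not
#' standardized (they are already on the common 0/1 scale).
#'
#' @param y Binary response vector (one node's column).
#' @param X Binary matrix of the remaining nodes' columns.
#' @param n_lambdas Path length (default 100).
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty
#'   (default 0.01).
#' @param gamma EBIC hyperparameter used for the recorded scores
#'   (default 0.25).
#' @param node_index Optional label of the node the path belongs to.
#' @return An object of class \code{"regularization_path"}: a list with
#'   \code{penalties} (strictly decreasing), \code{coefficients} (one
#'   column per path point), \code{intercepts}, \code{loglikelihoods},
#'   \code{ebic_scores}, \code{gamma}, \code{node_index}.
#' @export
l1_logistic_path <- function(y, X, n_lambdas = 100L, lambda_min_ratio = 0.01,
                             gamma = 0.25, node_index = NA_integer_) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, n_lambdas >= 2, lambda_min_ratio > 0,
            lambda_min_ratio < 1)
  if (stats::var(y) == 0)
    stop("response is constant; the path is undefined")
  if (any(apply(X, 2, stats::var) == 0))
    stop("a predictor column is constant; the path is undefined")
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambdas))
  fit <- glmnet_binomial(X, y, lambda = lambdas, standardize = FALSE,
                         thresh = 1e-10)
  beta <- unname(as.matrix(fit$beta))
  a0 <- unname(as.numeric(fit$a0))
  # the top of the grid satisfies the zero-coefficient KKT condition exactly
  beta[, 1] <- 0
  a0[1] <- stats::qlogis(mean(y))
  ll <- vapply(seq_len(n_lambdas), function(k)
    binomial_loglik(y, a0[k] + drop(X %*% beta[, k])), numeric(1))
  kk <- unname(colSums(beta != 0))
  ebic <- ebic_score(ll, kk, n, ncol(X) + 1L, gamma)
  structure(
    list(node_index = node_index, penalties = lambdas, coefficients = beta,
         intercepts = a0, loglikelihoods = ll, ebic_scores = ebic,
         gamma = gamma),
    class = "regularization_path"
  )
}

#' eLasso: nodewise L1 logistic regression with EBIC selection
#'
#' The sparsity-assuming estimator: for each node an L1-penalized logistic
#' regression path ([l1_logistic_path()]) is computed and the path point
#' minimizing the EBIC ([ebic_score()]) is selected (ties go to the larger
#' penalty, i.e. the sparser model). The directed coefficient matrix is
#' then combined with [symmetrize()]; defaults \eqn{\gamma = 0.25} and the
#' AND-rule. Because the L1 penalty sets coefficients exactly to zero,
#' the result is sparse whatever the generating network looked like: high
#' specificity always, but low sensitivity whenever the truth is dense.
#'
#' @param data 0/1 matrix, observations in rows; no constant columns.
#' @param gamma EBIC hyperparameter (default 0.25; 0 gives BIC selection).
#' @param rule \code{"AND"} (default) or \code{"OR"}.
#' @param n_lambdas,lambda_min_ratio Path grid, as [l1_logistic_path()].
#' @return An [ising_fit()] with method \code{"elasso"}; carries the
#'   selected per-node penalties in \code{selected_penalties}.
#' @export
fit_elasso <- function(data, gamma = 0.25, rule = c("AND", "OR"),
                       n_lambdas = 100L, lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  data <- check_estimation_input(data)
  P <- ncol(data)
  B <- matrix(0, P, P)
  thresholds <- numeric(P)
  sel_lambda <- numeric(P)
  for (j in seq_len(P)) {
    path <- l1_logistic_path(data[, j], data[, -j, drop = FALSE],
                             n_lambdas = n_lambdas,
                             lambda_min_ratio = lambda_min_ratio,
                             gamma = gamma, node_index = j)
    # penalties are strictly decreasing, so the first minimum is the
    # sparsest among ties
    best <- which.min(path$ebic_scores)
    B[j, -j] <- path$coefficients[, best]
    thresholds[j] <- path$intercepts[best]
    sel_lambda[j] <- path$penalties[best]
  }
  W <- symmetrize(B, rule)
  ising_fit(ising_model(thresholds, W), "elasso", rule = rule,
            gamma = gamma, selected_penalties = sel_lambda,
            converged = TRUE)
}

#' Elastic-net estimation with cross-validated tuning
#'
#' Per node, a two-dimensional grid over the elastic-net mixing parameter
#' \eqn{\alpha} (1 = LASSO, 0 = ridge) and the penalty \eqn{\lambda} is
#' searched by K-fold cross-validation of the logistic deviance; the fold
#' assignment is fixed by \code{seed} and shared across nodes and
#' \eqn{\alpha} values. The directed coefficients at the selected pair are
#' combined with the AND-rule on exact zeros (mean when both are nonzero,
#' 0 otherwise); when the data prefer \eqn{\alpha} near 0 (ridge) no
#' coefficient is exactly zero and the selected network is dense.
#'
#' @param data 0/1 matrix, observations in rows; no constant columns.
#' @param mixing_grid Candidate \eqn{\alpha} values in \[0, 1\]
#'   (default \code{seq(0, 1, by = 0.1)}).
#' @param n_lambdas Path length per \eqn{\alpha} (default 50).
#' @param folds Number of cross-validation folds (default 10); needs
#'   \eqn{n \ge} \code{folds}.
#' @param seed Integer seed fixing the fold assignment.
#' @return An [ising_fit()] with method \code{"elasticnet"}; carries the
#'   selected \eqn{\alpha} per node in \code{mixing} and the selected
#'   \eqn{\lambda} in \code{selected_penalties}.
#' @export
fit_elasticnet_cv <- function(data, mixing_grid = seq(0, 1, by = 0.1),
                              n_lambdas = 50L, folds = 10L, seed = 1) {
  data <- check_estimation_input(data)
  if (any(mixing_grid < 0 | mixing_grid > 1))
    stop("'mixing_grid' values must lie in [0, 1]")
  if (folds < 2) stop("'folds' must be at least 2")
  n <- nrow(data)
  P <- ncol(data)
  if (n < folds) stop("need at least as many observations as folds")
  foldid <- with_seed(seed_stream(seed, "cv-folds"),
                      sample(rep_len(seq_len(folds), n)))
  B <- matrix(0, P, P)
  thresholds <- numeric(P)
  mixing <- numeric(P)
  sel_lambda <- numeric(P)
  for (j in seq_len(P)) {
    y <- data[, j]
    X <- data[, -j, drop = FALSE]
    best <- NULL
    for (alpha in mixing_grid) {
      cv <- suppressWarnings(glmnet::cv.glmnet(
        if (ncol(X) >= 2L) X else cbind(X, pad__ = 0),
        y, family = "binomial", alpha = alpha, nlambda = n_lambdas,
        foldid = foldid, standardize = FALSE, type.measure = "deviance",
        exclude = if (ncol(X) >= 2L) integer(0) else 2L))
      k <- which.min(cv$cvm)
      if (is.null(best) || cv$cvm[k] < best$cvm) {
        co <- as.numeric(stats::coef(cv$glmnet.fit, s = cv$lambda[k]))
        best <- list(cvm = cv$cvm[k], alpha = alpha, lambda = cv$lambda[k],
                     intercept = co[1], beta = co[1 + seq_len(ncol(X))])
      }
    }
    B[j, -j] <- best$beta
    thresholds[j] <- best$intercept
    mixing[j] <- best$alpha
    sel_lambda[j] <- best$lambda
  }
  W <- symmetrize(B, "AND")
  ising_fit(ising_model(thresholds, W), "elasticnet",
            mixing = mixing, selected_penalties = sel_lambda,
            folds = folds, converged = TRUE)
}
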