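#' Edge-recovery metrics of an estimated network against the truth
#'
#' Compares the strict upper triangles of the two weight matrices over the
#' \eqn{P(P-1)/2} node pairs. An edge is "present" iff its absolute weight
#' exceeds \code{zero_tol}; the sign is ignored, since a negative edge is
#' still an edge. Reports the confusion counts, sensitivity (fraction of
#' true edges detected), specificity (fraction of true non-edges correctly
#' left out), mean absolute weight error, the Pearson correlation of the
#' weight vectors, and the estimated density. Sensitivity, specificity and
#' correlation are \code{NA} when undefined (no true edges, no true
#' non-edges, or a zero-variance weight vector).
#'
#' @param true_model,est_model [ising_model()] objects with equal node
#'   counts.
#' @param zero_tol Absolute weight below which an edge counts as absent
#'   (default 1e-8, separating the structural zeros of L1 selection from
#'   the numerically small weights of dense estimators).
#' @return A list of class \code{"recovery_metrics"}: \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{sensitivity}, \code{specificity},
#'   \code{weight_mae}, \code{weight_correlation},
#'   \code{estimated_density}.
#' @export
recovery_metrics <- function(true_model, est_model, zero_tol = 1e-8) {
  stopifnot(inherits(true_model, "ising_model"),
            inherits(est_model, "ising_model"))
  if (true_model$node_count != est_model$node_count)
    stop("models have different node counts (",
         true_model$node_count, " vs ", est_model$node_count, ")")
  ut <- upper.tri(true_model$weights)
  wt <- true_model$weights[ut]
  we <- est_model$weights[ut]
  true_edge <- abs(wt) > zero_tol
  est_edge <- abs(we) > zero_tol
  tp <- sum(true_edge & est_edge)
  fp <- sum(!true_edge & est_edge)
  tn <- sum(!true_edge & !est_edge)
  fn <- sum(true_edge & !est_edge)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    weight_mae = mean(abs(we - wt)),
    weight_correlation =
      if (stats::sd(wt) > 0 && stats::sd(we) > 0) stats::cor(wt, we)
      else NA_real_,
    estimated_density = mean(est_edge)
  ), class = "recovery_metrics")
}

#' Network density
#'
#' Fraction of the \eqn{P(P-1)/2} node pairs whose absolute weight exceeds
#' \code{zero_tol}.
#'
#' @param model An [ising_model()].
#' @param zero_tol Absolute-weight threshold (default 1e-8).
#' @return A number in \[0, 1\].
#' @export
network_density <- function(model, zero_tol = 1e-8) {
  stopifnot(inherits(model, "ising_model"))
  w <- model$weights[upper.tri(model$weights)]
  if (length(w) == 0) return(0)
  mean(abs(w) > zero_tol)
}

#' Within- minus between-cluster mean edge weight
#'
#' Quantifies how strongly a node partition (e.g. the two disorders in a
#' comorbidity network) clusters the network: the mean weight over
#' within-block pairs minus the mean weight over between-block pairs.
#' Known cross-cluster pairs that are not evidence against clustering --
#' the bridge pairs -- can be excluded from the between-block mean.
#'
#' @param model An [ising_model()].
#' @param partition Vector of block labels, one per node.
#' @param excluded_pairs Optional two-column matrix of node index pairs
#'   (must be between-block pairs) excluded from the between-block mean.
#' @return Within-mean minus between-mean; \code{NA} if either pair set is
#'   empty.
#' @export
clustering_contrast <- function(model, partition, excluded_pairs = NULL) {
  stopifnot(inherits(model, "ising_model"))
  P <- model$node_count
  if (length(partition) != P)
    stop("'partition' must have one label per node")
  pairs <- which(upper.tri(model$weights), arr.ind = TRUE)
  within <- partition[pairs[, 1]] == partition[pairs[, 2]]
  excluded <- rep(FALSE, nrow(pairs))
  if (!is.null(excluded_pairs)) {
    excluded_pairs <- as.matrix(excluded_pairs)
    for (r in seq_len(nrow(excluded_pairs))) {
      i <- min(excluded_pairs[r, ]); j <- max(excluded_pairs[r, ])
      hit <- pairs[, 1] == i & pairs[, 2] == j
      if (!any(hit)) stop("excluded pair (", i, ", ", j, ") is not a node pair")
      if (within[hit]) stop("excluded pair (", i, ", ", j,
                            ") is not a between-block pair")
      excluded[hit] <- TRUE
    }
  }
  w <- model$weights[upper.tri(model$weights)]
  if (!any(within) || !any(!within & !excluded)) return(NA_real_)
  mean(w[within]) - mean(w[!within & !excluded])
}
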