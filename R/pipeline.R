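.study_kinds <- c("dense_truth", "sparse_truth", "mirt_truth")
.method_names <- c("nodewise", "elasso", "rank_k", "loglinear", "elasticnet")

#' Configure a simulation study
#'
#' Validated configuration for [run_study()]. Three designs are available:
#' \describe{
#'   \item{dense_truth}{truth is a Curie-Weiss network, all edges 0.2 --
#'     dense and rank 1.}
#'   \item{sparse_truth}{truth is a random network with 20\% of the pairs
#'     at weight 0.2.}
#'   \item{mirt_truth}{data come from the two-disorder comorbidity MIRT
#'     model ([build_comorbidity_mirt()], 19 items); the reference network
#'     is a proxy truth: an unregularized Ising fit on \code{proxy_n}
#'     draws from the generator.}
#' }
#' Per replication one dataset of \code{max(n_grid)} rows is simulated and
#' every method is fitted on its first-\eqn{n} prefixes, so the smaller
#' samples are nested inside the larger ones.
#'
#' @param study One of \code{"dense_truth"}, \code{"sparse_truth"},
#'   \code{"mirt_truth"}.
#' @param node_count Nodes for the Ising truths (default 10; fixed at 19
#'   for \code{mirt_truth}).
#' @param n_grid Strictly increasing sample sizes (default
#'   \code{c(100, 250, 500, 1000)}).
#' @param reps Number of replications (default 20).
#' @param methods Subset of \code{"nodewise"}, \code{"elasso"},
#'   \code{"rank_k"}, \code{"loglinear"}, \code{"elasticnet"}.
#' @param gamma EBIC hyperparameter for eLasso (default 0.25).
#' @param rank Rank for the low-rank method (default 2).
#' @param proxy_n Sample size of the proxy-truth fit for
#'   \code{mirt_truth} (default 200000, a scaled-down stand-in for an
#'   effectively infinite sample).
#' @param seed Master seed; every random component derives its own stream
#'   from it via [seed_stream()].
#' @param zero_tol Edge-presence threshold for the metrics (default 1e-8).
#' @param edge_weight Common true edge weight (default 0.2).
#' @param density Edge density of the sparse truth (default 0.2).
#' @return A validated list of class \code{"study_config"}.
#' @export
study_config <- function(study, node_count = 10L,
                         n_grid = c(100L, 250L, 500L, 1000L),
                         reps = 20L,
                         methods = c("nodewise", "elasso", "rank_k"),
                         gamma = 0.25, rank = 2L, proxy_n = 200000L,
                         seed = 1L, zero_tol = 1e-8,
                         edge_weight = 0.2, density = 0.2) {
  study <- match.arg(study, .study_kinds)
  methods <- match.arg(methods, .method_names, several.ok = TRUE)
  if (study == "mirt_truth") node_count <- 19L
  node_count <- as.integer(node_count)
  n_grid <- as.integer(n_grid)
  if (length(n_grid) < 1 || any(n_grid < 1) ||
      any(diff(n_grid) <= 0))
    stop("'n_grid' must be strictly increasing positive integers")
  if (reps < 1) stop("'reps' must be >= 1")
  if ("loglinear" %in% methods && node_count > 15L)
    stop("method 'loglinear' enumerates 2^P cells and cannot run at P = ",
         node_count, "; drop it or reduce 'node_count'")
  if (study != "mirt_truth" && node_count > .enumeration_limit)
    stop("exact Ising simulation is limited to ", .enumeration_limit,
         " nodes")
  structure(list(
    study = study, node_count = node_count, n_grid = n_grid,
    reps = as.integer(reps), methods = methods, gamma = gamma,
    rank = as.integer(rank), proxy_n = as.integer(proxy_n),
    seed = as.integer(seed), zero_tol = zero_tol,
    edge_weight = edge_weight, density = density
  ), class = "study_config")
}

fit_one_method <- function(method, data, config) {
  switch(method,
    nodewise   = fit_nodewise(data),
    elasso     = fit_elasso(data, gamma = config$gamma),
    rank_k     = fit_low_rank(data, rank = config$rank,
                              seed = seed_stream(config$seed, "lowrank")),
    loglinear  = fit_loglinear(data),
    elasticnet = fit_elasticnet_cv(data,
                                   seed = seed_stream(config$seed, "cv")),
    stop("unknown method: ", method))
}

#' Run a configured simulation study
#'
#' Builds the true network, simulates \code{reps} datasets of
#' \code{max(n_grid)} rows, fits every configured method on the first-n
#' prefixes of each dataset, and scores each fit against the truth with
#' [recovery_metrics()]. For \code{mirt_truth} the reference is the proxy
#' truth: an unregularized Ising fit ([fit_loglinear()] when \eqn{P \le
#' 15}, else [fit_nodewise()]) on \code{proxy_n} fresh draws from the MIRT
#' generator. Fully deterministic given the config (all streams derive
#' from \code{config$seed}).
#'
#' @param config A [study_config()].
#' @param keep_fits Keep every fitted model in the result (default TRUE;
#'   set FALSE to save memory in large grids).
#' @return A list of class \code{"study_result"}: \code{config},
#'   \code{truth} (the reference [ising_model()]), \code{records} (one
#'   data.frame row per method x n x rep) and \code{fits} (nested list of
#'   [ising_fit()] objects, when kept).
#' @export
run_study <- function(config, keep_fits = TRUE) {
  stopifnot(inherits(config, "study_config"))
  P <- config$node_count
  n_max <- max(config$n_grid)
  truth <- switch(config$study,
    dense_truth = make_curie_weiss(P, config$edge_weight, 0),
    sparse_truth = make_random_sparse(P, config$density, config$edge_weight,
                                      0, seed = seed_stream(config$seed,
                                                            "truth")),
    mirt_truth = {
      gen <- build_comorbidity_mirt()
      proxy_data <- sample_mirt(gen, config$proxy_n,
                                seed = seed_stream(config$seed, "proxy"))
      proxy_fit <- if (P <= 15L) fit_loglinear(proxy_data)
                   else fit_nodewise(proxy_data)
      proxy_fit$model
    })
  simulate_rep <- function(rep) {
    s <- seed_stream(config$seed, paste0("rep", rep, "/data"))
    if (config$study == "mirt_truth")
      sample_mirt(build_comorbidity_mirt(), n_max, seed = s)
    else
      sample_ising(truth, n_max, seed = s, method = "exact")
  }
  records <- list()
  fits <- list()
  for (rep in seq_len(config$reps)) {
    data_full <- simulate_rep(rep)
    rep_fits <- list()
    for (n in config$n_grid) {
      data_n <- data_full[seq_len(n), , drop = FALSE]
      for (method in config$methods) {
        t0 <- proc.time()[["elapsed"]]
        fit <- fit_one_method(method, data_n, config)
        runtime <- proc.time()[["elapsed"]] - t0
        m <- recovery_metrics(truth, fit$model, config$zero_tol)
        records[[length(records) + 1L]] <- data.frame(
          study = config$study, method = method, n = n, rep = rep,
          tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
          sensitivity = m$sensitivity, specificity = m$specificity,
          weight_mae = m$weight_mae,
          weight_correlation = m$weight_correlation,
          estimated_density = m$estimated_density,
          runtime = runtime, stringsAsFactors = FALSE)
        if (keep_fits)
          rep_fits[[paste0(method, "/n", n)]] <- fit
      }
    }
    if (keep_fits) fits[[paste0("rep", rep)]] <- rep_fits
  }
  structure(list(config = config, truth = truth,
                 records = do.call(rbind, records),
                 fits = if (keep_fits) fits else NULL),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study '", x$config$study, "': ", nrow(x$records), " fits (",
      length(x$config$methods), " methods x ", length(x$config$n_grid),
      " sample sizes x ", x$config$reps, " reps)\n", sep = "")
  invisible(x)
}

#' Write / read an Ising model as a plain-text edge list
#'
#' The format is a TSV holding the strict upper triangle as rows
#' \code{node_i <TAB> node_j <TAB> weight} (1-based, \eqn{i < j}), preceded
#' by comment lines \code{# nodes P} and one \code{# threshold j value}
#' per node. Numbers carry 17 significant digits, so
#' \code{read_edge_list(write_edge_list(m, f))} reproduces the model
#' exactly.
#'
#' @param model An [ising_model()].
#' @param path File path.
#' @return \code{write_edge_list} returns \code{path} invisibly;
#'   \code{read_edge_list} returns the [ising_model()].
#' @export
write_edge_list <- function(model, path) {
  stopifnot(inherits(model, "ising_model"))
  P <- model$node_count
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste("# nodes", P),
    paste("# threshold", seq_len(P), num(model$thresholds)),
    "node_i\tnode_j\tweight")
  pairs <- which(upper.tri(model$weights), arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
    lines <- c(lines, sprintf("%d\t%d\t%s", pairs[, 1], pairs[, 2],
                              num(model$weights[pairs])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  perr <- function(ln, msg) stop("parse error at line ", ln, " of '",
                                 path, "': ", msg)
  if (length(lines) < 2 || !grepl("^# nodes [0-9]+$", lines[1]))
    perr(1, "expected '# nodes <P>'")
  P <- as.integer(sub("^# nodes ", "", lines[1]))
  thresholds <- rep(NA_real_, P)
  ln <- 2L
  while (ln <= length(lines) && startsWith(lines[ln], "#")) {
    m <- regmatches(lines[ln],
      regexec("^# threshold ([0-9]+) (\\S+)$", lines[ln]))[[1]]
    if (length(m) != 3) perr(ln, "expected '# threshold <node> <value>'")
    j <- as.integer(m[2])
    if (j < 1 || j > P) perr(ln, paste("node index", j, "out of range"))
    if (!is.na(thresholds[j])) perr(ln, paste("duplicate threshold for node", j))
    thresholds[j] <- as.numeric(m[3])
    ln <- ln + 1L
  }
  if (anyNA(thresholds)) stop("missing threshold lines in '", path, "'")
  if (ln > length(lines) || lines[ln] != "node_i\tnode_j\tweight")
    perr(ln, "expected header 'node_i\\tnode_j\\tweight'")
  W <- matrix(0, P, P)
  seen <- matrix(FALSE, P, P)
  for (k in seq_len(length(lines) - ln)) {
    row <- ln + k
    f <- strsplit(lines[row], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3) perr(row, "expected 3 tab-separated fields")
    i <- as.integer(f[1]); j <- as.integer(f[2]); w <- as.numeric(f[3])
    if (is.na(i) || is.na(j) || is.na(w)) perr(row, "malformed fields")
    if (i < 1 || j < 1 || i > P || j > P || i >= j)
      perr(row, paste0("pair (", i, ", ", j,
                       ") is not a strict upper-triangle pair"))
    if (seen[i, j]) perr(row, paste0("duplicate pair (", i, ", ", j, ")"))
    seen[i, j] <- TRUE
    W[i, j] <- W[j, i] <- w
  }
  ising_model(thresholds, W)
}

#' Write the metrics table of a study result as CSV
#'
#' One row per (method, n, rep) record, with the stable column order
#' \code{study, method, n, rep, tp, fp, tn, fn, sensitivity, specificity,
#' weight_mae, weight_correlation, estimated_density}. Undefined metrics
#' (\code{NA}) are written as empty fields. The byte content is a
#' deterministic function of the result.
#'
#' @param result A [run_study()] result.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_table <- function(result, path) {
  stopifnot(inherits(result, "study_result"))
  cols <- c("study", "method", "n", "rep", "tp", "fp", "tn", "fn",
            "sensitivity", "specificity", "weight_mae",
            "weight_correlation", "estimated_density")
  df <- result$records[, cols]
  num <- c("sensitivity", "specificity", "weight_mae",
           "weight_correlation", "estimated_density")
  for (cn in num) df[[cn]] <- ifelse(is.na(df[[cn]]), "",
                                     sprintf("%.17g", df[[cn]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a binary dataset as CSV
#'
#' Plain CSV of 0/1 values with a header row of node labels.
#'
#' @param data 0/1 matrix.
#' @param path File path.
#' @return \code{write_dataset} returns \code{path} invisibly;
#'   \code{read_dataset} returns the integer matrix.
#' @export
write_dataset <- function(data, path) {
  data <- check_binary_matrix(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  check_binary_matrix(m)
  m
}
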