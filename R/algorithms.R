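# User-facing federated fits composing losses, penalties and the solver,
# plus federated cross-validation over the lambda path.

fit_generic <- function(session, loss, penalty, lambda, C, graph,
                        ridge_eps, coupling, intercept, options) {
  problem <- mtl_problem(session, loss = loss, penalty = penalty,
                         lambda = 0, C = C, graph = graph,
                         ridge_eps = ridge_eps, coupling = coupling,
                         intercept = intercept)
  if (is.null(lambda) || length(lambda) > 1L) {
    return(solve_path(problem, lambdas = lambda, options = options))
  }
  problem$lambda <- lambda
  res <- fista_solve(problem, options)
  if (!guard_check(session, res$model$W))
    stop("disclosure guard: fitted model has more nonzero coefficients ",
         "than subjects on at least one server; refusing to release it ",
         "(disable via privacy_policy(nonzero_guard = FALSE))")
  res
}

#' Federated multi-task fit with joint feature selection (L2,1 penalty)
#'
#' One coefficient column per server; the row-wise L2,1 penalty zeroes
#' features jointly across tasks, so the selected features are shared while
#' each task keeps its own coefficient values (including opposite signs) on
#' them.  This is the estimator of choice for heterogeneous signatures:
#' cohorts affected in the same features but potentially opposite
#' directions.
#'
#' @param session A [create_session()] federation.
#' @param loss `"ls"` or `"logistic"`.
#' @param lambda A single penalty weight for one fit, a descending vector
#'   for a warm-started path, or `NULL` for a data-driven path
#'   ([lambda_max()] + [lambda_sequence()]).
#' @param C Optional small ridge weight for conditioning (default 0).
#' @param intercept Fit unpenalized per-task intercepts?
#' @param options A [solver_options()].
#' @return A `solve_result` for scalar `lambda`, otherwise a `reg_path`.
#' @export
fit_l21 <- function(session, loss = "ls", lambda = NULL, C = 0,
                    intercept = TRUE, options = solver_options()) {
  fit_generic(session, loss, "l21", lambda, C, NULL, 0, "multi_task",
              intercept, options)
}

#' Federated multi-task fit in a shared low-dimensional subspace (trace norm)
#'
#' The trace-norm penalty shrinks the singular values of the coefficient
#' matrix, constraining the task coefficient vectors to a shared low-rank
#' subspace while leaving room for task-specific variation within it.
#'
#' @inheritParams fit_l21
#' @return A `solve_result` for scalar `lambda`, otherwise a `reg_path`.
#' @export
fit_trace <- function(session, loss = "ls", lambda = NULL, C = 0,
                      intercept = TRUE, options = solver_options()) {
  fit_generic(session, loss, "trace", lambda, C, NULL, 0, "multi_task",
              intercept, options)
}

#' Federated multi-task fit with a task-network penalty
#'
#' Sparse per-task models (L1 penalty, weight `lambda`) coupled by the
#' smooth quadratic `C * (||W R||_F^2 + ridge_eps ||W||_F^2)` over the task
#' graph `R`.  The default mean-regularization graph pulls every task's
#' coefficient vector toward the across-task mean; as `C` grows the task
#' columns are driven toward equality.
#'
#' @inheritParams fit_l21
#' @param graph Task map `R` (see [mean_graph()], [read_task_graph()]).
#' @param C Weight of the graph coupling.
#' @param ridge_eps Small ridge added to the smooth part for conditioning.
#' @return A `solve_result` for scalar `lambda`, otherwise a `reg_path`.
#' @export
fit_net <- function(session, loss = "ls", lambda = NULL, C = 1,
                    graph = mean_graph(length(session$servers)),
                    ridge_eps = 1e-4, intercept = TRUE,
                    options = solver_options()) {
  fit_generic(session, loss, "l1", lambda, C, graph, ridge_eps,
              "multi_task", intercept, options)
}

#' Federated lasso (pooled coupling)
#'
#' A single L1-penalized coefficient vector over the union of all servers'
#' samples: per-server losses and gradients are aggregated with weights
#' `n_k / N`, so the fit equals a lasso on the concatenated data.  This is
#' the conventional federated machine-learning benchmark: it assumes one
#' common signal and has no mechanism for cohort-specific effects.
#'
#' @inheritParams fit_l21
#' @return A `solve_result` for scalar `lambda`, otherwise a `reg_path`.
#' @export
fit_lasso <- function(session, loss = "ls", lambda = NULL,
                      intercept = TRUE, options = solver_options()) {
  fit_generic(session, loss, "l1", lambda, 0, NULL, 0, "pooled",
              intercept, options)
}

fit_by_name <- function(algorithm, session, loss, lambda, options, C = 0) {
  switch(algorithm,
         l21 = fit_l21(session, loss, lambda, C = C, options = options),
         trace = fit_trace(session, loss, lambda, C = C, options = options),
         net = fit_net(session, loss, lambda, C = if (C > 0) C else 1,
                       options = options),
         lasso = fit_lasso(session, loss, lambda, options = options),
         stop("unknown algorithm: ", algorithm))
}

# Seeded, optionally stratified fold assignment for one server.
fold_assignment <- function(y, k_folds, stratify) {
  n <- length(y)
  folds <- integer(n)
  if (stratify) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k_folds), n))
  }
  folds
}

subset_dataset <- function(d, idx) {
  task_dataset(d$X[idx, , drop = FALSE], d$y[idx],
               feature_names = d$feature_names, task_id = d$task_id,
               outcome = d$outcome)
}

#' Federated cross-validation over the lambda path
#'
#' Folds are drawn within each server (stratified by class for binary
#' outcomes), so no sample ever moves between servers.  For each fold a
#' warm-started path is fitted on the in-fold union and every lambda's
#' model is scored on the held-out union, with the held-out metric computed
#' server-side and aggregated (one access per server per fold and lambda).
#' The common lambda grid is estimated once from the full federation so all
#' folds share it.
#'
#' @param session A [create_session()] federation; every server needs at
#'   least `k_folds` samples.
#' @param algorithm `"l21"`, `"trace"`, `"net"` or `"lasso"`.
#' @param loss `"ls"` or `"logistic"`.
#' @param k_folds Number of folds (default 5).
#' @param lambdas Descending lambda grid; default data-driven.
#' @param metric `"mse"` (continuous) or `"misclass"` (binary); default by
#'   loss.
#' @param seed Seed for the fold assignment.
#' @param C Smooth-penalty weight forwarded to the fit.
#' @param options A [solver_options()].
#' @return List of class `"cv_result"`: `lambda_best`, `cv_table`
#'   (data.frame of lambda, mean and sd of the held-out metric, number of
#'   contributing folds), `model` (the path refitted on all data, with
#'   `best` index), `folds`.
#' @export
cross_validate <- function(session, algorithm = c("l21", "trace", "net",
                                                  "lasso"),
                           loss = "ls", k_folds = 5, lambdas = NULL,
                           metric = NULL, seed = NULL, C = 0,
                           options = solver_options()) {
  algorithm <- match.arg(algorithm)
  if (is.null(metric)) metric <- if (loss == "logistic") "misclass" else "mse"
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  datasets <- lapply(session$servers, function(s) s$dataset)
  ns <- vapply(datasets, function(d) nrow(d$X), integer(1))
  if (any(ns < k_folds))
    stop("every server needs at least k_folds = ", k_folds,
         " samples; smallest has ", min(ns))
  if (is.null(lambdas)) {
    problem <- mtl_problem(session, loss = loss,
                           penalty = if (algorithm == "l21") "l21"
                                     else if (algorithm == "trace") "trace"
                                     else "l1",
                           coupling = if (algorithm == "lasso") "pooled"
                                      else "multi_task")
    lambdas <- lambda_sequence(lambda_max(problem), options$min_ratio,
                               options$depth)
  }
  folds <- with_seed(seed, lapply(datasets, function(d)
    fold_assignment(d$y, k_folds, stratify = d$outcome == "binary")))
  metric_mat <- matrix(NA_real_, k_folds, length(lambdas))
  for (f in seq_len(k_folds)) {
    train <- lapply(seq_along(datasets), function(i)
      subset_dataset(datasets[[i]], folds[[i]] != f))
    test <- lapply(seq_along(datasets), function(i)
      subset_dataset(datasets[[i]], folds[[i]] == f))
    tr_sess <- create_session(train, session$policy)
    te_sess <- create_session(test, session$policy)
    path <- fit_by_name(algorithm, tr_sess, loss, lambdas, options, C)
    for (j in seq_along(lambdas)) {
      m <- path$fits[[j]]$model
      if (is.null(m)) next                       # withheld by the guard
      vals <- fed_round(te_sess, function(id) {
        col <- if (ncol(m$W) > 1L) match(id, colnames(m$W)) else 1L
        server_compute(te_sess, id,
                       list(kind = "metric_value", metric = metric,
                            w = m$W[, col], c = m$c[col]))
      })
      # plain mean across servers: each cohort's held-out error counts
      # equally, matching how multi-cohort performance is reported
      metric_mat[f, j] <- mean(vapply(vals, `[[`, numeric(1), "metric"))
    }
    # fold-level communication is ephemeral; fold sessions are discarded
  }
  n_folds_ok <- colSums(!is.na(metric_mat))
  mean_metric <- ifelse(n_folds_ok == k_folds,
                        colMeans(metric_mat), NA_real_)
  if (all(is.na(mean_metric)))
    stop("no lambda was available in every fold (disclosure guard?)")
  best <- which.min(mean_metric)
  final <- fit_by_name(algorithm, session, loss, lambdas, options, C)
  structure(list(lambda_best = lambdas[best],
                 cv_table = data.frame(
                   lambda = lambdas,
                   mean_metric = colMeans(metric_mat, na.rm = TRUE),
                   sd_metric = apply(metric_mat, 2, stats::sd, na.rm = TRUE),
                   n_folds = n_folds_ok),
                 metric = metric, best = best,
                 model = final$fits[[best]]$model,
                 path = final, folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result: best lambda ", signif(x$lambda_best, 4), " (",
      x$metric, " = ", signif(x$cv_table$mean_metric[x$best], 4), ")\n",
      sep = "")
  invisible(x)
}
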