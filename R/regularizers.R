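# Client-side penalties: non-smooth sparsity-inducing terms with their
# proximal operators (lasso, row-group L2,1, trace norm) and smooth
# stabilizing terms with gradients (ridge, task-graph quadratic).

#' Soft-thresholding (proximal operator of the L1 norm)
#'
#' Entrywise `sign(w) * max(|w| - t, 0)`, the exact minimizer of
#' `0.5 (z - w)^2 + t |z|`.
#'
#' @param W Numeric vector or matrix.
#' @param t Threshold (step size times penalty weight), `>= 0`.
#' @return Object of the same shape as `W`.
#' @export
prox_l1 <- function(W, t) {
  if (t < 0) stop("'t' must be >= 0")
  sign(W) * pmax(abs(W) - t, 0)
}

#' Row-wise group soft-thresholding (proximal operator of the L2,1 norm)
#'
#' Each row (one feature's coefficients across tasks) is scaled by
#' `max(1 - t / ||row||_2, 0)`; rows with norm at most `t` are zeroed
#' jointly, which is what makes the L2,1 penalty select features shared
#' across tasks.
#'
#' @param W Numeric matrix, features by tasks.
#' @param t Threshold, `>= 0`.
#' @return Matrix of the same shape.
#' @export
prox_l21 <- function(W, t) {
  if (t < 0) stop("'t' must be >= 0")
  W <- as.matrix(W)
  rn <- sqrt(rowSums(W^2))
  shrink <- ifelse(rn > 0, pmax(1 - t / rn, 0), 0)
  W * shrink
}

#' Singular-value soft-thresholding (proximal operator of the trace norm)
#'
#' Computes the SVD of `W` and shrinks each singular value by `t`, dropping
#' those at or below `t`; this is the exact proximal map of `t * ||.||_*`
#' and the step that drives the coefficient matrix toward a shared
#' low-dimensional subspace.
#'
#' @inheritParams prox_l21
#' @return Matrix of the same shape, with trace norm reduced by at most
#'   `t * min(dim(W))`.
#' @export
prox_trace <- function(W, t) {
  if (t < 0) stop("'t' must be >= 0")
  W <- as.matrix(W)
  if (t == 0) return(W)
  sv <- svd(W)
  d <- pmax(sv$d - t, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(W), ncol(W)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Value of a non-smooth penalty
#'
#' @param kind `"l1"` (sum of absolute values), `"l21"` (sum of row L2
#'   norms) or `"trace"` (sum of singular values).
#' @param W Numeric matrix.
#' @return Scalar penalty value.
#' @export
penalty_value <- function(kind, W) {
  W <- as.matrix(W)
  switch(kind,
         l1 = sum(abs(W)),
         l21 = sum(sqrt(rowSums(W^2))),
         trace = sum(svd(W, nu = 0, nv = 0)$d),
         stop("unknown penalty kind: ", kind))
}

prox_op <- function(kind) {
  switch(kind,
         l1 = prox_l1, l21 = prox_l21, trace = prox_trace,
         stop("unknown penalty kind: ", kind))
}

#' Task-graph quadratic penalty value and gradient
#'
#' The smooth coupling term `||W R||_F^2` with gradient `2 W R R'`, where
#' the columns of `R` encode penalized contrasts between tasks.  With the
#' mean-regularization graph ([mean_graph()]) this pulls every task's
#' coefficient vector toward the across-task mean.
#'
#' @param W Coefficient matrix, features by tasks.
#' @param R Task map, tasks by contrasts (or tasks by tasks).
#' @return List with `value` and `grad` (same shape as `W`).
#' @export
graph_penalty_value_grad <- function(W, R) {
  W <- as.matrix(W); R <- as.matrix(R)
  if (ncol(W) != nrow(R))
    stop("R must have one row per task: ncol(W)=", ncol(W),
         ", nrow(R)=", nrow(R))
  WR <- W %*% R
  list(value = sum(WR^2), grad = 2 * (WR %*% t(R)))
}

#' Mean-regularization task graph
#'
#' The centering map `R = I - (1/T) 1 1'`, symmetric and idempotent, whose
#' quadratic form penalizes each task's deviation from the across-task mean
#' and leaves a shared solution unpenalized.  `T = 1` gives the zero map
#' (nothing to couple).
#'
#' @param n_tasks Number of tasks `T >= 1`.
#' @return A `T x T` matrix of class `"task_graph"`.
#' @export
mean_graph <- function(n_tasks) {
  stopifnot(n_tasks >= 1)
  R <- diag(n_tasks) - matrix(1 / n_tasks, n_tasks, n_tasks)
  class(R) <- c("task_graph", class(R))
  R
}

#' Read / write a task graph as dense numeric CSV
#'
#' @param R A task map matrix.
#' @param path CSV file path.
#' @return `read_task_graph` returns the matrix; `write_task_graph` returns
#'   the path invisibly.
#' @export
write_task_graph <- function(R, path) {
  utils::write.table(unclass(as.matrix(R)), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_task_graph
#' @export
read_task_graph <- function(path) {
  R <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(R) <- NULL
  storage.mode(R) <- "double"
  class(R) <- c("task_graph", class(R))
  R
}

#' Ridge penalty value and gradient
#'
#' `0.5 ||W||_F^2` with gradient `W`; the smooth stabilizer.
#'
#' @param W Numeric matrix.
#' @return List with `value` and `grad`.
#' @export
ridge_value_grad <- function(W) {
  list(value = 0.5 * sum(W^2), grad = W)
}
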