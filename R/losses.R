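# Per-cohort smooth loss functions: mean-form least squares for continuous
# outcomes and mean-form logistic negative log-likelihood for binary
# outcomes.  The mean (1/n_k) scaling makes cohorts of different sizes
# contribute comparably to a joint objective.

#' Construct a cohort dataset
#'
#' One cohort's feature matrix and outcome vector; in a federation each
#' task_dataset lives on exactly one server node.
#'
#' @param X Numeric matrix, samples by features, no missing values.
#' @param y Outcome vector: numeric for continuous outcomes; for binary
#'   outcomes labels in `{-1, +1}` (inputs coded `{0, 1}` are converted).
#' @param feature_names Character vector naming the columns of `X`; defaults
#'   to `colnames(X)` or `f1..fp`.
#' @param task_id Identifier for the cohort/task.
#' @param outcome `"continuous"` or `"binary"`.
#' @return An object of class `"task_dataset"`.
#' @export
task_dataset <- function(X, y, feature_names = NULL, task_id = "task1",
                         outcome = c("continuous", "binary")) {
  outcome <- match.arg(outcome)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("nrow(X) (", nrow(X), ") != length(y) (", length(y), ")")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (nrow(X) < 1L || ncol(X) < 1L) stop("X must have >= 1 row and column")
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  }
  if (length(feature_names) != ncol(X))
    stop("feature_names length does not match ncol(X)")
  colnames(X) <- feature_names
  if (outcome == "binary") {
    u <- sort(unique(y))
    if (identical(u, c(0, 1))) y <- 2 * y - 1
    if (!all(y %in% c(-1, 1)))
      stop("binary outcome must be coded {-1,+1} or {0,1}")
  }
  structure(list(X = X, y = y, feature_names = as.character(feature_names),
                 task_id = as.character(task_id), outcome = outcome),
            class = "task_dataset")
}

#' @export
print.task_dataset <- function(x, ...) {
  cat("task_dataset '", x$task_id, "': ", nrow(x$X), " samples x ",
      ncol(x$X), " features, ", x$outcome, " outcome\n", sep = "")
  invisible(x)
}

#' Center and scale the features of a cohort dataset
#'
#' Server-local standardization (zero mean, unit variance per feature).
#' Constant features are left centered with scale 1.  The applied center and
#' scale are recorded in the returned object so a model fitted on scaled
#' data can be interpreted or applied on the original scale.
#'
#' @param dataset A [task_dataset()].
#' @return The dataset with scaled `X` and attributes `center` and `scale`.
#' @export
scale_dataset <- function(dataset) {
  ctr <- colMeans(dataset$X)
  scl <- apply(dataset$X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  dataset$X <- sweep(sweep(dataset$X, 2, ctr), 2, scl, "/")
  dataset$center <- ctr
  dataset$scale <- scl
  dataset
}

#' Least-squares loss value and gradient
#'
#' Mean-form squared error for one cohort:
#' `value = ||X w + c - y||^2 / (2 n)`, with gradient
#' `grad_w = t(X) (X w + c - y) / n` and `grad_c` the mean residual.
#'
#' @param X Feature matrix (n x p).
#' @param y Continuous outcome vector (length n).
#' @param w Coefficient vector (length p).
#' @param c Intercept scalar.
#' @return List with `value`, `grad_w`, `grad_c`.
#' @export
least_squares_value_grad <- function(X, y, w, c = 0) {
  if (ncol(X) != length(w)) stop("dimension mismatch: ncol(X) != length(w)")
  n <- nrow(X)
  r <- as.numeric(X %*% w) + c - y
  list(value = sum(r^2) / (2 * n),
       grad_w = as.numeric(crossprod(X, r)) / n,
       grad_c = mean(r))
}

#' Logistic loss value and gradient
#'
#' Mean-form logistic negative log-likelihood with labels in `{-1,+1}`:
#' `value = mean(log(1 + exp(-y * (X w + c))))`.
#'
#' @inheritParams least_squares_value_grad
#' @param y Label vector in `{-1, +1}`.
#' @return List with `value`, `grad_w`, `grad_c`.
#' @export
logistic_value_grad <- function(X, y, w, c = 0) {
  if (ncol(X) != length(w)) stop("dimension mismatch: ncol(X) != length(w)")
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1,+1}")
  n <- nrow(X)
  m <- y * (as.numeric(X %*% w) + c)
  # log(1+exp(-m)) computed stably for large |m|
  val <- mean(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m))))
  s <- -y / (1 + exp(m))        # d loss_i / d margin * y chain
  list(value = val,
       grad_w = as.numeric(crossprod(X, s)) / n,
       grad_c = mean(s))
}

# Dispatch used by server_compute: evaluate the dataset's loss at (w, c).
loss_value_grad <- function(dataset, w, c, loss = NULL, want_grad = TRUE) {
  if (is.null(loss))
    loss <- if (dataset$outcome == "binary") "logistic" else "ls"
  f <- switch(loss,
              ls = least_squares_value_grad,
              logistic = logistic_value_grad,
              stop("unknown loss: ", loss))
  v <- f(dataset$X, dataset$y, w, c)
  if (!want_grad) v["value"] else v
}

#' Construct a coefficient model
#'
#' The feature-by-task coefficient matrix plus per-task intercepts: the unit
#' exchanged (quantized) between the client and the servers.
#'
#' @param W Numeric matrix, features by tasks.
#' @param c Numeric vector of intercepts, one per task.
#' @param feature_names Character vector, length `nrow(W)`.
#' @param task_ids Character vector, length `ncol(W)`.
#' @param loss The loss the model was fitted under (`"ls"` or `"logistic"`).
#' @return An object of class `"coef_model"`.
#' @export
coef_model <- function(W, c, feature_names = NULL, task_ids = NULL,
                       loss = "ls") {
  W <- as.matrix(W)
  if (length(c) != ncol(W)) stop("length(c) must equal ncol(W)")
  if (any(!is.finite(W)) || any(!is.finite(c)))
    stop("coefficients must be finite")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(nrow(W)))
  if (is.null(task_ids)) task_ids <- paste0("task", seq_len(ncol(W)))
  rownames(W) <- feature_names
  colnames(W) <- task_ids
  structure(list(W = W, c = stats::setNames(as.numeric(c), task_ids),
                 feature_names = as.character(feature_names),
                 task_ids = as.character(task_ids), loss = loss),
            class = "coef_model")
}

#' @export
print.coef_model <- function(x, ...) {
  cat("coef_model: ", nrow(x$W), " features x ", ncol(x$W), " task(s), ",
      sum(rowSums(x$W != 0) > 0), " active feature(s), loss=", x$loss,
      "\n", sep = "")
  invisible(x)
}

#' Predict from a coefficient model
#'
#' @param object A [coef_model()].
#' @param X Feature matrix with `nrow(object$W)` columns.
#' @param task_id Which task's coefficient column to use.
#' @param type `"link"` for linear scores `X w + c`; `"class"` (logistic
#'   models) for labels by the sign of the score, ties mapped to `+1`.
#' @param ... Unused.
#' @return Numeric vector of scores or labels.
#' @export
predict.coef_model <- function(object, X, task_id = object$task_ids[1L],
                               type = c("link", "class"), ...) {
  type <- match.arg(type)
  if (!task_id %in% object$task_ids) stop("unknown task_id: ", task_id)
  X <- as.matrix(X)
  if (ncol(X) != nrow(object$W))
    stop("X has ", ncol(X), " columns; model has ", nrow(object$W),
         " features")
  scores <- as.numeric(X %*% object$W[, task_id]) + object$c[[task_id]]
  if (type == "link") return(scores)
  ifelse(scores >= 0, 1, -1)
}
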