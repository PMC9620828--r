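# Metrics and non-collaborative baselines: prediction error, feature
# selection accuracy, per-cohort model bagging (lasso and NMF), signature
# overlap between independently fitted models, and communication-cost
# curves across server counts.

#' Mean squared error
#' @param pred Predicted values.
#' @param y Observed values.
#' @return Scalar MSE.
#' @export
mse <- function(pred, y) {
  stopifnot(length(pred) == length(y))
  mean((pred - y)^2)
}

#' Misclassification rate
#' @param pred_labels Predicted labels.
#' @param y Observed labels (same coding).
#' @return Proportion of mismatches.
#' @export
misclassification_rate <- function(pred_labels, y) {
  stopifnot(length(pred_labels) == length(y))
  mean(pred_labels != y)
}

#' Feature selection accuracy (precision at k)
#'
#' The proportion of the `k` top-scored features that belong to the truth
#' set; by default `k` is the truth size, so precision and recall
#' coincide.  Ties are broken by feature index, which makes the metric
#' deterministic.
#'
#' @param scores Numeric vector of per-feature scores (higher = more
#'   selected), optionally named.
#' @param truth_support Indices (or names, when `scores` is named) of the
#'   true features.
#' @param k Number of top features to take (default `length(truth_support)`).
#' @return `|top_k intersect truth| / k`.
#' @export
selection_accuracy <- function(scores, truth_support,
                               k = length(truth_support)) {
  stopifnot(k <= length(scores), k >= 1)
  if (is.character(truth_support)) {
    stopifnot(!is.null(names(scores)))
    truth_support <- match(truth_support, names(scores))
  }
  ord <- order(-scores, seq_along(scores))
  length(intersect(ord[seq_len(k)], truth_support)) / k
}

#' Per-feature scores of a multi-task model
#'
#' The row L2 norm of the coefficient matrix: a feature scores high when
#' any task uses it, regardless of sign, which is the right ranking for
#' heterogeneous (sign-flipped) signatures.
#'
#' @param model A [coef_model()] or a coefficient matrix.
#' @return Named numeric vector of scores.
#' @export
feature_scores <- function(model) {
  W <- if (inherits(model, "coef_model")) model$W else as.matrix(model)
  stats::setNames(sqrt(rowSums(W^2)), rownames(W))
}

# Plain single-matrix NMF (multiplicative updates, best of n_starts) used
# by the local baseline; deliberately has no notion of shared structure.
nmf_fit <- function(X, rank, n_starts = 5, max_iter = 200, tol = 1e-5,
                    seed = NULL) {
  stopifnot(all(X >= 0), rank >= 1, rank <= min(dim(X)))
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  n <- nrow(X); p <- ncol(X)
  scale <- sqrt(max(mean(X), INMF_EPS) / rank)
  best <- NULL
  for (s in seq_len(n_starts)) {
    W <- with_seed(seed + 2L * s, matrix(stats::runif(n * rank), n, rank)) *
      scale
    H <- with_seed(seed + 2L * s + 1L,
                   matrix(stats::runif(rank * p), rank, p)) * scale
    obj_prev <- Inf
    for (it in seq_len(max_iter)) {
      W <- W * (X %*% t(H)) / pmax(W %*% tcrossprod(H), INMF_EPS)
      H <- H * (crossprod(W, X)) / pmax(crossprod(W) %*% H, INMF_EPS)
      obj <- sum((X - W %*% H)^2)
      if (is.finite(obj_prev) &&
          abs(obj_prev - obj) / max(obj_prev, 1) < tol) break
      obj_prev <- obj
    }
    if (is.null(best) || obj < best$objective)
      best <- list(W = W, H = H, objective = obj)
  }
  best
}

#' Non-collaborative per-cohort baselines (model bagging)
#'
#' Fits an independent model on each cohort using only local data (zero
#' network accesses across cohorts) and aggregates:
#'
#' * `lasso_local`: a cross-validated lasso (glmnet) per cohort; the bagged
#'   per-feature score is the mean absolute coefficient across cohorts.
#' * `nmf_local`: a plain NMF per cohort; each cohort's gene score is the
#'   largest row-normalized metagene loading, the bagged shared-signature
#'   score is the across-cohort mean of those scores, and each cohort's
#'   own score vector doubles as its specific-signature estimate.
#'
#' @param datasets List of [task_dataset()] objects (local data only).
#' @param learner `"lasso_local"` or `"nmf_local"`.
#' @param rank NMF rank (nmf_local).
#' @param n_starts Random starts per local NMF.
#' @param seed Seed forwarded to the local learners.
#' @return List with `scores` (bagged per-feature scores), `per_cohort`
#'   (list of per-cohort score vectors) and, for `lasso_local`, `models`
#'   (per-cohort glmnet fits).
#' @export
bagging_baseline <- function(datasets, learner = c("lasso_local",
                                                   "nmf_local"),
                             rank = 4, n_starts = 5, seed = NULL) {
  learner <- match.arg(learner)
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  fn <- datasets[[1L]]$feature_names
  if (learner == "lasso_local") {
    models <- vector("list", length(datasets))
    per <- lapply(seq_along(datasets), function(i) {
      d <- datasets[[i]]
      fam <- if (d$outcome == "binary") "binomial" else "gaussian"
      yy <- if (d$outcome == "binary") factor(d$y) else d$y
      # one fold seed for every cohort, so identical cohorts give
      # identical local models
      cvfit <- with_seed(seed,
                         glmnet::cv.glmnet(d$X, yy, family = fam,
                                           nfolds = 5,
                                           standardize = FALSE))
      models[[i]] <<- cvfit
      co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1L]
      stats::setNames(abs(co), fn)
    })
    scores <- Reduce(`+`, per) / length(per)
    return(list(scores = scores, per_cohort = per, models = models))
  }
  per <- lapply(seq_along(datasets), function(i) {
    fit <- nmf_fit(datasets[[i]]$X, rank, n_starts = n_starts,
                   seed = seed)
    H <- fit$H
    mx <- apply(H, 1, max)
    Hn <- H / ifelse(mx > 0, mx, 1)
    stats::setNames(apply(Hn, 2, max), fn)
  })
  scores <- Reduce(`+`, per) / length(per)
  list(scores = scores, per_cohort = per)
}

#' Overlap and direction consistency of two top-k gene signatures
#'
#' Takes the `k` genes with the largest absolute score from each signed
#' score vector and counts how many are selected by both models
#' (`n_overlap`) and how many of those carry the same coefficient sign in
#' both (`n_consistent`).  Used to quantify reproducibility of signatures
#' fitted on independent dataset groups.
#'
#' @param scores_a,scores_b Named numeric vectors of signed per-gene
#'   scores (e.g. coefficients).
#' @param k Signature size (default 200).
#' @return List with `n_overlap`, `n_consistent` and the overlapping gene
#'   names.
#' @export
signature_overlap <- function(scores_a, scores_b, k = 200) {
  stopifnot(!is.null(names(scores_a)), !is.null(names(scores_b)))
  top <- function(s) {
    kk <- min(k, length(s))
    names(s)[order(-abs(s), seq_along(s))[seq_len(kk)]]
  }
  ta <- top(scores_a); tb <- top(scores_b)
  ov <- intersect(ta, tb)
  cons <- ov[sign(scores_a[ov]) == sign(scores_b[ov])]
  list(n_overlap = length(ov), n_consistent = length(cons), genes = ov)
}

#' Communication-cost experiment across server counts
#'
#' For each combination of server count `K` and per-task sample size,
#' generates a fresh federation, fits the requested algorithms at a fixed
#' point on their regularization path (`0.1 * lambda_max`), and records the
#' communication consumed.  Multi-task fits cost one round per gradient or
#' line-search evaluation regardless of `K` (each round touches every
#' server once), so their round counts are flat in `K` while total
#' accesses grow linearly; the pooled lasso shares the same round
#' structure but must aggregate every gradient across servers.
#'
#' @param K_range Server counts.
#' @param n_sweep Per-task sample sizes.
#' @param algorithms Subset of `c("l21", "lasso")`.
#' @param reps Repetitions to average over.
#' @param seed Seed.
#' @param p Number of features.
#' @param options A [solver_options()].
#' @return data.frame with columns `algorithm`, `K`, `n`, `rounds`,
#'   `total_accesses`, `iterations` (averaged over reps).
#' @export
comm_cost_experiment <- function(K_range = c(2, 5, 10, 20), n_sweep = 30,
                                 algorithms = c("l21", "lasso"), reps = 1,
                                 seed = NULL, p = 100,
                                 options = solver_options()) {
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  grid <- expand.grid(algorithm = algorithms, K = K_range, n = n_sweep,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    acc <- matrix(0, reps, 3)
    for (r in seq_len(reps)) {
      suite <- gen_scalability_suite(K_range = g$K, n_per_task = g$n,
                                     p = p, seed = seed + 1000L * r + i)
      sess <- suite[[1L]]
      problem <- mtl_problem(sess, loss = "ls",
                             penalty = if (g$algorithm == "l21") "l21"
                                       else "l1",
                             coupling = if (g$algorithm == "lasso")
                               "pooled" else "multi_task")
      lam <- 0.1 * lambda_max(problem)
      problem$lambda <- lam
      fit <- fista_solve(problem, options)
      acc[r, ] <- c(fit$comm$rounds, fit$comm$total_accesses,
                    fit$iterations)
    }
    data.frame(algorithm = g$algorithm, K = g$K, n = g$n,
               rounds = mean(acc[, 1]), total_accesses = mean(acc[, 2]),
               iterations = mean(acc[, 3]))
  })
  do.call(rbind, res)
}
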