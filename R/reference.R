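# Single-process reference implementations.
#
# These fit the same objectives as the federated solvers but operate
# directly on the in-memory data with no session, transport, metering or
# policy layer.  They exist so that every federated fit can be checked
# against a plain centralized computation on the concatenated data: with
# quantization unlimited the two must agree to high precision, which
# validates that the federated aggregation (per-task dispatch, sample-size
# weighting, numerator/denominator pooling) changes nothing but the
# location of the computation.

ref_loss <- function(X, y, w, c, loss) {
  n <- nrow(X)
  if (loss == "ls") {
    r <- as.numeric(X %*% w) + c - y
    list(value = sum(r^2) / (2 * n),
         gw = as.numeric(crossprod(X, r)) / n, gc = mean(r))
  } else {
    m <- y * (as.numeric(X %*% w) + c)
    s <- -y / (1 + exp(m))
    list(value = mean(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m)))),
         gw = as.numeric(crossprod(X, s)) / n, gc = mean(s))
  }
}

#' Centralized reference fit of the regularized multi-task objective
#'
#' Plain FISTA with backtracking run in a single process on the raw data
#' (no federation).  Multi-task coupling gives one coefficient column per
#' dataset; pooled coupling concatenates all datasets into one sample and
#' fits a single column.
#'
#' @param datasets List of [task_dataset()] objects.
#' @param loss `"ls"` or `"logistic"`.
#' @param penalty `"l1"`, `"l21"` or `"trace"`.
#' @param lambda Non-smooth penalty weight.
#' @param C Smooth penalty weight.
#' @param graph Optional task-graph matrix (see [mean_graph()]).
#' @param ridge_eps Ridge added alongside the graph.
#' @param coupling `"multi_task"` or `"pooled"`.
#' @param intercept Fit unpenalized intercepts?
#' @param max_iter,tol Iteration cap and relative-objective tolerance.
#' @param W0,c0 Optional warm start.
#' @return List with `W`, `c`, `objective` (final value) and `iterations`.
#' @export
reference_fit <- function(datasets, loss = "ls", penalty = "l1",
                          lambda = 0, C = 0, graph = NULL, ridge_eps = 0,
                          coupling = c("multi_task", "pooled"),
                          intercept = TRUE, max_iter = 5000, tol = 1e-10,
                          W0 = NULL, c0 = NULL) {
  coupling <- match.arg(coupling)
  if (coupling == "pooled") {
    X <- do.call(rbind, lapply(datasets, function(d) d$X))
    Y <- unlist(lapply(datasets, function(d) d$y), use.names = FALSE)
    Xs <- list(X); Ys <- list(Y)
  } else {
    Xs <- lapply(datasets, function(d) d$X)
    Ys <- lapply(datasets, function(d) d$y)
  }
  T <- length(Xs)
  p <- ncol(Xs[[1L]])
  smooth <- function(W, cv) {
    val <- 0; gW <- matrix(0, p, T); gc <- numeric(T)
    for (t in seq_len(T)) {
      l <- ref_loss(Xs[[t]], Ys[[t]], W[, t], cv[t], loss)
      val <- val + l$value; gW[, t] <- l$gw; gc[t] <- l$gc
    }
    if (C > 0) {
      if (!is.null(graph)) {
        WR <- W %*% graph
        val <- val + C * (sum(WR^2) + ridge_eps * sum(W^2))
        gW <- gW + C * (2 * WR %*% t(graph) + 2 * ridge_eps * W)
      } else {
        val <- val + C * 0.5 * sum(W^2)
        gW <- gW + C * W
      }
    }
    list(value = val, gW = gW, gc = gc)
  }
  pen <- function(W) if (lambda > 0) lambda * penalty_value(penalty, W)
                     else 0
  prox <- prox_op(penalty)
  W <- if (is.null(W0)) matrix(0, p, T) else matrix(W0, p, T)
  cv <- if (!intercept) rep(0, T)
        else if (!is.null(c0)) rep(c0, length.out = T)
        else vapply(seq_len(T), function(t) {
          if (loss == "ls") mean(Ys[[t]])
          else log(sum(Ys[[t]] > 0) / sum(Ys[[t]] <= 0))
        }, numeric(1))
  y <- W; yc <- cv
  a <- 1; t_step <- 1
  obj_prev <- Inf
  it <- 0L
  for (k in seq_len(max_iter)) {
    it <- k
    g <- smooth(y, yc)
    repeat {
      Z <- prox(y - t_step * g$gW, t_step * lambda)
      zc <- if (intercept) yc - t_step * g$gc else yc
      fz <- smooth(Z, zc)$value
      dW <- Z - y; dc <- zc - yc
      if (fz <= g$value + sum(g$gW * dW) + sum(g$gc * dc) +
            (sum(dW^2) + sum(dc^2)) / (2 * t_step) + 1e-12)
        break
      t_step <- t_step / 2
    }
    obj <- fz + pen(Z)
    if (is.finite(obj_prev) && obj > obj_prev) {
      # adaptive restart: drop the momentum when the objective rises
      y <- Z; yc <- zc; a <- 1
      W <- Z; cv <- zc
      obj_prev <- obj
      next
    }
    a_new <- (1 + sqrt(1 + 4 * a^2)) / 2
    y <- Z + ((a - 1) / a_new) * (Z - W)
    yc <- zc + ((a - 1) / a_new) * (zc - cv)
    W <- Z; cv <- zc; a <- a_new
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) / max(abs(obj_prev), 1) < tol) break
    obj_prev <- obj
  }
  list(W = W, c = cv, objective = obj_prev, iterations = it)
}

#' Centralized reference fit of integrative NMF
#'
#' The same alternating multiplicative scheme as [fit_inmf()] executed in a
#' single process, including the seed-derivation convention, so federated
#' and centralized runs with the same seed can be compared round by round.
#'
#' @param datasets List of [task_dataset()] objects holding non-negative
#'   matrices.
#' @inheritParams fit_inmf
#' @return List with `H`, `W` (per-cohort loadings), `V` (per-cohort
#'   specific factors), `objective`, `history`, `best_start`.
#' @export
reference_inmf <- function(datasets, rank, lambda_het = 0.003, n_starts = 5,
                           max_iter = 500, tol = 1e-6, seed = 1) {
  Xs <- lapply(datasets, function(d) d$X)
  K <- length(Xs)
  p <- ncol(Xs[[1L]])
  ns <- vapply(Xs, nrow, integer(1))
  xm <- sum(ns * vapply(Xs, mean, numeric(1))) / sum(ns)
  h_scale <- sqrt(max(xm, INMF_EPS) / rank)
  best <- NULL
  for (s in seq_len(n_starts)) {
    sseed <- seed * 1000L + s * 100L
    Ws <- Vs <- vector("list", K)
    for (k in seq_len(K)) {
      scale_k <- sqrt(max(mean(Xs[[k]]), INMF_EPS) / rank)
      Ws[[k]] <- with_seed(sseed + k,
                           matrix(stats::runif(ns[k] * rank), ns[k],
                                  rank)) * scale_k
      Vs[[k]] <- with_seed(sseed + k + 1L,
                           matrix(stats::runif(rank * p), rank, p)) *
        scale_k
    }
    H <- with_seed(sseed, matrix(stats::runif(rank * p), rank, p)) * h_scale
    objective <- function() {
      sum(vapply(seq_len(K), function(k)
        sum((Xs[[k]] - Ws[[k]] %*% (H + Vs[[k]]))^2) +
          lambda_het * sum((Ws[[k]] %*% Vs[[k]])^2), numeric(1)))
    }
    history <- numeric(0)
    for (it in seq_len(max_iter)) {
      history <- c(history, objective())
      A <- matrix(0, rank, p); B <- matrix(0, rank, p)
      for (k in seq_len(K)) {
        M <- H + Vs[[k]]
        num <- Xs[[k]] %*% t(M)
        den <- Ws[[k]] %*% (tcrossprod(M) + lambda_het *
                              tcrossprod(Vs[[k]]))
        Ws[[k]] <- Ws[[k]] * num / pmax(den, INMF_EPS)
        WtW <- crossprod(Ws[[k]])
        den <- WtW %*% (H + Vs[[k]]) + lambda_het * WtW %*% Vs[[k]]
        Vs[[k]] <- Vs[[k]] * crossprod(Ws[[k]], Xs[[k]]) /
          pmax(den, INMF_EPS)
        A <- A + crossprod(Ws[[k]], Xs[[k]])
        B <- B + crossprod(Ws[[k]]) %*% (H + Vs[[k]])
      }
      H <- H * A / pmax(B, INMF_EPS)
      kk <- length(history)
      if (kk >= 2L && abs(history[kk] - history[kk - 1L]) /
            max(abs(history[kk - 1L]), 1) < tol) break
    }
    final <- objective()
    history <- c(history, final)
    if (is.null(best) || final < best$objective)
      best <- list(H = H, W = Ws, V = Vs, objective = final,
                   history = history, best_start = s)
  }
  best
}
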