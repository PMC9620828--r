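# Federated accelerated proximal-gradient solver.
#
# All supervised fits minimize  sum_t L_t(w_t, c_t) + lambda * S(W) + C * A(W)
# where L_t is the cohort's mean-form loss (evaluated server-side), S is a
# non-smooth sparsity penalty handled through its proximal operator, and A is
# a smooth stabilizer (ridge or task-graph quadratic) evaluated client-side.
# The monotone FISTA variant is used so the recorded objective history is
# non-increasing by construction; plain FISTA oscillates and would make that
# invariant unassertable.

#' Describe a federated optimization problem
#'
#' @param session A [create_session()] federation.
#' @param loss `"ls"` or `"logistic"`.
#' @param penalty Non-smooth penalty `S`: `"l1"`, `"l21"` or `"trace"`.
#' @param lambda Weight of the non-smooth penalty, `>= 0`.
#' @param C Weight of the smooth penalty, `>= 0`.
#' @param graph Optional task-graph matrix `R` (see [mean_graph()]).  When
#'   supplied the smooth penalty is `C * (||W R||_F^2 + ridge_eps ||W||_F^2)`;
#'   without it, `C * 0.5 ||W||_F^2` (plain ridge).
#' @param ridge_eps Small ridge added alongside a task graph for
#'   conditioning.
#' @param coupling `"multi_task"` (one coefficient column per server) or
#'   `"pooled"` (a single column; per-server losses and gradients are
#'   aggregated with weights n_k / N, so the pooled objective equals the
#'   loss of the concatenated data).
#' @param intercept Fit per-task intercepts (never penalized)?
#' @return An object of class `"mtl_problem"`.
#' @export
mtl_problem <- function(session, loss = c("ls", "logistic"),
                        penalty = c("l1", "l21", "trace"),
                        lambda = 0, C = 0, graph = NULL, ridge_eps = 0,
                        coupling = c("multi_task", "pooled"),
                        intercept = TRUE) {
  loss <- match.arg(loss)
  penalty <- match.arg(penalty)
  coupling <- match.arg(coupling)
  stopifnot(lambda >= 0, C >= 0, ridge_eps >= 0)
  n_tasks <- if (coupling == "multi_task") length(session$servers) else 1L
  if (!is.null(graph)) {
    graph <- as.matrix(graph)
    if (nrow(graph) != n_tasks)
      stop("graph must have one row per task (", n_tasks, ")")
  }
  structure(list(session = session, loss = loss, penalty = penalty,
                 lambda = lambda, C = C, graph = graph,
                 ridge_eps = ridge_eps, coupling = coupling,
                 intercept = intercept, n_tasks = n_tasks),
            class = "mtl_problem")
}

# Smooth part (losses + C * smooth penalty) and its gradient, evaluated
# through the federation: one synchronization round, one access per server.
# With want_grad = FALSE only loss values are requested (used by the line
# search).
smooth_value_grad <- function(problem, W, cvec, want_grad = TRUE) {
  sess <- problem$session
  ids <- session_task_ids(sess)
  kind <- if (want_grad) "loss_value_grad" else "loss_value"
  p <- session_p(sess)
  if (problem$coupling == "multi_task") {
    resp <- fed_round(sess, function(id) {
      t <- match(id, ids)
      server_compute(sess, id, list(kind = kind, loss = problem$loss,
                                    w = W[, t], c = cvec[t]))
    })
    value <- sum(vapply(resp, `[[`, numeric(1), "value"))
    if (want_grad) {
      gW <- vapply(resp, `[[`, numeric(p), "grad_w")
      gW <- matrix(gW, nrow = p)
      gc <- vapply(resp, `[[`, numeric(1), "grad_c")
    }
  } else {
    resp <- fed_round(sess, function(id) {
      server_compute(sess, id, list(kind = kind, loss = problem$loss,
                                    w = W[, 1L], c = cvec[1L]))
    })
    ns <- unname(vapply(resp, `[[`, numeric(1), "n"))
    wts <- ns / sum(ns)
    value <- sum(wts * vapply(resp, `[[`, numeric(1), "value"))
    if (want_grad) {
      gW <- matrix(0, p, 1L)
      gc <- 0
      for (k in seq_along(resp)) {
        gW[, 1L] <- gW[, 1L] + wts[k] * resp[[k]]$grad_w
        gc <- gc + wts[k] * resp[[k]]$grad_c
      }
    }
  }
  if (problem$C > 0) {
    if (!is.null(problem$graph)) {
      gp <- graph_penalty_value_grad(W, problem$graph)
      value <- value + problem$C * (gp$value + problem$ridge_eps * sum(W^2))
      if (want_grad)
        gW <- gW + problem$C * (gp$grad + 2 * problem$ridge_eps * W)
    } else {
      value <- value + problem$C * 0.5 * sum(W^2)
      if (want_grad) gW <- gW + problem$C * W
    }
  }
  if (!want_grad) return(list(value = value))
  list(value = value, gW = gW, gc = gc)
}

# Per-task intercept-only optimum (closed form): mean outcome for least
# squares, log odds for logistic.  One summary round.
intercept_only_optimum <- function(problem) {
  sess <- problem$session
  if (!problem$intercept) return(rep(0, problem$n_tasks))
  stats <- fed_round(sess, function(id)
    server_compute(sess, id, list(kind = "summary_stats")))
  if (problem$coupling == "pooled") {
    ns <- vapply(stats, `[[`, numeric(1), "n")
    if (problem$loss == "ls") {
      ym <- vapply(stats, `[[`, numeric(1), "y_mean")
      return(sum(ns * ym) / sum(ns))
    }
    np <- sum(vapply(stats, `[[`, numeric(1), "n_pos"))
    nn <- sum(vapply(stats, `[[`, numeric(1), "n_neg"))
    if (np == 0 || nn == 0) stop("logistic fit needs both classes")
    return(log(np / nn))
  }
  vapply(stats, function(s) {
    if (problem$loss == "ls") return(s$y_mean)
    if (s$n_pos == 0 || s$n_neg == 0) stop("logistic fit needs both classes")
    log(s$n_pos / s$n_neg)
  }, numeric(1))
}

#' Smallest penalty weight that zeroes the model
#'
#' From the first-order (subgradient) optimality condition at the all-zero
#' coefficient matrix with intercepts at their intercept-only optimum:
#' the zero matrix is optimal iff the gradient of the smooth part lies in
#' `lambda` times the subdifferential of the penalty at zero.  This gives
#' `max |g|` for the L1 penalty, the largest row L2 norm for the L2,1
#' penalty, and the largest singular value for the trace norm, where `g` is
#' the loss gradient at the intercept-only fit.
#'
#' @param problem An [mtl_problem()]; its `lambda` is ignored.
#' @return The scalar `lambda_max`.
#' @export
lambda_max <- function(problem) {
  c_star <- intercept_only_optimum(problem)
  W0 <- matrix(0, session_p(problem$session), problem$n_tasks)
  g <- smooth_value_grad(problem, W0, c_star, want_grad = TRUE)
  G <- g$gW
  switch(problem$penalty,
         l1 = max(abs(G)),
         l21 = max(sqrt(rowSums(G^2))),
         trace = max(svd(G, nu = 0, nv = 0)$d))
}

#' Log-scale lambda sequence
#'
#' `depth` values geometrically interpolated from `lambda_max` down to
#' `min_ratio * lambda_max`; consecutive ratios are constant.
#'
#' @param lambda_max Largest penalty weight (the first value).
#' @param min_ratio Ratio of the smallest to the largest value, in (0,1).
#' @param depth Number of values, `>= 2`.  Shortening the sequence trades
#'   resolution of the regularization path for speed.
#' @return Strictly decreasing numeric vector of length `depth`.
#' @export
lambda_sequence <- function(lambda_max, min_ratio = 0.01, depth = 20) {
  stopifnot(min_ratio > 0, min_ratio < 1, depth >= 2)
  exp(seq(log(lambda_max), log(lambda_max * min_ratio), length.out = depth))
}

#' Solver options
#'
#' @param max_iter Maximum proximal-gradient iterations per fit.
#' @param tol Termination tolerance, `> 0`.
#' @param rule Termination rule: `"objective_rel"` (relative objective
#'   change), `"param_rel"` (relative coefficient change) or `"iter_only"`
#'   (run to `max_iter`).  The relative rules are the relaxed options; a
#'   looser `tol` shortens training at the cost of precision.
#' @param step_init Initial step size for backtracking.
#' @param step_shrink Multiplicative step shrink factor in (0,1).
#' @param min_ratio,depth Defaults forwarded to [lambda_sequence()] when a
#'   path is requested without an explicit sequence.
#' @return A list of class `"solver_options"`.
#' @export
solver_options <- function(max_iter = 1000, tol = 1e-5,
                           rule = c("objective_rel", "param_rel",
                                    "iter_only"),
                           step_init = 1, step_shrink = 0.5,
                           min_ratio = 0.01, depth = 20) {
  rule <- match.arg(rule)
  stopifnot(tol > 0 || rule == "iter_only",
            step_shrink > 0, step_shrink < 1, step_init > 0)
  structure(list(max_iter = max_iter, tol = tol, rule = rule,
                 step_init = step_init, step_shrink = step_shrink,
                 min_ratio = min_ratio, depth = depth),
            class = "solver_options")
}

#' Check a termination rule against an objective history
#'
#' @param history Numeric vector of objective values (accepted iterates).
#' @param rule `"objective_rel"`, `"param_rel"` or `"iter_only"`.
#' @param tol Tolerance.
#' @param params For `"param_rel"`, a list with matrices `W_prev` and `W`.
#' @return `TRUE` if the rule fires.  `"iter_only"` never fires (the
#'   iteration cap governs); relative rules need at least two history
#'   points.
#' @export
check_termination <- function(history, rule, tol, params = NULL) {
  switch(rule,
         iter_only = FALSE,
         objective_rel = {
           k <- length(history)
           if (k < 2L) return(FALSE)
           abs(history[k] - history[k - 1L]) /
             max(abs(history[k - 1L]), 1) < tol ||
             (tol == 0 && history[k] == history[k - 1L])
         },
         param_rel = {
           if (is.null(params)) return(FALSE)
           sqrt(sum((params$W - params$W_prev)^2)) /
             max(sqrt(sum(params$W_prev^2)), 1) < tol
         },
         stop("unknown termination rule: ", rule))
}

#' Solve a federated problem by monotone FISTA with backtracking
#'
#' Accelerated proximal gradient: at each iteration the gradient of the
#' smooth part is fetched at the momentum point (one synchronization round),
#' a proximal step is taken, and the step size is shrunk until the quadratic
#' upper-bound condition holds (each candidate evaluation costs one further
#' round).  The monotone variant keeps the best iterate, so the objective
#' history is non-increasing.
#'
#' @param problem An [mtl_problem()].
#' @param options A [solver_options()].
#' @param W0,c0 Warm-start coefficients and intercepts; defaults are the
#'   zero matrix and the intercept-only optimum.
#' @return A list of class `"solve_result"`: `model` ([coef_model()]),
#'   `objective` (history), `iterations`, `converged`, `lambda`, `comm`
#'   (rounds/accesses consumed by this fit).
#' @export
fista_solve <- function(problem, options = solver_options(),
                        W0 = NULL, c0 = NULL) {
  sess <- problem$session
  snap <- comm_snapshot(sess)
  p <- session_p(sess)
  T <- problem$n_tasks
  lam <- problem$lambda
  prox <- prox_op(problem$penalty)
  pen <- function(W) if (lam > 0) lam * penalty_value(problem$penalty, W)
                     else 0
  if (is.null(W0)) W0 <- matrix(0, p, T)
  W0 <- matrix(as.numeric(W0), p, T)
  if (is.null(c0)) c0 <- intercept_only_optimum(problem)
  c0 <- rep(as.numeric(c0), length.out = T)
  if (!problem$intercept) c0 <- rep(0, T)

  x <- W0; xc <- c0
  y <- x; yc <- xc
  f0 <- smooth_value_grad(problem, x, xc, want_grad = FALSE)$value
  Fx <- f0 + pen(x)
  if (!is.finite(Fx))
    stop("non-finite objective at the starting point (value = ", Fx, ")")
  history <- Fx
  a <- 1
  t <- options$step_init
  x_old <- x; xc_old <- xc
  converged <- FALSE
  iters <- 0L
  for (k in seq_len(options$max_iter)) {
    iters <- k
    g <- smooth_value_grad(problem, y, yc, want_grad = TRUE)
    repeat {
      z <- prox(y - t * g$gW, t * lam)
      zc <- if (problem$intercept) yc - t * g$gc else yc
      fz <- smooth_value_grad(problem, z, zc, want_grad = FALSE)$value
      dW <- z - y; dc <- zc - yc
      bound <- g$value + sum(g$gW * dW) + sum(g$gc * dc) +
        (sum(dW^2) + sum(dc^2)) / (2 * t)
      if (fz <= bound + 1e-12 * max(1, abs(bound))) break
      t <- t * options$step_shrink
      if (t < 1e-20)
        stop("backtracking failed: step size underflow (objective ", fz, ")")
    }
    Fz <- fz + pen(z)
    if (!is.finite(Fz))
      stop("non-finite objective at iteration ", k, " (value = ", Fz, ")")
    # monotone step: keep the better of the proximal candidate and the
    # previous iterate.  A rejected candidate means the momentum
    # extrapolation overshot, so the momentum sequence is restarted from
    # the current iterate (otherwise the solver can stall on a flat
    # objective and terminate prematurely).
    accepted <- Fz <= Fx
    x_old <- x; xc_old <- xc
    if (accepted) {
      x_new <- z; xc_new <- zc; F_new <- Fz
      a_new <- (1 + sqrt(1 + 4 * a^2)) / 2
      y <- x_new + (a / a_new) * (z - x_new) +
        ((a - 1) / a_new) * (x_new - x)
      yc <- xc_new + (a / a_new) * (zc - xc_new) +
        ((a - 1) / a_new) * (xc_new - xc)
      a <- a_new
    } else {
      x_new <- x; xc_new <- xc; F_new <- Fx
      y <- x; yc <- xc
      a <- 1
    }
    x <- x_new; xc <- xc_new; Fx <- F_new
    history <- c(history, Fx)
    if (accepted &&
        check_termination(history, options$rule, options$tol,
                          list(W_prev = x_old, W = x))) {
      converged <- TRUE
      break
    }
  }
  task_ids <- if (problem$coupling == "multi_task")
    session_task_ids(sess) else "pooled"
  model <- coef_model(x, xc,
                      feature_names =
                        sess$servers[[1L]]$dataset$feature_names,
                      task_ids = task_ids, loss = problem$loss)
  structure(list(model = model, objective = history, iterations = iters,
                 converged = converged, lambda = lam,
                 comm = comm_diff(sess, snap)),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat("solve_result: lambda=", signif(x$lambda, 4), ", ", x$iterations,
      " iteration(s), objective ", signif(utils::tail(x$objective, 1), 6),
      if (x$converged) ", converged" else ", iteration cap reached",
      "\n", sep = "")
  cat("  comm: rounds=", x$comm$rounds, ", accesses=",
      x$comm$total_accesses, "\n", sep = "")
  invisible(x)
}

# Does a fitted model pass the disclosure guard of the session policy?
# Multi-task columns are compared against their own server's sample count;
# a pooled vector against the total across servers.
guard_check <- function(session, W) {
  if (!session$policy$nonzero_guard) return(TRUE)
  ns <- session_n(session)
  if (ncol(W) == length(ns)) {
    all(vapply(seq_along(ns), function(t)
      disclosure_guard(W[, t], ns[t]), logical(1)))
  } else {
    disclosure_guard(W[, 1L], sum(ns))
  }
}

#' Fit a warm-started regularization path
#'
#' Fits the problem at each value of a descending lambda sequence, warm
#' starting each fit from the previous solution.  The first fit starts from
#' the zero matrix with intercept-only intercepts; at `lambda_max` that
#' starting point is already optimal, so the first path entry is the
#' all-zero model.  When the session policy enables the disclosure guard,
#' solutions whose nonzero count exceeds the releasing server's sample count
#' are withheld: the path entry keeps its lambda and objective but carries
#' no model.
#'
#' @param problem An [mtl_problem()]; its `lambda` field is overridden by
#'   the sequence.
#' @param lambdas Descending lambda sequence; default
#'   [lambda_sequence()] from [lambda_max()] with the options' `min_ratio`
#'   and `depth`.
#' @param options A [solver_options()].
#' @return An object of class `"reg_path"`: list with `lambdas` and `fits`
#'   (one [fista_solve()] result per lambda, `model = NULL` where the guard
#'   withheld it).
#' @export
solve_path <- function(problem, lambdas = NULL,
                       options = solver_options()) {
  if (is.null(lambdas)) {
    lmax <- lambda_max(problem)
    lambdas <- lambda_sequence(lmax, options$min_ratio, options$depth)
  }
  if (any(diff(lambdas) >= 0)) stop("'lambdas' must be strictly decreasing")
  p <- session_p(problem$session)
  W <- matrix(0, p, problem$n_tasks)
  cvec <- NULL
  fits <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    problem$lambda <- lambdas[i]
    res <- fista_solve(problem, options, W0 = W, c0 = cvec)
    W <- res$model$W
    cvec <- res$model$c
    res$guard_rejected <- !guard_check(problem$session, W)
    if (res$guard_rejected) res$model <- NULL
    fits[[i]] <- res
  }
  structure(list(lambdas = lambdas, fits = fits,
                 penalty = problem$penalty, coupling = problem$coupling),
            class = "reg_path")
}

#' @export
print.reg_path <- function(x, ...) {
  nz <- vapply(x$fits, function(f) {
    if (is.null(f$model)) NA_integer_
    else sum(rowSums(f$model$W != 0) > 0)
  }, integer(1))
  cat("reg_path (", x$penalty, "): ", length(x$lambdas),
      " lambda value(s) from ", signif(x$lambdas[1], 4), " to ",
      signif(utils::tail(x$lambdas, 1), 4), "\n", sep = "")
  cat("  active features per fit:", paste(nz, collapse = " "), "\n")
  invisible(x)
}
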