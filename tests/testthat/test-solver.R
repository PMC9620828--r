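test_that("unpenalized least squares matches the normal equations", {
  mk <- make_session(n_tasks = 1, p = 5, n = 30, s = 2, seed = 21)
  pr <- mtl_problem(mk$session, penalty = "l1", lambda = 0)
  fit <- fista_solve(pr, solver_options(tol = 1e-13, max_iter = 5000))
  d <- mk$datasets[[1]]
  ols <- stats::lm.fit(cbind(1, d$X), d$y)$coefficients
  expect_equal(unname(fit$model$W[, 1]), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(unname(fit$model$c[[1]]), unname(ols[1]), tolerance = 1e-6)
})

test_that("lambda_max matches hand-derived subgradient conditions", {
  # pooled lasso, X = [1; -1], y = (1, -1), no intercept: |X'y|/n = 1
  d <- task_dataset(matrix(c(1, -1), 2, 1), c(1, -1))
  sess <- create_session(list(d), privacy_policy(nonzero_guard = FALSE))
  pr <- mtl_problem(sess, penalty = "l1", coupling = "pooled",
                    intercept = FALSE)
  expect_equal(lambda_max(pr), 1)

  # two tasks each X = [1], y = (1), no intercept: row gradient (-1, -1)
  ds <- list(task_dataset(matrix(1), 1, task_id = "a"),
             task_dataset(matrix(1), 1, task_id = "b"))
  s2 <- create_session(ds, privacy_policy(nonzero_guard = FALSE))
  p2 <- mtl_problem(s2, penalty = "l21", intercept = FALSE)
  expect_equal(lambda_max(p2), sqrt(2))
})

test_that("lambda_max separates zero from nonzero solutions", {
  set.seed(31)
  for (pen in c("l1", "l21", "trace")) {
    mk <- make_session(n_tasks = 2, p = 8, n = 12, s = 2,
                       seed = sample.int(1e4, 1))
    pr <- mtl_problem(mk$session, penalty = pen)
    lm0 <- lambda_max(pr)
    pr$lambda <- lm0 * 1.001
    expect_true(all(fista_solve(pr)$model$W == 0), info = pen)
    pr$lambda <- lm0 * 0.9
    expect_true(any(fista_solve(pr)$model$W != 0), info = pen)
  }
})

test_that("lambda sequences interpolate on the log scale", {
  expect_equal(lambda_sequence(1, 0.01, 3), c(1, 0.1, 0.01))
  expect_equal(lambda_sequence(2, 0.5, 2), c(2, 1))
  s <- lambda_sequence(3.7, 0.001, 15)
  expect_length(s, 15)
  expect_equal(diff(log(s)), rep(diff(log(s))[1], 14))
  expect_true(all(diff(s) < 0))
  expect_error(lambda_sequence(1, 1.5, 5), "min_ratio")
})

test_that("termination rules read the history as specified", {
  expect_true(check_termination(c(1, 1), "objective_rel", 1e-5))
  expect_false(check_termination(1, "objective_rel", 1e-5))
  expect_true(check_termination(c(5, 5), "objective_rel", 0))
  expect_false(check_termination(c(5, 4.9), "objective_rel", 0))
  expect_false(check_termination(c(5, 4), "iter_only", 1e-3))
  expect_true(check_termination(
    c(2, 1), "param_rel", 1e-2,
    list(W_prev = diag(2), W = diag(2) + 1e-5)))
})

test_that("multi-task gradient rounds touch every server exactly once", {
  mk <- make_session(n_tasks = 3, p = 6, n = 10, s = 1, seed = 5)
  pr <- mtl_problem(mk$session, penalty = "l21")
  W <- matrix(0, 6, 3)
  fedmtl:::smooth_value_grad(pr, W, rep(0, 3))
  cs <- comm_summary(mk$session)
  expect_equal(cs$rounds, 1L)
  expect_equal(cs$total_accesses, 3L)
})

test_that("pooled gradients equal the centralized gradient on the union", {
  set.seed(33)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  halves <- list(task_dataset(X[1:25, ], y[1:25], task_id = "a"),
                 task_dataset(X[26:40, ], y[26:40], task_id = "b"))
  sess <- create_session(halves, privacy_policy(nonzero_guard = FALSE))
  pr <- mtl_problem(sess, penalty = "l1", coupling = "pooled")
  w <- rnorm(6); c0 <- 0.3
  g <- fedmtl:::smooth_value_grad(pr, matrix(w), c0)
  cen <- least_squares_value_grad(X, y, w, c0)
  expect_equal(g$gW[, 1], cen$grad_w, tolerance = 1e-12)
  expect_equal(g$gc, cen$grad_c, tolerance = 1e-12)
  expect_equal(g$value, cen$value, tolerance = 1e-12)
})

test_that("objective histories are non-increasing across random problems", {
  set.seed(34)
  for (i in 1:10) {
    pen <- sample(c("l1", "l21", "trace"), 1)
    mk <- make_session(n_tasks = 2, p = 7, n = 9, s = 2,
                       seed = sample.int(1e4, 1))
    pr <- mtl_problem(mk$session, penalty = pen,
                      lambda = runif(1, 0.01, 0.5))
    fit <- fista_solve(pr, solver_options(max_iter = 200))
    expect_true(all(diff(fit$objective) <= 1e-12), info = pen)
  }
})

test_that("warm-started paths match cold-started fits", {
  mk <- make_session(n_tasks = 2, p = 10, n = 30, s = 3, seed = 35)
  pr <- mtl_problem(mk$session, penalty = "l21")
  opts <- solver_options(tol = 1e-11, max_iter = 4000)
  lams <- lambda_sequence(lambda_max(pr), 0.05, 6)
  path <- solve_path(pr, lams, opts)
  expect_true(all(path$fits[[1]]$model$W == 0))   # all-zero at lambda_max
  for (j in c(3, 6)) {
    pr$lambda <- lams[j]
    cold <- fista_solve(pr, opts)
    expect_equal(path$fits[[j]]$model$W, cold$model$W, tolerance = 1e-4)
  }
  nz <- vapply(path$fits, function(f) sum(f$model$W != 0), numeric(1))
  expect_true(nz[1] <= nz[3] && nz[3] <= nz[6])   # sparsity loosens
})

test_that("quantized transport degrades gracefully with more digits", {
  base <- make_session(n_tasks = 2, p = 8, n = 20, s = 2, seed = 36)
  pr <- mtl_problem(base$session, penalty = "l21", lambda = 0.15)
  exact <- fista_solve(pr)$model$W
  devs <- vapply(c(2, 4, 6), function(dg) {
    mk <- make_session(n_tasks = 2, p = 8, n = 20, s = 2, seed = 36,
                       digits = dg)
    prq <- mtl_problem(mk$session, penalty = "l21", lambda = 0.15)
    max(abs(fista_solve(prq)$model$W - exact))
  }, numeric(1))
  expect_true(all(diff(devs) <= 0))
  expect_lt(devs[3], 1e-3)
})
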