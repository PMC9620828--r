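test_that("huge penalties give the all-zero model", {
  mk <- make_session(n_tasks = 3, p = 10, n = 15, s = 2, seed = 41)
  fit <- fit_l21(mk$session, lambda = 1e6)
  expect_true(all(fit$model$W == 0))
})

test_that("joint selection recovers a shared support on easy instances", {
  d <- gen_case1(n_tasks = 3, p = 30, n_per_task = 60, s = 3,
                 noise_sd = 0.3, seed = 42)
  sess <- create_session(d$datasets, privacy_policy(nonzero_guard = FALSE))
  pr <- mtl_problem(sess, penalty = "l21")
  fit <- fit_l21(sess, lambda = 0.2 * lambda_max(pr))
  selected <- which(rowSums(fit$model$W != 0) > 0)
  expect_true(all(d$truth$support %in% selected))
  expect_equal(selection_accuracy(feature_scores(fit$model),
                                  d$truth$support), 1)
})

test_that("trace-penalized fits lose rank as the penalty grows", {
  mk <- make_session(n_tasks = 3, p = 8, n = 25, s = 3, seed = 43)
  pr <- mtl_problem(mk$session, penalty = "trace")
  lmax <- lambda_max(pr)
  ranks <- vapply(c(0.05, 0.3, 0.7, 1.01) * lmax, function(l) {
    f <- fit_trace(mk$session, lambda = l)
    sum(svd(f$model$W, nu = 0, nv = 0)$d > 1e-8)
  }, numeric(1))
  expect_true(all(diff(ranks) <= 0))
  expect_equal(ranks[4], 0)
})

test_that("the task network drives coefficients together as C grows", {
  d <- gen_case1(n_tasks = 3, p = 10, n_per_task = 40, s = 2,
                 mode = "homogeneous", seed = 44)
  sess <- create_session(d$datasets, privacy_policy(nonzero_guard = FALSE))
  colvar <- function(C) {
    f <- fit_net(sess, lambda = 0.05, C = C)
    mean(apply(f$model$W, 1, stats::var))
  }
  expect_lt(colvar(50), 0.05 * colvar(0) + 1e-10)

  # C = 0 reduces to an independent lasso per task
  f0 <- fit_net(sess, lambda = 0.1, C = 0, ridge_eps = 0,
                options = solver_options(tol = 1e-11, max_iter = 3000))
  for (t in 1:3) {
    s1 <- create_session(d$datasets[t], privacy_policy(nonzero_guard = FALSE))
    ft <- fit_lasso(s1, lambda = 0.1,
                    options = solver_options(tol = 1e-11, max_iter = 3000))
    expect_lt(max(abs(f0$model$W[, t] - ft$model$W[, 1])), 1e-5)
  }
})

test_that("federated lasso equals glmnet on one server and is split-invariant", {
  d <- gen_case1(n_tasks = 1, p = 15, n_per_task = 40, s = 3, seed = 45)
  sess <- create_session(d$datasets, privacy_policy(nonzero_guard = FALSE))
  opts <- solver_options(tol = 1e-13, max_iter = 8000)
  fit <- fit_lasso(sess, lambda = 0.1, options = opts)
  g <- glmnet::glmnet(d$datasets[[1]]$X, d$datasets[[1]]$y, lambda = 0.1,
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(fit$model$W[, 1]), as.numeric(g$beta),
               tolerance = 1e-5)
  expect_equal(unname(fit$model$c[[1]]), as.numeric(g$a0),
               tolerance = 1e-5)

  # splitting the data across two servers changes nothing
  X <- d$datasets[[1]]$X; y <- d$datasets[[1]]$y
  halves <- list(task_dataset(X[1:23, ], y[1:23], task_id = "h1"),
                 task_dataset(X[24:40, ], y[24:40], task_id = "h2"))
  s2 <- create_session(halves, privacy_policy(nonzero_guard = FALSE))
  fit2 <- fit_lasso(s2, lambda = 0.1, options = opts)
  expect_equal(fit2$model$W, fit$model$W, tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("L2,1 fitting with one task reduces to the lasso", {
  d <- gen_case1(n_tasks = 1, p = 12, n_per_task = 30, s = 2, seed = 46)
  sess <- create_session(d$datasets, privacy_policy(nonzero_guard = FALSE))
  opts <- solver_options(tol = 1e-12, max_iter = 4000)
  f21 <- fit_l21(sess, lambda = 0.12, options = opts)
  fl <- fit_lasso(sess, lambda = 0.12, options = opts)
  expect_equal(f21$model$W, fl$model$W, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("federated cross-validation is deterministic and near-oracle", {
  d <- gen_case1(n_tasks = 2, p = 15, n_per_task = 40, s = 3,
                 noise_sd = 0.5, seed = 47)
  sess <- create_session(d$datasets, privacy_policy(nonzero_guard = FALSE))
  opts <- solver_options(max_iter = 300, depth = 10)
  cv1 <- cross_validate(sess, "l21", k_folds = 5, seed = 99, options = opts)
  cv2 <- cross_validate(sess, "l21", k_folds = 5, seed = 99, options = opts)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$lambda_best, cv2$lambda_best)
  expect_equal(nrow(cv1$cv_table), 10)
  # the selected model generalizes: held-out-style error close to the best
  # achievable along the grid
  expect_lte(cv1$cv_table$mean_metric[cv1$best],
             min(cv1$cv_table$mean_metric, na.rm = TRUE) + 1e-12)
  # selected support is informative on this easy instance
  expect_gte(selection_accuracy(feature_scores(cv1$model),
                                d$truth$support), 2 / 3)
  expect_error(cross_validate(sess, "l21", k_folds = 50), "k_folds")
})

test_that("binary outcomes stratify folds and use misclassification", {
  d <- gen_case1(n_tasks = 2, p = 8, n_per_task = 40, s = 2,
                 outcome = "binary", seed = 48)
  sess <- create_session(d$datasets, privacy_policy(nonzero_guard = FALSE))
  cv <- cross_validate(sess, "lasso", loss = "logistic", k_folds = 4,
                       seed = 3, options = solver_options(max_iter = 150,
                                                          depth = 8))
  expect_equal(cv$metric, "misclass")
  for (i in 1:2) {
    folds <- cv$folds[[i]]
    y <- d$datasets[[i]]$y
    per_fold_pos <- tapply(y > 0, folds, mean)
    expect_lt(diff(range(per_fold_pos)), 0.5)   # roughly balanced classes
  }
})

test_that("the disclosure guard blocks saturated releases", {
  d <- gen_case1(n_tasks = 2, p = 40, n_per_task = 8, s = 4, seed = 49)
  sess <- create_session(d$datasets, privacy_policy(nonzero_guard = TRUE))
  pr <- mtl_problem(sess, penalty = "l21")
  lmax <- lambda_max(pr)
  expect_error(fit_l21(sess, lambda = 1e-4 * lmax), "disclosure guard")
  path <- fit_l21(sess, lambda = lambda_sequence(lmax, 1e-4, 8))
  rejected <- vapply(path$fits, function(f) isTRUE(f$guard_rejected),
                     logical(1))
  expect_true(any(rejected))
  expect_true(all(vapply(path$fits[rejected],
                         function(f) is.null(f$model), logical(1))))
  expect_false(rejected[1])                      # zero model always passes
})
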