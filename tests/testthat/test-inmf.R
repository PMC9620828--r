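test_that("noiseless planted factors are recovered to high accuracy", {
  set.seed(61)
  r <- 2; p <- 40; ns <- c(25, 30)
  H <- matrix(runif(r * p), r, p)
  ds <- lapply(1:2, function(k) {
    W <- matrix(runif(ns[k] * r), ns[k], r)
    V <- matrix(runif(r * p, 0, 0.3), r, p)
    task_dataset(W %*% (H + V), rep(0, ns[k]),
                 task_id = paste0("cohort", k))
  })
  sess <- create_session(ds, privacy_policy(nonzero_guard = FALSE))
  m <- fit_inmf(sess, rank = 2, lambda_het = 0, n_starts = 5,
                max_iter = 800, tol = 1e-10, seed = 17)
  total <- sum(vapply(ds, function(d) sum(d$X^2), numeric(1)))
  rel_err <- sqrt(m$objective / total)
  expect_lt(rel_err, 1e-3)
  expect_true(all(diff(m$history) <= 1e-8 * pmax(1, abs(m$history[-1]))))
  expect_true(all(m$H >= 0))
})

test_that("update rounds meter one access per server and guard zeros", {
  d <- gen_case2(p = 30, n_per_cohort = 12, n_signal = 10, seed = 62)
  sess <- create_session(d$datasets, privacy_policy(nonzero_guard = FALSE))
  m <- fit_inmf(sess, rank = 2, n_starts = 1, max_iter = 3, tol = 1e-12,
                seed = 1)
  before <- comm_summary(sess)
  st <- inmf_update_round(sess, m$H)
  after <- comm_summary(sess)
  expect_equal(after$rounds - before$rounds, 1L)
  expect_equal(after$total_accesses - before$total_accesses, 2L)
  expect_true(all(is.finite(st$H)) && all(st$H >= 0))

  # all-zero data: denominators vanish but H stays finite
  zeros <- lapply(1:2, function(k)
    task_dataset(matrix(0, 5, 8), rep(0, 5), task_id = paste0("z", k)))
  zs <- create_session(zeros, privacy_policy(nonzero_guard = FALSE))
  mz <- fit_inmf(zs, rank = 2, n_starts = 1, max_iter = 5, seed = 2)
  expect_true(all(is.finite(mz$H)))
  expect_equal(inmf_objective(zs, matrix(0, 2, 8)), 0)
})

test_that("objective decreases monotonically over many rounds", {
  set.seed(63)
  ds <- lapply(1:2, function(k)
    task_dataset(matrix(runif(20 * 15), 20, 15), rep(0, 20),
                 task_id = paste0("c", k)))
  sess <- create_session(ds, privacy_policy(nonzero_guard = FALSE))
  m <- fit_inmf(sess, rank = 3, lambda_het = 0.01, n_starts = 1,
                max_iter = 100, tol = 1e-14, seed = 5)
  h <- m$history
  expect_true(all(diff(h) <= 1e-10 * pmax(1, abs(h[-length(h)]))))
  expect_equal(length(h), 101L)   # exactly one objective per round + final
})

test_that("federated and centralized iNMF agree round for round", {
  d <- gen_case2(p = 40, n_per_cohort = 20, n_signal = 12, seed = 64)
  sess <- create_session(d$datasets, privacy_policy(nonzero_guard = FALSE))
  m <- fit_inmf(sess, rank = 3, lambda_het = 0.003, n_starts = 2,
                max_iter = 40, tol = 1e-14, seed = 9)
  ref <- reference_inmf(d$datasets, rank = 3, lambda_het = 0.003,
                        n_starts = 2, max_iter = 40, tol = 1e-14, seed = 9)
  expect_equal(m$best_start, ref$best_start)
  expect_lt(max(abs(m$H - ref$H)), 1e-8)
  expect_equal(m$history, ref$history, tolerance = 1e-10)
})

test_that("signature extraction honors the policy and recovers plants", {
  # a single dominant H entry is the top-1 gene
  m <- structure(list(H = matrix(c(0.1, 0.1, 5, 0.1), 1, 4),
                      gene_names = paste0("g", 1:4)),
                 class = "inmf_model")
  expect_equal(extract_signatures(m, top_k = 1)$shared, "g3")

  d <- gen_case2(shared_fraction = 0.3, seed = 65)
  sess <- create_session(d$datasets)   # shared-only policy on
  m <- fit_inmf(sess, rank = 4, n_starts = 4, max_iter = 1000, tol = 1e-8,
                seed = 66)
  sig <- extract_signatures(m, sess, top_k = length(d$truth$shared))
  expect_gte(length(intersect(sig$shared, d$truth$shared)) /
               length(d$truth$shared), 0.8)
  sigs <- extract_signatures(m, sess,
                             top_k = length(d$truth$specific$cohort1))
  for (k in 1:2) {
    got <- sigs$specific[[paste0("cohort", k)]]
    expect_type(got, "character")      # names only, never factor values
    expect_gte(length(intersect(got, d$truth$specific[[k]])) /
                 length(got), 0.7)
  }
})

test_that("rank selection finds the planted rank by the objective elbow", {
  set.seed(67)
  r_true <- 3; p <- 30; n <- 40
  H <- matrix(runif(r_true * p), r_true, p)
  ds <- lapply(1:2, function(k)
    task_dataset(matrix(runif(n * r_true), n, r_true) %*% H +
                   abs(matrix(rnorm(n * p, sd = 0.05), n, p)),
                 rep(0, n), task_id = paste0("c", k)))
  sess <- create_session(ds, privacy_policy(nonzero_guard = FALSE))
  expect_equal(select_rank(sess, 4), 4L)   # singleton
  sel <- select_rank(sess, 2:5, lambda_het = 0, n_starts = 2,
                     max_iter = 250, tol = 1e-7, seed = 8)
  expect_equal(as.integer(sel), 3L)
  obj <- attr(sel, "objectives")$objective
  expect_true(all(diff(obj) < 0))          # objective falls with rank
})

test_that("invalid inputs are rejected", {
  neg <- task_dataset(matrix(c(-1, 2, 3, 4), 2, 2), c(0, 0))
  sess <- create_session(list(neg), privacy_policy(nonzero_guard = FALSE))
  expect_error(fit_inmf(sess, rank = 1, n_starts = 1, seed = 1),
               "negative entries")
  ok <- task_dataset(matrix(runif(6), 2, 3), c(0, 0))
  s2 <- create_session(list(ok), privacy_policy(nonzero_guard = FALSE))
  expect_error(fit_inmf(s2, rank = 5, n_starts = 1, seed = 1), "rank")
})
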