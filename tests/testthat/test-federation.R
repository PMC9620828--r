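test_that("session creation validates cohorts and starts with a clean log", {
  mk <- make_session(n_tasks = 3)
  cs <- comm_summary(mk$session)
  expect_equal(cs$rounds, 0L)
  expect_equal(cs$total_accesses, 0L)
  expect_length(mk$session$servers, 3L)

  single <- create_session(mk$datasets[1])
  expect_s3_class(single, "fed_session")
  expect_length(single$servers, 1L)

  permuted <- mk$datasets[[2]]
  perm <- rev(seq_along(permuted$feature_names))
  permuted <- task_dataset(permuted$X[, perm], permuted$y,
                           feature_names = permuted$feature_names[perm],
                           task_id = "task2")
  expect_error(create_session(list(mk$datasets[[1]], permuted)),
               "feature list")
  expect_error(create_session(list(mk$datasets[[1]], mk$datasets[[1]])),
               "duplicated task ids")
})

test_that("server_compute enforces the request contract and meters accesses", {
  mk <- make_session(n_tasks = 2, p = 5)
  sess <- mk$session
  p <- 5
  resp <- server_compute(sess, "task1",
                         list(kind = "loss_value_grad", loss = "ls",
                              w = rep(0, p), c = 0))
  expect_named(resp, c("value", "grad_w", "grad_c", "n"))
  expect_length(resp$grad_w, p)
  expect_length(resp$value, 1L)
  expect_equal(comm_summary(sess)$per_server_accesses[["task1"]], 1L)

  server_compute(sess, "task1", list(kind = "summary_stats"))
  expect_equal(comm_summary(sess)$per_server_accesses[["task1"]], 2L)
  expect_equal(comm_summary(sess)$per_server_accesses[["task2"]], 0L)

  expect_error(server_compute(sess, "task1", list(kind = "nonsense")),
               "unknown request kind")
  expect_error(server_compute(sess, "nope", list(kind = "summary_stats")),
               "unknown server id")
  expect_error(server_compute(sess, "task1",
                              list(kind = "loss_value", loss = "ls",
                                   w = rep(0, p + 2), c = 0)),
               "dimension mismatch")
})

test_that("no response payload carries row-level data", {
  mk <- make_session(n_tasks = 2, p = 6, n = 9)
  sess <- mk$session
  n_k <- 9
  kinds <- list(
    list(kind = "loss_value", loss = "ls", w = rep(0, 6), c = 0),
    list(kind = "loss_value_grad", loss = "ls", w = rep(0, 6), c = 0),
    list(kind = "summary_stats"),
    list(kind = "metric_value", metric = "mse", w = rep(0, 6), c = 0))
  for (req in kinds) {
    resp <- server_compute(sess, "task1", req)
    for (el in resp) {
      len <- if (is.matrix(el)) nrow(el) * ncol(el) else length(el)
      # aggregates only: nothing as large as the n x p data block, and no
      # element with one row per sample
      expect_lt(len, n_k * 6)
      if (is.matrix(el)) expect_false(nrow(el) == n_k)
    }
  }
})

test_that("quantize rounds half to even on the decimal representation", {
  expect_equal(quantize(3.14159, 2), 3.14)
  expect_equal(quantize(-0.005, 2), 0)
  expect_equal(quantize(0.005, 2), 0)
  expect_equal(quantize(0.015, 2), 0.02)
  expect_equal(quantize(0.025, 2), 0.02)
  x <- rnorm(50)
  expect_identical(quantize(x, Inf), x)
  M <- matrix(rnorm(6), 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(dim(quantize(M, 3)), dim(M))
  expect_equal(colnames(quantize(M, 3)), colnames(M))
  expect_error(quantize(1, 0), ">= 1")
})

test_that("quantize agrees with an exact integer-arithmetic decimal oracle", {
  ks <- c(-2005L, -515L, -250L, -15L, -5L, 0L, 5L, 15L, 25L, 35L, 125L,
          999L, 1005L, 123456L, seq(-400L, 400L, by = 7L))
  for (k in ks) {
    x <- k / 1000
    expect_equal(quantize(x, 2), dec_round_oracle(k, 3L, 2L),
                 info = paste("k =", k))
  }
  # idempotence
  xs <- rnorm(100)
  for (d in c(1, 3, 6))
    expect_identical(quantize(quantize(xs, d), d), quantize(xs, d))
})

test_that("disclosure guard rejects saturated coefficient vectors", {
  expect_false(disclosure_guard(rep(1, 6), 5))
  expect_true(disclosure_guard(rep(1, 5), 5))   # boundary: not 'exceeding'
  expect_true(disclosure_guard(rep(0, 10), 1))
})

test_that("communication metering is exact and replayable", {
  mk <- make_session(n_tasks = 3, p = 8, n = 20, s = 2, seed = 4)
  pr <- mtl_problem(mk$session, penalty = "l21", lambda = 0.1)
  f1 <- fista_solve(pr, solver_options(tol = 1e-8))
  cs <- comm_summary(mk$session)
  # every round touches each of the 3 servers exactly once
  expect_equal(cs$total_accesses, 3L * cs$rounds)
  expect_equal(unname(cs$per_server_accesses),
               rep(cs$rounds, 3L))
  # replay on a fresh identical session gives an identical log
  mk2 <- make_session(n_tasks = 3, p = 8, n = 20, s = 2, seed = 4)
  pr2 <- mtl_problem(mk2$session, penalty = "l21", lambda = 0.1)
  f2 <- fista_solve(pr2, solver_options(tol = 1e-8))
  expect_identical(comm_summary(mk2$session), cs)
  expect_identical(f1$model$W, f2$model$W)
  js <- comm_report_json(mk$session)
  expect_match(as.character(js), "rounds")
})

test_that("iNMF policy keeps cohort-specific factors on the server", {
  d <- gen_case2(p = 30, n_per_cohort = 15, n_signal = 10, seed = 2)
  sess <- create_session(d$datasets)    # default policy: shared-only
  m <- fit_inmf(sess, rank = 2, n_starts = 1, max_iter = 20, seed = 3)
  resp <- server_compute(sess, "cohort1",
                         list(kind = "inmf_H_stats", H = m$H))
  expect_named(resp, c("A", "B", "n"))
  expect_equal(dim(resp$A), dim(m$H))
  expect_error(server_compute(sess, "cohort1", list(kind = "inmf_factors")),
               "policy forbids")
  # with the flag off the factors may be requested explicitly
  sess2 <- create_session(d$datasets,
                          privacy_policy(inmf_shared_only = FALSE))
  m2 <- fit_inmf(sess2, rank = 2, n_starts = 1, max_iter = 5, seed = 3)
  fac <- server_compute(sess2, "cohort1", list(kind = "inmf_factors"))
  expect_named(fac, c("W", "V"))
  # server-side export never crosses the client boundary
  dir <- withr::local_tempdir()
  paths <- server_export_factors(sess, "cohort1", dir)
  expect_true(all(file.exists(paths)))
})
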