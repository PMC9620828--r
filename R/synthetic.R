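# Synthetic multi-cohort generators emulating the package's two simulation
# designs: (1) sparse linear/logistic signals with a support shared across
# cohorts but potentially cohort-specific signs ("heterogeneous"
# signatures), and (2) non-negative matrices superposing a shared and a
# cohort-specific signature.  Truth objects are returned separately from
# the datasets so any selection metric can be scored without re-deriving
# the generative process.

#' Generate multi-cohort sparse-signal regression data (case study 1)
#'
#' Each cohort draws an iid standard-normal feature matrix.  All cohorts
#' share the same coefficient support of size `s`; on the support the
#' coefficients are `+/- magnitude`, with signs drawn iid Rademacher per
#' cohort in `"heterogeneous"` mode (the comorbidity scenario: the same
#' genes, potentially opposite directions) or one shared sign vector in
#' `"homogeneous"` mode.  Continuous outcomes are `y = X w + noise`; binary
#' outcomes are sampled from the logistic model on the same linear score.
#'
#' @param n_tasks Number of cohorts/servers.
#' @param p Number of features.
#' @param n_per_task Samples per cohort (scalar or vector).
#' @param s Support size (default `0.1 * p`).
#' @param mode `"heterogeneous"` or `"homogeneous"`.
#' @param magnitude Absolute coefficient value on the support.
#' @param noise_sd Standard deviation of the additive noise (continuous
#'   outcomes).
#' @param outcome `"continuous"` or `"binary"`.
#' @param seed Seed; the same seed reproduces the datasets bitwise.
#' @return List with `datasets` (list of [task_dataset()]) and `truth`
#'   (list with `support` indices, `signs` s x T matrix, `W_true` p x T).
#' @export
gen_case1 <- function(n_tasks = 3, p = 200, n_per_task = 30,
                      s = max(1, round(0.1 * p)),
                      mode = c("heterogeneous", "homogeneous"),
                      magnitude = 1, noise_sd = 1,
                      outcome = c("continuous", "binary"), seed = NULL) {
  mode <- match.arg(mode)
  outcome <- match.arg(outcome)
  stopifnot(s <= p, all(n_per_task >= 1))
  n_per_task <- rep_len(n_per_task, n_tasks)
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  with_seed(seed, {
    support <- sort(sample.int(p, s))
    base_signs <- sample(c(-1, 1), s, replace = TRUE)
    signs <- if (mode == "homogeneous")
      matrix(base_signs, s, n_tasks)
    else
      matrix(sample(c(-1, 1), s * n_tasks, replace = TRUE), s, n_tasks)
    W_true <- matrix(0, p, n_tasks)
    W_true[support, ] <- magnitude * signs
    feature_names <- paste0("g", seq_len(p))
    datasets <- lapply(seq_len(n_tasks), function(t) {
      n <- n_per_task[t]
      X <- matrix(stats::rnorm(n * p), n, p)
      score <- as.numeric(X %*% W_true[, t])
      y <- if (outcome == "continuous")
        score + stats::rnorm(n, sd = noise_sd)
      else {
        pr <- 1 / (1 + exp(-score))
        2 * stats::rbinom(n, 1, pr) - 1
      }
      task_dataset(X, y, feature_names = feature_names,
                   task_id = paste0("task", t), outcome = outcome)
    })
    list(datasets = datasets,
         truth = list(support = support, signs = signs, W_true = W_true),
         seed = seed)
  })
}

#' Generate multi-cohort non-negative matrices with shared and specific
#' signatures (case study 2)
#'
#' Plants disjoint gene sets: a shared signature of `shared_fraction *
#' n_signal` genes loaded by the shared metagene matrix `H_true`, and one
#' cohort-specific signature per cohort of `(1 - shared_fraction) *
#' n_signal` genes loaded by that cohort's `V_k_true`.  Each signature gene
#' is assigned to one of `rank` metagenes with a `Uniform(0.5, 1.5)` loading
#' scaled by `magnitude` (so effect sizes vary three-fold but every planted
#' gene is genuinely loaded).  The two signatures are superposed with
#' independent sample-loading matrices,
#' `X_k = W_k H_true + U_k V_k_true + |noise|`, entrywise `Uniform(0,1)`
#' loadings: the comorbidity component and the disease-specific component
#' are expressed with their own patterns across samples, so a cohort's
#' local structure has up to `2 * rank` components even though each
#' signature has only `rank`.
#'
#' Per cohort the outcome-associated genes are the shared set plus that
#' cohort's own specific set; `shared_fraction` is the proportion of them
#' that is shared.
#'
#' @param n_cohorts Number of cohorts (default 2).
#' @param p Number of genes.
#' @param n_per_cohort Samples per cohort.
#' @param rank Number of metagenes in the planted factors.
#' @param n_signal Outcome-associated genes per cohort.
#' @param shared_fraction Proportion of each cohort's signal genes that is
#'   shared across cohorts, in (0,1).
#' @param magnitude Scale of the planted loadings.
#' @param noise_sd Standard deviation of the half-normal additive noise.
#' @param seed Seed.
#' @return List with `datasets` (list of [task_dataset()] carrying the
#'   non-negative matrices; the outcome slot holds a dummy zero vector),
#'   `truth` (`shared` gene names, `specific` named list of gene-name
#'   vectors, `H_true`, `V_true`), and `seed`.
#' @export
gen_case2 <- function(n_cohorts = 2, p = 200, n_per_cohort = 60, rank = 4,
                      n_signal = 50, shared_fraction = 0.2, magnitude = 1,
                      noise_sd = 0.1, seed = NULL) {
  stopifnot(shared_fraction > 0, shared_fraction < 1, rank >= 1)
  n_per_cohort <- rep_len(n_per_cohort, n_cohorts)
  n_shared <- round(shared_fraction * n_signal)
  n_specific <- n_signal - n_shared
  if (n_shared + n_cohorts * n_specific > p)
    stop("p too small for the requested signature sizes")
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  gene_names <- paste0("g", seq_len(p))
  with_seed(seed, {
    all_idx <- sample.int(p, n_shared + n_cohorts * n_specific)
    shared_idx <- sort(all_idx[seq_len(n_shared)])
    specific_idx <- lapply(seq_len(n_cohorts), function(k)
      sort(all_idx[n_shared + (k - 1L) * n_specific + seq_len(n_specific)]))
    plant <- function(idx) {
      L <- matrix(0, rank, p)
      rows <- sample(rep_len(seq_len(rank), length(idx)))
      # loadings spread 3-fold but bounded away from zero, so every
      # planted gene is a genuine signature member
      L[cbind(rows, idx)] <- magnitude * stats::runif(length(idx), 0.5, 1.5)
      L
    }
    H_true <- plant(shared_idx)
    V_true <- lapply(specific_idx, plant)
    datasets <- lapply(seq_len(n_cohorts), function(k) {
      n <- n_per_cohort[k]
      W <- matrix(stats::runif(n * rank), n, rank)
      U <- matrix(stats::runif(n * rank), n, rank)
      X <- W %*% H_true + U %*% V_true[[k]] +
        abs(matrix(stats::rnorm(n * p, sd = noise_sd), n, p))
      X[X < 0] <- 0
      task_dataset(X, rep(0, n), feature_names = gene_names,
                   task_id = paste0("cohort", k))
    })
    names(V_true) <- paste0("cohort", seq_len(n_cohorts))
    list(datasets = datasets,
         truth = list(shared = gene_names[shared_idx],
                      specific = stats::setNames(
                        lapply(specific_idx, function(i) gene_names[i]),
                        paste0("cohort", seq_len(n_cohorts)))),
         H_true = H_true, V_true = V_true, seed = seed)
  })
}

#' Generate a suite of federations for scalability experiments
#'
#' For each `K` in `K_range`, a session of `K` case-1-style cohorts with
#' fixed per-task sample size.  Sweeping `n_per_task` externally emulates
#' the varying subject-number arm of the scalability design.
#'
#' @param K_range Server counts (default `1:20`).
#' @param n_per_task Samples per server.
#' @param p Number of features.
#' @param seed Seed; each session derives its own sub-seed.
#' @param policy [privacy_policy()] for the sessions.
#' @param ... Further arguments passed to [gen_case1()].
#' @return Named list of [create_session()] objects (`K1`, `K2`, ...);
#'   session `Kk` has exactly `k` servers.
#' @export
gen_scalability_suite <- function(K_range = 1:20, n_per_task = 30, p = 100,
                                  seed = NULL,
                                  policy = privacy_policy(
                                    nonzero_guard = FALSE), ...) {
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  out <- lapply(seq_along(K_range), function(i) {
    K <- K_range[i]
    d <- gen_case1(n_tasks = K, p = p, n_per_task = n_per_task,
                   seed = seed + i, ...)
    sess <- create_session(d$datasets, policy)
    attr(sess, "truth") <- d$truth
    sess
  })
  stats::setNames(out, paste0("K", K_range))
}
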