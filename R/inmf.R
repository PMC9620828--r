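# Federated integrative non-negative matrix factorization.
#
# Each cohort's non-negative matrix X_k (samples x genes) is factorized as
#   X_k ~ W_k (H + V_k)
# with a shared metagene matrix H (r x genes, client-visible), cohort
# loadings W_k (n_k x r) and cohort-specific metagenes V_k (r x genes), both
# server-local.  The joint objective is
#   sum_k ||X_k - W_k (H + V_k)||_F^2 + lambda_het * sum_k ||W_k V_k||_F^2
# minimized by alternating multiplicative updates.  W_k and V_k are updated
# on their server; H is updated client-side from server-aggregated
# numerator/denominator statistics (r x genes each), so one access per
# server per round suffices and, under the shared-only policy, the
# cohort-specific factors never cross the network.

INMF_EPS <- 1e-12

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# --- server-side kernels (called from server_compute) -----------------------

inmf_server_init <- function(srv, request, server_id) {
  X <- srv$dataset$X
  if (any(X < 0))
    stop("server '", server_id, "': data matrix has negative entries; ",
         "integrative NMF requires non-negative input")
  r <- as.integer(request$rank)
  if (r < 1L || r > min(dim(X)))
    stop("rank must be in 1..min(dim(X)) on server '", server_id, "'")
  scale <- sqrt(max(mean(X), INMF_EPS) / r)
  st <- new.env(parent = emptyenv())
  st$W <- with_seed(request$seed,
                    matrix(stats::runif(nrow(X) * r), nrow(X), r)) * scale
  st$V <- with_seed(request$seed + 1L,
                    matrix(stats::runif(r * ncol(X)), r, ncol(X))) * scale
  st$lambda_het <- request$lambda_het
  if (is.null(srv$inmf_runs)) srv$inmf_runs <- list()
  srv$inmf_runs[[as.character(request$start)]] <- st
  srv$inmf_cur <- st
  list(n = nrow(X))
}

inmf_local_objective <- function(X, W, V, H, lambda_het) {
  sum((X - W %*% (H + V))^2) + lambda_het * sum((W %*% V)^2)
}

inmf_server_update <- function(srv, request, server_id) {
  st <- srv$inmf_cur
  if (is.null(st)) stop("server '", server_id, "': iNMF state not initialized")
  X <- srv$dataset$X
  H <- matrix(request$H, nrow = nrow(st$V), ncol = ncol(st$V))
  lam <- st$lambda_het
  obj_pre <- inmf_local_objective(X, st$W, st$V, H, lam)
  # W update: numerator X M', denominator W (M M' + lam V V')
  M <- H + st$V
  num <- X %*% t(M)
  den <- st$W %*% (tcrossprod(M) + lam * tcrossprod(st$V))
  st$W <- st$W * num / pmax(den, INMF_EPS)
  # V update with the fresh W
  WtW <- crossprod(st$W)
  WtX <- crossprod(st$W, X)
  den <- WtW %*% (H + st$V) + lam * WtW %*% st$V
  st$V <- st$V * WtX / pmax(den, INMF_EPS)
  # H statistics with the fresh factors
  A <- crossprod(st$W, X)
  B <- crossprod(st$W) %*% (H + st$V)
  list(obj_pre = obj_pre, A = A, B = B, n = nrow(X))
}

inmf_server_H_stats <- function(srv, request, server_id) {
  st <- srv$inmf_cur
  if (is.null(st)) stop("server '", server_id, "': iNMF state not initialized")
  X <- srv$dataset$X
  H <- matrix(request$H, nrow = nrow(st$V), ncol = ncol(st$V))
  list(A = crossprod(st$W, X),
       B = crossprod(st$W) %*% (H + st$V),
       n = nrow(X))
}

inmf_server_objective <- function(srv, request, server_id) {
  st <- srv$inmf_cur
  if (is.null(st)) stop("server '", server_id, "': iNMF state not initialized")
  H <- matrix(request$H, nrow = nrow(st$V), ncol = ncol(st$V))
  inmf_local_objective(srv$dataset$X, st$W, st$V, H, st$lambda_het)
}

# Aggregate per-metagene usage of this cohort: the column means of W_k.
# A length-r summary vector, the same disclosure class as a gradient.
inmf_server_loading_summary <- function(srv, request, server_id) {
  st <- srv$inmf_cur
  if (is.null(st)) stop("server '", server_id, "': iNMF state not initialized")
  list(w_mean = colMeans(st$W))
}

inmf_server_restore <- function(srv, request, server_id) {
  st <- srv$inmf_runs[[as.character(request$start)]]
  if (is.null(st)) stop("server '", server_id, "': no stored start ",
                        request$start)
  srv$inmf_cur <- st
  srv$inmf_runs <- srv$inmf_runs[as.character(request$start)]
  list(start = request$start)
}

# Returns gene NAMES selected from the server-local V_k; never the factor
# values themselves.
inmf_server_signature <- function(srv, request, server_id) {
  st <- srv$inmf_cur
  if (is.null(st)) stop("server '", server_id, "': iNMF state not initialized")
  genes <- signature_from_loadings(st$V, srv$dataset$feature_names,
                                   top_k = request$top_k,
                                   threshold_sd = request$threshold_sd)
  list(genes = genes)
}

inmf_server_factors <- function(srv, policy, server_id) {
  if (policy$inmf_shared_only)
    stop("policy forbids releasing cohort-specific factors from server '",
         server_id, "' (inmf_shared_only is set)")
  st <- srv$inmf_cur
  if (is.null(st)) stop("server '", server_id, "': iNMF state not initialized")
  list(W = st$W, V = st$V)
}

# Shared selection rule for H and V_k: rows are normalized to unit maximum
# (metagene scales are arbitrary), a gene is scored by its largest
# normalized loading, and either the top_k genes are taken (ties broken by
# gene index) or all genes whose score exceeds mean + threshold_sd * sd of
# the normalized loadings.
signature_from_loadings <- function(L, gene_names, top_k = NULL,
                                    threshold_sd = 2) {
  L <- as.matrix(L)
  mx <- apply(L, 1, max)
  Ln <- L / ifelse(mx > 0, mx, 1)
  score <- apply(Ln, 2, max)
  if (!is.null(top_k)) {
    k <- min(as.integer(top_k), length(score))
    ord <- order(-score, seq_along(score))
    return(gene_names[sort(ord[seq_len(k)])])
  }
  thr <- mean(Ln) + threshold_sd * stats::sd(Ln)
  gene_names[score > thr]
}

# --- client-side operations -------------------------------------------------

#' One synchronization round of federated integrative NMF
#'
#' Broadcasts the current shared metagene matrix `H`; each server updates
#' its local `W_k` and `V_k` multiplicatively and returns its H-update
#' numerator `A_k = W_k' X_k` and denominator `B_k = W_k' W_k (H + V_k)`
#' along with its objective contribution evaluated before the update
#' (i.e. the joint objective of the state produced by the previous round).
#' The client then updates `H <- H * sum(A_k) / sum(B_k)` with a small
#' epsilon guarding zero denominators.  Exactly one access per server.
#'
#' @param session A [create_session()] federation whose iNMF state has been
#'   initialized (see [fit_inmf()]).
#' @param H Current shared metagene matrix (rank x genes).
#' @return List with the updated `H` and `objective` (the pre-update joint
#'   objective).
#' @export
inmf_update_round <- function(session, H) {
  r <- nrow(H); p <- ncol(H)
  resp <- fed_round(session, function(id)
    server_compute(session, id, list(kind = "inmf_local_update", H = H)))
  A <- matrix(0, r, p); B <- matrix(0, r, p)
  for (re in resp) { A <- A + re$A; B <- B + re$B }
  H_new <- H * A / pmax(B, INMF_EPS)
  list(H = H_new,
       objective = sum(vapply(resp, `[[`, numeric(1), "obj_pre")))
}

#' Joint iNMF objective of the current federated state
#'
#' Sum over servers of the local residual plus heterogeneity penalty; one
#' access per server.
#'
#' @inheritParams inmf_update_round
#' @return Scalar objective value.
#' @export
inmf_objective <- function(session, H) {
  resp <- fed_round(session, function(id)
    server_compute(session, id, list(kind = "inmf_objective", H = H)))
  sum(vapply(resp, `[[`, numeric(1), "value"))
}

#' Fit federated integrative NMF
#'
#' Runs `n_starts` seeded random initializations of the alternating
#' multiplicative scheme and keeps the start with the lowest final
#' objective; within each start the objective is non-increasing round by
#' round.  Factors are initialized entrywise `Uniform(0,1)` scaled by
#' `sqrt(mean(X)/rank)` so the initial reconstruction has the data's
#' magnitude.
#'
#' @param session A [create_session()] whose servers hold non-negative
#'   matrices (use [task_dataset()] with a dummy outcome, or
#'   [gen_case2()]).
#' @param rank Factorization rank `r >= 1`.
#' @param lambda_het Heterogeneity penalty weight `>= 0`.  The penalty
#'   `lambda_het * sum ||W_k V_k||_F^2` only needs to break the allocation
#'   tie between `H` and the `V_k`: structure present in every cohort is
#'   cheaper to keep in `H`, structure unique to one cohort cannot leave
#'   `V_k` without a cross-cohort residual cost.  It should therefore be
#'   small (default 0.003); large values force genuinely cohort-specific
#'   structure into `H` and destroy the disentanglement.
#' @param n_starts Number of random initializations (best kept).
#' @param max_iter Maximum update rounds per start.
#' @param tol Relative objective-change tolerance for round convergence.
#' @param seed Base seed; all per-start, per-server draws are derived from
#'   it.
#' @return An object of class `"inmf_model"`: `H`, `objective`, `history`
#'   (objective per round of the best start), `rank`, `lambda_het`,
#'   `best_start`, `start_objectives`, `comm`, `seed`.  Under the
#'   shared-only policy the cohort-specific factors remain on their
#'   servers; use [extract_signatures()] to obtain gene names from them.
#' @export
fit_inmf <- function(session, rank, lambda_het = 0.003, n_starts = 5,
                     max_iter = 500, tol = 1e-6, seed = NULL) {
  stopifnot(rank >= 1, lambda_het >= 0, n_starts >= 1)
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  snap <- comm_snapshot(session)
  p <- session_p(session)
  ids <- session_task_ids(session)
  stats0 <- fed_round(session, function(id)
    server_compute(session, id, list(kind = "summary_stats")))
  ns <- vapply(stats0, `[[`, numeric(1), "n")
  xm <- sum(ns * vapply(stats0, `[[`, numeric(1), "x_mean")) / sum(ns)
  h_scale <- sqrt(max(xm, INMF_EPS) / rank)

  best <- NULL
  start_obj <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    sseed <- seed * 1000L + s * 100L
    fed_round(session, function(id)
      server_compute(session, id,
                     list(kind = "inmf_init", rank = rank,
                          lambda_het = lambda_het,
                          seed = sseed + match(id, ids), start = s)))
    H <- with_seed(sseed, matrix(stats::runif(rank * p), rank, p)) * h_scale
    history <- numeric(0)
    for (it in seq_len(max_iter)) {
      st <- inmf_update_round(session, H)
      H <- st$H
      history <- c(history, st$objective)
      k <- length(history)
      if (k >= 2L &&
          abs(history[k] - history[k - 1L]) /
            max(abs(history[k - 1L]), 1) < tol) break
    }
    final <- inmf_objective(session, H)
    history <- c(history, final)
    start_obj[s] <- final
    if (is.null(best) || final < best$objective)
      best <- list(H = H, objective = final, history = history, start = s)
  }
  # point every server back at the winning start's factors so later
  # signature/objective requests see the state matching the retained H
  fed_round(session, function(id)
    server_compute(session, id, list(kind = "inmf_restore",
                                     start = best$start)))
  structure(list(H = best$H, objective = best$objective,
                 history = best$history, rank = rank,
                 lambda_het = lambda_het, best_start = best$start,
                 start_objectives = start_obj, seed = seed,
                 gene_names = session$servers[[1L]]$dataset$feature_names,
                 comm = comm_diff(session, snap)),
            class = "inmf_model")
}

#' @export
print.inmf_model <- function(x, ...) {
  cat("inmf_model: rank ", x$rank, ", ", ncol(x$H), " genes, objective ",
      signif(x$objective, 6), " (best of ", length(x$start_objectives),
      " start(s))\n", sep = "")
  cat("  comm: rounds=", x$comm$rounds, ", accesses=",
      x$comm$total_accesses, "\n", sep = "")
  invisible(x)
}

#' Extract shared and cohort-specific gene signatures
#'
#' The shared signature is read off the client-visible `H`.  When the
#' fitting session is available, each metagene row of `H` is weighted by
#' every cohort's average loading on it (an aggregate the servers release,
#' one access per server) and a gene's shared score is the minimum over
#' cohorts of its largest weighted loading.  The weighting matters: the
#' factorization admits near-degenerate optima in which one cohort's
#' specific structure sits in a row of `H` that the other cohort simply
#' does not load, and requiring expression in every cohort filters exactly
#' those rows out.  Without a session, genes are scored on row-normalized
#' `H` alone.
#'
#' Either the `top_k` highest-scoring genes or all genes above
#' `mean + threshold_sd * sd` of the (normalized) scores are selected.
#' Cohort-specific signatures are computed with the analogous rule on each
#' server's local `V_k` and returned as gene names only, so the
#' shared-only policy is respected.
#'
#' @param model A fitted [fit_inmf()] model.
#' @param session The federation the model was fitted on; required for
#'   cohort-specific sets and for the cross-cohort weighting of the shared
#'   score.
#' @param top_k Select the `top_k` highest-scoring genes (ties broken by
#'   gene index); mutually exclusive with the threshold rule.
#' @param threshold_sd Threshold multiplier when `top_k` is `NULL`.
#' @return List with `shared` (character vector) and, when `session` is
#'   given, `specific` (named list of character vectors, one per server).
#' @export
extract_signatures <- function(model, session = NULL, top_k = NULL,
                               threshold_sd = 2) {
  if (!is.null(session)) {
    wb <- fed_round(session, function(id)
      server_compute(session, id, list(kind = "inmf_loading_summary")))
    per_cohort <- vapply(wb, function(re)
      apply(re$w_mean * model$H, 2, max), numeric(ncol(model$H)))
    score <- apply(per_cohort, 1, min)
    if (max(score) > 0) score <- score / max(score)
    shared <- if (!is.null(top_k)) {
      k <- min(as.integer(top_k), length(score))
      ord <- order(-score, seq_along(score))
      model$gene_names[sort(ord[seq_len(k)])]
    } else {
      model$gene_names[score > mean(score) + threshold_sd *
                         stats::sd(score)]
    }
  } else {
    shared <- signature_from_loadings(model$H, model$gene_names,
                                      top_k = top_k,
                                      threshold_sd = threshold_sd)
  }
  out <- list(shared = shared)
  if (!is.null(session)) {
    resp <- fed_round(session, function(id)
      server_compute(session, id,
                     list(kind = "inmf_signature", top_k = top_k,
                          threshold_sd = threshold_sd)))
    out$specific <- lapply(resp, `[[`, "genes")
  }
  out
}

#' Select the factorization rank by the objective elbow
#'
#' Fits each candidate rank and returns the elbow of the objective-vs-rank
#' curve, i.e. the candidate with the largest second difference.  With
#' fewer than three candidates the candidate with the lowest objective is
#' returned (a single candidate is returned as is).
#'
#' @inheritParams fit_inmf
#' @param ranks Integer vector of candidate ranks (ascending).
#' @param n_starts Random starts per candidate (fewer than for a final fit
#'   is usually enough to rank candidates).
#' @return The selected rank, with the objective table in attribute
#'   `"objectives"`.
#' @export
select_rank <- function(session, ranks, lambda_het = 0.003, n_starts = 2,
                        max_iter = 200, tol = 1e-5, seed = NULL) {
  ranks <- sort(unique(as.integer(ranks)))
  if (length(ranks) == 1L) return(ranks)
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  obj <- vapply(seq_along(ranks), function(i)
    fit_inmf(session, ranks[i], lambda_het, n_starts, max_iter, tol,
             seed = seed + i)$objective, numeric(1))
  sel <- if (length(ranks) < 3L) ranks[which.min(obj)] else {
    d2 <- diff(diff(obj))                 # o[i-1] - 2 o[i] + o[i+1]
    ranks[which.max(d2) + 1L]
  }
  structure(sel, objectives = data.frame(rank = ranks, objective = obj))
}

#' Export the server-local iNMF factors on the server side
#'
#' Writes `W_k` and `V_k` of one server to CSV files inside `dir`.  This is
#' a server-side export (the factors do not cross the client boundary); it
#' stands in for an authorized-retrieval mechanism and is refused when the
#' policy's shared-only flag is not set... the flag gates the client path,
#' so the export itself is always local to the server.
#'
#' @param session A federation with fitted iNMF state.
#' @param server_id Which server.
#' @param dir Directory to write `W_<id>.csv` and `V_<id>.csv` into.
#' @return The two file paths, invisibly.
#' @export
server_export_factors <- function(session, server_id, dir) {
  srv <- session$servers[[server_id]]
  if (is.null(srv)) stop("unknown server id: ", server_id)
  st <- srv$inmf_cur
  if (is.null(st)) stop("server '", server_id, "': iNMF state not initialized")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pw <- file.path(dir, paste0("W_", server_id, ".csv"))
  pv <- file.path(dir, paste0("V_", server_id, ".csv"))
  utils::write.table(st$W, pw, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(st$V, pv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(pw, pv))
}
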