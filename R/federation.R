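# In-process simulation of a client-server data federation.
#
# Server nodes hold the raw cohort data; the analysis client only ever sees
# what `server_compute()` returns: scalar losses, gradient vectors, factor
# update statistics and other aggregates.  Every request-response exchange is
# metered, and the node's privacy policy (payload quantization, disclosure
# guard, shared-component-only returns) is applied at the boundary.  The
# transport is a plain in-process function call so that a networked backend
# could be substituted without touching the algorithms.

#' Privacy policy applied at the server boundary
#'
#' @param digits Number of decimal places retained on any numeric payload
#'   crossing the client-server boundary (round-half-to-even on the decimal
#'   representation).  `Inf` (the default) transmits full precision.
#'   Truncating digits trades accuracy of the federated fit for smaller
#'   payloads and lower network latency.
#' @param nonzero_guard If `TRUE`, a server refuses to release a fitted
#'   coefficient vector whose number of nonzero entries exceeds the number of
#'   subjects held by that server (an anti-saturation disclosure control; see
#'   [disclosure_guard()]).
#' @param inmf_shared_only If `TRUE`, integrative NMF fits only ever return
#'   the shared metagene matrix H to the client; the cohort-specific factors
#'   W_k and V_k never leave their server.
#'
#' @return An object of class `"privacy_policy"`.
#' @seealso [create_session()], [quantize()], [disclosure_guard()]
#' @export
privacy_policy <- function(digits = Inf, nonzero_guard = TRUE,
                           inmf_shared_only = TRUE) {
  if (is.finite(digits)) {
    digits <- as.integer(digits)
    if (digits < 1L) stop("'digits' must be >= 1 when finite")
  }
  structure(list(digits = digits,
                 nonzero_guard = isTRUE(nonzero_guard),
                 inmf_shared_only = isTRUE(inmf_shared_only)),
            class = "privacy_policy")
}

#' Round numeric payloads to a fixed number of decimal places
#'
#' Rounds each entry to `digits` decimal places using round-half-to-even on
#' the shortest decimal representation of the value, so that e.g.
#' `quantize(-0.005, 2)` is `0` (the tie resolves to the even last digit).
#' This is the transformation applied to every numeric payload exchanged
#' between client and servers when the policy's `digits` is finite; it is
#' idempotent, and `digits = Inf` is the identity.
#'
#' @param x Numeric vector, matrix or array.
#' @param digits Decimal places to retain (`>= 1`), or `Inf` for identity.
#' @return `x` with each entry rounded; dimensions are preserved.
#' @examples
#' quantize(3.14159, 2)
#' quantize(-0.005, 2)   # 0: half rounds to even
#' @export
quantize <- function(x, digits = Inf) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (!is.finite(digits)) return(x)
  digits <- as.integer(digits)
  if (digits < 1L) stop("'digits' must be >= 1 when finite")
  out <- vapply(as.numeric(x), quantize1, numeric(1), digits = digits)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

# Decimal round-half-to-even of one double.  Works on the shortest decimal
# string that round-trips to x, so ties are decided on the decimal the user
# sees, not on the binary expansion.
quantize1 <- function(x, digits) {
  if (!is.finite(x)) return(x)
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  if (as.numeric(s) != x)
    s <- format(x, digits = 17, scientific = FALSE, trim = TRUE)
  neg <- startsWith(s, "-")
  if (neg) s <- substring(s, 2L)
  parts <- strsplit(s, ".", fixed = TRUE)[[1L]]
  int <- parts[1L]
  frac <- if (length(parts) > 1L) parts[2L] else ""
  if (nchar(frac) <= digits) return(x)
  keep <- substring(frac, 1L, digits)
  rest <- substring(frac, digits + 1L)
  r0 <- as.integer(substring(rest, 1L, 1L))
  tail_nonzero <- grepl("[1-9]", substring(rest, 2L))
  up <- r0 > 5L || (r0 == 5L && tail_nonzero)
  if (r0 == 5L && !tail_nonzero) {
    last <- as.integer(substring(keep, digits, digits))
    up <- last %% 2L == 1L
  }
  d <- as.integer(strsplit(paste0(int, keep), "")[[1L]])
  if (up) {
    i <- length(d)
    repeat {
      d[i] <- d[i] + 1L
      if (d[i] < 10L) break
      d[i] <- 0L
      if (i == 1L) { d <- c(1L, d); break }
      i <- i - 1L
    }
  }
  ds <- paste(d, collapse = "")
  n <- nchar(ds)
  val <- as.numeric(paste0(substring(ds, 1L, n - digits), ".",
                           substring(ds, n - digits + 1L)))
  if (neg) -val else val
}

# Apply the policy's quantization recursively to a payload list.
quantize_payload <- function(payload, digits) {
  if (!is.finite(digits)) return(payload)
  rapply(payload, function(el) {
    if (is.numeric(el)) quantize(el, digits) else el
  }, how = "replace")
}

#' Disclosure guard on released coefficient vectors
#'
#' A server-side anti-saturation rule: a fitted coefficient vector may only
#' be released if its number of nonzero entries does not exceed the number of
#' subjects on the server.  A saturated model can interpolate individual
#' observations and is therefore more vulnerable to model-inversion and
#' membership-inference attacks.
#'
#' @param coefficients Numeric vector of fitted coefficients (intercept
#'   excluded).
#' @param n_subjects Number of subjects held by the releasing server.
#' @return `TRUE` (pass) if `sum(coefficients != 0) <= n_subjects`, otherwise
#'   `FALSE` (reject).
#' @export
disclosure_guard <- function(coefficients, n_subjects) {
  stopifnot(n_subjects >= 1)
  sum(coefficients != 0) <= n_subjects
}

#' Create a simulated federation session
#'
#' Wraps one server node around each cohort dataset and attaches an empty
#' communication log.  All cohorts must share an identical feature list (same
#' names, same order): federated fits exchange coefficient vectors indexed by
#' position, so a permuted feature space on one server would silently
#' misalign the model.
#'
#' @param datasets List of [task_dataset()] objects, one per server.
#' @param policy A [privacy_policy()]; applied to every exchange with every
#'   server in the session.
#' @return An object of class `"fed_session"`: an environment holding the
#'   server nodes, the policy and the communication log.  The raw data inside
#'   a node is only reachable through [server_compute()].
#' @examples
#' d <- gen_case1(n_tasks = 2, p = 10, n_per_task = 8, s = 2, seed = 1)
#' sess <- create_session(d$datasets)
#' comm_summary(sess)
#' @export
create_session <- function(datasets, policy = privacy_policy()) {
  if (!is.list(datasets) || length(datasets) < 1L)
    stop("'datasets' must be a non-empty list of task_dataset objects")
  if (!inherits(policy, "privacy_policy"))
    stop("'policy' must be a privacy_policy object")
  for (d in datasets) {
    if (!inherits(d, "task_dataset"))
      stop("every element of 'datasets' must be a task_dataset")
  }
  ref <- datasets[[1L]]$feature_names
  ids <- vapply(datasets, function(d) d$task_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated task ids across servers: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  for (d in datasets) {
    if (!identical(d$feature_names, ref))
      stop("server '", d$task_id,
           "' has a feature list that differs from server '",
           datasets[[1L]]$task_id, "' (names must match in the same order)")
  }
  session <- new.env(parent = emptyenv())
  session$policy <- policy
  session$rounds <- 0L
  session$accesses <- stats::setNames(integer(length(ids)), ids)
  session$servers <- stats::setNames(lapply(datasets, function(d) {
    srv <- new.env(parent = emptyenv())
    srv$dataset <- d
    srv
  }), ids)
  class(session) <- "fed_session"
  session
}

#' @export
print.fed_session <- function(x, ...) {
  ns <- vapply(x$servers, function(s) nrow(s$dataset$X), integer(1))
  cat("Federated session:", length(x$servers), "server(s)\n")
  cat("  servers:",
      paste(sprintf("%s (n=%d)", names(x$servers), ns), collapse = ", "), "\n")
  cat("  features:", length(x$servers[[1L]]$dataset$feature_names), "\n")
  d <- x$policy$digits
  cat("  policy: digits=", if (is.finite(d)) d else "unlimited",
      ", guard=", x$policy$nonzero_guard,
      ", inmf shared-only=", x$policy$inmf_shared_only, "\n", sep = "")
  cat("  comm: rounds=", x$rounds, ", total accesses=",
      sum(x$accesses), "\n", sep = "")
  invisible(x)
}

session_task_ids <- function(session) names(session$servers)

session_p <- function(session)
  length(session$servers[[1L]]$dataset$feature_names)

session_n <- function(session)
  vapply(session$servers, function(s) nrow(s$dataset$X), integer(1))

# One client-initiated synchronization round (a broadcast touching each
# server once).  `fun(server_id)` must perform exactly one server_compute
# call per server.
fed_round <- function(session, fun) {
  session$rounds <- session$rounds + 1L
  lapply(stats::setNames(nm = session_task_ids(session)), fun)
}

#' Execute one request on one server node
#'
#' The only channel through which server-held data can be used.  The request
#' payload is quantized per the session policy before it reaches the server,
#' the response is quantized on the way out, and the per-server access
#' counter is incremented by one.  Responses contain aggregates only
#' (scalars, gradient vectors, factor-update numerator/denominator matrices);
#' no request kind returns row-level data.
#'
#' Request kinds: `loss_value`, `loss_value_grad`, `summary_stats`,
#' `metric_value`, `inmf_init`, `inmf_local_update`, `inmf_H_stats`,
#' `inmf_objective`, `inmf_signature`.
#'
#' @param session A [create_session()] object.
#' @param server_id Which server to address.
#' @param request A list with a `kind` field and kind-specific payload
#'   entries (see Details in the package vignette).
#' @return The server's response list (aggregates only), quantized per
#'   policy.
#' @export
server_compute <- function(session, server_id, request) {
  srv <- session$servers[[server_id]]
  if (is.null(srv)) stop("unknown server id: ", server_id)
  if (!is.list(request) || is.null(request$kind))
    stop("request must be a list with a 'kind' field")
  digits <- session$policy$digits
  request <- quantize_payload(request, digits)
  session$accesses[[server_id]] <- session$accesses[[server_id]] + 1L
  ds <- srv$dataset
  p <- length(ds$feature_names)
  check_w <- function(w) {
    if (length(w) != p)
      stop("payload dimension mismatch on server '", server_id,
           "': got length ", length(w), ", expected ", p)
  }
  response <- switch(
    request$kind,
    loss_value = {
      check_w(request$w)
      v <- loss_value_grad(ds, request$w, request$c, request$loss,
                           want_grad = FALSE)
      list(value = v$value, n = nrow(ds$X))
    },
    loss_value_grad = {
      check_w(request$w)
      v <- loss_value_grad(ds, request$w, request$c, request$loss,
                           want_grad = TRUE)
      list(value = v$value, grad_w = v$grad_w, grad_c = v$grad_c,
           n = nrow(ds$X))
    },
    summary_stats = {
      y <- ds$y
      list(n = nrow(ds$X), y_mean = mean(y),
           n_pos = sum(y > 0), n_neg = sum(y <= 0),
           x_mean = mean(ds$X))
    },
    metric_value = {
      check_w(request$w)
      scores <- as.numeric(ds$X %*% request$w) + request$c
      m <- if (identical(request$metric, "misclass")) {
        lab <- ifelse(scores >= 0, 1, -1)
        mean(lab != ds$y)
      } else {
        mean((scores - ds$y)^2)
      }
      list(metric = m, n = nrow(ds$X))
    },
    inmf_init = inmf_server_init(srv, request, server_id),
    inmf_local_update = inmf_server_update(srv, request, server_id),
    inmf_H_stats = inmf_server_H_stats(srv, request, server_id),
    inmf_objective = list(value = inmf_server_objective(srv, request,
                                                        server_id)),
    inmf_signature = inmf_server_signature(srv, request, server_id),
    inmf_restore = inmf_server_restore(srv, request, server_id),
    inmf_loading_summary = inmf_server_loading_summary(srv, request,
                                                       server_id),
    inmf_factors = inmf_server_factors(srv, session$policy, server_id),
    stop("unknown request kind: ", request$kind)
  )
  quantize_payload(response, digits)
}

#' Summarize the communication log of a session
#'
#' @param session A [create_session()] object.
#' @return A list with `rounds` (client-initiated synchronization rounds),
#'   `total_accesses` (request-response exchanges summed over servers) and
#'   `per_server_accesses` (named vector).  Both conventions are reported
#'   because scalability behaves differently under each: a multi-task
#'   gradient round costs one access per server but only one round, so round
#'   counts are flat in the number of servers while access counts grow
#'   linearly.
#' @export
comm_summary <- function(session) {
  list(rounds = session$rounds,
       total_accesses = sum(session$accesses),
       per_server_accesses = session$accesses)
}

#' Serialize a communication summary to JSON
#'
#' @param session A [create_session()] object.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
comm_report_json <- function(session, path = NULL) {
  js <- jsonlite::toJSON(comm_summary(session), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# Snapshot helper used by solvers to report the communication consumed by a
# single fit.
comm_snapshot <- function(session) {
  list(rounds = session$rounds, accesses = session$accesses)
}

comm_diff <- function(session, snap) {
  list(rounds = session$rounds - snap$rounds,
       total_accesses = sum(session$accesses - snap$accesses),
       per_server_accesses = session$accesses - snap$accesses)
}
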