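# Shared test oracles and fixture builders.  Everything is generated in
# code; no fixture files.

# Central finite-difference gradient of f at x (vector or matrix).
fd_grad <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Exact decimal round-half-to-even oracle on the grid k / 10^d_in, rounded
# to d_out < d_in places, using integer arithmetic only.
dec_round_oracle <- function(k, d_in, d_out) {
  stopifnot(d_in > d_out)
  m <- 10L^(d_in - d_out)
  q <- k %/% m
  r <- k %% m
  half <- m %/% 2L
  up <- r > half || (r == half && q %% 2L != 0L)
  (q + as.integer(up)) / 10^d_out
}

# Small federation over freshly generated regression cohorts.
make_session <- function(n_tasks = 3, p = 12, n = 25, s = 3, seed = 1,
                         guard = FALSE, digits = Inf, ...) {
  d <- gen_case1(n_tasks = n_tasks, p = p, n_per_task = n, s = s,
                 seed = seed, ...)
  sess <- create_session(d$datasets,
                         privacy_policy(digits = digits,
                                        nonzero_guard = guard))
  list(session = sess, data = d,
       datasets = lapply(sess$servers, function(srv) srv$dataset))
}

# Proximal-operator oracle: numerical minimization of
# 0.5 ||Z - W||_F^2 + t * penalty(Z) over small matrices.  Each penalty is
# rewritten in an equivalent smooth form so BFGS converges to full
# precision: z = a^2 - b^2 with |z| = a^2 + b^2 at the optimum (L1),
# epsilon-smoothed row norms (L2,1), and the variational factorization
# ||Z||_* = 0.5 min_{Z = U V'} (||U||^2 + ||V||^2) (trace norm).
prox_oracle <- function(W, t, penalty) {
  # isolate the oracle's multi-start seeding from the caller's RNG stream
  has_rng <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_rng) old_rng <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_rng) assign(".Random.seed", old_rng, envir = globalenv()))
  np <- length(W)
  if (penalty == "l1") {
    obj <- function(ab) {
      z <- ab[1:np]^2 - ab[np + 1:np]^2
      0.5 * sum((z - W)^2) + t * sum(ab^2)
    }
    best <- NULL
    for (s in 1:3) {
      set.seed(s)
      r <- stats::optim(runif(2 * np, 0, 0.5), obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-15))
      if (is.null(best) || r$value < best$value) best <- r
    }
    return(matrix(best$par[1:np]^2 - best$par[np + 1:np]^2,
                  nrow(W), ncol(W)))
  }
  if (penalty == "l21") {
    eps <- 1e-18
    obj <- function(z) {
      Z <- matrix(z, nrow(W), ncol(W))
      0.5 * sum((Z - W)^2) + t * sum(sqrt(rowSums(Z^2) + eps))
    }
    grd <- function(z) {
      Z <- matrix(z, nrow(W), ncol(W))
      as.numeric(Z - W + t * Z / sqrt(rowSums(Z^2) + eps))
    }
    par <- as.numeric(W)
    for (rs in 1:4)   # BFGS restarts reset the Hessian approximation
      par <- stats::optim(par, obj, grd, method = "BFGS",
                          control = list(maxit = 10000,
                                         reltol = 1e-16))$par
    return(matrix(par, nrow(W), ncol(W)))
  }
  r0 <- min(dim(W))
  nu <- nrow(W) * r0
  obj <- function(uv) {
    U <- matrix(uv[1:nu], nrow(W), r0)
    V <- matrix(uv[-(1:nu)], ncol(W), r0)
    0.5 * sum((U %*% t(V) - W)^2) + 0.5 * t * sum(uv^2)
  }
  best <- NULL
  for (s in 1:4) {
    set.seed(s * 11)
    r <- stats::optim(rnorm(nu + ncol(W) * r0, sd = 0.5), obj,
                      method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-15))
    if (is.null(best) || r$value < best$value) best <- r
  }
  U <- matrix(best$par[1:nu], nrow(W), r0)
  V <- matrix(best$par[-(1:nu)], ncol(W), r0)
  U %*% t(V)
}
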