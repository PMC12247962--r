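# Internal numerics and plumbing shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# scalar checks -------------------------------------------------------------

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Cholesky factorization with escalating jitter
#'
#' All Gram-matrix solves in the package go through this single policy:
#' jitter starts at `jitter0` (scaled by the kernel variance upstream) and is
#' escalated tenfold up to `max_jitter` before failing with a condition-number
#' estimate.
#'
#' @return list with `L` (lower-triangular factor), `jitter` actually used.
#' @noRd
chol_jitter <- function(K, jitter0 = 1e-6, max_jitter = 1e-2) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  jit <- jitter0
  n <- nrow(K)
  while (jit <= max_jitter) {
    R <- tryCatch(chol(K + diag(jit, n)), error = function(e) NULL)
    if (!is.null(R)) return(list(L = t(R), jitter = jit))
    jit <- jit * 10
  }
  kap <- tryCatch(kappa(K, exact = FALSE), error = function(e) NA_real_)
  stop(sprintf(
    "Cholesky factorization failed up to jitter %.1e (condition estimate %.3g)",
    max_jitter, kap), call. = FALSE)
}

# triangular solves against a lower factor L (from chol_jitter)
solve_lower <- function(L, B) forwardsolve(L, B)
solve_chol <- function(L, B) backsolve(t(L), forwardsolve(L, B))

logistic <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# row-wise softmax of a matrix
softmax_rows <- function(X) {
  Z <- exp(X - apply(X, 1L, max))
  Z / rowSums(Z)
}

# Adam optimizer over a named list of numeric arrays ------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# key for a (subject, timepoint) sample
sample_key <- function(subject_id, timepoint) {
  paste0(subject_id, "::", timepoint)
}
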