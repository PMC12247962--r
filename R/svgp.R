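# Sparse variational Gaussian process over cell embeddings.
#
# The GP prior f ~ GP(0, k) is summarized by O inducing points Z with
# outputs u; q(u) = N(mu, Sigma) and q(f, u) = q(u) p(f | u).  All solves
# against K_ZZ go through one jittered Cholesky policy, and training uses
# the diagonal of the marginal covariance only, so no M x M matrix is ever
# formed (cost O(O^3 + O^2 M) instead of O(M^3)).

#' Squared-exponential kernel
#'
#' `k(a, b) = variance * exp(-||a - b||^2 / (2 * lengthscale^2))`.
#'
#' @param lengthscale Positive scale parameter (default 0.1).
#' @param variance Output variance, fixed at 1 by default.
#' @return List of class `se_kernel`.
#' @export
se_kernel <- function(lengthscale = 0.1, variance = 1) {
  stop_if_not_scalar_number(lengthscale, "lengthscale", positive = TRUE)
  stop_if_not_scalar_number(variance, "variance", positive = TRUE)
  structure(list(lengthscale = lengthscale, variance = variance),
            class = "se_kernel")
}

# squared Euclidean cross-distances, a x b
sqdist <- function(A, B) {
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

#' Kernel Gram matrix between two point sets
#'
#' @param A,B Matrices with matching column count `q` (rows are points).
#' @param kernel An [se_kernel()].
#' @return `nrow(A)` x `nrow(B)` matrix of kernel evaluations.  Symmetric
#'   with unit diagonal when `A` and `B` coincide and `variance = 1`.
#' @export
kernel_matrix <- function(A, B, kernel = se_kernel()) {
  same <- identical(A, B)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("dimension mismatch between point sets",
                               call. = FALSE)
  D2 <- sqdist(A, B)
  if (same) diag(D2) <- 0  # k(h, h) = v exactly
  kernel$variance * exp(-D2 / (2 * kernel$lengthscale^2))
}

#' Initialize the inducing-point state
#'
#' @param Z O x q matrix of inducing inputs (same latent space as the
#'   embeddings).
#' @param mu O-vector variational mean (default 0).
#' @param L O x O lower-triangular factor with positive diagonal;
#'   `Sigma = L %*% t(L)` is the variational covariance.  Default identity.
#' @return List of class `inducing_state`.
#' @export
inducing_state <- function(Z, mu = NULL, L = NULL) {
  Z <- as.matrix(Z)
  O <- nrow(Z)
  if (is.null(mu)) mu <- numeric(O)
  if (is.null(L)) L <- diag(O)
  stopifnot(length(mu) == O, nrow(L) == O, ncol(L) == O)
  if (any(diag(L) <= 0)) stop("`L` must have a positive diagonal",
                              call. = FALSE)
  L[upper.tri(L)] <- 0
  structure(list(Z = Z, mu = as.numeric(mu), L = L),
            class = "inducing_state")
}

#' Place inducing points at k-means centroids of embeddings
#'
#' Runs k-means on (a random subsample of) the latent embeddings; falls back
#' to a random subset of rows if k-means degenerates.
#'
#' @param H M x q latent matrix.
#' @param n_inducing Number of inducing points O (default 100; capped at the
#'   number of distinct rows).
#' @param max_cells Subsample cap before clustering (default 10000).
#' @param seed Integer seed.
#' @return An [inducing_state()] with prior-matched `mu = 0`.
#' @export
init_inducing <- function(H, n_inducing = 100L, max_cells = 10000L,
                          seed = 1L) {
  H <- as.matrix(H)
  with_seed(seed, {
    if (nrow(H) > max_cells) H <- H[sample.int(nrow(H), max_cells), ,
                                    drop = FALSE]
    Hu <- unique(H)
    O <- min(n_inducing, nrow(Hu))
    Z <- tryCatch(
      stats::kmeans(Hu, centers = O, iter.max = 30L, nstart = 1L)$centers,
      error = function(e) Hu[sample.int(nrow(Hu), O), , drop = FALSE])
    inducing_state(Z)
  })
}

# Internal: shared forward pass of the variational marginal.
# Returns A = Kzz^{-1} Kzh and friends; all downstream ops reuse this.
svgp_precompute <- function(H, state, kernel, jitter0 = NULL) {
  if (is.null(jitter0)) jitter0 <- 1e-6 * kernel$variance
  Kzz <- kernel_matrix(state$Z, state$Z, kernel)
  fac <- chol_jitter(Kzz, jitter0 = jitter0)
  Kzh <- kernel_matrix(state$Z, H, kernel)
  A <- solve_chol(fac$L, Kzh)   # O x M
  list(Kzz = Kzz, Kzh = Kzh, A = A, Lk = fac$L, jitter = fac$jitter)
}

#' Conditional prior of f given the inducing outputs
#'
#' The conditional of the joint GP prior:
#' mean `K_HZ K_ZZ^{-1} u`, covariance
#' `K_HH - K_HZ K_ZZ^{-1} K_ZH` (independent of `u`).
#'
#' @param H M x q input embeddings.
#' @param u O-vector of inducing outputs.
#' @param state An [inducing_state()].
#' @param kernel An [se_kernel()].
#' @param diag_only If `TRUE` (default) return only the diagonal of the
#'   conditional covariance, never forming an M x M matrix.
#' @param jitter0 Initial diagonal jitter for the K_ZZ factorization
#'   (default `1e-6 * variance`; escalated tenfold on failure).
#' @return List with `mean` (M-vector) and `var` (M-vector) or `cov`
#'   (M x M matrix when `diag_only = FALSE`).
#' @export
conditional_prior <- function(H, u, state, kernel = se_kernel(),
                              diag_only = TRUE, jitter0 = NULL) {
  H <- as.matrix(H)
  pre <- svgp_precompute(H, state, kernel, jitter0 = jitter0)
  mean <- drop(crossprod(pre$A, u))
  if (diag_only) {
    v <- kernel$variance - colSums(pre$Kzh * pre$A)
    list(mean = mean, var = pmax(v, 0))
  } else {
    Khh <- kernel_matrix(H, H, kernel)
    list(mean = mean, cov = Khh - crossprod(pre$Kzh, pre$A))
  }
}

#' Marginal variational posterior q(f)
#'
#' Integrates the conditional prior against `q(u) = N(mu, Sigma)`:
#' `mu_f = K_HZ K_ZZ^{-1} mu` and
#' `Sigma_f = K_HH - K_HZ K_ZZ^{-1} (K_ZZ - Sigma) K_ZZ^{-1} K_ZH`.
#'
#' @inheritParams conditional_prior
#' @param state An [inducing_state()] carrying `mu` and the factor `L`.
#' @param var_floor Diagonal clamp applied before any factorization
#'   (default 1e-8).
#' @return List of class `marginal_posterior` with `mean`, and `var`
#'   (diagonal mode) or `cov` plus its factor `Lf`.
#' @export
marginal_variational_posterior <- function(H, state, kernel = se_kernel(),
                                           diag_only = TRUE,
                                           var_floor = 1e-8, jitter0 = NULL) {
  H <- as.matrix(H)
  pre <- svgp_precompute(H, state, kernel, jitter0 = jitter0)
  mean <- drop(crossprod(pre$A, state$mu))
  C <- crossprod(state$L, pre$A)          # O x M, = L^T A
  if (diag_only) {
    v <- kernel$variance - colSums(pre$Kzh * pre$A) + colSums(C * C)
    out <- list(mean = mean, var = pmax(v, var_floor), diag_only = TRUE)
  } else {
    Khh <- kernel_matrix(H, H, kernel)
    cov <- Khh - crossprod(pre$Kzh, pre$A) + crossprod(C)
    cov <- (cov + t(cov)) / 2
    dg <- diag(cov)
    diag(cov) <- pmax(dg, var_floor)
    Lf <- chol_jitter(cov, jitter0 = 1e-10, max_jitter = 1e-4)$L
    out <- list(mean = mean, cov = cov, Lf = Lf, diag_only = FALSE)
  }
  class(out) <- "marginal_posterior"
  out
}

#' Draw reparameterized samples from q(f)
#'
#' `f = mu_f + L_f %*% eps` with `eps ~ N(0, I)`; in diagonal mode
#' `L_f = sqrt(var)` elementwise.
#'
#' @param post A `marginal_posterior`.
#' @param B Number of samples (>= 1).
#' @param seed Integer seed.
#' @return M x B matrix; column b is the b-th sample.
#' @export
sample_f <- function(post, B, seed = NULL) {
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  M <- length(post$mean)
  with_seed(seed, {
    eps <- matrix(stats::rnorm(M * B), M, B)
    if (isTRUE(post$diag_only)) {
      post$mean + sqrt(post$var) * eps
    } else {
      post$mean + post$Lf %*% eps
    }
  })
}

#' KL divergence from q(u) to the prior p(u) = N(0, K_ZZ)
#'
#' Closed form for Gaussians:
#' `KL = (tr(K^{-1} Sigma) + mu' K^{-1} mu - O + log det K - log det Sigma) / 2`.
#' Always nonnegative; zero iff `q(u)` equals the prior.
#'
#' @param state An [inducing_state()].
#' @param kernel An [se_kernel()].
#' @return Nonnegative scalar.
#' @export
kl_term <- function(state, kernel = se_kernel(), jitter0 = NULL) {
  if (is.null(jitter0)) jitter0 <- 1e-6 * kernel$variance
  Kzz <- kernel_matrix(state$Z, state$Z, kernel)
  fac <- chol_jitter(Kzz, jitter0 = jitter0)
  O <- nrow(Kzz)
  Linv_L <- solve_lower(fac$L, state$L)       # Lk^{-1} L
  tr <- sum(Linv_L * Linv_L)                  # tr(K^{-1} Sigma)
  alpha <- solve_lower(fac$L, state$mu)
  quad <- sum(alpha * alpha)
  logdetK <- 2 * sum(log(diag(fac$L)))
  logdetS <- 2 * sum(log(diag(state$L)))
  max(0.5 * (tr + quad - O + logdetK - logdetS), 0)
}

# ---------------------------------------------------------------------------
# Gaussian-likelihood regression path.  Used to validate the variational
# machinery against exact GP regression (the bound is tight when the
# inducing points coincide with the inputs), and as a small standalone
# sparse-GP regression utility.

#' Analytic ELBO for Gaussian-likelihood sparse GP regression
#'
#' For `y_i = f_i + e_i`, `e_i ~ N(0, noise)`, the expected log-likelihood
#' under `q(f)` is available in closed form, so no Monte-Carlo sampling is
#' needed:
#' `sum_i log N(y_i | mu_f_i, noise) - Sigma_f_ii / (2 noise) - KL`.
#'
#' @param H n x q inputs.
#' @param y n-vector of targets.
#' @param state An [inducing_state()].
#' @param kernel An [se_kernel()].
#' @param noise Observation noise variance.
#' @return Scalar ELBO (a lower bound on the exact log marginal likelihood).
#' @export
elbo_gaussian <- function(H, y, state, kernel = se_kernel(), noise = 0.1,
                          jitter0 = NULL) {
  post <- marginal_variational_posterior(H, state, kernel, diag_only = TRUE,
                                         var_floor = 0, jitter0 = jitter0)
  ll <- sum(stats::dnorm(y, post$mean, sqrt(noise), log = TRUE)) -
    sum(post$var) / (2 * noise)
  ll - kl_term(state, kernel, jitter0 = jitter0)
}

#' Closed-form optimal q(u) for Gaussian-likelihood regression
#'
#' The collapsed optimum: with `Lam = K_ZZ + K_ZH K_HZ / noise`,
#' `Sigma* = K_ZZ Lam^{-1} K_ZZ` and `mu* = K_ZZ Lam^{-1} K_ZH y / noise`.
#'
#' @inheritParams elbo_gaussian
#' @return The input state with `mu` and `L` replaced by the optimum.
#' @export
svgp_optimal_gaussian <- function(H, y, state, kernel = se_kernel(),
                                  noise = 0.1, jitter0 = NULL) {
  if (is.null(jitter0)) jitter0 <- 1e-6 * kernel$variance
  Kzz <- kernel_matrix(state$Z, state$Z, kernel)
  # the same jittered K_ZZ defines the prior everywhere downstream
  jit <- chol_jitter(Kzz, jitter0 = jitter0)$jitter
  Kzz_eff <- Kzz + diag(jit, nrow(Kzz))
  Kzh <- kernel_matrix(state$Z, H, kernel)
  Lam <- Kzz_eff + tcrossprod(Kzh) / noise
  facL <- chol_jitter(Lam, jitter0 = 1e-12)
  Sig <- Kzz_eff %*% solve_chol(facL$L, Kzz_eff)
  Sig <- (Sig + t(Sig)) / 2
  mu <- drop(Kzz_eff %*% solve_chol(facL$L, Kzh %*% y)) / noise
  state$mu <- mu
  state$L <- chol_jitter(Sig, jitter0 = 1e-12)$L
  state
}

#' Fit a sparse variational GP regression by direct gradient ascent
#'
#' Optimizes the variational parameters `(mu, L)` of `q(u)` with Adam on the
#' analytic Gaussian-likelihood ELBO, holding `Z` and the kernel fixed.
#' With inducing points at all inputs the optimum coincides with exact GP
#' regression and the ELBO is tight against the exact log marginal
#' likelihood.
#'
#' @inheritParams elbo_gaussian
#' @param iters,lr Adam iterations and learning rate.
#' @return List with the optimized `state`, the final `elbo`, the per-iter
#'   `trace`, and the predictive `mean`/`var` at `H`.
#' @export
svgp_fit_gaussian <- function(H, y, state, kernel = se_kernel(),
                              noise = 0.1, iters = 1000L, lr = 0.05,
                              jitter0 = NULL) {
  H <- as.matrix(H)
  params <- list(mu = state$mu, Llog = L_to_param(state$L))
  opt <- adam_init(params)
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    state$mu <- params$mu
    state$L <- param_to_L(params$Llog)
    gr <- svgp_gaussian_grad(H, y, state, kernel, noise, jitter0 = jitter0)
    trace[it] <- gr$elbo
    upd <- adam_step(params, list(mu = -gr$dmu, Llog = -gr$dLlog), opt, lr)
    params <- upd$params; opt <- upd$state
  }
  state$mu <- params$mu
  state$L <- param_to_L(params$Llog)
  post <- marginal_variational_posterior(H, state, kernel, jitter0 = jitter0)
  list(state = state,
       elbo = elbo_gaussian(H, y, state, kernel, noise, jitter0 = jitter0),
       trace = trace, mean = post$mean, var = post$var)
}

# lower-triangular factor <-> unconstrained parameterization (log diagonal)
L_to_param <- function(L) {
  P <- L
  diag(P) <- log(diag(L))
  P
}
param_to_L <- function(P) {
  L <- P
  L[upper.tri(L)] <- 0
  diag(L) <- exp(diag(P))
  L
}
# chain gradient wrt L into the unconstrained parameterization
grad_L_to_param <- function(dL, L) {
  G <- dL
  G[upper.tri(G)] <- 0
  diag(G) <- diag(dL) * diag(L)
  G
}

# gradient of the Gaussian ELBO wrt (mu, Llog); Z and kernel held fixed
svgp_gaussian_grad <- function(H, y, state, kernel, noise, jitter0 = NULL) {
  pre <- svgp_precompute(H, state, kernel, jitter0 = jitter0)
  A <- pre$A
  muf <- drop(crossprod(A, state$mu))
  C <- crossprod(state$L, A)
  vf <- kernel$variance - colSums(pre$Kzh * A) + colSums(C * C)
  n <- length(y)
  elbo <- sum(stats::dnorm(y, muf, sqrt(noise), log = TRUE)) -
    sum(vf) / (2 * noise) - kl_term(state, kernel, jitter0 = jitter0)
  # d elbo / d muf and / d vf
  gm <- (y - muf) / noise
  gv <- rep(-1 / (2 * noise), n)
  dmu <- drop(A %*% gm)
  Ag <- sweep(A, 2L, gv, "*")
  dL_lik <- 2 * Ag %*% t(C)                    # = 2 A diag(gv) A^T L
  # KL gradients (subtracted from the ELBO)
  KinvL <- solve_chol(pre$Lk, state$L)
  Linv <- forwardsolve(state$L, diag(nrow(state$L)))
  dKL_dmu <- solve_chol(pre$Lk, state$mu)
  dKL_dL <- KinvL - t(Linv)
  dmu <- dmu - dKL_dmu
  dL <- dL_lik - dKL_dL
  list(elbo = elbo, dmu = dmu, dLlog = grad_L_to_param(dL, state$L))
}

#' Exact GP regression oracle
#'
#' Dense exact GP regression (posterior mean at the training inputs and the
#' exact log marginal likelihood).  O(n^3); intended for validation at small
#' n, not for routine use.
#'
#' @inheritParams elbo_gaussian
#' @return List with `mean` (posterior mean at `H`) and `log_evidence`.
#' @export
gp_regression_exact <- function(H, y, kernel = se_kernel(), noise = 0.1) {
  H <- as.matrix(H)
  n <- nrow(H)
  K <- kernel_matrix(H, H, kernel)
  Ky <- K + diag(noise, n)
  fac <- chol_jitter(Ky, jitter0 = 1e-12, max_jitter = 1e-8)
  alpha <- solve_chol(fac$L, y)
  list(mean = drop(K %*% alpha),
       log_evidence = -0.5 * sum(y * alpha) - sum(log(diag(fac$L))) -
         n / 2 * log(2 * pi))
}
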