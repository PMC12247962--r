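# Attention pooling per timepoint and the classification head.
#
# Each timepoint owns its own gated-attention scorer (shared across
# subjects): cell i gets score e_i = w' (tanh(V a_i) * sigmoid(U a_i)),
# weights are the softmax over a sample's cells, and the pooled scalar is
# the weighted sum of cell values.  For GP outputs the value is the scalar
# f_i itself; in the AE-only baseline the value is a learned linear
# projection of the latent vector.

#' Initialize per-timepoint attention heads
#'
#' @param input_dim Dimension of the per-cell input (1 for GP outputs,
#'   `q` for the AE-only baseline).
#' @param n_timepoints Number of visits `T`; one independent head per visit.
#' @param hidden Width of the gated scorer (default 8).
#' @param seed Integer seed for initialization.
#' @return List of class `attention_head`; one parameter set per timepoint.
#'   When `input_dim == 1` the value projection is fixed at 1 so the pooled
#'   scalar is exactly the attention-weighted mean of the f values.
#' @export
attention_init <- function(input_dim, n_timepoints, hidden = 8L, seed = 1L) {
  d <- as.integer(input_dim); k <- as.integer(hidden)
  with_seed(seed, {
    heads <- lapply(seq_len(n_timepoints), function(t) {
      list(V = matrix(stats::rnorm(k * d, sd = 0.5), k, d),
           U = matrix(stats::rnorm(k * d, sd = 0.5), k, d),
           w = stats::rnorm(k, sd = 0.5),
           vproj = if (d == 1L) 1 else stats::rnorm(d, sd = sqrt(1 / d)))
    })
    structure(list(heads = heads, input_dim = d, hidden = k,
                   train_vproj = d > 1L),
              class = "attention_head")
  })
}

# forward with caches for backprop; A is m x d
attend_forward <- function(A, par) {
  preT <- A %*% t(par$V)
  preU <- A %*% t(par$U)
  Tm <- tanh(preT)
  Sm <- logistic(preU)
  G <- Tm * Sm
  e <- drop(G %*% par$w)
  wgt <- softmax_vec(e)
  val <- drop(A %*% par$vproj)
  s <- sum(wgt * val)
  list(s = s, weights = wgt,
       cache = list(A = A, Tm = Tm, Sm = Sm, G = G, wgt = wgt, val = val,
                    s = s))
}

# backward: ds is scalar gradient wrt the pooled output.
# Returns parameter gradients and dA (m x d).
attend_backward <- function(ds, par, cache, train_vproj) {
  wgt <- cache$wgt; val <- cache$val
  de <- ds * wgt * (val - cache$s)
  dG <- outer(de, par$w)
  dpreT <- dG * cache$Sm * (1 - cache$Tm^2)
  dpreU <- dG * cache$Tm * cache$Sm * (1 - cache$Sm)
  dA <- dpreT %*% par$V + dpreU %*% par$U +
    outer(ds * wgt, par$vproj)
  list(dV = crossprod(dpreT, cache$A),
       dU = crossprod(dpreU, cache$A),
       dw = drop(crossprod(cache$G, de)),
       dvproj = if (train_vproj) drop(crossprod(cache$A, ds * wgt)) else NULL,
       dA = dA)
}

#' Attention-pool one sample's per-cell values
#'
#' @param f_values m-vector of per-cell GP outputs (or an m x d matrix for
#'   vector-valued inputs) for one (subject, timepoint) sample; `m >= 1`.
#' @param head An [attention_init()] result.
#' @param timepoint Which per-timepoint head to use.
#' @return List with `s` (the pooled scalar `s_nt`) and `weights`
#'   (nonnegative, summing to 1, invariant to cell permutation up to the
#'   same permutation).
#' @export
attend <- function(f_values, head, timepoint) {
  A <- if (is.matrix(f_values)) f_values else matrix(f_values, ncol = 1L)
  if (nrow(A) < 1L) {
    stop("attend() needs at least one cell; missing visits are handled by ",
         "zero padding upstream", call. = FALSE)
  }
  if (ncol(A) != head$input_dim) stop("input dimension mismatch",
                                      call. = FALSE)
  fw <- attend_forward(A, head$heads[[timepoint]])
  list(s = fw$s, weights = fw$weights)
}

#' Assemble the subject representation with zero padding
#'
#' @param s_by_timepoint Named or positional list/vector of pooled scalars;
#'   `NA` or `NULL` entries mark missing visits.
#' @param n_timepoints Total number of visits `T`.
#' @return T-vector `s_n`; missing visits contribute 0.
#' @export
subject_representation <- function(s_by_timepoint, n_timepoints) {
  s <- numeric(n_timepoints)
  present <- FALSE
  for (t in seq_len(n_timepoints)) {
    v <- if (t <= length(s_by_timepoint)) s_by_timepoint[[t]] else NULL
    if (!is.null(v) && !is.na(v)) {
      s[t] <- v
      present <- TRUE
    }
  }
  if (!present) stop("subject has no observed timepoint", call. = FALSE)
  s
}

#' Initialize the classification head
#'
#' @param n_timepoints Length of the subject representation `s_n`.
#' @param n_covariates Number of subject-level covariates appended to the
#'   linear score (default 0).
#' @param n_classes 2 for the sigmoid (Bernoulli) head; > 2 switches to a
#'   softmax (multinomial) head with one weight row per class.
#' @return List of class `classifier_head`.  The binary head starts at
#'   `weights = 1, intercept = 0`, which reduces to `p = sigmoid(s_n)` when
#'   `T = 1`.
#' @export
head_init <- function(n_timepoints, n_covariates = 0L, n_classes = 2L) {
  T <- as.integer(n_timepoints)
  nc <- as.integer(n_covariates)
  C <- as.integer(n_classes)
  if (C < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (C == 2L) {
    structure(list(weights = rep(1, T), cov_coef = numeric(nc),
                   intercept = 0, n_classes = 2L), class = "classifier_head")
  } else {
    structure(list(W = matrix(0, C, T), cov_W = matrix(0, C, nc),
                   intercept = numeric(C), n_classes = C),
              class = "classifier_head")
  }
}

#' Outcome probability from a subject representation
#'
#' Binary: `sigmoid(w' s_n + c' z_n + b)`.  Multiclass: softmax over
#' per-class linear scores.
#'
#' @param s_n T-vector subject representation (or N x T matrix for several
#'   subjects).
#' @param head A [head_init()] result.
#' @param covariates Optional covariate vector (or N x ncov matrix).
#' @return Probability in (0, 1), or a class-probability vector/matrix
#'   summing to 1 per subject.
#' @export
predict_proba <- function(s_n, head, covariates = NULL) {
  S <- if (is.matrix(s_n)) s_n else matrix(s_n, nrow = 1L)
  if (head$n_classes == 2L) {
    if (ncol(S) != length(head$weights)) stop("dimension mismatch",
                                              call. = FALSE)
    eta <- drop(S %*% head$weights) + head$intercept
    if (length(head$cov_coef)) {
      Zc <- if (is.matrix(covariates)) covariates else
        matrix(covariates, nrow = nrow(S))
      if (is.null(covariates) || ncol(Zc) != length(head$cov_coef)) {
        stop("covariate dimension mismatch", call. = FALSE)
      }
      eta <- eta + drop(Zc %*% head$cov_coef)
    }
    p <- logistic(eta)
    if (!is.matrix(s_n)) p <- unname(p[1L])
    p
  } else {
    if (ncol(S) != ncol(head$W)) stop("dimension mismatch", call. = FALSE)
    eta <- tcrossprod(S, head$W)
    eta <- sweep(eta, 2L, head$intercept, "+")
    if (ncol(head$cov_W)) {
      Zc <- if (is.matrix(covariates)) covariates else
        matrix(covariates, nrow = nrow(S))
      eta <- eta + tcrossprod(Zc, head$cov_W)
    }
    P <- softmax_rows(eta)
    colnames(P) <- paste0("class", seq_len(head$n_classes) - 1L)
    if (!is.matrix(s_n)) P <- drop(P)
    P
  }
}
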