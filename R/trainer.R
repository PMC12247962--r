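# End-to-end training: AE pretraining, then joint maximization of the
# Monte-Carlo ELBO over encoder weights, inducing points, kernel
# lengthscale, variational parameters, attention and head, with Adam.
# All gradients are hand-derived reverse-mode; the kernel-matrix chain
# rules are the only nontrivial pieces and are spelled out inline.

#' Training configuration
#'
#' @param latent_dim,hidden_dims Autoencoder architecture (defaults 4 and a
#'   single hidden layer of 16; use `c(256, 64, 16)` for scRNA-seq input).
#' @param pretrain_epochs,pretrain_batch,pretrain_lr AE pretraining schedule.
#'   Defaults follow the cytometry schedule (1000 epochs, batch 128,
#'   lr 1e-6); pass a large `pretrain_batch` for cheap full-batch training
#'   on small simulated cohorts.
#' @param epochs,lr,subject_batch Fine-tuning schedule: Adam learning rate
#'   (default 1e-4), subject-level batch size (default 10; a batch carries
#'   all cells of its subjects across all timepoints so attention always
#'   sees complete samples), epochs (default 100).  `epochs = 0` returns the
#'   pretrained-AE model without fine-tuning.
#' @param mc_samples Monte-Carlo samples B for the likelihood term
#'   (default 8; predictions always use the posterior mean).
#' @param n_inducing Number of inducing points O (default 100).
#' @param lengthscale Initial SE-kernel lengthscale: `"auto"` (median
#'   pairwise distance of pretrained embeddings) or a positive number (the
#'   classical choice is 0.1).  The lengthscale is trained either way; the
#'   kernel variance stays fixed at 1.
#' @param attention_hidden Width of the gated attention scorer (default 8).
#' @param baseline_mode `"gp_attention"` (full model) or `"ae_only"` (GP layer
#'   bypassed; attention pools the latent embeddings directly).
#' @param var_floor Clamp on the marginal posterior variance (default 1e-8).
#' @param seed Master seed; every random choice derives from it.
#' @return List of class `train_config`.
#' @export
train_config <- function(latent_dim = 4L, hidden_dims = 16L,
                         pretrain_epochs = 1000L, pretrain_batch = 128L,
                         pretrain_lr = 1e-6,
                         epochs = 100L, lr = 1e-4, subject_batch = 10L,
                         mc_samples = 8L, n_inducing = 100L,
                         lengthscale = "auto", attention_hidden = 8L,
                         baseline_mode = c("gp_attention", "ae_only"),
                         var_floor = 1e-8, seed = 1L) {
  baseline_mode <- match.arg(baseline_mode)
  if (subject_batch < 1L) stop("`subject_batch` must be >= 1", call. = FALSE)
  structure(list(
    latent_dim = as.integer(latent_dim),
    hidden_dims = as.integer(hidden_dims),
    pretrain_epochs = as.integer(pretrain_epochs),
    pretrain_batch = as.integer(pretrain_batch),
    pretrain_lr = pretrain_lr,
    epochs = as.integer(epochs), lr = lr,
    subject_batch = as.integer(subject_batch),
    mc_samples = as.integer(mc_samples),
    n_inducing = as.integer(n_inducing),
    lengthscale = lengthscale,
    attention_hidden = as.integer(attention_hidden),
    baseline_mode = baseline_mode,
    var_floor = var_floor,
    seed = as.integer(seed)), class = "train_config")
}

# median pairwise distance of (subsampled) embeddings
median_lengthscale <- function(H, max_cells = 500L, seed = 1L) {
  with_seed(seed, {
    if (nrow(H) > max_cells) H <- H[sample.int(nrow(H), max_cells), ,
                                    drop = FALSE]
  })
  m <- stats::median(stats::dist(H))
  if (!is.finite(m) || m <= 0) 1 else m
}

# stack the batch subjects' cells; index ranges per present sample
stack_batch <- function(cohort, subjects) {
  idx <- list()
  mats <- list()
  off <- 0L
  for (sj in subjects) {
    for (t in seq_len(cohort$n_timepoints)) {
      s <- get_sample(cohort, sj, t)
      if (is.null(s) || nrow(s$values) == 0L) next
      m <- nrow(s$values)
      idx[[length(idx) + 1L]] <- list(subject = sj, timepoint = t,
                                      rows = off + seq_len(m))
      mats[[length(mats) + 1L]] <- s$values
      off <- off + m
    }
  }
  list(X = do.call(rbind, mats), index = idx)
}

# gather flat parameter list for Adam
gather_params <- function(model) {
  out <- mlp_flatten(model$ae$encoder, "enc_")
  if (model$baseline_mode == "gp_attention") {
    out$mu <- model$state$mu
    out$Llog <- L_to_param(model$state$L)
    out$Z <- model$state$Z
    out$logls <- log(model$kernel$lengthscale)
  }
  for (t in seq_along(model$attention$heads)) {
    h <- model$attention$heads[[t]]
    out[[paste0("att", t, "_V")]] <- h$V
    out[[paste0("att", t, "_U")]] <- h$U
    out[[paste0("att", t, "_w")]] <- h$w
    if (model$attention$train_vproj) {
      out[[paste0("att", t, "_vproj")]] <- h$vproj
    }
  }
  if (model$head$n_classes == 2L) {
    out$head_w <- model$head$weights
    out$head_b <- model$head$intercept
    if (length(model$head$cov_coef)) out$head_cov <- model$head$cov_coef
  } else {
    out$head_W <- model$head$W
    out$head_b <- model$head$intercept
    if (ncol(model$head$cov_W)) out$head_covW <- model$head$cov_W
  }
  out
}

scatter_params <- function(model, flat) {
  model$ae$encoder <- mlp_unflatten(flat, model$ae$encoder, "enc_")
  if (model$baseline_mode == "gp_attention") {
    model$state$mu <- flat$mu
    model$state$L <- param_to_L(flat$Llog)
    model$state$Z <- flat$Z
    model$kernel$lengthscale <- exp(flat$logls)
  }
  for (t in seq_along(model$attention$heads)) {
    model$attention$heads[[t]]$V <- flat[[paste0("att", t, "_V")]]
    model$attention$heads[[t]]$U <- flat[[paste0("att", t, "_U")]]
    model$attention$heads[[t]]$w <- flat[[paste0("att", t, "_w")]]
    if (model$attention$train_vproj) {
      model$attention$heads[[t]]$vproj <- flat[[paste0("att", t, "_vproj")]]
    }
  }
  if (model$head$n_classes == 2L) {
    model$head$weights <- flat$head_w
    model$head$intercept <- flat$head_b
    if (!is.null(flat$head_cov)) model$head$cov_coef <- flat$head_cov
  } else {
    model$head$W <- flat$head_W
    model$head$intercept <- flat$head_b
    if (!is.null(flat$head_covW)) model$head$cov_W <- flat$head_covW
  }
  model
}

# ---------------------------------------------------------------------------
# One batch: forward ELBO + full reverse-mode gradient.
# Returns list(elbo = scalar, grads = named list matching gather_params,
#              and, when input_grad = TRUE, dX for the explainer).
batch_grad <- function(model, cohort, subjects, B, scale,
                       input_grad = FALSE, deterministic = FALSE,
                       X_override = NULL) {
  stk <- stack_batch(cohort, subjects)
  if (!is.null(X_override)) stk$X <- X_override
  Mb <- nrow(stk$X)
  q <- model$ae$config$latent_dim
  enc <- mlp_forward(stk$X, model$ae$encoder, cache = TRUE)
  H <- enc$out
  gp_mode <- model$baseline_mode == "gp_attention"
  if (gp_mode) {
    ls <- model$kernel$lengthscale
    v <- model$kernel$variance
    Z <- model$state$Z
    D2zz <- sqdist(Z, Z)
    Kzz <- v * exp(-D2zz / (2 * ls^2))
    fac <- chol_jitter(Kzz, jitter0 = 1e-6 * v)
    D2zh <- sqdist(Z, H)
    Kzh <- v * exp(-D2zh / (2 * ls^2))
    A <- solve_chol(fac$L, Kzh)             # O x Mb
    muf <- drop(crossprod(A, model$state$mu))
    C <- crossprod(model$state$L, A)        # O x Mb
    vf_raw <- v - colSums(Kzh * A) + colSums(C * C)
    clamped <- vf_raw < model$var_floor
    vf <- pmax(vf_raw, model$var_floor)
    sdv <- sqrt(vf)
    kl <- kl_term(model$state, model$kernel)
  } else {
    kl <- 0
  }
  y <- cohort$outcomes
  covs <- cohort$covariates
  n_draw <- if (deterministic || !gp_mode) 1L else B
  rows_map <- list()
  for (smp in stk$index) {
    rows_map[[sample_key(smp$subject, smp$timepoint)]] <- smp$rows
  }
  # accumulators
  grads <- lapply(gather_params(model), function(p) p * 0)
  gm <- numeric(Mb)      # d loss / d f (summed over draws)
  gsd_eps <- numeric(Mb) # sum over draws of (d loss / d f) * eps
  dH_att <- matrix(0, Mb, q)  # attention input grads in ae_only mode
  loglik <- 0
  for (b in seq_len(n_draw)) {
    if (gp_mode) {
      eps <- if (deterministic) numeric(Mb) else stats::rnorm(Mb)
      fdraw <- muf + sdv * eps
    }
    srep <- list()
    caches <- list()
    for (smp in stk$index) {
      t <- smp$timepoint
      rows <- smp$rows
      Ain <- if (gp_mode) matrix(fdraw[rows], ncol = 1L) else
        H[rows, , drop = FALSE]
      fw <- attend_forward(Ain, model$attention$heads[[t]])
      if (is.null(srep[[smp$subject]])) {
        srep[[smp$subject]] <- numeric(cohort$n_timepoints)
      }
      srep[[smp$subject]][t] <- fw$s
      caches[[sample_key(smp$subject, t)]] <- fw$cache
    }
    for (sj in subjects) {
      s_n <- srep[[sj]]
      if (is.null(s_n)) next  # subject with no usable cells
      z_n <- if (!is.null(covs)) covs[sj, ] else NULL
      if (model$head$n_classes == 2L) {
        eta <- sum(model$head$weights * s_n) + model$head$intercept
        if (length(model$head$cov_coef)) {
          eta <- eta + sum(model$head$cov_coef * z_n)
        }
        pr <- logistic(eta)
        pr <- min(max(pr, 1e-12), 1 - 1e-12)
        yn <- y[[sj]]
        loglik <- loglik + (yn * log(pr) + (1 - yn) * log(1 - pr))
        deta <- scale * (pr - yn) / n_draw     # gradient of loss
        grads$head_w <- grads$head_w + deta * s_n
        grads$head_b <- grads$head_b + deta
        if (!is.null(grads$head_cov)) {
          grads$head_cov <- grads$head_cov + deta * z_n
        }
        ds_n <- deta * model$head$weights
      } else {
        eta <- drop(model$head$W %*% s_n) + model$head$intercept
        if (ncol(model$head$cov_W)) eta <- eta + drop(model$head$cov_W %*% z_n)
        P <- softmax_vec(eta)
        yn <- y[[sj]]
        loglik <- loglik + log(max(P[yn + 1L], 1e-12))
        dd <- P
        dd[yn + 1L] <- dd[yn + 1L] - 1
        dd <- scale * dd / n_draw
        grads$head_W <- grads$head_W + outer(dd, s_n)
        grads$head_b <- grads$head_b + dd
        if (!is.null(grads$head_covW)) {
          grads$head_covW <- grads$head_covW + outer(dd, z_n)
        }
        ds_n <- drop(crossprod(model$head$W, dd))
      }
      for (t in seq_len(cohort$n_timepoints)) {
        cache <- caches[[sample_key(sj, t)]]
        if (is.null(cache)) next  # missing visit: zero-padded, no gradient
        bw <- attend_backward(ds_n[t], model$attention$heads[[t]], cache,
                              model$attention$train_vproj)
        grads[[paste0("att", t, "_V")]] <-
          grads[[paste0("att", t, "_V")]] + bw$dV
        grads[[paste0("att", t, "_U")]] <-
          grads[[paste0("att", t, "_U")]] + bw$dU
        grads[[paste0("att", t, "_w")]] <-
          grads[[paste0("att", t, "_w")]] + bw$dw
        if (model$attention$train_vproj) {
          grads[[paste0("att", t, "_vproj")]] <-
            grads[[paste0("att", t, "_vproj")]] + bw$dvproj
        }
        rows <- rows_map[[sample_key(sj, t)]]
        if (gp_mode) {
          gm[rows] <- gm[rows] + drop(bw$dA)
          if (!deterministic) gsd_eps[rows] <- gsd_eps[rows] +
              drop(bw$dA) * eps[rows]
        } else {
          dH_att[rows, ] <- dH_att[rows, ] + bw$dA
        }
      }
    }
  }
  loglik <- loglik / n_draw
  elbo <- scale * loglik - kl
  # ----- SVGP backward -----
  dH <- matrix(0, Mb, q)
  if (gp_mode) {
    gv <- gsd_eps / (2 * sdv)
    gv[clamped] <- 0
    # mean path: muf = A' mu
    grads$mu <- grads$mu + drop(A %*% gm)
    Ag <- sweep(A, 2L, gv, "*")
    dL <- 2 * Ag %*% t(C)                     # variance path wrt L
    # dA: mean + variance paths
    dA <- outer(model$state$mu, gm) - sweep(Kzh, 2L, gv, "*") +
      2 * sweep(model$state$L %*% C, 2L, gv, "*")
    dKzh <- -Ag + solve_chol(fac$L, dA)       # direct + through A
    dKzz <- -solve_chol(fac$L, dA) %*% t(A)
    # KL gradients (loss includes +KL)
    O <- nrow(Kzz)
    Kinv <- solve_chol(fac$L, diag(O))
    alpha <- drop(Kinv %*% model$state$mu)
    KinvL <- Kinv %*% model$state$L
    Linv <- forwardsolve(model$state$L, diag(O))
    grads$mu <- grads$mu + alpha
    dL <- dL + KinvL - t(Linv)
    dKzz <- dKzz + 0.5 * (Kinv - KinvL %*% t(KinvL) - outer(alpha, alpha))
    grads$Llog <- grads$Llog + grad_L_to_param(dL, model$state$L)
    # kernel chains
    ls <- model$kernel$lengthscale
    E <- dKzh * Kzh
    grads$Z <- grads$Z + (E %*% H - rowSums(E) * Z) / ls^2
    dH <- dH + (crossprod(E, Z) - colSums(E) * H) / ls^2
    grads$logls <- grads$logls + sum(E * D2zh) / ls^2
    Ez <- dKzz * Kzz
    grads$Z <- grads$Z +
      (Ez %*% Z + crossprod(Ez, Z) - (rowSums(Ez) + colSums(Ez)) * Z) / ls^2
    grads$logls <- grads$logls + sum(Ez * D2zz) / ls^2
  } else {
    dH <- dH_att
  }
  # ----- encoder backward -----
  benc <- mlp_backward(dH, model$ae$encoder, enc$caches)
  enc_names <- names(mlp_flatten(model$ae$encoder, "enc_"))
  enc_grads <- stats::setNames(
    unlist(lapply(benc$layers, function(g) list(g$W, g$b)),
           recursive = FALSE), enc_names)
  for (nm in enc_names) grads[[nm]] <- grads[[nm]] + enc_grads[[nm]]
  out <- list(elbo = elbo, grads = grads)
  if (input_grad) out$dX <- benc$input
  out
}

#' Monte-Carlo ELBO estimate on a subject batch
#'
#' Expected Bernoulli/categorical log-likelihood under `q(f)` (estimated
#' with B reparameterized samples, rescaled by `N / |batch|` so the
#' full-data ELBO is unbiased under subject mini-batching) minus the KL term.
#'
#' @param model A fitted (or initialized) model from [fit()].
#' @param cohort A `cytogp_cohort`.
#' @param subjects Subject subset (default: all; no rescaling then).
#' @param B Number of MC samples.
#' @param seed Integer seed for the reparameterized draws.
#' @return Scalar ELBO estimate.
#' @export
elbo <- function(model, cohort, subjects = NULL, B = 8L, seed = 1L) {
  if (is.null(subjects)) subjects <- cohort$subjects
  scale <- length(cohort$subjects) / length(subjects)
  res <- with_seed(seed,
    batch_grad(model, cohort, subjects, B = B, scale = scale))
  if (!is.finite(res$elbo)) stop("ELBO is non-finite (divergence)",
                                 call. = FALSE)
  res$elbo
}

#' Fit the full model on a cohort
#'
#' Pipeline: (1) pretrain the autoencoder by reconstruction on all training
#' cells (no labels used); (2) place inducing points at k-means centroids of
#' the pretrained embeddings and initialize `q(u)` at the prior; (3) jointly
#' fine-tune encoder, inducing points, kernel lengthscale, variational
#' parameters, attention and head by maximizing the Monte-Carlo ELBO with
#' Adam over subject mini-batches.
#'
#' @param cohort A preprocessed `cytogp_cohort`.
#' @param config A [train_config()].
#' @param ae Optionally, an already pretrained `ae_params` to reuse
#'   (pretraining is skipped).
#' @return Object of class `cytogp_model` with components `ae`, `state`,
#'   `kernel`, `attention`, `head`, the `config`, and `history` (per-epoch
#'   mean ELBO estimate; empty when `epochs = 0`).
#' @export
fit <- function(cohort, config = train_config(), ae = NULL) {
  stopifnot(inherits(cohort, "cytogp_cohort"))
  p <- length(cohort$marker_names)
  n_classes <- max(2L, max(cohort$outcomes) + 1L)
  X_all <- cohort_cell_matrix(cohort)
  if (is.null(X_all) || nrow(X_all) == 0L) stop("cohort has no cells",
                                                call. = FALSE)
  if (is.null(ae)) {
    aecfg <- ae_config(p, config$hidden_dims, config$latent_dim,
                       seed = config$seed)
    ae <- pretrain(X_all, aecfg, epochs = config$pretrain_epochs,
                   batch_size = config$pretrain_batch,
                   lr = config$pretrain_lr, seed = config$seed)
  }
  H_all <- encode(X_all, ae)
  if (config$baseline_mode == "gp_attention") {
    ls0 <- if (identical(config$lengthscale, "auto")) {
      median_lengthscale(H_all, seed = config$seed + 1L)
    } else config$lengthscale
    kernel <- se_kernel(ls0, 1)
    state <- init_inducing(H_all, config$n_inducing, seed = config$seed + 2L)
    Kzz <- kernel_matrix(state$Z, state$Z, kernel)
    state$L <- chol_jitter(Kzz, jitter0 = 1e-6)$L  # q(u) starts at the prior
    att_dim <- 1L
  } else {
    kernel <- NULL
    state <- NULL
    att_dim <- config$latent_dim
  }
  attention <- attention_init(att_dim, cohort$n_timepoints,
                              hidden = config$attention_hidden,
                              seed = config$seed + 3L)
  n_cov <- if (!is.null(cohort$covariates)) ncol(cohort$covariates) else 0L
  head <- head_init(cohort$n_timepoints, n_cov, n_classes)
  model <- structure(list(
    ae = ae, state = state, kernel = kernel, attention = attention,
    head = head, baseline_mode = config$baseline_mode,
    var_floor = config$var_floor, marker_names = cohort$marker_names,
    n_timepoints = cohort$n_timepoints, config = config,
    history = numeric(0)), class = "cytogp_model")
  if (config$epochs == 0L) return(model)
  flat <- gather_params(model)
  opt <- adam_init(flat)
  N <- length(cohort$subjects)
  bs <- min(config$subject_batch, N)
  history <- numeric(config$epochs)
  with_seed(config$seed + 10L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(cohort$subjects)
      starts <- seq(1L, N, by = bs)
      ep_elbo <- 0
      for (st in starts) {
        batch <- ord[st:min(st + bs - 1L, N)]
        res <- batch_grad(model, cohort, batch, B = config$mc_samples,
                          scale = N / length(batch))
        if (!is.finite(res$elbo)) {
          stop("training diverged (non-finite ELBO); last finite state kept",
               call. = FALSE)
        }
        upd <- adam_step(flat, res$grads, opt, config$lr)
        flat <- upd$params; opt <- upd$state
        model <- scatter_params(model, flat)
        ep_elbo <- ep_elbo + res$elbo
      }
      history[ep] <- ep_elbo / length(starts)
    }
  })
  model$history <- history
  model
}

#' @export
print.cytogp_model <- function(x, ...) {
  cat(sprintf(
    "<cytogp_model> %s | %d markers, q = %d, T = %d%s\n",
    x$baseline_mode, length(x$marker_names), x$ae$config$latent_dim,
    x$n_timepoints,
    if (x$baseline_mode == "gp_attention")
      sprintf(", O = %d, lengthscale = %.3g", nrow(x$state$Z),
              x$kernel$lengthscale) else ""))
  if (length(x$history)) {
    cat(sprintf("  final ELBO estimate: %.3f\n", utils::tail(x$history, 1)))
  }
  invisible(x)
}

check_schema <- function(model, cohort) {
  if (!identical(model$marker_names, cohort$marker_names)) {
    diff <- c(setdiff(model$marker_names, cohort$marker_names),
              setdiff(cohort$marker_names, model$marker_names))
    stop(sprintf("marker schema mismatch; differing markers: %s",
                 paste(unique(diff), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict subject outcomes
#'
#' Deterministic inference: attention consumes the GP posterior mean
#' `mu_f` (no sampling), missing visits are zero-padded at the pooled-scalar
#' level, and any per-sample cell count >= 1 is handled without subsampling
#' or padding of cells.
#'
#' @param object A `cytogp_model`.
#' @param cohort A `cytogp_cohort` with the training marker schema.
#' @param ... Unused.
#' @return data.frame with `subject_id`, predicted probability (binary:
#'   `prob`; multiclass: one `prob_class*` column per class) and `label`.
#' @export
predict.cytogp_model <- function(object, cohort, ...) {
  check_schema(object, cohort)
  S <- matrix(0, length(cohort$subjects), cohort$n_timepoints)
  rownames(S) <- cohort$subjects
  seen <- stats::setNames(logical(length(cohort$subjects)), cohort$subjects)
  for (key in names(cohort$samples)) {
    s <- cohort$samples[[key]]
    if (nrow(s$values) == 0L) next
    H <- encode(s$values, object$ae)
    fvals <- if (object$baseline_mode == "gp_attention") {
      matrix(marginal_variational_posterior(H, object$state,
                                            object$kernel)$mean, ncol = 1L)
    } else H
    att <- attend(fvals, object$attention, s$timepoint)
    S[s$subject_id, s$timepoint] <- att$s
    seen[s$subject_id] <- TRUE
  }
  if (!all(seen)) {
    stop(sprintf("subject(s) with no observed cells: %s",
                 paste(names(seen)[!seen], collapse = ", ")), call. = FALSE)
  }
  covs <- cohort$covariates
  if (object$head$n_classes == 2L) {
    pr <- predict_proba(S, object$head, covariates = covs)
    data.frame(subject_id = cohort$subjects, prob = unname(pr),
               label = as.integer(pr >= 0.5), stringsAsFactors = FALSE,
               row.names = NULL)
  } else {
    P <- predict_proba(S, object$head, covariates = covs)
    out <- data.frame(subject_id = cohort$subjects,
                      stringsAsFactors = FALSE)
    colnames(P) <- paste0("prob_", colnames(P))
    out <- cbind(out, as.data.frame(P))
    out$label <- max.col(P) - 1L
    rownames(out) <- NULL
    out
  }
}

# subset a cohort by subject ids
cohort_subset <- function(cohort, subjects) {
  keep <- vapply(cohort$samples, function(s) s$subject_id %in% subjects,
                 logical(1))
  cohort$samples <- cohort$samples[keep]
  cohort$subjects <- intersect(cohort$subjects, subjects)
  cohort$outcomes <- cohort$outcomes[cohort$subjects]
  if (!is.null(cohort$covariates)) {
    cohort$covariates <- cohort$covariates[cohort$subjects, , drop = FALSE]
  }
  cohort$missing <- cohort$missing[cohort$missing$subject_id %in% subjects, ,
                                   drop = FALSE]
  cohort$total_cells <- sum(vapply(cohort$samples, function(s)
    nrow(s$values), integer(1)))
  cohort
}

# stratified subject fold assignment
make_folds <- function(y, folds, stratified, seed) {
  with_seed(seed, {
    assign <- integer(length(y))
    names(assign) <- names(y)
    ids <- if (stratified) {
      # per-class shuffles concatenated, then one global round-robin, so
      # folds stay class-balanced and no fold is left empty
      unlist(lapply(sort(unique(y)), function(cls) sample(names(y)[y == cls])))
    } else {
      sample(names(y))
    }
    assign[ids] <- rep(seq_len(folds), length.out = length(ids))
    assign
  })
}

#' Subject-level cross-validation
#'
#' Folds partition subjects (no subject straddles train and test), by
#' default stratified by outcome.  Within each fold, AE pretraining,
#' inducing-point initialization and all fitting see only that fold's
#' training subjects; fold models are reinitialized with seed
#' `config$seed + fold`.
#'
#' @param cohort A preprocessed `cytogp_cohort`.
#' @param config A [train_config()].
#' @param folds Number of folds (default 5); `folds = N` gives
#'   leave-one-subject-out.
#' @param stratified Stratify folds by outcome (default `TRUE`).
#' @param protocol Optional robustness protocol applied to the cohort before
#'   splitting: `"none"`, `"subsample_cells"` (retain
#'   `protocol_args$fraction`, default 0.5) or `"mask_timepoint"` (mask
#'   `protocol_args$fraction`, default 0.1, of subjects at
#'   `protocol_args$timepoint`, default 2).
#' @param protocol_args Named list of protocol parameters.
#' @return Object of class `cytogp_cv`: `folds` (per-fold AUC/F1/precision/
#'   recall; AUC is `NA` with a warning for single-class test folds),
#'   `summary` (mean and SD), `predictions`, `fold_assign`.
#' @export
cross_validate <- function(cohort, config = train_config(), folds = 5L,
                           stratified = TRUE,
                           protocol = c("none", "subsample_cells",
                                        "mask_timepoint"),
                           protocol_args = list()) {
  protocol <- match.arg(protocol)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  if (folds > length(cohort$subjects)) {
    stop("more folds than subjects", call. = FALSE)
  }
  if (protocol == "subsample_cells") {
    fr <- protocol_args$fraction %||% 0.5
    cohort <- subsample_cells(cohort, fr, seed = config$seed + 1000L)
  } else if (protocol == "mask_timepoint") {
    fr <- protocol_args$fraction %||% 0.1
    tp <- protocol_args$timepoint %||% 2L
    cohort <- mask_timepoint(cohort, tp, fr, seed = config$seed + 1000L)
  }
  assign <- make_folds(cohort$outcomes, folds, stratified,
                       seed = config$seed + 500L)
  fold_rows <- list()
  preds <- list()
  for (k in seq_len(folds)) {
    test_sub <- names(assign)[assign == k]
    train_sub <- names(assign)[assign != k]
    train_co <- cohort_subset(cohort, train_sub)
    test_co <- cohort_subset(cohort, test_sub)
    cfg <- config
    cfg$seed <- config$seed + k
    model <- fit(train_co, cfg)
    pr <- predict(model, test_co)
    pr$fold <- k
    pr$truth <- unname(cohort$outcomes[pr$subject_id])
    preds[[k]] <- pr
    if (model$head$n_classes == 2L) {
      mt <- if (length(unique(pr$truth)) < 2L) {
        warning(sprintf("fold %d has a single class in test; AUC missing", k))
        suppressWarnings(compute_metrics(pr$truth, pr$prob))
      } else compute_metrics(pr$truth, pr$prob)
      fold_rows[[k]] <- data.frame(fold = k, auc = mt$auc, f1 = mt$f1,
                                   precision = mt$precision,
                                   recall = mt$recall)
    } else {
      acc <- mean(pr$label == pr$truth)
      fold_rows[[k]] <- data.frame(fold = k, accuracy = acc)
    }
  }
  fold_df <- do.call(rbind, fold_rows)
  met_cols <- setdiff(names(fold_df), "fold")
  summ <- data.frame(
    metric = met_cols,
    mean = vapply(met_cols, function(cn) mean(fold_df[[cn]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(met_cols, function(cn) stats::sd(fold_df[[cn]],
                                                 na.rm = TRUE), numeric(1)),
    row.names = NULL)
  structure(list(folds = fold_df, summary = summ,
                 predictions = do.call(rbind, preds),
                 fold_assign = assign, protocol = protocol),
            class = "cytogp_cv")
}

#' @export
print.cytogp_cv <- function(x, ...) {
  cat("<cytogp_cv>", nrow(x$folds), "folds")
  if (x$protocol != "none") cat(" | protocol:", x$protocol)
  cat("\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
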