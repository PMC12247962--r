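# Post-hoc global marker importance via relaxed Bernoulli column masks.
#
# Search for a minimal marker set whose preservation keeps the frozen
# model's predictions intact: non-selected columns are replaced by their
# mean over all analysis cells, the per-column keep-probabilities P are
# optimized through a binary-concrete (Gumbel-Softmax) relaxation, and a
# relaxed L1 penalty lambda * sum(P) presses toward sparsity.  P_j is the
# final importance score of marker j.

#' Mean-impute masked-out marker columns
#'
#' `Xm[, j] = mask[j] * X[, j] + (1 - mask[j]) * mean[j]`: a column's mask
#' value is shared by all cells (global masking).
#'
#' @param X Cells x p matrix.
#' @param mask_columns p-vector in \[0, 1\].
#' @param column_means p-vector of per-marker means over the analysis set's
#'   cells (on the preprocessed scale).
#' @return Perturbed matrix of the same shape.
#' @export
perturb <- function(X, mask_columns, column_means) {
  X <- as.matrix(X)
  if (length(mask_columns) != ncol(X) || length(column_means) != ncol(X)) {
    stop("`mask_columns` and `column_means` must have length ncol(X)",
         call. = FALSE)
  }
  Xm <- sweep(X, 2L, mask_columns, "*")
  sweep(Xm, 2L, column_means * (1 - mask_columns), "+")
}

#' Sample a relaxed Bernoulli (binary-concrete) mask
#'
#' Per column: `sigmoid((logit(P) + logit(e)) / tau)` with `e ~ U(0, 1)`.
#' Differentiable in `P`; concentrates on \{0, 1\} as `tau -> 0`.
#'
#' @param P p-vector of keep probabilities (clamped to \[1e-6, 1 - 1e-6\]).
#' @param temperature Relaxation temperature `tau > 0`.
#' @param seed Integer seed.
#' @return p-vector in (0, 1).
#' @export
sample_relaxed_mask <- function(P, temperature, seed = NULL) {
  stop_if_not_scalar_number(temperature, "temperature", positive = TRUE)
  P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
  with_seed(seed, {
    e <- stats::runif(length(P))
    logistic((log(P / (1 - P)) + log(e / (1 - e))) / temperature)
  })
}

#' Global marker-importance explanation of a fitted model
#'
#' Minimizes the expected masked-prediction loss plus `lambda * sum(P)`
#' by Adam on `logit(P)`, sampling one relaxed mask per iteration and
#' back-propagating through the frozen model to the input columns.  The
#' temperature is annealed geometrically from `tau_start` to `tau_end`.
#'
#' @param model A fitted `cytogp_model`; its parameters are never modified.
#' @param cohort The analysis cohort (preprocessed scale).
#' @param lambda Sparsity penalty weight (default 0.05).  `lambda <= 0`
#'   triggers a warning (no pressure toward a minimal set).
#' @param iters,lr Adam iterations (default 150) and learning rate
#'   (default 0.1).
#' @param subject_batch Subjects per stochastic iteration (default: all).
#' @param tau_start,tau_end Temperature schedule (defaults 1 -> 0.1).
#' @param seed Integer seed.
#' @return Object of class `cytogp_importance`: `scores` data.frame
#'   (marker, P, rank — rank 1 is most important), `P` named vector,
#'   `trace` (per-iteration objective), `lambda`.
#' @export
explain <- function(model, cohort, lambda = 0.05, iters = 150L, lr = 0.1,
                    subject_batch = NULL, tau_start = 1, tau_end = 0.1,
                    seed = 1L) {
  check_schema(model, cohort)
  if (lambda <= 0) warning("lambda <= 0: no sparsity pressure on the mask")
  p <- length(cohort$marker_names)
  full <- stack_batch(cohort, cohort$subjects)
  col_means <- colMeans(full$X)
  N <- length(cohort$subjects)
  bs <- min(subject_batch %||% N, N)
  phi <- numeric(p)  # logit(P), start at P = 0.5 (maximum entropy)
  opt <- adam_init(list(phi = phi))
  trace <- numeric(iters)
  with_seed(seed, {
    for (it in seq_len(iters)) {
      tau <- tau_start * (tau_end / tau_start)^((it - 1) /
                                                  max(iters - 1, 1))
      batch <- if (bs < N) sample(cohort$subjects, bs) else cohort$subjects
      stk <- stack_batch(cohort, batch)
      e <- stats::runif(p)
      m <- logistic((phi + log(e / (1 - e))) / tau)
      Xm <- perturb(stk$X, m, col_means)
      # loss is the per-subject mean, so lambda has the same leverage at
      # any cohort size
      res <- batch_grad(model, cohort, batch, B = 1L, scale = 1 / bs,
                        input_grad = TRUE, deterministic = TRUE,
                        X_override = Xm)
      P <- logistic(phi)
      obj <- -res$elbo + lambda * sum(P)
      if (!is.finite(obj)) stop("explainer diverged (non-finite objective)",
                                call. = FALSE)
      trace[it] <- obj
      dm <- colSums(res$dX * sweep(stk$X, 2L, col_means, "-"))
      dphi <- dm * m * (1 - m) / tau + lambda * P * (1 - P)
      upd <- adam_step(list(phi = phi), list(phi = dphi), opt, lr)
      phi <- upd$params$phi
      opt <- upd$state
    }
  })
  P <- logistic(phi)
  names(P) <- cohort$marker_names
  scores <- data.frame(marker = cohort$marker_names, P = unname(P),
                       rank = rank(-P, ties.method = "min"),
                       stringsAsFactors = FALSE)
  scores <- scores[order(scores$rank), ]
  rownames(scores) <- NULL
  structure(list(scores = scores, P = P, trace = trace, lambda = lambda),
            class = "cytogp_importance")
}

#' @export
print.cytogp_importance <- function(x, ...) {
  cat("<cytogp_importance> top markers:\n")
  print(utils::head(x$scores, 10L), row.names = FALSE)
  invisible(x)
}

#' Marker importance within labeled cell subsets
#'
#' Runs [explain()] restricted to the cells of each subset (e.g. manual
#' gating labels); column means are recomputed within the subset.
#'
#' @param model A fitted `cytogp_model`.
#' @param cohort The analysis cohort.
#' @param cell_labels Named list keyed by sample key
#'   (`subject::timepoint`) holding one label per cell of that sample.
#' @param ... Passed to [explain()].
#' @return Named list of `cytogp_importance`, one per subset label; empty
#'   subsets are skipped with a warning.
#' @export
explain_subset <- function(model, cohort, cell_labels, ...) {
  labs <- unique(unlist(cell_labels, use.names = FALSE))
  out <- list()
  for (lv in labs) {
    samples <- list()
    for (key in names(cohort$samples)) {
      s <- cohort$samples[[key]]
      lab <- cell_labels[[key]]
      if (is.null(lab)) next
      if (length(lab) != nrow(s$values)) {
        stop(sprintf("labels for %s have length %d but the sample has %d cells",
                     key, length(lab), nrow(s$values)), call. = FALSE)
      }
      keep <- lab == lv
      if (!any(keep)) next
      s$values <- s$values[keep, , drop = FALSE]
      samples[[key]] <- s
    }
    if (length(samples) == 0L) {
      warning(sprintf("subset '%s' is empty; skipped", lv))
      next
    }
    subj <- unique(vapply(samples, `[[`, "", "subject_id"))
    sub <- assemble_cohort(samples, cohort$outcomes[subj],
                           covariates = cohort$covariates,
                           n_timepoints = cohort$n_timepoints)
    out[[as.character(lv)]] <- explain(model, sub, ...)
  }
  out
}
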