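# Metrics and the batch-effect diagnostic.

#' Rank-based AUC with half-credit for ties
#'
#' Equivalent to the pairwise concordance probability: a concordant
#' (positive scored above negative) pair counts 1, a tie counts 1/2.
#'
#' @param y_true Binary 0/1 labels.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\]; `NA` (with a warning) if only one class present.
#' @export
auc_score <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  y <- as.integer(y_true)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)   # mid-ranks give ties half credit
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics report
#'
#' AUC (rank definition), plus precision, recall and F1 at a probability
#' threshold.  Undefined quantities (e.g. precision with no predicted
#' positives) are reported as `NA`, never as 0.
#'
#' @param y_true Binary 0/1 labels.
#' @param scores Predicted probabilities or scores.
#' @param threshold Decision threshold for the thresholded metrics
#'   (default 0.5).
#' @return List of class `metrics_report` with `auc`, `f1`, `precision`,
#'   `recall` and the 2 x 2 `confusion` matrix.
#' @examples
#' compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))  # AUC 0.75, F1 0.5
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores))
  y <- as.integer(y_true)
  auc <- auc_score(y, scores)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(
    auc = auc, f1 = f1, precision = precision, recall = recall,
    confusion = matrix(c(tn, fp, fn, tp), 2L, 2L,
                       dimnames = list(predicted = c("0", "1"),
                                       truth = c("0", "1")))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUC %.3f | F1 %.3f | precision %.3f | recall %.3f\n",
              x$auc, x$f1, x$precision, x$recall))
  invisible(x)
}

#' Multiclass confusion matrix
#'
#' @param y_true,y_pred Class labels (coerced to a common factor).
#' @return Square contingency matrix; row `i`, column `j` counts subjects
#'   of true class `j` predicted as class `i`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  lev <- sort(unique(c(y_true, y_pred)))
  table(predicted = factor(y_pred, levels = lev),
        truth = factor(y_true, levels = lev))
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] (rank-based H with tie
#' correction; p from the chi-square approximation with `groups - 1` df,
#' regardless of group size).
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return List with `statistic` (H), `p_value` and `df`.  If all values are
#'   identical the statistic is 0 and `p_value = 1` (with a warning).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0L)) {
    stop("need at least two nonempty groups", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    warning("all values identical; returning p = 1")
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Per-layer activation scores for the batch-effect diagnostic
#'
#' For each sample (one subject at one timepoint) and each stage of the
#' model, the activation score is the mean of that stage's outputs over the
#' sample's cells and output dimensions: the raw input matrix, the AE latent
#' embedding, the GP posterior mean, and the attention-pooled scalar
#' `s_nt` itself.  Comparing the scores' spread across acquisition batches
#' layer by layer (Kruskal-Wallis) quantifies how much batch heterogeneity
#' survives each stage.
#'
#' @param model A fitted model from [fit()].
#' @param cohort A `cytogp_cohort` (preprocessed scale).
#' @return data.frame with columns `subject_id`, `timepoint`, `layer`
#'   (input/ae/gp/attention) and `score`.
#' @export
activation_scores <- function(model, cohort) {
  check_schema(model, cohort)
  rows <- list()
  for (key in names(cohort$samples)) {
    s <- cohort$samples[[key]]
    if (nrow(s$values) == 0L) next
    H <- encode(s$values, model$ae)
    layer_scores <- c(input = mean(s$values), ae = mean(H))
    if (model$baseline_mode == "gp_attention") {
      post <- marginal_variational_posterior(H, model$state, model$kernel)
      fvals <- matrix(post$mean, ncol = 1L)
      layer_scores <- c(layer_scores, gp = mean(post$mean))
    } else {
      fvals <- H
    }
    att <- attend(fvals, model$attention, s$timepoint)
    layer_scores <- c(layer_scores, attention = att$s)
    rows[[key]] <- data.frame(
      subject_id = s$subject_id, timepoint = s$timepoint,
      layer = names(layer_scores), score = unname(layer_scores),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Batch-effect diagnostic across model layers
#'
#' Computes [activation_scores()] and, per layer, the Kruskal-Wallis p-value
#' of the scores grouped by batch.
#'
#' @param model A fitted model.
#' @param cohort A `cytogp_cohort`.
#' @param batch Named vector mapping sample key (`subject::timepoint`) or
#'   subject id to a batch label.
#' @return data.frame with columns `layer`, `statistic`, `p_value`,
#'   `neg_log10_p`, ordered input -> ae -> gp -> attention.
#' @export
batch_diagnostic <- function(model, cohort, batch) {
  sc <- activation_scores(model, cohort)
  key <- sample_key(sc$subject_id, sc$timepoint)
  b <- batch[key]
  if (anyNA(b)) b <- batch[sc$subject_id]
  if (anyNA(b)) stop("`batch` must cover every sample", call. = FALSE)
  layers <- intersect(c("input", "ae", "gp", "attention"), unique(sc$layer))
  out <- do.call(rbind, lapply(layers, function(ly) {
    sel <- sc$layer == ly
    kw <- kruskal_wallis(split(sc$score[sel], b[sel]))
    data.frame(layer = ly, statistic = kw$statistic, p_value = kw$p_value,
               neg_log10_p = -log10(kw$p_value), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
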