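# Preprocessing: arcsinh for cytometry, filter/normalize/log1p/HVG for
# scRNA-seq.

#' Preprocessing configuration
#'
#' @param mode `"cytof"`, `"flow"` or `"scrnaseq"`.
#' @param cofactor Arcsinh cofactor `c` in `arcsinh(x / c)`; controls the
#'   width of the near-zero linear region.  Defaults to 5 for mass cytometry
#'   and 150 for (compensated) flow cytometry; ignored for scRNA-seq.
#' @param min_cells_per_gene Genes expressed in fewer than this many cells
#'   are removed (scRNA-seq; default 10).
#' @param target_depth Per-cell total after depth normalization (default
#'   10000).
#' @param n_hvg Number of highly variable genes retained (default 1000).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(mode = c("cytof", "flow", "scrnaseq"),
                              cofactor = NULL, min_cells_per_gene = 10L,
                              target_depth = 1e4, n_hvg = 1000L) {
  mode <- match.arg(mode)
  if (is.null(cofactor)) {
    cofactor <- switch(mode, cytof = 5, flow = 150, scrnaseq = NA_real_)
  }
  if (mode != "scrnaseq") stop_if_not_scalar_number(cofactor, "cofactor",
                                                    positive = TRUE)
  stop_if_not_scalar_number(target_depth, "target_depth", positive = TRUE)
  if (n_hvg < 1L) stop("`n_hvg` must be >= 1", call. = FALSE)
  structure(list(mode = mode, cofactor = cofactor,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 target_depth = target_depth, n_hvg = as.integer(n_hvg)),
            class = "preprocess_config")
}

#' Arcsinh-transform raw marker intensities
#'
#' Applies `y = arcsinh(x / c) = log(x/c + sqrt((x/c)^2 + 1))` entrywise.
#' Strictly monotone, odd, and linear near zero, so zero and small negative
#' post-compensation values pass through gracefully (they are not clipped).
#'
#' @param x A [cell_matrix()] or numeric matrix/vector of raw intensities.
#' @param cofactor Positive cofactor `c` (5 for CyTOF, 150 for flow).
#' @return Same shape/class as `x`, transformed.
#' @examples
#' arcsinh_transform(5, cofactor = 5)  # log(1 + sqrt(2)) ~ 0.8814
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  stop_if_not_scalar_number(cofactor, "cofactor", positive = TRUE)
  if (inherits(x, "cell_matrix")) {
    x$values <- asinh(x$values / cofactor)
    return(x)
  }
  asinh(x / cofactor)
}

#' Apply the cytometry preprocessing to a whole cohort
#'
#' @param cohort A `cytogp_cohort` of raw intensities.
#' @param config A [preprocess_config()] in `"cytof"` or `"flow"` mode.
#' @return The cohort with every sample arcsinh-transformed.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config("cytof")) {
  stopifnot(inherits(cohort, "cytogp_cohort"))
  if (config$mode == "scrnaseq") {
    stop("use preprocess_scrnaseq() for count matrices", call. = FALSE)
  }
  cohort$samples <- lapply(cohort$samples, arcsinh_transform,
                           cofactor = config$cofactor)
  cohort
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their (already log1p-normalized)
#' expression; ties are broken by ascending gene index so the selection is
#' deterministic.  Mean-dispersion binned statistics are a possible
#' alternative but are not what this function computes.
#'
#' @param log_expr Cells x genes numeric matrix.
#' @param n_hvg Number of genes to keep; must not exceed `ncol(log_expr)`.
#' @return Integer vector of `n_hvg` gene column indices, in ascending order.
#' @export
select_hvg <- function(log_expr, n_hvg) {
  log_expr <- as.matrix(log_expr)
  if (n_hvg > ncol(log_expr)) {
    stop("`n_hvg` exceeds the number of genes", call. = FALSE)
  }
  v <- apply(log_expr, 2L, stats::var)
  # order(): ties resolved by ascending index
  sort(order(-v)[seq_len(n_hvg)])
}

#' Preprocess an scRNA-seq count matrix
#'
#' The chain is: (i) drop genes expressed (nonzero) in fewer than
#' `min_cells_per_gene` cells; (ii) scale each cell so its total count equals
#' `target_depth`; (iii) `log1p`; (iv) keep the top `n_hvg` highly variable
#' genes, which become the marker set.  Filtering precedes normalization.
#'
#' @param counts Cells x genes nonnegative count matrix with gene column
#'   names (names are generated if absent).
#' @param config A [preprocess_config()]; only the scRNA-seq fields are used.
#' @param subject_id,timepoint Identity passed to the resulting
#'   [cell_matrix()].
#' @return A [cell_matrix()] of log-normalized expression over the HVGs.
#' @export
preprocess_scrnaseq <- function(counts, config = preprocess_config("scrnaseq"),
                                subject_id = "sample", timepoint = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  }
  expressed_in <- colSums(counts > 0)
  keep <- expressed_in >= config$min_cells_per_gene
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) == 0L) {
    stop("no genes survive the expression filter", call. = FALSE)
  }
  depth <- rowSums(counts)
  if (any(depth == 0)) {
    stop(sprintf(
      "cell %d has zero total count and cannot be depth-normalized",
      which(depth == 0)[1L]), call. = FALSE)
  }
  norm <- counts * (config$target_depth / depth)
  logn <- log1p(norm)
  if (config$n_hvg > ncol(logn)) {
    stop(sprintf("n_hvg = %d exceeds the %d genes surviving the filter",
                 config$n_hvg, ncol(logn)), call. = FALSE)
  }
  idx <- select_hvg(logn, config$n_hvg)
  out <- logn[, idx, drop = FALSE]
  cell_matrix(out, colnames(out), subject_id, timepoint)
}
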