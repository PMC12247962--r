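# Synthetic cohort simulator with known ground truth.
#
# Cells are drawn from a K-component Gaussian mixture on the arcsinh-like
# scale (simulated values are treated as already preprocessed).  Class-1
# subjects have their population means shifted by +delta on a designated
# informative marker set, optionally only at selected timepoints.  Batch
# effects are additive per-marker shifts shared by all samples of a batch.

#' Simulation configuration
#'
#' @param n_subjects,n_timepoints Cohort dimensions N and T.
#' @param n_markers Marker count p.
#' @param n_populations Number of Gaussian cell populations K.
#' @param informative Indices of the outcome-informative marker set S.
#' @param effect_size Class-1 mean shift delta (>= 0) applied on S.
#' @param effect_timepoints Timepoints at which the shift applies
#'   (default: all).
#' @param mixture_weights K-vector of population weights (shared by both
#'   classes; default uniform).
#' @param population_means Optional K x p matrix; drawn N(0, 2) under the
#'   seed if omitted.
#' @param population_sd Within-population spread (shared, diagonal;
#'   default 1).
#' @param cells_range Per-sample cell count range `c(m_lo, m_hi)`, drawn
#'   uniformly (default `c(200, 800)`).
#' @param n_batches Number of acquisition batches (default 1 = no batch
#'   structure).
#' @param batch_sd Magnitude (SD) of the additive per-batch, per-marker
#'   shifts (default 0).
#' @param missing_prob Probability that a visit at `t >= 2` is missing
#'   (default 0).
#' @param class_balance Fraction of class-1 subjects (default 0.5).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 60L, n_timepoints = 2L, n_markers = 10L,
                       n_populations = 3L, informative = 1:3,
                       effect_size = 1.5, effect_timepoints = NULL,
                       mixture_weights = NULL, population_means = NULL,
                       population_sd = 1, cells_range = c(200L, 800L),
                       n_batches = 1L, batch_sd = 0, missing_prob = 0,
                       class_balance = 0.5, seed = 1L) {
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  if (any(informative < 1L) || any(informative > n_markers)) {
    stop("`informative` must index markers 1..p", call. = FALSE)
  }
  if (cells_range[1L] < 1L || cells_range[2L] < cells_range[1L]) {
    stop("invalid `cells_range`", call. = FALSE)
  }
  if (is.null(mixture_weights)) {
    mixture_weights <- rep(1 / n_populations, n_populations)
  }
  if (abs(sum(mixture_weights) - 1) > 1e-8 || any(mixture_weights < 0)) {
    stop("`mixture_weights` must be nonnegative and sum to 1", call. = FALSE)
  }
  if (is.null(effect_timepoints)) effect_timepoints <- seq_len(n_timepoints)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_timepoints = as.integer(n_timepoints),
    n_markers = as.integer(n_markers),
    n_populations = as.integer(n_populations),
    informative = as.integer(informative),
    effect_size = effect_size,
    effect_timepoints = as.integer(effect_timepoints),
    mixture_weights = mixture_weights,
    population_means = population_means,
    population_sd = population_sd,
    cells_range = as.integer(cells_range),
    n_batches = as.integer(n_batches),
    batch_sd = batch_sd,
    missing_prob = missing_prob,
    class_balance = class_balance,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a cytometry-like cohort with ground truth
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a `cytogp_cohort`) and `truth`: outcomes,
#'   the informative set, effect size, per-subject batch labels, per-cell
#'   population labels (keyed by sample), and the population means used.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_markers; K <- config$n_populations
  with_seed(config$seed, {
    mu_pop <- config$population_means
    if (is.null(mu_pop)) mu_pop <- matrix(stats::rnorm(K * p, sd = 2), K, p)
    n1 <- round(config$n_subjects * config$class_balance)
    y <- sample(c(rep(1L, n1), rep(0L, config$n_subjects - n1)))
    subjects <- sprintf("S%03d", seq_len(config$n_subjects))
    names(y) <- subjects
    batch <- stats::setNames(
      rep(seq_len(config$n_batches), length.out = config$n_subjects),
      subjects)
    batch_shift <- matrix(stats::rnorm(config$n_batches * p,
                                       sd = config$batch_sd),
                          config$n_batches, p)
    samples <- list()
    pop_labels <- list()
    for (n in seq_along(subjects)) {
      for (t in seq_len(config$n_timepoints)) {
        if (t >= 2L && stats::runif(1) < config$missing_prob) next
        m <- config$cells_range[1L] +
          sample.int(config$cells_range[2L] - config$cells_range[1L] + 1L,
                     1L) - 1L
        pop <- sample.int(K, m, replace = TRUE,
                          prob = config$mixture_weights)
        mu <- mu_pop[pop, , drop = FALSE]
        if (y[n] == 1L && t %in% config$effect_timepoints) {
          mu[, config$informative] <- mu[, config$informative] +
            config$effect_size
        }
        X <- mu + matrix(stats::rnorm(m * p, sd = config$population_sd),
                         m, p)
        X <- sweep(X, 2L, batch_shift[batch[n], ], "+")
        key <- sample_key(subjects[n], t)
        samples[[key]] <- cell_matrix(
          X, paste0("M", seq_len(p)), subjects[n], t)
        pop_labels[[key]] <- pop
      }
    }
    cohort <- assemble_cohort(samples, y,
                              n_timepoints = config$n_timepoints)
    list(cohort = cohort,
         truth = list(outcomes = y,
                      informative = config$informative,
                      effect_size = config$effect_size,
                      batch = batch,
                      batch_shift = batch_shift,
                      population = pop_labels,
                      population_means = mu_pop))
  })
}

#' Simulate an scRNA-seq-like count matrix
#'
#' Poisson counts with per-cell depth variation (lognormal factor around
#' `depth`) and class-shifted expression rates on the informative gene set,
#' for exercising the scRNA-seq preprocessing path.
#'
#' @param config A [sim_config()] (`n_markers` read as the gene count).
#' @param depth Expected per-cell total count; `depth = 0` yields an
#'   all-zero matrix.
#' @param n_cells Number of cells per class drawn (total `2 * n_cells`).
#' @return List with `counts` (cells x genes integer matrix), `class`
#'   (per-cell 0/1) and `rates` (per-class expected gene proportions).
#' @export
simulate_counts <- function(config, depth = 2000, n_cells = 200L) {
  p <- config$n_markers
  with_seed(config$seed, {
    base <- stats::rgamma(p, shape = 2, rate = 2) + 0.05
    rate1 <- base
    rate1[config$informative] <- rate1[config$informative] *
      exp(config$effect_size)
    prop0 <- base / sum(base)
    prop1 <- rate1 / sum(rate1)
    cls <- rep(c(0L, 1L), each = n_cells)
    size <- depth * exp(stats::rnorm(2L * n_cells, sd = 0.3))
    lam <- rbind(matrix(prop0, n_cells, p, byrow = TRUE),
                 matrix(prop1, n_cells, p, byrow = TRUE)) * size
    counts <- matrix(stats::rpois(2L * n_cells * p, lam), 2L * n_cells, p)
    colnames(counts) <- paste0("gene", seq_len(p))
    list(counts = counts, class = cls, rates = cbind(prop0, prop1))
  })
}
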