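# Cohort data model: ragged per-(subject, timepoint) cell matrices.

#' Create a cell matrix (one sample: one subject at one timepoint)
#'
#' A sample holds the single-cell marker-expression matrix measured for one
#' subject at one visit: rows are cells, columns are markers.  Cell counts
#' may differ between samples (the ragged contract); the marker panel must
#' be shared cohort-wide.
#'
#' @param values Numeric matrix, cells x markers.  All values must be finite.
#'   Zero-row matrices are allowed (a degenerate sample).
#' @param marker_names Character vector naming the columns.
#' @param subject_id Subject identifier (single string).
#' @param timepoint 1-based integer visit index.
#' @return An object of class `cell_matrix`.
#' @examples
#' cm <- cell_matrix(matrix(rnorm(6), 3, 2), c("CD8", "KLRG1"), "S1", 1)
#' dim(cm$values)
#' @export
cell_matrix <- function(values, marker_names, subject_id, timepoint) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(marker_names) != ncol(values)) {
    stop("length(marker_names) must equal ncol(values)", call. = FALSE)
  }
  if (nrow(values) > 0 && !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at cell %d, marker '%s'",
                 bad[1L], marker_names[bad[2L]]), call. = FALSE)
  }
  timepoint <- as.integer(timepoint)
  if (is.na(timepoint) || timepoint < 1L) {
    stop("`timepoint` must be a positive integer", call. = FALSE)
  }
  colnames(values) <- marker_names
  structure(
    list(values = values,
         marker_names = as.character(marker_names),
         subject_id = as.character(subject_id),
         timepoint = timepoint),
    class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> subject %s, timepoint %d: %d cells x %d markers\n",
              x$subject_id, x$timepoint, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read one sample from a delimited table
#'
#' Reads a comma- or tab-separated table (autodetected from the header line)
#' with one header row of marker names and one row per cell, as exported from
#' typical FCS preprocessing workflows.
#'
#' @param path Path to the delimited file.
#' @param subject_id,timepoint Identity of the sample.
#' @return A [cell_matrix()].
#' @details A header-only file yields a valid zero-cell sample.  Missing or
#'   non-numeric entries raise a format error naming the offending row and
#'   column.
#' @export
load_sample_table <- function(path, subject_id, timepoint) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    stop(sprintf("%s: missing header row", path), call. = FALSE)
  }
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  markers <- strsplit(header, sep, fixed = TRUE)[[1L]]
  markers <- trimws(markers)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           blank.lines.skip = TRUE)
  if (ncol(raw) != length(markers)) {
    stop(sprintf("%s: inconsistent column count", path), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(cell_matrix(matrix(numeric(0), 0L, length(markers)),
                       markers, subject_id, timepoint))
  }
  vals <- suppressWarnings(
    vapply(raw, function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw))
  if (anyNA(vals) || !all(is.finite(vals))) {
    bad <- which(!is.finite(vals) | is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "%s: non-numeric value '%s' at data row %d, column '%s'",
      path, raw[bad[1L], bad[2L]], bad[1L], markers[bad[2L]]),
      call. = FALSE)
  }
  cell_matrix(vals, markers, subject_id, timepoint)
}

#' Write a sample back to a delimited table
#'
#' Values are serialized with 17 significant digits so that
#' `load_sample_table(write_sample_table(x))` round-trips doubles exactly.
#'
#' @param x A [cell_matrix()].
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "cell_matrix"))
  lines <- paste(x$marker_names, collapse = sep)
  if (nrow(x$values) > 0L) {
    body <- apply(x$values, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = sep))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Assemble samples into a cohort
#'
#' @param samples List of [cell_matrix()] objects sharing one marker panel
#'   (identical names, identical order).
#' @param outcomes Named vector mapping subject_id to outcome label.  Binary
#'   outcomes must be coded 0/1; multiclass outcomes as class indices
#'   `0..C-1`.
#' @param covariates Optional numeric matrix or data.frame of subject-level
#'   covariates with rownames matching subject ids (e.g. condition dummies).
#' @param n_timepoints Number of visits `T`; defaults to the largest
#'   timepoint seen.
#' @return An object of class `cytogp_cohort` with fields `samples` (keyed
#'   `subject::timepoint`), `subjects`, `outcomes`, `covariates`,
#'   `n_timepoints`, `marker_names`, `missing` (registry of absent visits,
#'   a data.frame with columns subject_id/timepoint) and `total_cells`.
#'   Missing visits are recorded, never silently dropped.
#' @export
assemble_cohort <- function(samples, outcomes, covariates = NULL,
                            n_timepoints = NULL) {
  if (length(samples) == 0L) stop("no samples supplied", call. = FALSE)
  stopifnot(all(vapply(samples, inherits, logical(1), "cell_matrix")))
  markers <- samples[[1L]]$marker_names
  for (s in samples) {
    if (!identical(s$marker_names, markers)) {
      stop(sprintf(
        "marker panel mismatch for subject %s timepoint %d (expected: %s)",
        s$subject_id, s$timepoint, paste(markers, collapse = ", ")),
        call. = FALSE)
    }
  }
  keys <- vapply(samples, function(s) sample_key(s$subject_id, s$timepoint), "")
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicate sample: %s", keys[duplicated(keys)][1L]),
         call. = FALSE)
  }
  samples <- samples[order(keys)]
  names(samples) <- sort(keys)
  subjects <- sort(unique(vapply(samples, `[[`, "", "subject_id")))
  if (is.null(names(outcomes))) stop("`outcomes` must be named by subject id",
                                     call. = FALSE)
  missing_y <- setdiff(subjects, names(outcomes))
  if (length(missing_y)) {
    stop(sprintf("no outcome for subject(s): %s",
                 paste(missing_y, collapse = ", ")), call. = FALSE)
  }
  y <- outcomes[subjects]
  y <- stats::setNames(as.integer(y), subjects)
  if (anyNA(y) || any(y < 0L)) {
    stop("outcomes must be nonnegative integer class labels", call. = FALSE)
  }
  if (length(unique(y)) <= 2L && !all(y %in% c(0L, 1L))) {
    stop("binary outcomes must be coded exactly 0/1", call. = FALSE)
  }
  tps <- vapply(samples, `[[`, 1L, "timepoint")
  if (is.null(n_timepoints)) n_timepoints <- max(tps)
  n_timepoints <- as.integer(n_timepoints)
  if (any(tps > n_timepoints)) stop("timepoint exceeds n_timepoints",
                                    call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (is.null(rownames(covariates)) ||
        !all(subjects %in% rownames(covariates))) {
      stop("`covariates` must have rownames covering all subjects",
           call. = FALSE)
    }
    covariates <- covariates[subjects, , drop = FALSE]
  }
  grid <- expand.grid(subject_id = subjects,
                      timepoint = seq_len(n_timepoints),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  present <- sample_key(grid$subject_id, grid$timepoint) %in% names(samples)
  missing <- grid[!present, , drop = FALSE]
  rownames(missing) <- NULL
  structure(
    list(samples = samples,
         subjects = subjects,
         outcomes = y,
         covariates = covariates,
         n_timepoints = n_timepoints,
         marker_names = markers,
         missing = missing,
         total_cells = sum(vapply(samples, function(s)
           nrow(s$values), integer(1)))),
    class = "cytogp_cohort")
}

#' @export
print.cytogp_cohort <- function(x, ...) {
  cat(sprintf(
    "<cytogp_cohort> %d subjects x %d timepoints, %d markers, %d cells total\n",
    length(x$subjects), x$n_timepoints, length(x$marker_names),
    x$total_cells))
  if (nrow(x$missing)) {
    cat(sprintf("  %d missing visit(s)\n", nrow(x$missing)))
  }
  tab <- table(x$outcomes)
  cat("  outcomes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `cytogp_cohort`.
#' @return Integer count.
#' @export
n_subjects <- function(cohort) length(cohort$subjects)

# fetch a sample or NULL if the visit is missing
get_sample <- function(cohort, subject_id, timepoint) {
  cohort$samples[[sample_key(subject_id, timepoint)]]
}

# stack all cells of (a subset of) subjects into one matrix
cohort_cell_matrix <- function(cohort, subjects = cohort$subjects) {
  mats <- lapply(cohort$samples, function(s) {
    if (s$subject_id %in% subjects) s$values else NULL
  })
  mats <- Filter(Negate(is.null), mats)
  do.call(rbind, c(mats, list(deparse.level = 0)))
}

#' Randomly subsample cells within every sample
#'
#' Each sample independently retains `ceiling(fraction * m)` of its `m` cells,
#' drawn uniformly without replacement.  Ceiling (not floor) guarantees a
#' nonempty sample stays nonempty for any `fraction > 0`.  Used for the
#' reduced-cell-number robustness protocol (50% subsampling).
#'
#' @param cohort A `cytogp_cohort`.
#' @param fraction Retained fraction, in `(0, 1]`.
#' @param seed Integer seed; fixed seed gives identical retained rows.
#' @return A new `cytogp_cohort`.
#' @export
subsample_cells <- function(cohort, fraction, seed = 1L) {
  stop_if_not_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  if (fraction == 1) return(cohort)
  with_seed(seed, {
    cohort$samples <- lapply(cohort$samples, function(s) {
      m <- nrow(s$values)
      if (m == 0L) return(s)
      keep <- sort(sample.int(m, ceiling(fraction * m)))
      s$values <- s$values[keep, , drop = FALSE]
      s
    })
  })
  cohort$total_cells <- sum(vapply(cohort$samples, function(s)
    nrow(s$values), integer(1)))
  cohort
}

#' Mask a timepoint for a random fraction of subjects
#'
#' Removes the chosen visit for a uniformly drawn subject subset and records
#' it in the missingness registry, emulating missed follow-up visits (e.g.
#' masking 10% of second-timepoint samples).  Downstream, masked visits are
#' zero-padded at the pooled-representation level.
#'
#' @param cohort A `cytogp_cohort`.
#' @param timepoint Visit index to mask.
#' @param fraction Fraction of subjects to mask, in `[0, 1]`.  The number of
#'   masked subjects is `round(fraction * N)`.
#' @param seed Integer seed.
#' @return A new `cytogp_cohort`.
#' @export
mask_timepoint <- function(cohort, timepoint, fraction, seed = 1L) {
  timepoint <- as.integer(timepoint)
  if (timepoint < 1L || timepoint > cohort$n_timepoints) {
    stop("`timepoint` out of range", call. = FALSE)
  }
  stop_if_not_scalar_number(fraction, "fraction")
  if (fraction < 0 || fraction > 1) {
    stop("`fraction` must be in [0, 1]", call. = FALSE)
  }
  n_mask <- round(fraction * length(cohort$subjects))
  if (n_mask == 0L) return(cohort)
  masked <- with_seed(seed, sample(cohort$subjects, n_mask))
  keys <- sample_key(masked, timepoint)
  drop <- names(cohort$samples) %in% keys
  cohort$samples <- cohort$samples[!drop]
  add <- data.frame(subject_id = masked, timepoint = timepoint,
                    stringsAsFactors = FALSE)
  cohort$missing <- unique(rbind(cohort$missing, add))
  rownames(cohort$missing) <- NULL
  present_any <- vapply(cohort$subjects, function(sj)
    any(vapply(cohort$samples, function(s) s$subject_id == sj, logical(1))),
    logical(1))
  if (!all(present_any)) {
    stop("masking removed all visits for some subject(s)", call. = FALSE)
  }
  cohort$total_cells <- sum(vapply(cohort$samples, function(s)
    nrow(s$values), integer(1)))
  cohort
}

#' Load a cohort from a manifest file
#'
#' The manifest (YAML or JSON, by file extension) lists one record per
#' sample: `subject_id`, `timepoint`, `file` (path relative to the manifest),
#' `outcome`, and optionally named covariates.
#'
#' @param manifest Path to the manifest file.
#' @return A `cytogp_cohort`.
#' @export
load_cohort <- function(manifest) {
  ext <- tolower(tools::file_ext(manifest))
  recs <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML manifests", call. = FALSE)
    }
    yaml::read_yaml(manifest)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the 'jsonlite' package is required for JSON manifests",
           call. = FALSE)
    }
    jsonlite::fromJSON(manifest, simplifyVector = FALSE)
  }
  if (!is.null(recs$samples)) recs <- recs$samples
  base <- dirname(manifest)
  samples <- lapply(recs, function(r) {
    load_sample_table(file.path(base, r$file), r$subject_id, r$timepoint)
  })
  outcomes <- vapply(recs, function(r) as.numeric(r$outcome), numeric(1))
  names(outcomes) <- vapply(recs, function(r) as.character(r$subject_id), "")
  outcomes <- outcomes[!duplicated(names(outcomes))]
  covn <- setdiff(names(recs[[1L]]),
                  c("subject_id", "timepoint", "file", "outcome"))
  covariates <- NULL
  if (length(covn)) {
    covariates <- do.call(rbind, lapply(recs, function(r)
      vapply(covn, function(k) as.numeric(r[[k]]), numeric(1))))
    rownames(covariates) <- vapply(recs, function(r)
      as.character(r$subject_id), "")
    covariates <- covariates[!duplicated(rownames(covariates)), , drop = FALSE]
  }
  assemble_cohort(samples, outcomes, covariates)
}
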