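# Metrics, exhaustive AUC oracle, Kruskal-Wallis, activation scores.

test_that("AUC equals brute-force pairwise concordance (with ties)", {
  set.seed(1)
  for (rep in 1:30) {
    n <- sample(2:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    # include heavy ties by rounding some scores
    s <- round(runif(n), sample(c(1, 2, 8), 1))
    expect_equal(auc_score(y, s), auc_bruteforce(y, s))
  }
  # worked example: 3 of 4 pairs concordant
  expect_equal(auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2)), 0.75)
  # degenerate conventions
  expect_equal(auc_score(c(0, 1), c(0.2, 0.9)), 1)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)  # all ties
  expect_warning(a <- auc_score(c(1, 1), c(0.1, 0.2)), "one class")
  expect_true(is.na(a))
})

test_that("thresholded metrics and their consistency", {
  m <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))
  expect_equal(m$auc, 0.75)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  # f1 is the harmonic mean whenever precision + recall > 0
  set.seed(2)
  for (rep in 1:20) {
    y <- rbinom(30, 1, 0.4); y[1:2] <- c(0L, 1L)
    s <- runif(30)
    mm <- suppressWarnings(compute_metrics(y, s))
    if (!is.na(mm$f1)) {
      expect_equal(mm$f1,
                   2 * mm$precision * mm$recall / (mm$precision + mm$recall))
    }
    expect_equal(sum(mm$confusion), 30)
    # confusion columns sum to the per-class true counts
    expect_equal(unname(colSums(mm$confusion)),
                 unname(c(sum(y == 0), sum(y == 1))))
  }
  # no predicted positives: precision missing, not zero
  m0 <- compute_metrics(c(1, 0), c(0.1, 0.2))
  expect_true(is.na(m0$precision))
  # perfect separation
  mp <- compute_metrics(c(1, 0, 1), c(0.9, 0.1, 0.8))
  expect_equal(mp$auc, 1)
  expect_equal(mp$f1, 1)
})

test_that("Kruskal-Wallis matches the hand rank formula and calibrates", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # ranks 1..6, H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-10)
  expect_equal(kw$p_value, stats::pchisq(27 / 7, df = 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # rank invariance to within-group permutation
  kw2 <- kruskal_wallis(list(c(3, 1, 2), c(6, 4, 5)))
  expect_equal(kw2$statistic, kw$statistic)
  # identical values convention
  expect_warning(kw3 <- kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_equal(kw3$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "two nonempty")
  # null calibration: p approximately uniform
  set.seed(3)
  ps <- replicate(400, kruskal_wallis(
    split(rnorm(30), rep(1:3, each = 10)))$p_value)
  expect_lt(suppressWarnings(ks.test(ps, "punif")$statistic), 0.1)
})

test_that("activation scores are per-layer per-sample means", {
  sim <- tiny_cohort(seed = 51)
  co <- sim$cohort
  model <- fit(co, fast_config(epochs = 2L))
  sc <- activation_scores(model, co)
  expect_setequal(unique(sc$layer), c("input", "ae", "gp", "attention"))
  key <- names(co$samples)[1]
  s1 <- co$samples[[key]]
  # input score = grand mean of the sample's matrix
  got <- sc$score[sc$subject_id == s1$subject_id &
                    sc$timepoint == s1$timepoint & sc$layer == "input"]
  expect_equal(got, mean(s1$values))
  # attention score = the pooled scalar itself
  H <- encode(s1$values, model$ae)
  mu_f <- marginal_variational_posterior(H, model$state, model$kernel)$mean
  expect_equal(
    sc$score[sc$subject_id == s1$subject_id & sc$timepoint == s1$timepoint &
               sc$layer == "attention"],
    attend(mu_f, model$attention, s1$timepoint)$s)
  # constant-valued sample scores its constant at the input layer
  co2 <- co
  co2$samples[[key]]$values[] <- 2.5
  sc2 <- activation_scores(model, co2)
  expect_equal(sc2$score[sc2$subject_id == s1$subject_id &
                           sc2$timepoint == s1$timepoint &
                           sc2$layer == "input"], 2.5)
})

test_that("batch diagnostic reports one row per layer", {
  sim <- simulate_cohort(sim_config(n_subjects = 12L, n_batches = 2L,
                                    batch_sd = 1.5,
                                    cells_range = c(10L, 20L), seed = 52))
  model <- fit(sim$cohort, fast_config(epochs = 2L))
  bd <- batch_diagnostic(model, sim$cohort, sim$truth$batch)
  expect_equal(bd$layer, c("input", "ae", "gp", "attention"))
  expect_true(all(bd$p_value >= 0 & bd$p_value <= 1))
})
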