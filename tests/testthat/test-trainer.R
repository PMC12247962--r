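# End-to-end training, gradient flow, cross-validation hygiene.

test_that("batch gradients match finite differences", {
  sim <- tiny_cohort(seed = 31)
  co <- sim$cohort
  model <- fit(co, fast_config(epochs = 0L, pretrain_epochs = 3L))
  bg <- cytogp:::batch_grad
  flat <- cytogp:::gather_params(model)
  loss_at <- function(f) {
    m <- cytogp:::scatter_params(model, f)
    set.seed(11)
    -bg(m, co, co$subjects, B = 2, scale = 1)$elbo
  }
  set.seed(11)
  g <- bg(model, co, co$subjects, B = 2, scale = 1)$grads
  eps <- 1e-6
  set.seed(99)
  for (nm in names(flat)) {
    x <- flat[[nm]]
    idxs <- if (length(x) > 3) sample(length(x), 3) else seq_along(x)
    for (i in idxs) {
      f1 <- flat; f1[[nm]][i] <- f1[[nm]][i] + eps
      f2 <- flat; f2[[nm]][i] <- f2[[nm]][i] - eps
      num <- (loss_at(f1) - loss_at(f2)) / (2 * eps)
      ana <- g[[nm]][i]
      # tolerance is set by central-difference truncation noise, not by
      # the analytic gradients
      expect_true(abs(num - ana) <= 1e-5 ||
                    abs(num - ana) / max(abs(num), abs(ana)) < 2e-3,
                  label = sprintf("grad %s[%d] num %.3g ana %.3g",
                                  nm, i, num, ana))
    }
  }
})

test_that("fit raises the ELBO and gradients reach every component", {
  sim <- tiny_cohort(n_subjects = 10L, delta = 2, seed = 32)
  co <- sim$cohort
  m0 <- fit(co, fast_config(epochs = 0L, seed = 33))
  m1 <- fit(co, fast_config(epochs = 15L, seed = 33))
  # training history improves
  expect_gt(utils::tail(m1$history, 1), m1$history[1])
  # every trainable component moved: encoder, mu, Z, lengthscale, attention
  expect_false(isTRUE(all.equal(m0$ae$encoder[[1]]$W, m1$ae$encoder[[1]]$W)))
  expect_false(isTRUE(all.equal(m0$state$mu, m1$state$mu)))
  expect_false(isTRUE(all.equal(m0$state$Z, m1$state$Z)))
  expect_false(isTRUE(all.equal(m0$kernel$lengthscale,
                                m1$kernel$lengthscale)))
  expect_false(isTRUE(all.equal(m0$attention$heads[[1]]$w,
                                m1$attention$heads[[1]]$w)))
  # epochs = 0 still predicts
  pr0 <- predict(m0, co)
  expect_true(all(is.finite(pr0$prob)))
  # fixed seed: refit is identical
  m2 <- fit(co, fast_config(epochs = 15L, seed = 33))
  expect_identical(m1$state$mu, m2$state$mu)
  expect_identical(predict(m1, co)$prob, predict(m2, co)$prob)
})

test_that("ae_only baseline bypasses the GP but shares the data path", {
  sim <- tiny_cohort(n_subjects = 8L, seed = 34)
  co <- sim$cohort
  m <- fit(co, fast_config(epochs = 4L, baseline_mode = "ae_only"))
  expect_null(m$state)
  expect_null(m$kernel)
  pr <- predict(m, co)
  expect_true(all(is.finite(pr$prob)))
  expect_equal(nrow(pr), 8L)
})

test_that("covariates enter the head and multiclass softmax trains", {
  sim <- tiny_cohort(n_subjects = 8L, seed = 35)
  co <- sim$cohort
  covs <- matrix(rnorm(16), 8, 2,
                 dimnames = list(co$subjects, c("I1", "I2")))
  co$covariates <- covs
  m <- fit(co, fast_config(epochs = 3L))
  expect_length(m$head$cov_coef, 2L)
  expect_true(all(is.finite(predict(m, co)$prob)))
  # three classes
  co3 <- co
  co3$covariates <- NULL
  co3$outcomes <- stats::setNames(rep(0:2, length.out = 8), co$subjects)
  m3 <- fit(co3, fast_config(epochs = 3L))
  pr3 <- predict(m3, co3)
  probs <- as.matrix(pr3[, grep("^prob_", names(pr3))])
  expect_equal(unname(rowSums(probs)), rep(1, 8), tolerance = 1e-9)
  expect_true(all(pr3$label %in% 0:2))
})

test_that("cross-validation keeps subjects whole and stratifies folds", {
  sim <- tiny_cohort(n_subjects = 20L, seed = 36)
  co <- sim$cohort
  cv <- cross_validate(co, fast_config(epochs = 2L), folds = 5L)
  expect_equal(nrow(cv$folds), 5L)
  # every subject tested exactly once
  expect_setequal(cv$predictions$subject_id, co$subjects)
  expect_equal(nrow(cv$predictions), 20L)
  # stratification: 10/10 classes -> 2 per class per test fold
  for (k in 1:5) {
    yk <- co$outcomes[cv$predictions$subject_id[cv$predictions$fold == k]]
    expect_equal(unname(table(yk)), array(c(2L, 2L)))
  }
  expect_equal(cv$summary$metric, c("auc", "f1", "precision", "recall"))
  # leave-one-subject-out boundary: folds = N gives singleton test folds
  co8 <- cytogp:::cohort_subset(co, co$subjects[1:6])
  w <- capture_warnings(
    cv6 <- cross_validate(co8, fast_config(epochs = 1L), folds = 6L))
  expect_true(any(grepl("single class", w)))
  expect_true(all(is.na(cv6$folds$auc)))
  expect_error(cross_validate(co, fast_config(), folds = 1L), "folds")
})

test_that("robustness protocols run through the one-flag interface", {
  sim <- tiny_cohort(n_subjects = 10L, seed = 37)
  co <- sim$cohort
  cv_sub <- cross_validate(co, fast_config(epochs = 1L), folds = 2L,
                           protocol = "subsample_cells",
                           protocol_args = list(fraction = 0.5))
  expect_equal(cv_sub$protocol, "subsample_cells")
  expect_true(all(is.finite(cv_sub$predictions$prob)))
  cv_mask <- cross_validate(co, fast_config(epochs = 1L), folds = 2L,
                            protocol = "mask_timepoint",
                            protocol_args = list(timepoint = 2L,
                                                 fraction = 0.2))
  expect_true(all(is.finite(cv_mask$predictions$prob)))
})

test_that("prediction refuses a mismatched marker schema", {
  sim <- tiny_cohort(seed = 38)
  model <- fit(sim$cohort, fast_config(epochs = 1L))
  co2 <- sim$cohort
  co2$marker_names[2] <- "other"
  expect_error(predict(model, co2), "schema mismatch.*other")
})
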