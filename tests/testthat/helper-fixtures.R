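# Shared fixtures: tiny cohorts built in code and a fast training preset.

tiny_cohort <- function(n_subjects = 6L, n_timepoints = 2L, p = 5L,
                        cells = c(5L, 9L), delta = 1, seed = 3L) {
  simulate_cohort(sim_config(
    n_subjects = n_subjects, n_timepoints = n_timepoints, n_markers = p,
    n_populations = 2L, informative = seq_len(min(2L, p)),
    effect_size = delta, cells_range = cells, seed = seed))
}

# light schedule for unit tests: full-batch AE pretraining, few epochs
fast_config <- function(epochs = 4L, seed = 7L, pretrain_epochs = 10L, ...) {
  train_config(latent_dim = 2L, hidden_dims = 6L,
               pretrain_epochs = pretrain_epochs,
               pretrain_batch = 100000L,
               pretrain_lr = 1e-2, epochs = epochs, lr = 0.02,
               subject_batch = 6L, mc_samples = 2L, n_inducing = 8L,
               attention_hidden = 3L, seed = seed, ...)
}

# schedule used for the simulated study cohorts (N = 60, ~60k cells)
study_config <- function(seed, epochs = 8L, ...) {
  train_config(pretrain_epochs = 40L, pretrain_batch = 1000000L,
               pretrain_lr = 1e-2, epochs = epochs, lr = 0.02,
               subject_batch = 10L, mc_samples = 1L, n_inducing = 50L,
               lengthscale = "auto", seed = seed, ...)
}

study_cohort <- function(delta, seed) {
  simulate_cohort(sim_config(n_subjects = 60L, n_timepoints = 2L,
                             n_markers = 10L, n_populations = 3L,
                             informative = 1:3, effect_size = delta,
                             cells_range = c(200L, 800L), seed = seed))
}

# brute-force pairwise-concordance AUC oracle (ties get half credit)
auc_bruteforce <- function(y, s) {
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
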