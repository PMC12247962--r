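# cytogp

Subject-level outcome prediction from longitudinal single-cell cytometry
data — flow cytometry, mass cytometry (CyTOF), and an scRNA-seq input mode
— with single-cell resolution kept end to end, plus a global
marker-importance explainer.

## Who this is for

Immunology studies (immunotherapy trials, vaccine trials, infection
cohorts) that profile each subject's blood at one or more visits and want
to predict a per-subject outcome (responder vs non-responder, infected vs
control, ...) directly from the cells, without first collapsing each
sample to gated subset proportions or mean marker intensities. Typical
cohorts are small (tens of subjects), samples are ragged (cell counts vary
per sample), and visits are longitudinal — the three constraints this
model is built around.

## The model

For subject *n* at visit *t* with cells `X(n,t) ∈ R^{m(n,t) × p}`:

1. an **autoencoder** (pretrained on all cells by reconstruction, no
   labels) embeds each cell, `h_i = g(x_i) ∈ R^q`, `q = 4`;
2. a **sparse variational Gaussian process** with squared-exponential
   kernel `k(h, h') = exp(−‖h − h'‖² / 2σ²)` and `O` inducing points maps
   each embedding to a scalar `f_i`, at `O(O³ + O²M)` cost via a
   variational posterior `q(u) = N(μ, Σ)` over the inducing outputs;
3. per-visit **gated attention** pools each sample's scalars into
   `s_nt = Σ_i softmax(e)_i f_i`, giving the subject representation
   `s_n = (s_n1, …, s_nT)` (missing visits are zero-padded);
4. a **logistic head** (softmax for multiclass; optional subject
   covariates) yields `p(y_n = 1 | s_n) = sigm(wᵀs_n + cᵀz_n + b)`.

Everything is trained jointly by maximising the Monte-Carlo evidence lower
bound `E_q(f)[log p(y|f)] − KL[q(u)‖p(u)]` with Adam; gradients through
the kernel, the reparameterised sampling and the encoder are hand-derived
reverse-mode and finite-difference-checked in the test suite. A
Gumbel-Softmax (binary-concrete) mask explainer then scores each marker's
global importance `P_j ∈ [0, 1]` on the frozen model. See
`vignettes/cytogp-methods.Rmd` for the full account.

## Worked example

Simulate a cohort with known ground truth (60 subjects, 2 visits, 10
markers, 3 Gaussian cell populations, markers 1–3 carry a +1.5 class
shift), cross-validate, and explain:

```r
library(cytogp)

sim <- simulate_cohort(sim_config(seed = 101))  # defaults = the above
cfg <- train_config(pretrain_epochs = 40, pretrain_batch = 1e6,
                    pretrain_lr = 1e-2, epochs = 25, lr = 0.02,
                    mc_samples = 1, n_inducing = 50, seed = 5)

cv <- cross_validate(sim$cohort, cfg, folds = 5)
print(cv)
#> <cytogp_cv> 5 folds
#>     metric mean sd
#>        auc    1  0
#>         f1    1  0
#>  precision    1  0
#>     recall    1  0

model <- fit(sim$cohort, cfg)
ex <- explain(model, sim$cohort, iters = 60, lr = 0.2,
              subject_batch = 15, seed = 1)
round(ex$P, 2)
#>   M1   M2   M3   M4   M5   M6   M7   M8   M9  M10
#> 0.79 0.99 0.96 0.00 0.00 0.00 0.00 0.01 0.00 0.00
```

Every test fold is classified perfectly (per-fold AUC, F1, precision and
recall all 1.0), and the explainer assigns high keep-probabilities to
exactly the three planted informative markers and ≈ 0 to the rest.

On real data, start from delimited per-sample tables via a manifest
(`load_cohort()`), then `preprocess_cohort()` (arcsinh, cofactor 5 for
CyTOF / 150 for flow) or `preprocess_scrnaseq()` (gene filter, depth
10 000, log1p, top-1000 HVGs) before fitting. A thin CLI covers the same
steps: `exec/cytogp simulate|ingest|train|cv|predict|explain`.

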