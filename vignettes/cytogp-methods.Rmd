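---
title: "Methods: GP-attention networks for longitudinal cytometry outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GP-attention networks for longitudinal cytometry outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytogp)
```

## The problem

Immunological studies — immunotherapy trials, vaccine trials, infection
cohorts — routinely profile each subject's blood by flow or mass cytometry
at several visits, yielding for subject $n$ and timepoint $t$ a matrix
$X^{(n,t)} \in \mathbb{R}^{m(n,t)\times p}$ of $m(n,t)$ cells by $p$
markers, together with a subject-level outcome $y_n$ (responder /
non-responder, protected / unprotected, ...).  Three features make this
prediction problem awkward for off-the-shelf classifiers: cell counts vary
wildly across samples (the data are *ragged*), cohorts are small (tens of
subjects) while cells are plentiful (10^4–10^6 per sample), and the visits
are longitudinal, so the temporal structure carries signal.

`cytogp` models this directly, keeping single-cell resolution end to end.

## The model

Four stages, trained jointly:

1. **Cell embedding.** An autoencoder with encoder $g$ and mirrored decoder
   $h$ maps each cell $x_i$ to a latent $h_i = g(x_i) \in \mathbb{R}^q$
   ($q = 4$ by default; one ReLU hidden layer of 16 units for cytometry,
   256–64–16 for scRNA-seq expression; linear outputs since targets are
   real-valued arcsinh intensities).  The AE is pretrained by minimising
   the mean squared reconstruction error over all cells pooled across
   subjects and visits — no outcome labels are used, so the abundant cells
   compensate for the scarce subjects.  Only the encoder is kept afterwards.

2. **Sparse variational GP.** A zero-mean GP prior with squared-exponential
   kernel $k(h, h') = v\,\exp(-\lVert h-h'\rVert^2 / 2\sigma^2)$ (variance
   $v$ fixed at 1) maps each embedding to a scalar $f_i$.  Exact inference
   costs $O(M^3)$ in the total cell count $M$, so we use $O$ inducing
   points $Z$ (default 100) with outputs $u$: the joint prior factorises as
   $p(f, u) = p(u)\,p(f \mid u)$ with
   $f \mid u \sim N(K_{HZ} K_{ZZ}^{-1} u,\; K_{HH} - K_{HZ} K_{ZZ}^{-1} K_{ZH})$.
   A variational posterior $q(u) = N(\mu, \Sigma)$ (with
   $\Sigma = LL^\top$ kept as a lower-triangular factor) and
   $q(f, u) = q(u)\,p(f\mid u)$ give the marginal
   $q(f) = N(\mu_f, \Sigma_f)$ in closed form; training touches only
   $\mathrm{diag}(\Sigma_f)$, so no $M \times M$ matrix is ever formed and
   the cost is $O(O^3 + O^2 M)$.

3. **Attention pooling.** Per timepoint, a gated attention layer scores
   each cell, $e_i = w^\top(\tanh(V f_i) \odot \mathrm{sigm}(U f_i))$,
   softmax-normalises the scores into weights, and pools
   $s_{nt} = \sum_i \mathrm{softmax}(e)_i\, f_i$.  Each visit owns its own
   attention parameters, so the pooled subject representation
   $s_n = (s_{n1}, \dots, s_{nT})$ lets the head weigh timepoints
   separately.  Pooling is permutation-invariant and defined for any
   $m \geq 1$, which is what makes ragged cell sets unproblematic.

4. **Outcome head.** Binary outcomes use
   $p(y_n = 1 \mid s_n) = \mathrm{sigm}(w_s^\top s_n + c^\top z_n + b)$,
   with optional subject covariates $z_n$ (e.g. stimulation-condition
   dummies); multiclass outcomes replace the sigmoid by a softmax with one
   weight row per class.  With $T = 1$, unit weight and zero intercept this
   reduces to $\mathrm{sigm}(s_n)$.

### Learning

All parameters — encoder weights, inducing inputs $Z$, kernel lengthscale,
$(\mu, L)$, attention and head — are learned by maximising the evidence
lower bound
$\mathbb{E}_{q(f)}[\log p(y \mid f)] - \mathrm{KL}[q(u)\,\|\,p(u)]$
with Adam.  The likelihood expectation is estimated by Monte Carlo through
the reparameterisation $f = \mu_f + \sqrt{\mathrm{diag}(\Sigma_f)}\,
\varepsilon$ (B samples per step, default 8); mini-batches are formed over
*subjects*, carrying all of a subject's cells at every visit so attention
always sees complete samples, and the likelihood term is rescaled by
$N/|\text{batch}|$ so the full-data ELBO is unbiased.  At prediction time
attention consumes $\mu_f$ directly, making predictions deterministic.  All
gradients in this package are hand-derived reverse-mode expressions
(including the kernel-matrix chains into $Z$, $\sigma$ and the encoder) and
are verified against central finite differences in the test suite.

Missing visits are recorded in an explicit registry, never as zero-row
matrices; at prediction and training time a missing visit contributes a
zero to $s_n$ (zero padding at the pooled-scalar level, keeping the cell
sets themselves ragged and untouched).

### Defaults and the parameters that matter

| parameter | default | meaning |
|---|---|---|
| `latent_dim` | 4 | embedding dimension $q$ |
| `hidden_dims` | 16 | encoder hidden widths (scRNA-seq: 256, 64, 16) |
| `n_inducing` | 100 | inducing points $O$ |
| `lengthscale` | `"auto"` | SE kernel init; see below |
| pretraining | 1000 epochs, batch 128, lr 1e-6 | cytometry schedule (scRNA-seq: 200, 256, 1e-3) |
| fine-tuning | 100 epochs, subject batch 10, lr 1e-4 | Adam |
| `mc_samples` | 8 | ELBO Monte-Carlo draws B |
| arcsinh cofactor | 5 (CyTOF), 150 (flow) | width of the linear region |

**Lengthscale initialisation.** The classical choice for this architecture
is a fixed initial lengthscale of 0.1.  That value is tied to a particular
latent scale: if the pretrained embeddings live on a larger scale, an SE
kernel with $\sigma = 0.1$ underflows to zero almost everywhere and its
gradients vanish with it, so training cannot recover.  `fit()` therefore
defaults to `lengthscale = "auto"`, the median pairwise distance of a
subsample of pretrained embeddings — scale-free and safe — and trains the
lengthscale from there (the kernel variance stays fixed at 1).  Passing
`lengthscale = 0.1` restores the fixed convention.

**Inducing initialisation.** $Z$ starts at k-means centroids of (at most
10 000 subsampled) pretrained embeddings, with a random-subset fallback;
$q(u)$ starts at the prior ($\mu = 0$, $\Sigma = K_{ZZ}$, so the KL term
starts at zero).

### Numerical choices

* Every solve against $K_{ZZ}$ goes through one Cholesky policy: jitter
  starts at $10^{-6} v$ and escalates tenfold to at most $10^{-2}$ before
  failing with a condition estimate.  The Gaussian-likelihood validation
  path accepts an explicit `jitter0` so the bound can be compared with
  exact GP regression at matching precision.
* The marginal variance is clamped at `var_floor` ($10^{-8}$) before the
  square root; clamped entries get zero variance-gradient.
* $\Sigma = LL^\top$ is parameterised with a log-diagonal, keeping it
  positive definite by construction; the lengthscale is optimised as
  $\log \sigma$.
* HVG selection for scRNA-seq ranks genes by the variance of the
  log1p-normalised expression; ties break by ascending gene index.
  (Mean–dispersion binned statistics are a reasonable alternative; the
  variance ranking is what this package computes.)
* AUC uses the rank definition with half credit for ties; F1, precision
  and recall are computed at threshold 0.5 and reported as `NA` (never 0)
  when undefined.  Kruskal–Wallis uses the chi-square approximation at any
  group size.
* Negative (post-compensation) flow values pass through arcsinh untouched;
  no per-marker standardisation is applied before the AE.

## Post-hoc marker importance

The explainer asks: *which minimal marker set must be preserved for the
frozen model's predictions to survive?*  A shared per-column mask
$m \in [0,1]^p$ blends each column toward its mean over all analysis
cells, $X^m_{:,j} = m_j X_{:,j} + (1 - m_j)\bar{X}_j$.  Columns are
treated as Bernoulli$(P_j)$ draws, relaxed to binary-concrete samples
$\mathrm{sigm}((\mathrm{logit}\,P_j + \mathrm{logit}\,e_j)/\tau)$,
$e_j \sim U(0,1)$, so $P$ can be optimised by gradient descent on

$$\mathbb{E}_m\big[\tfrac{1}{N}\textstyle\sum_n \mathcal{L}(F(X^m), y_n)\big]
  + \lambda \textstyle\sum_j P_j .$$

$P_j$ is the importance score of marker j.  Choices worth recording:

* The prediction loss is the **per-subject mean**, so a given $\lambda$
  exerts the same sparsity pressure at any cohort size.  With a summed
  loss the penalty becomes irrelevant as $N$ grows and every marker's
  score saturates near 1 — we observed exactly this failure before
  normalising.
* $\lambda$ defaults to 0.05.  On simulated cohorts with known informative
  sets, 0.05 cleanly separates planted from incidental markers across
  models and seeds, whereas 0.01 is too weak whenever the (overfit,
  saturated) model leans on markers that carry no class signal: masking
  them still perturbs predictions, and only a penalty of comparable
  magnitude pushes their scores down.  Values an order of magnitude higher
  start suppressing genuinely informative markers, so sweeping
  $\lambda$ over, say, $\{0.01, 0.02, 0.05, 0.1, 0.25\}$ and inspecting
  the score gap remains good practice on real data.
* The penalty applies to $P$ (the expected mask), which is smooth and
  unbiased, rather than to sampled masks.
* Temperature anneals geometrically from 1.0 to 0.1 over the run;
  $P$ starts at 0.5 (maximum entropy); the model itself is frozen
  (asserted by checksum in the tests).
* One shared mask spans all timepoints by default (global markers);
  per-visit importance comes from running the explainer on one visit's
  data, and per-cell-subset importance from `explain_subset()`, which
  recomputes column means within each subset.

## The synthetic cohort generator

`simulate_cohort()` draws each sample's cells from a K-component Gaussian
mixture on an arcsinh-like scale (simulated values are treated as already
preprocessed, matching the pipeline entry point).  Class-1 subjects have
all population means shifted by $+\delta$ on a designated informative
marker set, optionally at selected timepoints only; per-sample cell counts
are uniform on a range; batches add a per-marker shift shared by all of a
batch's samples; visits after baseline can go missing with a configured
probability; the ground truth (labels, informative set, batch labels,
per-cell population labels) is returned alongside.

The default configuration — 60 subjects, 2 visits, 10 markers, 3
populations, 3 informative markers, $\delta = 1.5$, 200–800 cells per
sample — is the study condition used throughout the tests and the
acceptance script: large enough that subject-level signal is real, small
enough that a 5-fold cross-validation sweep runs in minutes on one CPU.
For these simulated cohorts the tests use a compressed training schedule
(about 40 full-batch pretraining iterations at lr $10^{-2}$, 8 fine-tuning
epochs at lr 0.02, B = 1, O = 50), which reaches ceiling accuracy on this
generator; the package defaults remain the conservative long schedule
above.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: spillover and compensation artefacts,
doublets, acquisition drift within a run, heavy-tailed or zero-inflated
marker distributions, population-abundance (rather than mean-shift)
signal, and outcome-correlated missingness.  Results on this generator
validate the machinery, not clinical performance.

## Evaluation and the batch-effect diagnostic

`cross_validate()` partitions *subjects* (never cells) into folds,
stratified by outcome by default — small cohorts otherwise risk
single-class folds, for which AUC is reported missing with a warning.
Within each fold, AE pretraining, inducing initialisation and all fitting
see only that fold's training subjects, and every fold reinitialises from
seed `config$seed + fold`.  Robustness protocols mirror common stress
tests: retaining 50% of cells per sample, or masking 10% of
second-timepoint visits, both behind one `protocol` flag.

`activation_scores()` summarises each sample at each stage — raw input, AE
latent, GP posterior mean, attention output — by the mean over the
sample's cells and output dimensions.  Grouping these scores by
acquisition batch and applying Kruskal–Wallis per layer quantifies how
much batch heterogeneity survives each stage; on simulated batched
cohorts the input layer separates batches sharply while the attention
layer does not, the qualitative signature of the model absorbing batch
shifts while retaining outcome signal.

## Known limitations

* The cytometry-side attention consumes scalar GP outputs, so its gating
  network is small; it cannot re-weight cells on features the GP scalar
  has already collapsed.
* A single GP is shared across visits; an additional GP dedicated to
  time-step correlations is deliberately out of scope (reported elsewhere
  as unhelpful at small N).
* The explainer scores global (or per-subset) marker masks, not per-cell
  attributions.
* The explainer explains the *model*, not the data-generating process: if
  a training run converges to a decision function that routes the class
  signal through correlated incidental markers (which an overparameterised
  model on a small cohort occasionally does), the recovered set faithfully
  reflects that model's reliance and will differ from the generative
  ground truth.  Explaining a well-converged model (saturated training
  probabilities) makes this rare but cannot exclude it.
* Binary FCS parsing is not included; ingestion expects delimited tables
  exported from standard FCS workflows (a manifest maps files to
  subjects, visits, outcomes and covariates).
* Training is single-threaded R; cohorts in the tens of subjects with
  10^4–10^5 cells per sample are the intended operating range.
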