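---
title: "Methods: information-bottleneck analysis of multimodal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-bottleneck analysis of multimodal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, estimators, parameter choices and known
limitations behind `mmib`. It states no empirical numbers beyond what the test
suite and `scripts/acceptance.R` compute themselves.

## The model

Given modalities $X^{(1)}, \dots, X^{(M)}$ and a categorical target $Y$, the
variational multimodal information bottleneck (VMIB) learns a stochastic
encoder $q_\phi(z \mid x^{(1:M)})$ and predictor $q_\theta(y \mid z)$ by
minimizing

$$
\mathcal{L} \;=\; \mathbb{E}\big[-\log q_\theta(y \mid z)\big]
\;+\; \lambda\, \mathbb{E}\big[\mathrm{KL}\!\left(q_\phi(z \mid x^{(1:M)})
\,\|\, \mathcal{N}(0, I)\right)\big].
$$

The KL term is an upper bound on the compression $I(Z; X^{(1:M)})$ (it equals
it when the prior matches the aggregate posterior), and
$H(Y) - \mathrm{CE}(Y \mid Z)$ is a lower bound on the prediction $I(Z; Y)$
(it can never exceed $H(Y)$, which the tests assert). $\lambda \ge 0$ sets the
operating point on the compression–prediction trade-off; sweeping it traces a
trajectory in the information plane.

**Architecture.** One MLP encoder per modality (`encoder_depth` blocks of
dense $\to$ batch-norm $\to$ ReLU $\to$ dropout), concatenation fusion, a
single linear head producing the posterior mean and log-variance
(log-variance clamped to $[-10, 10]$ for numerical safety), and a two-layer
softmax predictor. The prior is a fixed standard normal; learned priors
(mixtures, VampPrior-style) are out of scope. Attention or graph fusion
variants are likewise out of scope — concatenation keeps the information
accounting transparent.

**Training.** Adam (learning rate $10^{-3}$, cosine annealing), minibatches of
128, one reparameterized latent sample per example during training and the
posterior mean at evaluation, 100 epochs by default. All randomness
(initialization, shuffling, dropout, latent noise) flows from one seed, so
training is bit-reproducible; the test suite asserts identical parameters for
repeated runs. Gradients are clipped to a global norm of 5: the forward-KL
consistency penalty (below) contains inverse-variance factors that can spike
in early epochs, and clipping prevents the feedback loop without altering the
objective. Divergence (non-finite loss) aborts with the last good epoch in the
error message.

### Defaults and what they mean

| parameter | default | role |
|---|---|---|
| `latent_dim` | 32 | bottleneck width $d_Z$; the KL bound grows with it |
| `hidden` | 256 | encoder layer width |
| `encoder_depth` | 2 | hidden layers per modality encoder |
| `dropout_rate` | 0.3 | within-encoder dropout |
| `lambda` | 0.01 | compression weight; ~the knee of the sweep on the built-in generators |
| `epochs` | 100 | enough for the built-in generators to plateau |
| `grad_clip` | 5 | global gradient-norm ceiling |

## Mutual-information estimation

All MI values are **classifier-based lower bounds**
$I(X;Y) \ge H(Y) + \mathbb{E}[\log q(y \mid x)]$, estimated by 5-fold
stratified cross-validation: per fold, features are standardized with
training-fold statistics, a single-hidden-layer probe (256 units) is trained
with early stopping on an 80/20 stratified validation split, and the held-out
fold supplies the expectation. $H(Y)$ is the full-sample empirical label
entropy. The reported value is the fold mean; the fold standard deviation is
the dispersion measure used throughout.

Two backends estimate subset MI for the decomposition:

* `separate` (default): a fresh probe per modality subset. Bound tightness can
  differ across input dimensionalities, so a superset's estimate may fall
  below a subset's; raw values are reported unclamped (flagged when negative)
  because differences of lower bounds are not bounds on differences.
* `masked`: one probe per fold trained on all modalities with random modality
  zeroing (drop probability 0.3, keep-one rule), each subset evaluated by
  zeroing the complementary blocks. One model per fold means consistent bound
  tightness across subsets and well-defined fold-wise synergy dispersion; this
  backend is the default choice for synergy analyses.

The synergy proxy $S_{ij} = I(X_i, X_j; Y) - I(X_i;Y) - I(X_j;Y)$ (redundancy
$R = -S$) conflates the redundant and synergistic components of a full partial
information decomposition into one signed axis; it is a net indicator of
interaction type, not a four-way split, and an exact PID is deliberately not
attempted. $I_{miss}(S) = \max(0,\, \hat I(\text{full}) - \hat I(S))$ is
clamped at zero (and the clamping flagged) precisely because it subtracts two
bounds.

On discrete fixtures the plug-in estimator over the exact joint table is the
oracle; the tests require the classifier bound to converge to it within 0.05
nats at $n = 5000$ and to respect the data-processing inequality.

## Missing-modality robustness

Missing blocks are zero-imputed **post-standardization** at both training and
inference, so train- and test-time missingness are distributionally aligned.
Two strategies are implemented:

* **Modality dropout**: each block is independently zeroed with probability
  $p$ per sample; if all blocks of a sample are dropped one is restored
  uniformly at random, so no all-zero input reaches the encoder.
* **Consistency**: the objective gains
  $\gamma(t) \sum_{S \in \mathcal{S}}
  \mathrm{KL}\!\left(q_\phi(z \mid x^{\text{full}}) \,\|\,
  q_\phi(z \mid x^{S})\right)$, a *sum* over the configured subsets (default:
  all size $M-1$ subsets plus all singletons), with the full-information
  posterior first. The forward direction is deliberate: it makes the partial
  encoder cover the support of the full posterior (mean-seeking) instead of
  collapsing onto a mode. $\gamma(t)$ ramps linearly from 0 over
  `warmup_epochs` (30), and the partial passes reuse the full pass's dropout
  masks so the penalty isolates the effect of the missing blocks rather than
  dropout noise. Both posteriors come from the same encoder applied to masked
  input — no second network.

Cross-modal imputation is intentionally absent: by the data-processing
inequality an imputed block cannot add predictive information beyond the
observed blocks that generated it.

## Diagnostics

The fusion-collapse gap $\tilde G_i = \max(0, \mathrm{AUC(all)} -
\mathrm{AUC(ablate}\ i))$ is the operational proxy for the
information-theoretic gap $G_i = I(Z;Y) - I(Z;Y \mid X^{(i)})$; the MI form is
the target quantity but the AUC form is what is computed. Gaps are clamped at
zero (negative ablation effects are treated as noise) so the normalized gap
distribution is a valid probability vector, and are averaged over 3 seeds by
default. The balance index is the normalized entropy
$B = H(g/\sum g)/\log M$ with $B := 0$ for an all-zero profile (flagged
degenerate). Both $G_i$ and $B$ are marginal-ablation quantities: in
synergy-dominated tasks a modality can be essential yet have $\tilde G_i
\approx 0$, so the gap profile carries a warning flag whenever positive
synergy proxies are supplied alongside it.

Adaptation diagnostics compare four strategies (scratch, linear probe,
partial fine-tune, full fine-tune) by predictive gain versus the shift in mean
posterior-to-prior KL on a fixed evaluation split. The linear probe freezes
the encoders *including batch-norm running statistics* (otherwise the encoder
drifts silently); partial fine-tuning unfreezes the last dense layer (and its
batch norm) of each encoder plus the predictor. The efficiency ratio divides
the AUC gain by $\max(\Delta\mathrm{KL}, 10^{-3})$.

The representation entropy is the Gaussian form
$\tfrac12 \log\big((2\pi e)^d \det(\hat\Sigma + 10^{-6} I)\big)$ — an upper
bound on the differential entropy (the Gaussian maximizes entropy at fixed
covariance). The estimator choice is recorded because the quantity is
estimator-dependent.

## Uncertainty tools

Per-sample predictive entropy $H(\hat p(\cdot \mid z))$ drives both the OOD
protocol (train without one class, compare mean entropy on in-distribution
test samples versus the held-out class) and selective prediction (retain the
$\lceil c n \rceil$ lowest-entropy samples at coverage $c$, ties broken by
stable input order so results are deterministic; the random baseline averages
100 seeded uniform draws). Predictive entropy is not guaranteed to exceed the
true conditional entropy — an overconfident model can undershoot — so the
cross-entropy gap against a known true conditional is also provided, but it is
computable only on the synthetic generators where $p(y \mid x)$ is known.
Expected calibration error uses 10 equal-width confidence bins on $[0,1]$ with
top-1 confidence — the standard construction, stated here because binning
conventions differ across the literature. Conformal prediction sets are out of
scope.

## Longitudinal information flow

Transfer entropy $TE_{X \to Y} = I(X_{t-k:t-1}; Y_t \mid Y_{t-\ell:t-1})$
(defaults $k = \ell = 1$: consecutive visit pairs) is estimated as the
difference of two predictive-information fits sharing one subject-level fold
assignment. For categorical (or binarized — default rule: impaired vs normal,
$y > 0$) targets both fits are classifier MI bounds. For continuous targets a
Gaussian-regression backend is used: with held-out Gaussian log-densities the
target's differential entropy cancels in the difference, leaving a
cross-fitted log-density improvement; this is exact for linear-Gaussian
dynamics and is validated against the closed form for coupled AR(1) processes
(`gaussian_ar_te_closed_form()`, itself cross-checked against a
covariance-iteration oracle in the tests). Raw TE may be slightly negative
(flagged) — it is a conditional MI, nonnegative in theory, and small negative
estimates are estimation noise; a within-subject permutation null is provided
to calibrate that noise. Continuous histories are fed to the fits directly,
without discretization, to avoid binning bias. Subject-level folds are
mandatory for the sequential ladder (logistic regression per step) to prevent
within-subject leakage. Multi-step prediction horizons and recurrent
sequential-bottleneck training are out of scope; the ladder plus TE covers the
next-visit analyses.

## Synthetic generators

The generators define the package's study conditions; all stochastic claims in
the test suite are made under their defaults.

* `gen_interaction()`: $X^{(1)}, X^{(2)} \sim \mathcal{N}(0,1)$ i.i.d.,
  $Y \sim \mathrm{Bernoulli}(\sigma(\beta_1 X^{(1)} + \beta_2 X^{(2)} +
  \alpha X^{(1)} X^{(2)}))$. Defaults $n = 5000$, $\beta_1 = \beta_2 = 0.5$,
  $\alpha$ grid $\{0, 1, 2, 3\}$, 5 seeds. At $\alpha = 0$ the logit is
  additive and the synergy proxy is near zero; the interaction term creates
  genuinely joint information. The exact label rate is available by 2-D
  quadrature (`interaction_label_rate()`), and the true conditional is stored
  for cross-entropy-gap analyses.
* `gen_latent_class()`: a latent-class model shaped like a small multi-omics
  cohort — 5 imbalanced classes, $n = 900$ (70/30 split), three modalities
  reading the same 3-D latent coordinates at signal scales 2.0 / 0.7 / 0.35,
  giving one dominant, one medium-redundant and one weak modality. Chosen to
  emulate the dominance/redundancy profile typical of expression-centred
  multi-omics panels, where one assay dominates and the others are partially
  redundant with it. Orderings (not absolute values) are the test surface.
* `gen_coupled_ar()`: severity $s_t = a\, s_{t-1} + b\, x_{t-1} + \epsilon_y$
  driven by an AR(1) source $x_t$; stage = severity thresholded at 0.3 and 1.0
  stationary standard deviations into three levels, emulating a three-level
  clinical dementia staging; two stage markers equal severity plus noise whose
  sd is smallest at the marker's designed stage. The analytic lag-1 TE of the
  source and the lag-1 autocorrelation are attached to the metadata, so the
  estimators can be checked against ground truth at any size.
* `gen_discrete_joint()`: XOR / binary-symmetric-channel / copy / independent
  joints returned as exact pmf tables plus i.i.d. samples.

What the generators do **not** emulate: realistic omics marginals (counts,
heavy tails), batch effects, feature correlation structure beyond the shared
latent, irregular visit spacing, and missingness that is informative rather
than imposed. Passing tests therefore demonstrate estimator correctness and
qualitative robustness patterns, not performance on any particular real
cohort.

## Problem sizes in the checks

The acceptance-grade tests use the generator defaults: $n = 5000$ with 5 seeds
for the synergy recovery, $n = 900$ for the $\lambda$ sweep and the
robustness/adaptation comparisons, and 2000 subjects with 11 visits (20,000
consecutive pairs) for the transfer-entropy agreement, with 10 random
stationary parameter draws. These sizes were chosen so that estimator noise is
comfortably below the tolerances being asserted (0.05 nats for MI and TE
agreement; 0.02–0.03 AUC for the robustness margins).

## Known limitations

* All MI values are lower bounds from finite-capacity probes; differences of
  bounds (synergy proxies, $I_{miss}$) inherit that caveat and are reported as
  indicative, with dispersion.
* The balance index inherits the marginal-ablation blindness of $\tilde G_i$
  in synergy-dominated tasks.
* The Gaussian representation entropy is an upper-bound form; non-Gaussian
  latent structure inflates it.
* The consistency penalty is harder to optimize than modality dropout
  (inverse-variance terms; hence the warmup and gradient clipping), and on the
  built-in generators dropout typically matches or beats it — consistent with
  the interpretation of dropout as a Monte-Carlo approximation of the same
  consistency principle.
* The TE estimator assumes within-subject stationarity across the observed
  visits and equal visit spacing.
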