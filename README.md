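# mmib — information-theoretic analysis of multimodal biomedical data

Multimodal biomedical studies routinely combine heterogeneous measurements —
multi-omics profiles, imaging-derived features, clinical scores — to predict a
clinical target. `mmib` treats that problem as one of **information control**:
how much predictive information each modality carries, how a fused
representation should trade compression against prediction, how performance
must degrade when modalities go missing, and when a model's own uncertainty
can be trusted. It is aimed at computational biologists and ML practitioners
who want quantitative, estimator-backed answers to those questions on tabular
multimodal data (one numeric matrix per modality plus a categorical label, or
long-format longitudinal records).

## What's inside

**Variational multimodal information bottleneck (VMIB).** Per-modality MLP
encoders (batch norm, dropout), concatenation fusion, a diagonal-Gaussian
latent bottleneck with standard-normal prior, and a softmax predictor, trained
with Adam on the objective

```
L = E[ -log q_theta(y | z) ]  +  lambda * E[ KL( q_phi(z | x_1..M) || N(0, I) ) ]
```

The KL term upper-bounds the compression `I(Z; X)`; `H(Y) - CE(Y|Z)`
lower-bounds the prediction `I(Z; Y)`, so every trained model yields a point
in the information plane (`information_plane_sweep()`).

**Mutual-information decomposition.** Classifier-based lower bounds
`I(X;Y) >= H(Y) + E[log q(y|x)]` per modality subset (5-fold stratified CV,
early-stopped MLP probes), the redundancy/synergy proxy
`S_ij = I(X_i, X_j; Y) - I(X_i; Y) - I(X_j; Y)`, and the conditional
information loss `Imiss(S)` under missing modalities. Exact plug-in MI on
discrete joints (`plugin_mi_discrete()`) serves as the oracle.

**Missing-modality robustness.** Modality-dropout training (random block
zeroing with a keep-one rule) and a forward-KL consistency penalty
`gamma * sum_S KL(q(z|x_full) || q(z|x_S))`, plus a systematic ablation grid
that pairs each observed subset's AUC with its `Imiss`.

**Diagnostics.** Fusion-collapse detection via per-modality predictive gaps
`G_i = AUC(all) - AUC(ablate i)` and their normalized-entropy balance index;
adaptation efficiency (`delta AUC` per unit `delta KL`) for scratch /
linear-probe / partial / full fine-tuning; Gaussian representation entropy.

**Uncertainty.** Per-sample predictive entropy, selective prediction with
deferral curves against a random-deferral baseline, expected calibration
error, and a held-out-class OOD protocol.

**Longitudinal information flow.** Transfer entropy
`TE(X -> Y) = I(X_hist; Y_t | Y_hist)` via paired predictive-information fits
(classifier bounds for categorical targets, Gaussian regression for continuous
ones), an analytic closed form for coupled AR(1) processes, a sequential
prediction ladder with subject-level CV, and stage-conditioned modality
discriminability.

**Synthetic generators** with known information structure
(`gen_interaction()`, `gen_latent_class()`, `gen_coupled_ar()`,
`gen_discrete_joint()`) make every claim testable without external data.

All information quantities are in nats.

## Worked example

```r
library(mmib)

# two 1-D modalities; the label depends on their product (pure interaction)
d <- gen_interaction(n = 5000, beta1 = 0.5, beta2 = 0.5, alpha = 3, seed = 1)
dec <- decompose_information(d, subsets = list("x1", "x2", c("x1", "x2")),
                             seed = 1, estimator = "masked")
print(dec)
#> <info_decomposition> H(Y) = 0.6931 nats; estimator: masked
#>   I(x1; Y) = 0.001 +/- 0.003 (0.2% of H(Y))
#>   I(x2; Y) = -0.003 +/- 0.008 (-0.5% of H(Y))
#>   I(x1+x2; Y) = 0.232 +/- 0.012 (33.5% of H(Y))
#>   S[x1,x2] = +0.234
```

Neither modality predicts the label on its own (both singleton bounds sit at
zero within fold noise; the small negative value is the unclamped bound doing
its job), yet jointly the modalities carry 0.23 nats — a third of the label
entropy. The positive synergy proxy `S = +0.23` flags exactly this
"accessible only jointly" structure. With `alpha = 0` the same analysis
returns `S` within noise of zero.

Fusion-collapse arithmetic works on any gap profile, e.g. a model whose
ablation gaps are 0.203, 0.017 and 0 AUC across three modalities:

```r
balance_index(c(0.203, 0.017, 0.000))
#> [1] 0.2476  # heavily collapsed onto one modality (1 = perfectly balanced)
```

## Command line

A thin CLI over `run_experiment()` lives at `inst/cli/mmib`:

```sh
Rscript inst/cli/mmib simulate --out out/sim --seed 7 --config cfg.json
Rscript inst/cli/mmib decompose --out out/dec --seed 7 --config cfg.json
```

Tasks: `simulate`, `decompose`, `sweep`, `robustness`, `diagnose`,
`uncertainty`, `temporal`. Every run writes CSV tables plus a `report.json`
carrying the seed and configuration echo.

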