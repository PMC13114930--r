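#' Configuration for missing-modality robustness training
#'
#' @param strategy `"standard"`, `"dropout"` (random modality zeroing), or
#'   `"consistency"` (forward-KL penalty between full- and
#'   partial-observation posteriors).
#' @param dropout_prob Per-sample, per-modality drop probability for the
#'   dropout strategy (default 0.3).
#' @param gamma Consistency penalty strength (default 0.05).
#' @param warmup_epochs Epochs over which `gamma` is ramped linearly from 0
#'   (default 30).
#' @param subsets List of modality subsets for the consistency penalty;
#'   defaults (at training time) to all size `M-1` subsets plus all
#'   singletons.
#' @return A list of class `robustness_config`.
#' @export
robustness_config <- function(strategy = c("standard", "dropout", "consistency"),
                              dropout_prob = 0.3, gamma = 0.05,
                              warmup_epochs = 30L, subsets = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, gamma >= 0)
  structure(list(strategy = strategy, dropout_prob = dropout_prob,
                 gamma = gamma, warmup_epochs = as.integer(warmup_epochs),
                 subsets = subsets),
            class = "robustness_config")
}

#' Random modality zeroing with a keep-one rule
#'
#' Independently zeroes each modality block of each sample with probability
#' `p`. When every block of a sample would be dropped, one uniformly chosen
#' block is restored, so each sample always retains at least one modality.
#' Draws from R's global RNG (seed it for reproducibility).
#'
#' @param batch Named list of per-modality matrices with equal row counts.
#' @param p Drop probability in `[0, 1]`.
#' @return List of matrices with dropped blocks zeroed.
#' @export
apply_modality_dropout <- function(batch, p) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) return(batch)
  n <- nrow(batch[[1]])
  M <- length(batch)
  drop <- matrix(stats::runif(n * M) < p, n, M)
  all_dropped <- rowSums(drop) == M
  if (any(all_dropped)) {
    keep <- sample.int(M, sum(all_dropped), replace = TRUE)
    drop[cbind(which(all_dropped), keep)] <- FALSE
  }
  for (m in seq_len(M)) {
    rows <- drop[, m]
    if (any(rows)) batch[[m]][rows, ] <- 0
  }
  batch
}

#' Forward KL consistency penalty between posteriors
#'
#' \eqn{KL(q(z|x_{full}) \| q(z|x_{partial}))} in nats — the full-information
#' posterior is the first argument. The forward direction encourages the
#' partial-observation encoder to cover the support of the full encoder
#' (mean-seeking) rather than collapse onto a mode.
#'
#' @param full_posterior,partial_posterior [diag_gaussian()] posteriors of
#'   equal dimension.
#' @return Penalty in nats (0 iff the posteriors are identical).
#' @export
consistency_penalty <- function(full_posterior, partial_posterior) {
  kl_diag_gaussian(full_posterior, partial_posterior)
}

#' Train a VMIB with a missing-modality robustness strategy
#'
#' `strategy = "dropout"` applies [apply_modality_dropout()] to every
#' minibatch. `strategy = "consistency"` augments the VMIB objective with
#' `gamma(t)` times the forward-KL consistency penalty summed over the
#' configured subsets, where `gamma(t)` ramps linearly from 0 over
#' `warmup_epochs`. `strategy = "standard"` is identical to [train_vmib()].
#'
#' @param data A [multimodal_dataset()].
#' @param config A [vmib_config()].
#' @param robustness A [robustness_config()].
#' @return A trained `vmib` model (with `$strategy` recording the variant).
#' @export
train_robust_vmib <- function(data, config = vmib_config(),
                              robustness = robustness_config()) {
  stopifnot(inherits(robustness, "robustness_config"))
  mods <- names(data$modalities)
  if (robustness$strategy == "standard") {
    return(train_vmib_impl(data, config, strategy = "standard"))
  }
  if (robustness$strategy == "dropout") {
    return(train_vmib_impl(data, config, strategy = "dropout",
                           dropout_p = robustness$dropout_prob))
  }
  subsets <- robustness$subsets
  if (is.null(subsets)) {
    subsets <- c(utils::combn(mods, length(mods) - 1L, simplify = FALSE),
                 lapply(mods, identity))
    subsets <- unique(subsets)
  }
  if (length(subsets) == 0L ||
      any(vapply(subsets, length, integer(1)) %in% c(0L, length(mods)))) {
    stop("consistency subsets must be non-empty proper subsets", call. = FALSE)
  }
  train_vmib_impl(data, config, strategy = "consistency",
                  consistency = list(subsets = subsets,
                                     gamma = robustness$gamma,
                                     warmup_epochs = robustness$warmup_epochs))
}

#' Evaluate a model under systematic modality ablation
#'
#' For each observed subset, the unobserved modality blocks are zero-imputed
#' (post-standardization) at inference and test-split AUC/accuracy are
#' reported alongside the information loss `Imiss` from the decomposition.
#'
#' @param model A trained `vmib` model.
#' @param data A [multimodal_dataset()] with a test split.
#' @param decomp An [decompose_information()] result containing the full set
#'   and every evaluated subset (for `Imiss`); may be `NULL` to skip `Imiss`.
#' @param subsets List of observed-modality subsets; defaults to the full set,
#'   all size `M-1` subsets and all singletons.
#' @return Data frame with columns `subset`, `imiss`, `auc`, `accuracy`.
#' @export
evaluate_ablation_grid <- function(model, data, decomp = NULL, subsets = NULL) {
  mods <- model$modality_names
  if (is.null(subsets)) {
    subsets <- c(list(mods),
                 utils::combn(mods, length(mods) - 1L, simplify = FALSE),
                 lapply(mods, identity))
    subsets <- unique(subsets)
  }
  if (any(vapply(subsets, length, integer(1)) == 0L)) {
    stop("every subset must contain at least one observed modality",
         call. = FALSE)
  }
  te <- split_indices(data, "test")
  y <- data$labels[te]
  rows <- lapply(subsets, function(S) {
    probs <- predict(model, data, type = "prob", split = "test", observed = S)
    data.frame(subset = subset_key(mods[mods %in% S]),
               imiss = if (is.null(decomp)) NA_real_ else
                 as.numeric(info_loss_imiss(decomp, S)),
               auc = macro_auc(probs, y),
               accuracy = accuracy_score(probs, y))
  })
  do.call(rbind, rows)
}
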