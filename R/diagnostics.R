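#' Normalized balance index of a predictive-gap profile
#'
#' Normalized Shannon entropy of the gap distribution:
#' `B = H(g / sum(g)) / log(M)` with `0 log 0 = 0`. `B = 1` indicates
#' perfectly balanced reliance across the `M` modalities; `B = 0` indicates a
#' single modality carries all predictive reliance. An all-zero gap vector
#' (no measurable reliance) yields `B = 0` with a `degenerate` attribute.
#' The index is invariant to permutation and positive rescaling of the gaps.
#'
#' @param gaps Non-negative vector of per-modality predictive gaps,
#'   length >= 2.
#' @return Balance index in `[0, 1]`.
#' @examples
#' balance_index(c(0.203, 0.017, 0.000)) # 0.248 -> collapsed towards one modality
#' balance_index(c(0.1, 0.1, 0.1))       # 1, perfectly balanced
#' @export
balance_index <- function(gaps) {
  gaps <- as.numeric(gaps)
  if (length(gaps) < 2L) stop("need gaps for at least 2 modalities", call. = FALSE)
  if (any(gaps < 0)) stop("gaps must be non-negative", call. = FALSE)
  s <- sum(gaps)
  if (s == 0) return(structure(0, degenerate = TRUE))
  entropy_categorical(gaps / s) / log(length(gaps))
}

#' Modality-conditioned predictive gap profile
#'
#' The empirical fusion-collapse diagnostic: for each modality `i`,
#' `G_i = max(0, AUC(all modalities) - AUC(modality i zero-ablated))`,
#' averaged over independently trained models (one per seed). A gap near the
#' full-model AUC margin for one modality with near-zero gaps elsewhere
#' indicates fusion collapse onto that modality. Because the gaps are
#' marginal-ablation quantities, they can understate the importance of a
#' modality whose contribution is purely synergistic; when a decomposition
#' with positive synergy proxies is supplied, the profile carries a warning
#' flag.
#'
#' @param model_factory Function `seed -> vmib` returning a trained model
#'   (train one fresh model per seed, or return a shared model).
#' @param data A [multimodal_dataset()] with a test split.
#' @param seeds Integer vector of seeds (default `1:3`).
#' @param decomp Optional [decompose_information()] result used only to flag
#'   synergy-dominated settings.
#' @return Object of class `gap_profile`: `gaps` (named, AUC units),
#'   `balance`, `reliance_share`, `auc_all`, `n_seeds`, `synergy_warning`.
#' @export
predictive_gap_profile <- function(model_factory, data, seeds = 1:3,
                                   decomp = NULL) {
  stopifnot(length(seeds) >= 1L)
  te <- split_indices(data, "test")
  if (nlevels(droplevels(data$labels[te])) < 2L) {
    stop("test split needs at least 2 classes", call. = FALSE)
  }
  y <- data$labels[te]
  gap_mat <- NULL
  auc_all_v <- numeric(0)
  for (s in seeds) {
    model <- model_factory(s)
    mods <- model$modality_names
    auc_all <- macro_auc(predict(model, data, type = "prob", split = "test"), y)
    gaps <- vapply(mods, function(m) {
      probs <- predict(model, data, type = "prob", split = "test",
                       observed = setdiff(mods, m))
      max(0, auc_all - macro_auc(probs, y))
    }, numeric(1))
    gap_mat <- rbind(gap_mat, gaps)
    auc_all_v <- c(auc_all_v, auc_all)
  }
  gaps <- colMeans(gap_mat)
  share <- if (sum(gaps) > 0) gaps / sum(gaps) else gaps * 0
  structure(list(gaps = gaps,
                 balance = as.numeric(balance_index(gaps)),
                 reliance_share = share,
                 auc_all = mean(auc_all_v),
                 n_seeds = length(seeds),
                 synergy_warning = !is.null(decomp) &&
                   any(decomp$pairwise_synergy > 0)),
            class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  cat("<gap_profile> AUC(all) =", round(x$auc_all, 3),
      "| balance index B =", round(x$balance, 2),
      sprintf("(%d seed%s)\n", x$n_seeds, if (x$n_seeds > 1) "s" else ""))
  for (m in names(x$gaps)) {
    cat(sprintf("  G[%s] = %.3f (%.0f%% of reliance)\n",
                m, x$gaps[[m]], 100 * x$reliance_share[[m]]))
  }
  if (isTRUE(x$synergy_warning)) {
    cat("  warning: positive synergy proxies present; marginal gaps may",
        "understate jointly informative modalities\n")
  }
  invisible(x)
}

adapt_trainable <- function(nets, strategy) {
  all_true <- lapply(nets, function(l) rep(TRUE, length(l)))
  if (strategy %in% c("scratch", "full_finetune")) return(all_true)
  tr <- lapply(nets, function(l) rep(FALSE, length(l)))
  tr$pred <- rep(TRUE, length(nets$pred))
  if (strategy == "partial_finetune") {
    for (key in grep("^enc:", names(nets), value = TRUE)) {
      lin_idx <- which(vapply(nets[[key]], function(l) l$type == "linear",
                              logical(1)))
      last <- max(lin_idx)
      tr[[key]][last] <- TRUE
      if (last < length(nets[[key]]) && nets[[key]][[last + 1L]]$type == "bn") {
        tr[[key]][last + 1L] <- TRUE
      }
    }
  }
  tr
}

#' Adaptation diagnostics for a pretrained VMIB
#'
#' Adapts a pretrained model to a (typically small) labelled dataset with one
#' of four strategies and reports predictive gain versus latent-sensitivity
#' shift: `delta_auc` is the test AUC change relative to the pretrained
#' baseline and `delta_kl` the change in mean posterior-to-prior KL on the
#' same fixed evaluation split. `efficiency = delta_auc / max(delta_kl, eps)`.
#'
#' Strategies: `"scratch"` trains a fresh model of the same architecture;
#' `"linear_probe"` freezes the encoders and posterior head (including
#' batch-norm running statistics) and retrains only the predictor;
#' `"full_finetune"` updates all parameters; `"partial_finetune"` updates the
#' final linear (+ batch-norm) layer of each encoder and the predictor.
#' With `epochs = 0` the adapted model is the pretrained model itself
#' (identity adaptation).
#'
#' @param pretrained A trained `vmib` model.
#' @param data_small A [multimodal_dataset()] with train/test split, same
#'   modalities and label levels as the pretraining data.
#' @param strategy One of `"scratch"`, `"linear_probe"`, `"full_finetune"`,
#'   `"partial_finetune"`.
#' @param epochs Adaptation epochs (default 30; 0 = identity adaptation).
#' @param lr Adaptation learning rate (default the pretrained model's).
#' @param seed Seed for the adaptation run.
#' @param eps Floor for the efficiency denominator (default 1e-3).
#' @return Object of class `adaptation_report` (also a one-row data frame)
#'   with `strategy`, `auc`, `delta_auc`, `delta_kl`, `efficiency`.
#' @export
adaptation_report <- function(pretrained, data_small,
                              strategy = c("scratch", "linear_probe",
                                           "full_finetune", "partial_finetune"),
                              epochs = 30L, lr = NULL, seed = 1L,
                              eps = 1e-3) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(pretrained, "vmib"))
  if (!identical(names(data_small$modalities), pretrained$modality_names) ||
      !all(vapply(data_small$modalities, ncol, integer(1)) ==
             pretrained$modality_dims)) {
    stop("data_small modalities do not match the pretrained model", call. = FALSE)
  }
  if (!all(levels(data_small$labels) %in% pretrained$label_levels)) {
    stop("data_small labels outside the pretrained label set", call. = FALSE)
  }
  cfg <- pretrained$config
  cfg$epochs <- as.integer(max(epochs, 1L))
  if (!is.null(lr)) cfg$lr <- lr
  cfg$seed <- as.integer(seed)

  y_te <- data_small$labels[split_indices(data_small, "test")]
  base_probs <- predict(pretrained, data_small, type = "prob", split = "test")
  base_auc <- macro_auc(base_probs, y_te)
  base_kl <- mean(predict(pretrained, data_small, type = "latent",
                          split = "test")$kl)

  if (epochs == 0L) {
    adapted <- pretrained
  } else if (strategy == "scratch") {
    adapted <- train_vmib_impl(data_small, cfg, strategy = "scratch",
                               std = pretrained$std, seed = seed)
  } else {
    trainable <- adapt_trainable(pretrained$nets, strategy)
    adapted <- train_vmib_impl(data_small, cfg, strategy = strategy,
                               nets = pretrained$nets, trainable = trainable,
                               std = pretrained$std, seed = seed)
  }
  probs <- predict(adapted, data_small, type = "prob", split = "test")
  auc <- macro_auc(probs, y_te)
  kl <- mean(predict(adapted, data_small, type = "latent",
                     split = "test")$kl)
  out <- data.frame(strategy = strategy, auc = auc,
                    delta_auc = auc - base_auc,
                    delta_kl = kl - base_kl,
                    efficiency = (auc - base_auc) / max(kl - base_kl, eps),
                    baseline_auc = base_auc)
  class(out) <- c("adaptation_report", class(out))
  attr(out, "model") <- adapted
  out
}
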