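#' Selective prediction via entropy-based deferral
#'
#' For each coverage `c`, retains the `ceiling(c * n)` samples with the lowest
#' predictive entropy (ties broken by stable input order) and reports the
#' accuracy on the retained set, together with the entropy threshold `tau(c)`
#' that defines the retained set (`entropy <= tau`) and a random-deferral
#' baseline (uniform subsets of equal size, averaged over 100 seeded draws).
#'
#' @param pred_probs Matrix samples x classes of predicted probabilities.
#' @param labels Factor or integer class labels.
#' @param coverages Vector of retention fractions in `(0, 1]`; default
#'   `1.0, 0.9, ..., 0.3`.
#' @param seed Seed for the random baseline.
#' @param n_random Number of random-baseline draws (default 100).
#' @return Data frame of class `deferral_curve` with columns `coverage`,
#'   `n_retained`, `accuracy_retained`, `accuracy_random`,
#'   `entropy_threshold`.
#' @export
deferral_curve <- function(pred_probs, labels,
                           coverages = seq(1.0, 0.3, by = -0.1),
                           seed = 1L, n_random = 100L) {
  pred_probs <- as.matrix(pred_probs)
  if (any(coverages <= 0 | coverages > 1)) {
    stop("coverages must lie in (0, 1]", call. = FALSE)
  }
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  n <- nrow(pred_probs)
  if (n == 0L) stop("empty input", call. = FALSE)
  H <- predictive_entropy(pred_probs)
  correct <- as.numeric(max.col(pred_probs, ties.method = "first") == y)
  ord <- order(H) # stable: ties keep input order
  coverages <- sort(coverages, decreasing = TRUE)
  set.seed(seed)
  rows <- lapply(coverages, function(cv) {
    k <- ceiling(cv * n)
    keep <- ord[seq_len(k)]
    acc_rand <- mean(vapply(seq_len(n_random), function(i) {
      mean(correct[sample.int(n, k)])
    }, numeric(1)))
    data.frame(coverage = cv, n_retained = k,
               accuracy_retained = mean(correct[keep]),
               accuracy_random = acc_rand,
               entropy_threshold = max(H[keep]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("deferral_curve", class(out))
  out
}

#' Held-out-class OOD detection via predictive entropy
#'
#' Trains a model without one class and compares mean predictive entropy on
#' in-distribution (ID) test samples against samples of the held-out class,
#' which act as a surrogate out-of-distribution (OOD) population. Distribution
#' shift reduces the usable predictive information, inflating entropy, so the
#' OOD/ID entropy ratio above 1 signals a usable OOD score. A threshold sweep
#' reports, for each entropy threshold `tau`, the OOD detection rate (fraction
#' of OOD samples with entropy above `tau`) and the ID false-positive rate.
#'
#' @param model_factory Function `(data, seed) -> model` where the returned
#'   model supports `predict(model, data, type = "prob", split = "test")`;
#'   typically a wrapper around [train_vmib()].
#' @param data A [multimodal_dataset()] with a train/test split.
#' @param held_out_class Label (level) to exclude from training.
#' @param threshold_grid Entropy thresholds for the sweep; default 21 points
#'   spanning `[0, log K]`.
#' @param seed Seed passed to the factory.
#' @return Object of class `ood_report`: `mean_entropy_id`,
#'   `mean_entropy_ood`, `ratio`, and a `sweep` data frame.
#' @export
ood_entropy_protocol <- function(model_factory, data, held_out_class,
                                 threshold_grid = NULL, seed = 1L) {
  held_out_class <- as.character(held_out_class)
  if (!held_out_class %in% levels(data$labels)) {
    stop("held-out class not present in the data", call. = FALSE)
  }
  if (nlevels(droplevels(data$labels)) < 2L ||
      all(as.character(data$labels) == held_out_class)) {
    stop("held-out class cannot be the only class", call. = FALSE)
  }
  is_ood <- as.character(data$labels) == held_out_class
  id_data <- subset_samples(data, !is_ood)
  ood_data <- subset_samples(data, is_ood)
  model <- model_factory(id_data, seed)
  probs_id <- predict(model, id_data, type = "prob", split = "test")
  # the held-out class was never seen in training: score all its samples
  ood_eval <- ood_data
  ood_eval$split <- NULL
  probs_ood <- predict(model, ood_eval, type = "prob")
  h_id <- predictive_entropy(probs_id)
  h_ood <- predictive_entropy(probs_ood)
  if (is.null(threshold_grid)) {
    threshold_grid <- seq(0, log(ncol(probs_id)), length.out = 21L)
  }
  sweep <- data.frame(
    tau = threshold_grid,
    ood_detection_rate = vapply(threshold_grid,
                                function(t) mean(h_ood > t), numeric(1)),
    id_false_positive_rate = vapply(threshold_grid,
                                    function(t) mean(h_id > t), numeric(1)))
  structure(list(mean_entropy_id = mean(h_id),
                 mean_entropy_ood = mean(h_ood),
                 ratio = mean(h_ood) / mean(h_id),
                 sweep = sweep,
                 held_out_class = held_out_class,
                 n_id = length(h_id), n_ood = length(h_ood)),
            class = "ood_report")
}

#' @export
print.ood_report <- function(x, ...) {
  cat(sprintf("<ood_report> held-out class '%s': H_ID = %.3f, H_OOD = %.3f (%.1fx)\n",
              x$held_out_class, x$mean_entropy_id, x$mean_entropy_ood, x$ratio))
  invisible(x)
}

#' Cross-entropy gap against a known true conditional
#'
#' The model-mismatch term `E[-log q(y|x)] - H(Y|X)` (nats), computable only
#' when the true conditional class probabilities are known — i.e. on synthetic
#' generators. Non-negative in expectation (Gibbs' inequality).
#'
#' @param pred_probs Predicted class-probability matrix.
#' @param true_cond_probs True conditional probability matrix of the same
#'   shape.
#' @param labels Class labels.
#' @return Scalar gap in nats.
#' @export
cross_entropy_gap <- function(pred_probs, true_cond_probs, labels) {
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  pred_probs <- as.matrix(pred_probs)
  true_cond_probs <- as.matrix(true_cond_probs)
  ce <- -mean(log(pmax(pred_probs[cbind(seq_along(y), y)], 1e-12)))
  hyx <- mean(predictive_entropy(true_cond_probs))
  ce - hyx
}
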