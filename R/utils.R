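# shared helpers: folds, standardization, AUC, seed derivation

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, stratified by class so every fold
#' approximately preserves the label distribution.
#'
#' @param labels Factor or vector of class labels.
#' @param k Number of folds.
#' @param seed Integer seed controlling the assignment.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    ix <- which(labels == cl)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

# train-statistics standardization; constant columns are left centred only
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
standardize_apply <- function(X, st) {
  X <- row_add(as.matrix(X), -st$mu)
  X * rep(1 / st$sd, each = nrow(X))
}

#' Macro-averaged one-vs-rest AUC
#'
#' For each class present in `labels`, computes the ROC AUC of that class's
#' predicted probability against the one-vs-rest indicator, then averages over
#' classes. Classes absent from `labels` are skipped.
#'
#' @param pred_probs Matrix samples x classes; columns ordered as
#'   `levels(labels)` (or as supplied class order for integer labels).
#' @param labels Factor or integer class labels.
#' @return Macro one-vs-rest AUC in `[0, 1]`.
#' @export
macro_auc <- function(pred_probs, labels) {
  pred_probs <- as.matrix(pred_probs)
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  aucs <- c()
  for (k in sort(unique(y))) {
    resp <- as.integer(y == k)
    if (length(unique(resp)) < 2L) next
    a <- as.numeric(pROC::auc(response = resp, predictor = pred_probs[, k],
                              levels = c(0L, 1L), direction = "<",
                              quiet = TRUE))
    aucs <- c(aucs, a)
  }
  if (length(aucs) == 0L) return(NA_real_)
  mean(aucs)
}

# small deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483629
  as.integer(s) + 1L
}

accuracy_score <- function(pred_probs, labels) {
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  mean(max.col(as.matrix(pred_probs), ties.method = "first") == y)
}
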