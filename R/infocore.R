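#' Shannon entropy of a categorical distribution
#'
#' Computes \eqn{H(p) = -\sum_k p_k \log p_k} in nats, with the convention
#' \eqn{0 \log 0 = 0}. All information quantities in this package use the
#' natural logarithm.
#'
#' @param p Numeric vector of probabilities. Must be non-negative and sum to 1
#'   (tolerance `1e-9`).
#' @return Entropy in nats, a value in `[0, log(length(p))]`.
#' @examples
#' entropy_categorical(rep(1 / 5, 5)) # log(5)
#' entropy_categorical(c(1, 0, 0))    # 0
#' @export
entropy_categorical <- function(p) {
  validate_prob_vector(p)
  p <- p[p > .mmib_zero_tol]
  -sum(p * log(p))
}

# probabilities below this are treated as exact zeros in plug-in estimators
.mmib_zero_tol <- 1e-15

validate_prob_vector <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("probability vector must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p))) stop("probabilities must be finite", call. = FALSE)
  if (any(p < -tol)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  }
  invisible(p)
}

#' Diagonal Gaussian distribution
#'
#' Lightweight container for a factorized Gaussian \eqn{N(\mu, diag(\sigma^2))},
#' used for encoder posteriors and latent priors.
#'
#' @param mean Numeric vector of means.
#' @param var Numeric vector of strictly positive variances, same length.
#' @return An object of class `diag_gaussian`.
#' @export
diag_gaussian <- function(mean, var) {
  if (length(mean) != length(var)) {
    stop("mean and variance must have the same dimension", call. = FALSE)
  }
  if (any(!is.finite(mean)) || any(!is.finite(var))) {
    stop("mean and variance must be finite", call. = FALSE)
  }
  if (any(var <= 0)) stop("variances must be strictly positive", call. = FALSE)
  structure(list(mean = as.numeric(mean), var = as.numeric(var)),
            class = "diag_gaussian")
}

#' KL divergence between diagonal Gaussians
#'
#' Closed-form \eqn{KL(q \| r)} in nats for two factorized Gaussians of equal
#' dimension:
#' \deqn{KL = 0.5 \sum_j \left( \sigma_{q,j}^2/\sigma_{r,j}^2 +
#'   (\mu_{r,j}-\mu_{q,j})^2/\sigma_{r,j}^2 - 1 +
#'   \log \sigma_{r,j}^2 - \log \sigma_{q,j}^2 \right).}
#'
#' @param q,r Objects of class [diag_gaussian()].
#' @return KL divergence in nats (non-negative; zero iff `q == r`).
#' @examples
#' kl_diag_gaussian(diag_gaussian(1, 1), diag_gaussian(0, 1)) # 0.5
#' @export
kl_diag_gaussian <- function(q, r) {
  stopifnot(inherits(q, "diag_gaussian"), inherits(r, "diag_gaussian"))
  if (length(q$mean) != length(r$mean)) {
    stop("dimension mismatch between q and r", call. = FALSE)
  }
  0.5 * sum(q$var / r$var + (r$mean - q$mean)^2 / r$var - 1 +
              log(r$var) - log(q$var))
}

#' Exact joint probability table over discrete variables
#'
#' A `discrete_joint` wraps a probability array over the product support of a
#' set of named discrete variables. It is the brute-force oracle against which
#' the classifier-based mutual-information bounds are validated.
#'
#' @param pmf Numeric array; `dimnames` give the state labels, and the names of
#'   `dimnames` give the variable names. Entries must be non-negative and sum
#'   to 1.
#' @return An object of class `discrete_joint`.
#' @export
discrete_joint <- function(pmf) {
  if (is.null(dim(pmf))) dim(pmf) <- length(pmf)
  if (any(pmf < -1e-12)) stop("pmf entries must be non-negative", call. = FALSE)
  if (abs(sum(pmf) - 1) > 1e-9) stop("pmf must sum to 1", call. = FALSE)
  if (is.null(dimnames(pmf))) {
    dimnames(pmf) <- lapply(dim(pmf), function(k) as.character(seq_len(k) - 1L))
  }
  if (is.null(names(dimnames(pmf)))) {
    names(dimnames(pmf)) <- paste0("v", seq_along(dim(pmf)))
  }
  structure(list(pmf = pmf, vars = names(dimnames(pmf))), class = "discrete_joint")
}

#' @export
print.discrete_joint <- function(x, ...) {
  cat("<discrete_joint> variables:", paste(x$vars, collapse = ", "),
      "| states:", paste(dim(x$pmf), collapse = " x "), "\n")
  invisible(x)
}

resolve_axes <- function(joint, block) {
  if (is.character(block)) {
    idx <- match(block, joint$vars)
    if (anyNA(idx)) stop("unknown variable(s): ",
                         paste(block[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  } else {
    idx <- as.integer(block)
    if (any(idx < 1L | idx > length(joint$vars))) stop("axis out of range", call. = FALSE)
    idx
  }
}

#' Marginal pmf over a block of variables
#'
#' @param joint A [discrete_joint()].
#' @param block Variable names or axis indices to keep.
#' @return Numeric array of marginal probabilities over `block`.
#' @export
marginalize_joint <- function(joint, block) {
  stopifnot(inherits(joint, "discrete_joint"))
  idx <- resolve_axes(joint, block)
  m <- apply(joint$pmf, idx, sum)
  if (is.null(dim(m))) dim(m) <- length(m)
  m
}

#' Plug-in mutual information between two blocks of a discrete joint
#'
#' Exact \eqn{I(B_1; B_2) = H(B_1) + H(B_2) - H(B_1, B_2)} in nats, computed
#' from the joint table. The two blocks must partition all variables of the
#' joint.
#'
#' @param joint A [discrete_joint()].
#' @param block1,block2 Variable names or axis indices for the two blocks.
#' @return Mutual information in nats (non-negative up to roundoff).
#' @examples
#' j <- gen_discrete_joint("bsc", list(flip = 0.1))$joint
#' plugin_mi_discrete(j, "x1", "y") # log(2) - binary entropy(0.1)
#' @export
plugin_mi_discrete <- function(joint, block1, block2) {
  stopifnot(inherits(joint, "discrete_joint"))
  i1 <- resolve_axes(joint, block1)
  i2 <- resolve_axes(joint, block2)
  if (length(i1) == 0L || length(i2) == 0L) stop("empty block", call. = FALSE)
  if (length(intersect(i1, i2)) > 0L ||
      length(union(i1, i2)) != length(joint$vars)) {
    stop("blocks must partition the joint's variables", call. = FALSE)
  }
  h <- function(p) entropy_categorical(as.numeric(p) / sum(p))
  h(marginalize_joint(joint, i1)) + h(marginalize_joint(joint, i2)) -
    h(joint$pmf)
}

#' Conditional mutual information on a discrete joint
#'
#' Computes \eqn{I(B_1; B_2 \mid C)} exactly by conditioning on each state of
#' the conditioning block and averaging the conditional MI with the marginal
#' conditioning probabilities.
#'
#' @param joint A [discrete_joint()].
#' @param block1,block2,cond Variable names or axis indices; together with
#'   `cond` the three blocks must partition all variables.
#' @return Conditional MI in nats.
#' @export
cond_mi_discrete <- function(joint, block1, block2, cond) {
  stopifnot(inherits(joint, "discrete_joint"))
  i1 <- resolve_axes(joint, block1)
  i2 <- resolve_axes(joint, block2)
  ic <- resolve_axes(joint, cond)
  all_idx <- sort(c(i1, i2, ic))
  if (length(all_idx) != length(joint$vars) || anyDuplicated(c(i1, i2, ic))) {
    stop("blocks must partition the joint's variables", call. = FALSE)
  }
  pc <- marginalize_joint(joint, ic)
  # enumerate states of the conditioning block
  cond_states <- expand.grid(lapply(dim(joint$pmf)[ic], seq_len))
  total <- 0
  for (s in seq_len(nrow(cond_states))) {
    idx_list <- rep(list(quote(expr = )), length(dim(joint$pmf)))
    for (k in seq_along(ic)) idx_list[[ic[k]]] <- cond_states[s, k]
    slice <- do.call(`[`, c(list(joint$pmf), idx_list, list(drop = FALSE)))
    w <- sum(slice)
    if (w <= .mmib_zero_tol) next
    sub <- array(slice / w, dim = dim(joint$pmf)[-ic])
    dimnames(sub) <- dimnames(joint$pmf)[-ic]
    sub_joint <- discrete_joint(sub)
    remap <- function(i) match(joint$vars[i], sub_joint$vars)
    total <- total + w * plugin_mi_discrete(sub_joint, remap(i1), remap(i2))
  }
  total
}

#' Expected calibration error
#'
#' Standard ECE with equal-width confidence bins on `[0, 1]`: the confidence of
#' a prediction is its top-1 probability, predictions are grouped into
#' `n_bins` bins by confidence, and the ECE is the sample-weighted mean of
#' `|bin accuracy - bin mean confidence|`.
#'
#' @param pred_probs Matrix of predicted class probabilities
#'   (samples x classes); each row must be a valid probability vector.
#' @param labels Integer class indices in `1..ncol(pred_probs)`, or a factor.
#' @param n_bins Number of equal-width bins (default 10).
#' @return ECE in `[0, 1]`.
#' @export
expected_calibration_error <- function(pred_probs, labels, n_bins = 10L) {
  pred_probs <- as.matrix(pred_probs)
  if (nrow(pred_probs) == 0L) stop("empty input", call. = FALSE)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  if (is.factor(labels)) labels <- as.integer(labels)
  if (any(labels < 1L | labels > ncol(pred_probs))) {
    stop("labels out of range", call. = FALSE)
  }
  apply(pred_probs, 1L, validate_prob_vector, tol = 1e-6)
  conf <- apply(pred_probs, 1L, max)
  pred <- max.col(pred_probs, ties.method = "first")
  correct <- as.numeric(pred == labels)
  # bin i covers ((i-1)/B, i/B]; confidence 0 falls in bin 1
  bin <- pmax(1L, ceiling(conf * n_bins - 1e-12))
  bin <- pmin(bin, n_bins)
  n <- length(conf)
  ece <- 0
  for (b in unique(bin)) {
    sel <- bin == b
    ece <- ece + sum(sel) / n * abs(mean(correct[sel]) - mean(conf[sel]))
  }
  ece
}

#' Per-sample predictive entropy
#'
#' Row-wise Shannon entropy (nats) of a matrix of predicted class
#' probabilities; the basis for selective prediction and OOD detection.
#'
#' @param pred_probs Matrix samples x classes of probabilities.
#' @return Numeric vector of entropies, one per row.
#' @export
predictive_entropy <- function(pred_probs) {
  pred_probs <- as.matrix(pred_probs)
  apply(pred_probs, 1L, function(p) {
    p <- p[p > .mmib_zero_tol]
    -sum(p * log(p))
  })
}
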