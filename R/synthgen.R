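#' Two-modality interaction generator (synergy testbed)
#'
#' Draws two independent standard-normal 1-D modalities and a binary target
#' from the logistic-interaction model
#' \deqn{Y \mid X^{(1)}, X^{(2)} \sim
#'   Bernoulli(\sigma(\beta_1 X^{(1)} + \beta_2 X^{(2)} +
#'   \alpha X^{(1)} X^{(2)})).}
#' With `alpha = 0` the modalities contribute additively and the synergy proxy
#' is near zero; `alpha > 0` creates predictive information accessible only
#' through joint observation, so the synergy proxy grows with `alpha`. The
#' true conditional `P(Y = 1 | x)` is stored in `meta$true_prob`.
#'
#' @param n Number of samples (default 5000).
#' @param beta1,beta2 Additive coefficients (default 0.5 each).
#' @param alpha Interaction strength `>= 0` (default 0).
#' @param train_frac Fraction assigned to the train split (default 0.7).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A [multimodal_dataset()] with modalities `x1`, `x2` and binary
#'   labels `0`/`1`.
#' @export
gen_interaction <- function(n = 5000L, beta1 = 0.5, beta2 = 0.5, alpha = 0,
                            train_frac = 0.7, seed = 1L) {
  stopifnot(n >= 1L, alpha >= 0)
  set.seed(seed)
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  p <- stats::plogis(beta1 * x1 + beta2 * x2 + alpha * x1 * x2)
  y <- stats::rbinom(n, 1L, p)
  split <- ifelse(seq_len(n) <= round(train_frac * n), "train", "test")
  multimodal_dataset(list(x1 = matrix(x1, ncol = 1L),
                          x2 = matrix(x2, ncol = 1L)),
                     labels = factor(y, levels = c(0L, 1L)),
                     split = split,
                     meta = list(generator = "interaction", n = n,
                                 beta1 = beta1, beta2 = beta2, alpha = alpha,
                                 seed = seed,
                                 true_prob = cbind(`0` = 1 - p, `1` = p)))
}

#' Analytic label frequency of the interaction generator
#'
#' `E[sigma(beta1 X1 + beta2 X2 + alpha X1 X2)]` for independent standard
#' normal inputs, by 2-D Gauss-Hermite-style quadrature on a dense grid; the
#' independent oracle for the sampled label frequency.
#'
#' @inheritParams gen_interaction
#' @param grid_n Quadrature grid points per axis (default 400).
#' @return Expected `P(Y = 1)`.
#' @export
interaction_label_rate <- function(beta1 = 0.5, beta2 = 0.5, alpha = 0,
                                   grid_n = 400L) {
  x <- seq(-8, 8, length.out = grid_n)
  w <- stats::dnorm(x)
  w <- w / sum(w)
  P <- outer(x, x, function(a, b) stats::plogis(beta1 * a + beta2 * b +
                                                  alpha * a * b))
  as.numeric(t(w) %*% P %*% w)
}

#' Latent-class multimodal generator
#'
#' Emulates the shape of a multi-omics subtype dataset: samples belong to one
#' of `n_classes` (imbalanced prior), each class has a centroid in a latent
#' space, and every modality is a noisy linear readout of designated latent
#' coordinates. Per-modality signal-to-noise ratios and shared latent
#' coordinates give a known dominance ordering and known redundancy structure
#' (modalities reading the same coordinates are redundant). `snr = 0` yields a
#' pure-noise modality.
#'
#' @param n Number of samples (default 900).
#' @param n_classes Number of classes (default 5).
#' @param modalities Named list; each element is
#'   `list(d = total dims, informative = informative dims, snr = signal scale,
#'   latent_idx = latent coordinates read)`. Defaults to three modalities of
#'   decreasing informativeness reading the same latent coordinates
#'   (redundancy-dominated, one dominant modality).
#' @param class_prior Class prior (default imbalanced, 5 classes).
#' @param latent_dim Latent dimensionality (default 3).
#' @param centroid_scale Separation of class centroids (default 2).
#' @param latent_noise Within-class latent noise sd (default 1).
#' @param train_frac Train fraction (default 0.7).
#' @param seed Integer seed.
#' @return A [multimodal_dataset()]; `meta$dominance` records the designed
#'   informativeness ordering (most informative first).
#' @export
gen_latent_class <- function(n = 900L, n_classes = 5L,
                             modalities = list(
                               m1 = list(d = 20L, informative = 8L, snr = 2.0,
                                         latent_idx = 1:3),
                               m2 = list(d = 15L, informative = 6L, snr = 0.7,
                                         latent_idx = 1:3),
                               m3 = list(d = 10L, informative = 4L, snr = 0.35,
                                         latent_idx = 1:3)),
                             class_prior = NULL, latent_dim = 3L,
                             centroid_scale = 2, latent_noise = 1,
                             train_frac = 0.7, seed = 1L) {
  if (is.null(class_prior)) {
    class_prior <- c(0.35, 0.25, 0.18, 0.12, 0.10)[seq_len(n_classes)]
    class_prior <- class_prior / sum(class_prior)
  }
  stopifnot(length(class_prior) == n_classes, all(class_prior > 0))
  for (sp in modalities) {
    if (sp$informative > sp$d) stop("informative dims exceed total dims",
                                    call. = FALSE)
    if (sp$snr < 0) stop("snr must be >= 0", call. = FALSE)
    if (any(sp$latent_idx > latent_dim)) {
      stop("redundancy map references latent coordinate beyond latent_dim",
           call. = FALSE)
    }
  }
  set.seed(seed)
  centroids <- matrix(stats::rnorm(n_classes * latent_dim), n_classes) *
    centroid_scale
  cls <- sample.int(n_classes, n, replace = TRUE, prob = class_prior)
  L <- centroids[cls, , drop = FALSE] +
    matrix(stats::rnorm(n * latent_dim), n) * latent_noise
  mats <- lapply(modalities, function(sp) {
    X <- matrix(stats::rnorm(n * sp$d), n)
    if (sp$informative > 0L && sp$snr > 0) {
      q <- length(sp$latent_idx)
      A <- matrix(stats::rnorm(q * sp$informative), q) / sqrt(q)
      X[, seq_len(sp$informative)] <- X[, seq_len(sp$informative)] +
        sp$snr * (L[, sp$latent_idx, drop = FALSE] %*% A)
    }
    X
  })
  split <- ifelse(seq_len(n) <= round(train_frac * n), "train", "test")
  snrs <- vapply(modalities, `[[`, numeric(1), "snr")
  multimodal_dataset(mats, labels = factor(cls, levels = seq_len(n_classes)),
                     split = split,
                     meta = list(generator = "latent_class", n = n,
                                 n_classes = n_classes, seed = seed,
                                 modality_spec = modalities,
                                 class_prior = class_prior,
                                 dominance = names(sort(snrs,
                                                        decreasing = TRUE))))
}

#' Coupled autoregressive longitudinal generator
#'
#' Emulates a longitudinal disease cohort with analytically known transfer
#' entropy. A latent severity follows the coupled recursion
#' `s_t = a s_{t-1} + b x_{t-1} + e_y` driven by a source process
#' `x_t = rho x_{t-1} + e_x`. The recorded target is the severity; the disease
#' stage is the severity thresholded into three levels (thresholds expressed
#' in stationary-sd units). Recorded modalities: `src` (the coupled source),
#' `noise` (white noise, zero TE), and two stage markers `marker_s0`,
#' `marker_s1` equal to the severity plus noise whose sd depends on the
#' current stage (each marker is designed to be most informative at its
#' stage). The analytic lag-1 transfer entropy of `src` is attached as
#' `meta$te_analytic`.
#'
#' @param n_subjects Number of subjects (default 150).
#' @param n_visits Visits per subject (default 4, `>= 2`).
#' @param a Severity persistence, `|a| < 1` (default 0.7).
#' @param b Source-to-severity coupling (default 0.5).
#' @param rho Source persistence, `|rho| < 1` (default 0.5).
#' @param sigma_x,sigma_y Innovation sds (default 1).
#' @param stage_thresholds Two thresholds in stationary-sd units (default
#'   `c(0.3, 1.0)`) defining stages 0/1/2.
#' @param marker_sd Matrix (2 markers x 3 stages) of marker noise sds; default
#'   makes `marker_s0` sharp at stage 0 and `marker_s1` sharp at stage 1.
#' @param seed Integer seed.
#' @return A [longitudinal_dataset()] with target `severity` and stage column
#'   `stage`.
#' @export
gen_coupled_ar <- function(n_subjects = 150L, n_visits = 4L, a = 0.7, b = 0.5,
                           rho = 0.5, sigma_x = 1, sigma_y = 1,
                           stage_thresholds = c(0.3, 1.0),
                           marker_sd = rbind(marker_s0 = c(0.4, 1.5, 1.5),
                                             marker_s1 = c(1.5, 0.4, 1.5)),
                           seed = 1L) {
  if (abs(a) >= 1 || abs(rho) >= 1) stop("non-stationary parameters",
                                         call. = FALSE)
  stopifnot(n_visits >= 2L, sigma_x > 0, sigma_y > 0)
  set.seed(seed)
  burn <- 50L
  Tn <- n_visits + burn
  x <- matrix(0, n_subjects, Tn)
  s <- matrix(0, n_subjects, Tn)
  x[, 1L] <- stats::rnorm(n_subjects, 0, sigma_x / sqrt(1 - rho^2))
  s[, 1L] <- stats::rnorm(n_subjects, 0, sigma_y)
  for (t in 2:Tn) {
    s[, t] <- a * s[, t - 1L] + b * x[, t - 1L] +
      stats::rnorm(n_subjects, 0, sigma_y)
    x[, t] <- rho * x[, t - 1L] + stats::rnorm(n_subjects, 0, sigma_x)
  }
  x <- x[, (burn + 1L):Tn, drop = FALSE]
  s <- s[, (burn + 1L):Tn, drop = FALSE]
  # stationary sd of the severity, for the stage thresholds
  q <- sigma_x^2 / (1 - rho^2)
  cxy <- rho * b * q / (1 - a * rho)
  vy <- (b^2 * q + 2 * a * b * cxy + sigma_y^2) / (1 - a^2)
  thr <- stage_thresholds * sqrt(vy)
  stage <- matrix(findInterval(s, thr), n_subjects, n_visits)
  mk <- function(row) {
    sdv <- matrix(marker_sd[row, stage + 1L], n_subjects, n_visits)
    s + matrix(stats::rnorm(length(s)), n_subjects) * sdv
  }
  rec <- data.frame(
    subject = rep(seq_len(n_subjects), each = n_visits),
    visit = rep(seq_len(n_visits), times = n_subjects),
    src = as.vector(t(x)),
    noise = stats::rnorm(n_subjects * n_visits),
    marker_s0 = as.vector(t(mk(1L))),
    marker_s1 = as.vector(t(mk(2L))),
    severity = as.vector(t(s)),
    stage = as.vector(t(stage)))
  longitudinal_dataset(rec,
                       modality_cols = c("src", "noise", "marker_s0",
                                         "marker_s1"),
                       target_col = "severity", stage_col = "stage",
                       meta = list(generator = "coupled_ar",
                                   n_subjects = n_subjects,
                                   n_visits = n_visits, a = a, b = b,
                                   rho = rho, sigma_x = sigma_x,
                                   sigma_y = sigma_y, seed = seed,
                                   te_analytic = gaussian_ar_te_closed_form(
                                     a, b, sigma_x, sigma_y, rho),
                                   autocorr_lag1 = (a * vy + b * cxy) / vy))
}

#' Exact discrete joint fixtures with sampled datasets
#'
#' Builds small discrete joints with known information structure, returning
#' both the exact pmf (the plug-in oracle) and an i.i.d. sample from it as a
#' [multimodal_dataset()], so estimators can be compared to exact truth.
#'
#' Kinds: `"xor"` (fair independent bits, `y = x1 XOR x2`: each input alone
#' carries zero information, jointly `log 2` — pure synergy); `"bsc"` (binary
#' symmetric channel with flip probability `params$flip`); `"copy"`
#' (`y = x1`, `x2` an independent noise bit); `"independent"` (three
#' independent fair bits).
#'
#' @param kind One of `"xor"`, `"bsc"`, `"copy"`, `"independent"`.
#' @param params List of parameters (`flip` for `"bsc"`).
#' @param n Samples to draw (0 = pmf only).
#' @param train_frac Train fraction of the sampled dataset.
#' @param seed Integer seed.
#' @return List with `joint` (a [discrete_joint()]) and `data` (a
#'   [multimodal_dataset()] or `NULL`).
#' @export
gen_discrete_joint <- function(kind = c("xor", "bsc", "copy", "independent"),
                               params = list(), n = 0L, train_frac = 0.7,
                               seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "xor") {
    pmf <- array(0, c(2, 2, 2),
                 dimnames = list(x1 = 0:1, x2 = 0:1, y = 0:1))
    for (i in 0:1) for (j in 0:1) pmf[i + 1, j + 1, bitwXor(i, j) + 1] <- 0.25
  } else if (kind == "bsc") {
    flip <- params$flip
    if (is.null(flip) || flip < 0 || flip > 1) {
      stop("bsc requires params$flip in [0, 1]", call. = FALSE)
    }
    pmf <- array(0, c(2, 2), dimnames = list(x1 = 0:1, y = 0:1))
    pmf[1, ] <- 0.5 * c(1 - flip, flip)
    pmf[2, ] <- 0.5 * c(flip, 1 - flip)
  } else if (kind == "copy") {
    pmf <- array(0, c(2, 2, 2),
                 dimnames = list(x1 = 0:1, x2 = 0:1, y = 0:1))
    for (i in 0:1) for (j in 0:1) pmf[i + 1, j + 1, i + 1] <- 0.25
  } else {
    pmf <- array(1 / 8, c(2, 2, 2),
                 dimnames = list(x1 = 0:1, x2 = 0:1, y = 0:1))
  }
  joint <- discrete_joint(pmf)
  data <- NULL
  if (n > 0L) {
    set.seed(seed)
    states <- expand.grid(lapply(dim(joint$pmf), function(k) 0:(k - 1)))
    cells <- sample.int(nrow(states), n, replace = TRUE,
                        prob = as.numeric(joint$pmf))
    draw <- states[cells, , drop = FALSE]
    vars <- joint$vars
    xs <- setdiff(vars, "y")
    mods <- lapply(xs, function(v) {
      matrix(as.numeric(draw[[which(vars == v)]]), ncol = 1L)
    })
    names(mods) <- xs
    split <- ifelse(seq_len(n) <= round(train_frac * n), "train", "test")
    data <- multimodal_dataset(mods,
                               labels = factor(draw[[which(vars == "y")]],
                                               levels = 0:1),
                               split = split,
                               meta = list(generator = "discrete_joint",
                                           kind = kind, params = params,
                                           seed = seed))
  }
  list(joint = joint, data = data)
}
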