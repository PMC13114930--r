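#' Configuration for the variational multimodal information bottleneck
#'
#' The VMIB model maps each modality through its own MLP encoder
#' (batch-normalized, dropout-regularized), fuses the encoder outputs by
#' concatenation, produces a diagonal-Gaussian posterior over a latent
#' bottleneck, and predicts the class from a single reparameterized latent
#' sample. The training objective is
#' \deqn{L = E[-\log q_\theta(y|z)] + \lambda\, E[KL(q_\phi(z|x) \| N(0, I))],}
#' where `lambda` trades prediction against compression.
#'
#' @param latent_dim Latent bottleneck dimension (default 32).
#' @param hidden Hidden units per encoder layer (default 256).
#' @param encoder_depth Number of hidden layers per encoder (default 2).
#' @param dropout_rate Dropout rate inside encoders (default 0.3).
#' @param lambda Compression weight `lambda >= 0` (default 0.01).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs Training epochs (default 100).
#' @param batch_size Minibatch size (default 128).
#' @param predictor_hidden Hidden units of the two-layer predictor (default 64).
#' @param schedule Learning-rate schedule, `"cosine"` (default) or
#'   `"constant"`.
#' @param grad_clip Global gradient-norm ceiling per step (default 5);
#'   stabilizes the KL-driven objectives (notably the consistency penalty,
#'   whose inverse-variance terms can spike early in training).
#' @param seed Integer seed; training is bit-reproducible given
#'   `(data, config, seed)`.
#' @return A list of class `vmib_config`.
#' @export
vmib_config <- function(latent_dim = 32L, hidden = 256L, encoder_depth = 2L,
                        dropout_rate = 0.3, lambda = 0.01, lr = 1e-3,
                        epochs = 100L, batch_size = 128L,
                        predictor_hidden = 64L,
                        schedule = c("cosine", "constant"), grad_clip = 5,
                        seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(latent_dim >= 1L, lambda >= 0, epochs >= 1L, grad_clip > 0)
  structure(list(latent_dim = as.integer(latent_dim), hidden = as.integer(hidden),
                 encoder_depth = as.integer(encoder_depth),
                 dropout_rate = dropout_rate, lambda = lambda, lr = lr,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 predictor_hidden = as.integer(predictor_hidden),
                 schedule = schedule, grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "vmib_config")
}

grad_sq_norm <- function(g) {
  if (is.null(g)) return(0)
  if (is.list(g)) return(sum(vapply(g, grad_sq_norm, numeric(1))))
  sum(g^2)
}

scale_grads <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, scale_grads, s = s))
  g * s
}

vmib_init_nets <- function(dims, K, config) {
  enc <- function(d) {
    layers <- list()
    d_in <- d
    for (i in seq_len(config$encoder_depth)) {
      layers <- c(layers, list(nn_linear(d_in, config$hidden),
                               nn_bn(config$hidden), nn_relu(),
                               nn_dropout(config$dropout_rate)))
      d_in <- config$hidden
    }
    layers
  }
  nets <- lapply(dims, enc)
  names(nets) <- paste0("enc:", names(dims))
  nets$post <- list(nn_linear(config$hidden * length(dims),
                              2L * config$latent_dim))
  nets$pred <- list(nn_linear(config$latent_dim, config$predictor_hidden),
                    nn_relu(),
                    nn_linear(config$predictor_hidden, K))
  nets
}

# encode a batch (list of standardized per-modality matrices) to the Gaussian
# posterior. Returns mu, logvar (clamped to [-10, 10]), caches for backprop,
# and batch-norm-updated nets when training.
vmib_encode_pass <- function(nets, mod_names, Xb, latent_dim,
                             training = FALSE, update_nets = TRUE,
                             frozen = character(0), mask_source = NULL) {
  enc_out <- vector("list", length(mod_names))
  enc_caches <- vector("list", length(mod_names))
  for (i in seq_along(mod_names)) {
    key <- paste0("enc:", mod_names[i])
    tr_i <- training && !(key %in% frozen)
    fixed <- if (!is.null(mask_source)) {
      lapply(mask_source$enc_caches[[i]], function(cc) cc$mask)
    }
    fw <- net_forward(nets[[key]], Xb[[i]], training = tr_i,
                      fixed_masks = fixed)
    if (tr_i && update_nets) nets[[key]] <- fw$layers
    enc_out[[i]] <- fw$out
    enc_caches[[i]] <- fw$caches
  }
  H <- do.call(cbind, enc_out)
  fw_post <- net_forward(nets$post, H,
                         training = training && !("post" %in% frozen))
  raw <- fw_post$out
  mu <- raw[, seq_len(latent_dim), drop = FALSE]
  lv_raw <- raw[, latent_dim + seq_len(latent_dim), drop = FALSE]
  lv <- pmin(pmax(lv_raw, -10), 10)
  list(mu = mu, logvar = lv, clamp_mask = (lv_raw > -10 & lv_raw < 10),
       enc_caches = enc_caches, post_caches = fw_post$caches,
       enc_width = vapply(enc_out, ncol, integer(1)), nets = nets)
}

# backprop d(mu, logvar) through posterior head and encoders; returns grads
# keyed like nets
vmib_encode_backward <- function(nets, mod_names, pass, dmu, dlv) {
  dlv <- dlv * pass$clamp_mask
  bw_post <- net_backward(nets$post, pass$post_caches, cbind(dmu, dlv))
  grads <- list(post = bw_post$grads)
  offs <- c(0L, cumsum(pass$enc_width))
  for (i in seq_along(mod_names)) {
    dH <- bw_post$dX[, (offs[i] + 1L):offs[i + 1L], drop = FALSE]
    key <- paste0("enc:", mod_names[i])
    grads[[key]] <- net_backward(nets[[key]], pass$enc_caches[[i]], dH)$grads
  }
  grads
}

add_grad_lists <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (!is.list(b)) return(a + b)
  keys <- if (is.null(names(b))) seq_along(b) else names(b)
  for (k in keys) {
    if (is.null(b[[k]])) next # assigning NULL would drop the slot
    if (is.null(a[[k]])) {
      a[[k]] <- b[[k]]
    } else {
      a[[k]] <- add_grad_lists(a[[k]], b[[k]])
    }
  }
  a
}

# gaussian KL to the standard-normal prior, per sample (sum over latent dims)
kl_to_prior <- function(mu, logvar) {
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

# core training loop shared by train_vmib, train_robust_vmib and the
# adaptation strategies
vmib_train_core <- function(Xs, y, K, config, nets = NULL,
                            trainable = NULL, dropout_p = 0,
                            consistency = NULL, seed = config$seed) {
  mod_names <- names(Xs)
  n <- nrow(Xs[[1]])
  set.seed(seed)
  if (is.null(nets)) {
    dims <- vapply(Xs, ncol, integer(1))
    nets <- vmib_init_nets(dims, K, config)
  }
  if (is.null(trainable)) {
    trainable <- lapply(nets, function(l) rep(TRUE, length(l)))
  }
  frozen_net <- vapply(trainable, function(tr) !any(tr), logical(1))
  frozen_keys <- names(frozen_net)[frozen_net]
  state <- lapply(nets, adam_init)
  history <- data.frame(epoch = integer(0), nll = numeric(0), kl = numeric(0),
                        consistency = numeric(0), lr = numeric(0))
  t_step <- 0L
  L <- config$latent_dim
  lambda <- config$lambda
  for (ep in seq_len(config$epochs)) {
    lr_ep <- if (config$schedule == "cosine") {
      cosine_lr(config$lr, ep, config$epochs)
    } else config$lr
    gamma_t <- if (!is.null(consistency)) {
      consistency$gamma * min(1, (ep - 1) / max(consistency$warmup_epochs, 1L))
    } else 0
    ord <- sample.int(n)
    ep_nll <- ep_kl <- ep_cons <- 0
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      m <- length(idx)
      Xb <- lapply(Xs, function(x) x[idx, , drop = FALSE])
      if (dropout_p > 0) Xb <- apply_modality_dropout(Xb, dropout_p)
      pass <- vmib_encode_pass(nets, mod_names, Xb, L,
                               training = TRUE, update_nets = TRUE,
                               frozen = frozen_keys)
      nets_bn <- pass$nets # batch-norm running stats updated by the full pass
      sd_z <- exp(pass$logvar / 2)
      eps <- matrix(stats::rnorm(m * L), m, L)
      z <- pass$mu + sd_z * eps
      fw_pred <- net_forward(nets$pred, z,
                             training = !("pred" %in% frozen_keys))
      probs <- softmax_rows(fw_pred$out)
      nll <- mean_nll(probs, y[idx])
      klv <- kl_to_prior(pass$mu, pass$logvar)
      if (!is.finite(nll) || !all(is.finite(klv))) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; last good epoch: ", ep - 1L, call. = FALSE)
      }
      dlogits <- (probs - one_hot(y[idx], K)) / m
      bw_pred <- net_backward(nets$pred, fw_pred$caches, dlogits)
      dz <- bw_pred$dX
      dmu <- dz + (lambda / m) * pass$mu
      dlv <- dz * eps * sd_z * 0.5 + (lambda / m) * 0.5 * (exp(pass$logvar) - 1)
      cons_val <- 0
      grads_extra <- NULL
      if (!is.null(consistency) && gamma_t > 0) {
        # the penalty sums over the configured subsets
        scale <- gamma_t / m
        v1 <- exp(pass$logvar)
        for (S in consistency$subsets) {
          Xm <- Xb
          for (j in seq_along(mod_names)) {
            if (!(mod_names[j] %in% S)) Xm[[j]] <- Xm[[j]] * 0
          }
          # reuse the full pass's dropout masks so the penalty isolates the
          # effect of the missing blocks, not the dropout noise
          pp <- vmib_encode_pass(nets, mod_names, Xm, L,
                                 training = TRUE, update_nets = FALSE,
                                 frozen = frozen_keys, mask_source = pass)
          v2 <- exp(pp$logvar)
          dmean <- pp$mu - pass$mu
          klc <- 0.5 * rowSums(v1 / v2 + dmean^2 / v2 - 1 +
                                 pp$logvar - pass$logvar)
          cons_val <- cons_val + mean(klc)
          # forward KL(full || partial): gradients into both posteriors
          dmu <- dmu - scale * (dmean / v2)
          dlv <- dlv + scale * 0.5 * (v1 / v2 - 1)
          dmu2 <- scale * (dmean / v2)
          dlv2 <- scale * 0.5 * (1 - v1 / v2 - dmean^2 / v2)
          grads_extra <- add_grad_lists(
            grads_extra,
            vmib_encode_backward(nets, mod_names, pp, dmu2, dlv2))
        }
      }
      grads <- vmib_encode_backward(nets, mod_names, pass, dmu, dlv)
      grads$pred <- bw_pred$grads
      grads <- add_grad_lists(grads, grads_extra)
      gnorm <- sqrt(grad_sq_norm(grads))
      if (is.finite(gnorm) && gnorm > config$grad_clip) {
        grads <- scale_grads(grads, config$grad_clip / gnorm)
      }
      nets <- nets_bn
      t_step <- t_step + 1L
      for (key in names(nets)) {
        if (frozen_net[[key]] || is.null(grads[[key]])) next
        upd <- adam_step(nets[[key]], grads[[key]], state[[key]], lr_ep, t_step,
                         trainable = trainable[[key]])
        nets[[key]] <- upd$layers
        state[[key]] <- upd$state
      }
      ep_nll <- ep_nll + nll
      ep_kl <- ep_kl + mean(klv)
      ep_cons <- ep_cons + cons_val
      nb <- nb + 1L
    }
    history <- rbind(history, data.frame(epoch = ep, nll = ep_nll / nb,
                                         kl = ep_kl / nb,
                                         consistency = ep_cons / nb,
                                         lr = lr_ep))
  }
  list(nets = nets, history = history)
}

#' Train a variational multimodal information bottleneck model
#'
#' Fits the VMIB to the training split of `data` (all samples when no split is
#' present): per-modality encoders, concatenation fusion, diagonal-Gaussian
#' bottleneck with standard-normal prior, and a softmax predictor trained on
#' one reparameterized latent sample per example. Features are standardized
#' with training-split statistics (stored in the model); prediction uses the
#' posterior mean and batch-norm running statistics.
#'
#' @param data A [multimodal_dataset()].
#' @param config A [vmib_config()].
#' @return An object of class `vmib` with the trained networks, the
#'   standardization statistics, and the per-epoch training history
#'   (`nll`, `kl`, `consistency` loss components).
#' @export
train_vmib <- function(data, config = vmib_config()) {
  train_vmib_impl(data, config, strategy = "standard")
}

train_vmib_impl <- function(data, config, strategy = "standard",
                            dropout_p = 0, consistency = NULL,
                            nets = NULL, trainable = NULL, std = NULL,
                            seed = config$seed) {
  stopifnot(inherits(data, "multimodal_dataset"))
  tr <- split_indices(data, "train")
  if (length(tr) == 0L) stop("training split is empty", call. = FALSE)
  labels <- droplevels(data$labels[tr])
  if (nlevels(labels) < 2L) stop("need at least 2 classes in the training split",
                                 call. = FALSE)
  lvl <- levels(data$labels)
  y <- as.integer(data$labels[tr])
  if (is.null(std)) {
    std <- lapply(data$modalities, function(mmat) {
      standardize_fit(mmat[tr, , drop = FALSE])
    })
  }
  Xs <- mapply(function(mmat, st) standardize_apply(mmat[tr, , drop = FALSE], st),
               data$modalities, std, SIMPLIFY = FALSE)
  out <- vmib_train_core(Xs, y, length(lvl), config, nets = nets,
                         trainable = trainable, dropout_p = dropout_p,
                         consistency = consistency, seed = seed)
  structure(list(nets = out$nets, std = std, config = config,
                 label_levels = lvl,
                 modality_names = names(data$modalities),
                 modality_dims = vapply(data$modalities, ncol, integer(1)),
                 history = out$history, strategy = strategy),
            class = "vmib")
}

#' @export
print.vmib <- function(x, ...) {
  cat("<vmib>", length(x$modality_names), "modalities (",
      paste(x$modality_names, collapse = ", "), ") ->",
      x$config$latent_dim, "latent dims ->", length(x$label_levels),
      "classes\n")
  cat("  lambda =", x$config$lambda, "| strategy =", x$strategy,
      "| epochs =", nrow(x$history), "\n")
  cat(sprintf("  final nll = %.4f, kl = %.4f nats\n",
              utils::tail(x$history$nll, 1), utils::tail(x$history$kl, 1)))
  invisible(x)
}

# standardize + optional zero-masking of unobserved modalities
vmib_prepare_inputs <- function(model, data, idx, observed = NULL) {
  mapply(function(nm, st) {
    X <- standardize_apply(data$modalities[[nm]][idx, , drop = FALSE], st)
    if (!is.null(observed) && !(nm %in% observed)) X <- X * 0
    X
  }, model$modality_names, model$std[model$modality_names], SIMPLIFY = FALSE)
}

#' Predict from a trained VMIB model
#'
#' @param object A trained [train_vmib()] model.
#' @param data A [multimodal_dataset()] with the same modalities.
#' @param type `"prob"` for class probabilities (at the posterior mean),
#'   `"latent"` for the posterior parameters (`mu`, `logvar`), `"class"` for
#'   hard labels.
#' @param split Optional `"train"`/`"test"` restriction; default all samples.
#' @param observed Optional character vector of observed modalities; the
#'   remaining blocks are zero-imputed post-standardization (the same encoding
#'   used by modality-dropout training).
#' @param ... Unused.
#' @return Matrix of probabilities, list of latent parameters, or factor.
#' @export
predict.vmib <- function(object, data, type = c("prob", "latent", "class"),
                         split = NULL, observed = NULL, ...) {
  type <- match.arg(type)
  idx <- if (is.null(split)) seq_along(data$labels) else split_indices(data, split)
  Xs <- vmib_prepare_inputs(object, data, idx, observed = observed)
  pass <- vmib_encode_pass(object$nets, object$modality_names, Xs,
                           object$config$latent_dim, training = FALSE)
  if (type == "latent") {
    return(list(mu = pass$mu, logvar = pass$logvar,
                kl = kl_to_prior(pass$mu, pass$logvar)))
  }
  probs <- softmax_rows(net_forward(object$nets$pred, pass$mu,
                                    training = FALSE)$out)
  colnames(probs) <- object$label_levels
  if (type == "class") {
    return(factor(object$label_levels[max.col(probs, ties.method = "first")],
                  levels = object$label_levels))
  }
  probs
}

#' VMIB loss components from closed forms
#'
#' Pure arithmetic form of the VMIB objective for given per-sample true-class
#' probabilities and posterior parameters:
#' `loss = mean(-log p_true) + lambda * mean(KL(posterior || N(0, I)))`.
#'
#' @param p_true Vector of predicted probabilities of the true class.
#' @param mu,logvar Posterior mean and log-variance matrices
#'   (samples x latent).
#' @param lambda Compression weight.
#' @return List with `loss`, `nll`, `kl` (all scalars, nats).
#' @examples
#' vmib_loss_components(0.8, matrix(1), matrix(0), 0.1)$loss # 0.2731
#' @export
vmib_loss_components <- function(p_true, mu, logvar, lambda) {
  stopifnot(lambda >= 0, length(p_true) >= 1L)
  mu <- as.matrix(mu)
  logvar <- as.matrix(logvar)
  nll <- mean(-log(pmax(p_true, 1e-12)))
  kl <- mean(kl_to_prior(mu, logvar))
  list(loss = nll + lambda * kl, nll = nll, kl = kl)
}

#' Evaluate the VMIB objective on a dataset
#'
#' Computes the predictive negative log-likelihood and the mean posterior-to-
#' prior KL on a data split, either at the posterior mean (default,
#' evaluation behaviour) or with one reparameterized sample.
#'
#' @param model A trained `vmib` model.
#' @param data A [multimodal_dataset()].
#' @param lambda Compression weight; defaults to the model's configured value.
#' @param split Optional split restriction.
#' @param sample If `TRUE`, draw one latent sample (seeded) instead of using
#'   the posterior mean.
#' @param seed Seed for the latent sample.
#' @return List with `loss`, `nll`, `kl`.
#' @export
vmib_loss <- function(model, data, lambda = NULL, split = NULL,
                      sample = FALSE, seed = 1L) {
  if (is.null(lambda)) lambda <- model$config$lambda
  idx <- if (is.null(split)) seq_along(data$labels) else split_indices(data, split)
  if (length(idx) == 0L) stop("empty batch", call. = FALSE)
  Xs <- vmib_prepare_inputs(model, data, idx)
  pass <- vmib_encode_pass(model$nets, model$modality_names, Xs,
                           model$config$latent_dim, training = FALSE)
  z <- pass$mu
  if (sample) {
    set.seed(seed)
    z <- pass$mu + exp(pass$logvar / 2) *
      matrix(stats::rnorm(length(pass$mu)), nrow(pass$mu), ncol(pass$mu))
  }
  probs <- softmax_rows(net_forward(model$nets$pred, z, training = FALSE)$out)
  y <- as.integer(data$labels[idx])
  vmib_loss_components(probs[cbind(seq_along(y), y)], pass$mu, pass$logvar,
                       lambda)
}

#' Information-plane summary of a trained model
#'
#' `compression_bound` is the mean posterior-to-prior KL (an upper bound on
#' `I(Z;X)`); `prediction_bound` is `H(Y) - CE(Y|Z)` on the test split (a
#' lower bound on `I(Z;Y)`), with the training-split version also reported.
#'
#' @param model A trained `vmib` model.
#' @param data A [multimodal_dataset()] with a train/test split.
#' @return One-row data frame with `lambda`, `compression_bound`,
#'   `prediction_bound`, `prediction_bound_train`, `accuracy`, `auc`.
#' @export
info_plane_point <- function(model, data) {
  te <- split_indices(data, "test")
  tr <- split_indices(data, "train")
  hy <- entropy_categorical(as.numeric(table(data$labels)) / length(data$labels))
  lat <- predict(model, data, type = "latent", split = "test")
  probs_te <- predict(model, data, type = "prob", split = "test")
  probs_tr <- predict(model, data, type = "prob", split = "train")
  y_te <- as.integer(data$labels[te])
  y_tr <- as.integer(data$labels[tr])
  data.frame(lambda = model$config$lambda,
             compression_bound = mean(lat$kl),
             prediction_bound = hy - mean_nll(probs_te, y_te),
             prediction_bound_train = hy - mean_nll(probs_tr, y_tr),
             accuracy = accuracy_score(probs_te, data$labels[te]),
             auc = macro_auc(probs_te, data$labels[te]),
             seed = model$config$seed)
}

#' Sweep the compression parameter across the information plane
#'
#' Trains one VMIB per value of `lambda` (fresh, seed-derived initialization
#' per point; seeds recorded in the result) and summarizes each with
#' [info_plane_point()]. Points are returned sorted by `lambda`.
#'
#' @param data A [multimodal_dataset()] with a train/test split.
#' @param base_config A [vmib_config()]; everything except `lambda` and `seed`
#'   is shared across points.
#' @param lambda_grid Non-empty numeric vector of `lambda >= 0` values.
#' @return Data frame of class `info_plane_sweep`, one row per `lambda`.
#' @export
information_plane_sweep <- function(data, base_config = vmib_config(),
                                    lambda_grid = c(1e-4, 1e-3, 1e-2, 1e-1, 1)) {
  if (length(lambda_grid) == 0L || any(lambda_grid < 0)) {
    stop("lambda_grid must be non-empty with values >= 0", call. = FALSE)
  }
  lambda_grid <- sort(lambda_grid)
  rows <- lapply(seq_along(lambda_grid), function(i) {
    cfg <- base_config
    cfg$lambda <- lambda_grid[i]
    cfg$seed <- derive_seed(base_config$seed, i)
    model <- tryCatch(train_vmib(data, cfg), error = function(e) {
      stop("training failed at lambda = ", lambda_grid[i], ": ",
           conditionMessage(e), call. = FALSE)
    })
    info_plane_point(model, data)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("info_plane_sweep", class(out))
  out
}

#' Linear-probe retention of a modality in the latent space
#'
#' Fits an ordinary-least-squares probe from the latent posterior means
#' (training split) to the features of one modality and reports the held-out
#' coefficient of determination averaged over features, clamped to `[-1, 1]`.
#' Constant features are excluded (recorded in the `"excluded"` attribute).
#'
#' @param model A trained `vmib` model.
#' @param data A [multimodal_dataset()] with a train/test split.
#' @param modality_name Name of the modality to probe.
#' @return Mean held-out R-squared, with attribute `per_feature`.
#' @export
probe_retention <- function(model, data, modality_name) {
  if (!modality_name %in% model$modality_names) {
    stop("unknown modality: ", modality_name, call. = FALSE)
  }
  tr <- split_indices(data, "train")
  te <- split_indices(data, "test")
  Ztr <- predict(model, data, type = "latent", split = "train")$mu
  Zte <- predict(model, data, type = "latent", split = "test")$mu
  Ytr <- data$modalities[[modality_name]][tr, , drop = FALSE]
  Yte <- data$modalities[[modality_name]][te, , drop = FALSE]
  keep <- apply(Ytr, 2L, stats::sd) > 1e-12
  if (!any(keep)) stop("all features of '", modality_name, "' are constant",
                       call. = FALSE)
  Ytr <- Ytr[, keep, drop = FALSE]
  Yte <- Yte[, keep, drop = FALSE]
  qx <- qr(cbind(1, Ztr))
  beta <- qr.coef(qx, Ytr)
  beta[is.na(beta)] <- 0
  pred <- cbind(1, Zte) %*% beta
  ss_res <- colSums((Yte - pred)^2)
  ss_tot <- colSums(sweep(Yte, 2L, colMeans(Yte))^2)
  r2 <- ifelse(ss_tot > 1e-12, 1 - ss_res / ss_tot, NA_real_)
  r2 <- pmin(pmax(r2, -1), 1)
  structure(mean(r2, na.rm = TRUE), per_feature = r2,
            excluded = sum(!keep))
}

#' Gaussian-approximation entropy of a representation
#'
#' Differential entropy of the fitted Gaussian
#' \eqn{0.5 \log((2\pi e)^d \det \hat\Sigma)} in nats, with a ridge of `1e-6`
#' added to the covariance diagonal. This is an upper bound on the true
#' differential entropy of the representation (the Gaussian maximizes entropy
#' for a given covariance).
#'
#' @param latents Numeric matrix (samples x dimensions); requires at least
#'   `d + 2` samples.
#' @param ridge Diagonal regularization (default 1e-6).
#' @return Entropy in nats.
#' @export
representation_entropy <- function(latents, ridge = 1e-6) {
  latents <- as.matrix(latents)
  d <- ncol(latents)
  if (nrow(latents) < d + 2L) {
    stop("need at least d + 2 samples to estimate the covariance; ",
         "reduce dimensionality or supply more samples", call. = FALSE)
  }
  sigma <- stats::cov(latents) + diag(ridge, d)
  ld <- 2 * sum(log(diag(chol(sigma))))
  0.5 * (d * log(2 * pi * exp(1)) + ld)
}
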