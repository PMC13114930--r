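# Minimal dense-network engine: linear / ReLU / batch-norm / dropout layers,
# softmax cross-entropy, Adam with cosine annealing. All randomness is drawn
# from R's global RNG so training is deterministic given set.seed().

nn_linear <- function(d_in, d_out) {
  list(type = "linear",
       W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = rep(0, d_out))
}
nn_relu <- function() list(type = "relu")
nn_bn <- function(d) {
  list(type = "bn", gamma = rep(1, d), beta = rep(0, d),
       rm = rep(0, d), rv = rep(1, d), mom = 0.9, eps = 1e-5)
}
nn_dropout <- function(p) list(type = "dropout", p = p)

# row-broadcast add of a vector
row_add <- function(M, v) M + rep(v, each = nrow(M))

# forward pass; returns output, per-layer caches, and (possibly updated) layers
# since batch-norm running statistics are refreshed in training mode
net_forward <- function(layers, X, training = FALSE, fixed_masks = NULL) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "linear") {
      caches[[i]] <- list(X = X)
      X <- row_add(X %*% l$W, l$b)
    } else if (l$type == "relu") {
      caches[[i]] <- list(X = X)
      X <- pmax(X, 0)
    } else if (l$type == "bn") {
      if (training && nrow(X) > 1L) {
        mu <- colMeans(X)
        v <- colMeans(X^2) - mu^2
        layers[[i]]$rm <- l$mom * l$rm + (1 - l$mom) * mu
        layers[[i]]$rv <- l$mom * l$rv + (1 - l$mom) * v
      } else {
        mu <- l$rm
        v <- l$rv
      }
      xc <- row_add(X, -mu)
      inv_sd <- 1 / sqrt(v + l$eps)
      xhat <- xc * rep(inv_sd, each = nrow(X))
      caches[[i]] <- list(xc = xc, xhat = xhat, inv_sd = inv_sd,
                          batch_stats = training && nrow(X) > 1L)
      X <- row_add(xhat * rep(l$gamma, each = nrow(X)), l$beta)
    } else if (l$type == "dropout") {
      if (training && l$p > 0) {
        mask <- if (!is.null(fixed_masks) && !is.null(fixed_masks[[i]])) {
          fixed_masks[[i]]
        } else {
          matrix(stats::runif(length(X)) >= l$p, nrow(X), ncol(X))
        }
        caches[[i]] <- list(mask = mask)
        X <- X * mask / (1 - l$p)
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    }
  }
  list(out = X, caches = caches, layers = layers)
}

# backward pass; returns per-layer parameter gradients and gradient wrt input
net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "linear") {
      grads[[i]] <- list(W = crossprod(cc$X, dout), b = colSums(dout))
      dout <- tcrossprod(dout, l$W)
    } else if (l$type == "relu") {
      dout <- dout * (cc$X > 0)
    } else if (l$type == "bn") {
      n <- nrow(dout)
      dgamma <- colSums(dout * cc$xhat)
      dbeta <- colSums(dout)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dxhat <- dout * rep(l$gamma, each = n)
      if (isTRUE(cc$batch_stats)) {
        # standard batch-norm backward through batch statistics
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * cc$xhat)
        dout <- (dxhat - row_add(cc$xhat * rep(s2 / n, each = n), s1 / n)) *
          rep(cc$inv_sd, each = n)
      } else {
        dout <- dxhat * rep(cc$inv_sd, each = n)
      }
    } else if (l$type == "dropout") {
      if (!is.null(cc$mask)) dout <- dout * cc$mask / (1 - l$p)
    }
  }
  list(grads = grads, dX = dout)
}

nn_param_names <- function(l) {
  switch(l$type, linear = c("W", "b"), bn = c("gamma", "beta"), character(0))
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    pn <- nn_param_names(l)
    if (length(pn) == 0L) return(NULL)
    st <- lapply(pn, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- pn
    st
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      trainable = NULL) {
  for (i in seq_along(layers)) {
    if (!is.null(trainable) && !trainable[i]) next
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

cosine_lr <- function(base_lr, epoch, total_epochs) {
  base_lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(total_epochs - 1, 1)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

one_hot <- function(y, K) {
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

mean_nll <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

# Two-layer (single hidden layer) softmax MLP with Adam, minibatches and
# early stopping on a stratified validation split. hidden = 0 gives softmax
# regression. Used as the probe classifier for MI lower bounds.
mlp_classifier_fit <- function(X, y, hidden = 256L, epochs = 80L,
                               batch_size = 256L, lr = 1e-3,
                               patience = 10L, val_frac = 0.2,
                               schedule = c("cosine", "constant"),
                               seed = 1L) {
  schedule <- match.arg(schedule)
  X <- as.matrix(X)
  y <- as.integer(y)
  K <- max(y)
  n <- nrow(X)
  set.seed(seed)
  # stratified validation split
  val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
    nv <- max(1L, round(length(ix) * val_frac))
    if (length(ix) <= 1L) return(integer(0))
    sample(ix, nv)
  }), use.names = FALSE)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(val_idx) == 0L) { tr_idx <- seq_len(n); val_idx <- seq_len(n) }
  Xtr <- X[tr_idx, , drop = FALSE]
  ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]
  yval <- y[val_idx]

  layers <- if (hidden > 0L) {
    list(nn_linear(ncol(X), hidden), nn_relu(), nn_linear(hidden, K))
  } else {
    list(nn_linear(ncol(X), K))
  }
  state <- adam_init(layers)
  best <- list(nll = Inf, layers = layers, epoch = 0L)
  t_step <- 0L
  ntr <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    lr_ep <- if (schedule == "cosine") cosine_lr(lr, ep, epochs) else lr
    ord <- sample.int(ntr)
    for (start in seq(1L, ntr, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, ntr)]
      fw <- net_forward(layers, Xtr[idx, , drop = FALSE], training = TRUE)
      layers <- fw$layers
      probs <- softmax_rows(fw$out)
      dlogits <- (probs - one_hot(ytr[idx], K)) / length(idx)
      bw <- net_backward(layers, fw$caches, dlogits)
      t_step <- t_step + 1L
      upd <- adam_step(layers, bw$grads, state, lr_ep, t_step)
      layers <- upd$layers
      state <- upd$state
    }
    vp <- softmax_rows(net_forward(layers, Xval, training = FALSE)$out)
    vnll <- mean_nll(vp, yval)
    if (!is.finite(vnll)) break
    if (vnll < best$nll - 1e-4) {
      best <- list(nll = vnll, layers = layers, epoch = ep)
    } else if (ep - best$epoch >= patience) {
      break
    }
  }
  structure(list(layers = best$layers, n_classes = K, val_nll = best$nll),
            class = "mmib_mlp")
}

#' @export
predict.mmib_mlp <- function(object, newdata, ...) {
  softmax_rows(net_forward(object$layers, as.matrix(newdata),
                           training = FALSE)$out)
}
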