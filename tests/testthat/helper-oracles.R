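# independent oracles used across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerical-integration oracle for KL between 1-D Gaussians
kl_gaussian_quadrature <- function(m1, v1, m2, v2) {
  integrand <- function(x) {
    q <- dnorm(x, m1, sqrt(v1))
    lr <- dnorm(x, m1, sqrt(v1), log = TRUE) - dnorm(x, m2, sqrt(v2), log = TRUE)
    q * lr
  }
  stats::integrate(integrand, m1 - 12 * sqrt(v1), m1 + 12 * sqrt(v1),
                   rel.tol = 1e-10)$value
}

# random discrete joint over (x1, x2, y) with given state counts
random_joint_3 <- function(k1 = 2L, k2 = 2L, ky = 2L) {
  p <- array(rexp(k1 * k2 * ky), c(k1, k2, ky),
             dimnames = list(x1 = seq_len(k1) - 1, x2 = seq_len(k2) - 1,
                             y = seq_len(ky) - 1))
  discrete_joint(p / sum(p))
}

# random Markov chain y -> x -> z via stochastic-matrix composition; returns
# the exact joints needed for the data-processing inequality
random_markov_chain <- function(ky = 3L, kx = 3L, kz = 3L) {
  py <- rexp(ky); py <- py / sum(py)
  Txy <- matrix(rexp(ky * kx), ky); Txy <- Txy / rowSums(Txy)
  Txz <- matrix(rexp(kx * kz), kx); Txz <- Txz / rowSums(Txz)
  pyx <- py * Txy                      # ky x kx joint of (y, x)
  pyz <- (py * Txy) %*% Txz            # ky x kz joint of (y, z)
  list(
    yx = discrete_joint(array(pyx, dim(pyx), list(y = 1:ky, x = 1:kx))),
    yz = discrete_joint(array(pyz, dim(pyz), list(y = 1:ky, z = 1:kz))))
}

# brute-force ECE by direct enumeration over bins
ece_enumerate <- function(probs, labels, n_bins = 10L) {
  conf <- apply(probs, 1, max)
  hit <- as.numeric(max.col(probs, ties.method = "first") == labels)
  bin <- pmin(pmax(1L, ceiling(conf * n_bins - 1e-12)), n_bins)
  tot <- 0
  for (b in unique(bin)) {
    s <- bin == b
    tot <- tot + mean(s) * abs(mean(hit[s]) - mean(conf[s]))
  }
  tot
}

# stationary covariance of the coupled AR pair solved by fixed-point
# iteration (independent check on the closed-form TE)
ar_te_by_covariance_iteration <- function(a, b, sigma_x, sigma_y, rho) {
  # state (x_t, y_t); iterate V = A V A' + Q to convergence
  A <- rbind(c(rho, 0), c(b, a))
  Q <- diag(c(sigma_x^2, sigma_y^2))
  V <- diag(2)
  for (i in 1:10000) {
    Vn <- A %*% V %*% t(A) + Q
    if (max(abs(Vn - V)) < 1e-14) { V <- Vn; break }
    V <- Vn
  }
  # cov of (y_t, y_{t-1}, x_{t-1}) from V and the recursion
  vy <- V[2, 2]
  cxy <- V[1, 2]
  cov_y_ylag <- a * vy + b * cxy
  var_cond_y <- vy - cov_y_ylag^2 / vy
  0.5 * log(var_cond_y / sigma_y^2)
}

# fast config for VMIB tests (small nets keep the suite quick; the defaults
# are exercised in the acceptance tests)
test_vmib_config <- function(...) {
  args <- utils::modifyList(list(hidden = 32L, latent_dim = 8L,
                                 predictor_hidden = 16L, epochs = 40L),
                            list(...))
  do.call(vmib_config, args)
}

test_protocol <- function(...) {
  args <- utils::modifyList(list(hidden = 32L, epochs = 60L, patience = 8L),
                            list(...))
  do.call(mi_protocol, args)
}
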