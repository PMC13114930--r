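test_that("VMIB loss components follow the closed-form objective", {
  # lambda = 0: loss equals the predictive NLL exactly
  lc <- vmib_loss_components(c(0.5, 0.25), matrix(rnorm(4), 2), matrix(0, 2, 2),
                             lambda = 0)
  expect_equal(lc$loss, lc$nll)
  expect_equal(lc$nll, mean(-log(c(0.5, 0.25))))
  # posterior equal to the prior: zero KL component
  lc0 <- vmib_loss_components(0.9, matrix(0, 1, 3), matrix(0, 1, 3), lambda = 5)
  expect_equal(lc0$kl, 0)
  # single sample, p_true = 0.8, posterior N(1, 1), lambda = 0.1
  lc1 <- vmib_loss_components(0.8, matrix(1), matrix(0), lambda = 0.1)
  expect_equal(lc1$loss, -log(0.8) + 0.1 * 0.5)
})

test_that("training is deterministic given (data, config, seed)", {
  d <- gen_latent_class(n = 150, n_classes = 2, class_prior = c(0.5, 0.5),
                        seed = 3,
                        modalities = list(
                          a = list(d = 4, informative = 2, snr = 1.5,
                                   latent_idx = 1),
                          b = list(d = 3, informative = 1, snr = 0.5,
                                   latent_idx = 2)),
                        latent_dim = 2)
  cfg <- test_vmib_config(epochs = 6L, seed = 42L)
  m1 <- train_vmib(d, cfg)
  m2 <- train_vmib(d, cfg)
  expect_identical(m1$nets, m2$nets)
  expect_identical(m1$history, m2$history)
})

test_that("an uncompressed model solves a separable two-class task", {
  d <- gen_latent_class(n = 500, n_classes = 2, class_prior = c(0.5, 0.5),
                        centroid_scale = 4, latent_dim = 2, latent_noise = 0.5,
                        seed = 8,
                        modalities = list(
                          a = list(d = 5, informative = 5, snr = 3,
                                   latent_idx = 1:2),
                          b = list(d = 4, informative = 2, snr = 1,
                                   latent_idx = 1:2)))
  m <- train_vmib(d, test_vmib_config(lambda = 0, epochs = 80L, seed = 5L))
  te <- which(d$split == "test")
  probs <- predict(m, d, split = "test")
  expect_gte(mean(max.col(probs) == as.integer(d$labels[te])), 0.95)
  # objective contracts: compression bound >= 0, prediction bound <= H(Y)
  pt <- info_plane_point(m, d)
  expect_gte(pt$compression_bound, 0)
  hy <- entropy_categorical(as.numeric(table(d$labels)) / length(d$labels))
  expect_lte(pt$prediction_bound, hy + 1e-9)
})

test_that("near-deterministic posteriors make sampling match the mean pass", {
  d <- gen_latent_class(n = 150, n_classes = 2, class_prior = c(0.5, 0.5),
                        seed = 3, latent_dim = 2,
                        modalities = list(
                          a = list(d = 4, informative = 2, snr = 1.5,
                                   latent_idx = 1),
                          b = list(d = 3, informative = 1, snr = 0.5,
                                   latent_idx = 2)))
  m <- train_vmib(d, test_vmib_config(epochs = 5L, seed = 2L))
  # force the posterior variance to its floor
  L <- m$config$latent_dim
  post <- m$nets$post[[1]]
  post$W[, L + seq_len(L)] <- 0
  post$b[L + seq_len(L)] <- -40 # clamped to logvar = -10
  m$nets$post[[1]] <- post
  det_loss <- vmib_loss(m, d, sample = FALSE)
  sto_loss <- vmib_loss(m, d, sample = TRUE, seed = 4)
  expect_equal(sto_loss$nll, det_loss$nll, tolerance = 1e-2)
})

test_that("degenerate training inputs are rejected", {
  d <- gen_latent_class(n = 60, n_classes = 2, class_prior = c(0.5, 0.5),
                        seed = 3, latent_dim = 1,
                        modalities = list(a = list(d = 2, informative = 1,
                                                   snr = 1, latent_idx = 1)))
  d1 <- d
  d1$labels <- factor(rep("x", 60))
  expect_error(train_vmib(d1, test_vmib_config()), "2 classes")
  d2 <- d
  d2$split <- rep("test", 60)
  expect_error(train_vmib(d2, test_vmib_config()), "empty")
})

test_that("representation entropy matches Gaussian closed forms", {
  set.seed(10)
  z <- matrix(rnorm(20000), ncol = 1)
  expect_equal(representation_entropy(z), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.01)
  # transformation law: scaling by c adds d * log(c)
  z2 <- matrix(rnorm(6000), ncol = 3)
  expect_equal(representation_entropy(3 * z2) - representation_entropy(z2),
               3 * log(3), tolerance = 1e-6)
  # correlated 2-D Gaussian with known covariance
  S <- rbind(c(2, 1.2), c(1.2, 1.5))
  A <- chol(S)
  z3 <- matrix(rnorm(40000), ncol = 2) %*% A
  expect_equal(representation_entropy(z3),
               0.5 * (2 * log(2 * pi * exp(1)) + log(det(S))),
               tolerance = 0.02)
  expect_error(representation_entropy(matrix(rnorm(12), 3, 4)), "samples")
})

test_that("linear probes retain informative modalities more than noise", {
  d <- gen_latent_class(n = 600, n_classes = 3,
                        class_prior = c(0.4, 0.3, 0.3), latent_dim = 2,
                        centroid_scale = 2.5, seed = 12,
                        modalities = list(
                          sig = list(d = 6, informative = 6, snr = 2,
                                     latent_idx = 1:2),
                          nz = list(d = 6, informative = 0, snr = 0,
                                    latent_idx = 1)))
  m <- train_vmib(d, test_vmib_config(lambda = 1e-3, epochs = 60L, seed = 3L))
  r_sig <- probe_retention(m, d, "sig")
  r_nz <- probe_retention(m, d, "nz")
  expect_gt(as.numeric(r_sig), as.numeric(r_nz))
  # under strong compression the nuisance modality is squeezed out of the
  # latent: its retention drops
  m_hi <- train_vmib(d, test_vmib_config(lambda = 1, epochs = 60L, seed = 3L))
  r_nz_hi <- probe_retention(m_hi, d, "nz")
  expect_lt(as.numeric(r_nz_hi), as.numeric(r_nz))
  # a latent that is exactly independent of a modality (encoder severed at the
  # first layer) cannot predict it
  m_cut <- m
  m_cut$nets$`enc:nz`[[1]]$W[] <- 0
  expect_lte(as.numeric(probe_retention(m_cut, d, "nz")), 0.05)
  expect_error(probe_retention(m, d, "missing"), "unknown")
})

test_that("the lambda sweep orders compression and logs per-point seeds", {
  d <- gen_latent_class(n = 300, n_classes = 2, class_prior = c(0.6, 0.4),
                        latent_dim = 2, seed = 21,
                        modalities = list(
                          a = list(d = 5, informative = 3, snr = 2,
                                   latent_idx = 1:2),
                          b = list(d = 4, informative = 2, snr = 0.8,
                                   latent_idx = 1:2)))
  sw <- information_plane_sweep(d, test_vmib_config(epochs = 30L, seed = 2L),
                                lambda_grid = c(0.5, 1e-3))
  expect_equal(sw$lambda, c(1e-3, 0.5)) # sorted
  expect_gt(sw$compression_bound[1], sw$compression_bound[2])
  expect_equal(length(unique(sw$seed)), 2L)
  expect_error(information_plane_sweep(d, lambda_grid = numeric(0)),
               "non-empty")
})
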