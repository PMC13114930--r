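test_that("modality dropout masks blocks with the keep-one guarantee", {
  batch <- list(a = matrix(1, 50, 2), b = matrix(1, 50, 3),
                c = matrix(1, 50, 1))
  set.seed(1)
  expect_identical(apply_modality_dropout(batch, 0), batch)
  # p = 1: exactly one retained modality per sample, never all-zero
  set.seed(2)
  out <- apply_modality_dropout(batch, 1)
  kept <- sapply(out, function(m) rowSums(m) > 0)
  expect_true(all(rowSums(kept) == 1))
  # p = 0.3: empirical pre-correction drop fraction near 0.3. With M = 3 the
  # keep-one rule restores one of the three blocks whenever all are dropped,
  # so the observed zero fraction is p - p^3 / 3.
  set.seed(3)
  n <- 1e5
  big <- list(a = matrix(1, n, 1), b = matrix(1, n, 1), c = matrix(1, n, 1))
  out <- apply_modality_dropout(big, 0.3)
  frac <- mean(sapply(out, function(m) mean(m == 0)))
  expect_equal(frac, 0.3 - 0.3^3 / 3, tolerance = 0.01)
})

test_that("consistency penalty is the forward KL with the full posterior first", {
  p <- diag_gaussian(0, 1)
  expect_equal(consistency_penalty(p, p), 0)
  expect_equal(consistency_penalty(diag_gaussian(0, 1), diag_gaussian(0, 4)),
               0.5 * (1 / 4 + log(4) - 1))
  # asymmetry of KL
  q <- diag_gaussian(0.5, 2)
  expect_false(isTRUE(all.equal(consistency_penalty(p, q),
                                consistency_penalty(q, p))))
})

test_that("zero-strength consistency training equals standard training", {
  d <- gen_latent_class(n = 150, n_classes = 2, class_prior = c(0.5, 0.5),
                        latent_dim = 2, seed = 3,
                        modalities = list(
                          a = list(d = 4, informative = 2, snr = 1.5,
                                   latent_idx = 1),
                          b = list(d = 3, informative = 1, snr = 0.5,
                                   latent_idx = 2)))
  cfg <- test_vmib_config(epochs = 6L, seed = 11L)
  m_std <- train_robust_vmib(d, cfg, robustness_config("standard"))
  m_c0 <- train_robust_vmib(d, cfg, robustness_config("consistency", gamma = 0))
  expect_identical(m_std$nets, m_c0$nets)
  expect_equal(m_std$history[c("nll", "kl")], m_c0$history[c("nll", "kl")])
})

test_that("consistency penalty vanishes when the masked input is the full input", {
  # a dataset whose second modality is identically zero: masking it changes
  # nothing, so the recorded consistency loss stays ~0 while gamma ramps
  set.seed(4)
  n <- 120
  x <- matrix(rnorm(n * 3), n)
  d <- multimodal_dataset(list(a = x, b = matrix(0 * rnorm(n), n, 1)),
                          labels = factor(rep(0:1, n / 2)),
                          split = rep(c("train", "test"), c(100, 20)))
  m <- train_robust_vmib(d, test_vmib_config(epochs = 8L, seed = 2L),
                         robustness_config("consistency", gamma = 0.5,
                                           warmup_epochs = 2L,
                                           subsets = list("a")))
  expect_lt(max(m$history$consistency), 1e-6)
})

test_that("the ablation grid reports Imiss = 0 and full AUC on the full subset", {
  d <- gen_latent_class(n = 500, seed = 7)
  cfg <- test_vmib_config(hidden = 64L, epochs = 60L, seed = 5L)
  m <- train_vmib(d, cfg)
  dec <- decompose_information(d, protocol = test_protocol(n_folds = 4L),
                               seed = 3, estimator = "masked")
  grid <- evaluate_ablation_grid(m, d, dec)
  full_row <- grid[grid$subset == "m1+m2+m3", ]
  expect_equal(full_row$imiss, 0)
  probs <- predict(m, d, split = "test")
  expect_equal(full_row$auc,
               macro_auc(probs, d$labels[d$split == "test"]))
  # dropping the dominant modality costs the most AUC
  aucs <- grid$auc[match(c("m2+m3", "m1+m3", "m1+m2"), grid$subset)]
  expect_equal(which.min(aucs), 1L)
  expect_error(evaluate_ablation_grid(m, d, dec, subsets = list(character(0))),
               "at least one")
})

test_that("nested observed subsets cannot lose less information (exact oracle)", {
  # exact plug-in version of Imiss monotonicity: S subset of S2 implies
  # Imiss(S) >= Imiss(S2)
  set.seed(9)
  for (i in 1:20) {
    j <- random_joint_3(2, 2, 3)
    i_full <- plugin_mi_discrete(j, c("x1", "x2"), "y")
    i_1 <- plugin_mi_discrete(discrete_joint(marginalize_joint(j, c("x1", "y"))),
                              1, 2)
    imiss_1 <- i_full - i_1       # observed {x1}
    imiss_full <- 0               # observed {x1, x2}
    expect_gte(imiss_1, imiss_full - 1e-12)
  }
})
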