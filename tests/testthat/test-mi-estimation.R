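test_that("classifier MI bound is near zero for uninformative features", {
  set.seed(1)
  X <- matrix(rnorm(2000 * 3), 2000)
  y <- factor(rep(0:1, 1000))
  est <- classifier_mi_bound(X, y, protocol = test_protocol(), seed = 2)
  expect_s3_class(est, "mi_estimate")
  expect_lt(abs(est$value), 0.05)
  expect_equal(est$n_folds, 5L)
  expect_gte(est$std, 0)
})

test_that("classifier MI bound recovers a deterministic binary channel", {
  d <- gen_discrete_joint("copy", n = 2000, seed = 4)$data
  est <- classifier_mi_bound(d$modalities$x1, d$labels,
                             protocol = test_protocol(epochs = 200L), seed = 3)
  expect_lt(abs(est$value - log(2)), 0.05)
  # duplicating feature columns leaves the estimate unchanged within fold noise
  est_dup <- classifier_mi_bound(cbind(d$modalities$x1, d$modalities$x1),
                                 d$labels,
                                 protocol = test_protocol(epochs = 200L),
                                 seed = 3)
  expect_lt(abs(est_dup$value - est$value), 0.05)
  expect_error(classifier_mi_bound(d$modalities$x1, factor(rep(1, 2000))),
               "2 classes")
})

test_that("classifier bound stays below plug-in truth and tightens with n", {
  truth <- plugin_mi_discrete(gen_discrete_joint("bsc", list(flip = 0.1))$joint,
                              "x1", "y")
  vals <- vapply(c(200, 1000, 5000), function(n) {
    d <- gen_discrete_joint("bsc", list(flip = 0.1), n = n, seed = 11)$data
    classifier_mi_bound(d$modalities$x1, d$labels,
                        protocol = test_protocol(n_folds = if (n == 200) 4 else 5),
                        seed = 7)$value
  }, numeric(1))
  expect_true(all(vals <= truth + 0.05))
  # monotone upward trend towards the plug-in value
  expect_true(vals[3] >= vals[1] - 0.02)
  expect_lt(abs(vals[3] - truth), 0.05)
})

test_that("MI bound estimates are bit-reproducible given (data, protocol, seed)", {
  d <- gen_discrete_joint("bsc", list(flip = 0.2), n = 600, seed = 5)$data
  e1 <- classifier_mi_bound(d$modalities$x1, d$labels,
                            protocol = test_protocol(), seed = 9)
  e2 <- classifier_mi_bound(d$modalities$x1, d$labels,
                            protocol = test_protocol(), seed = 9)
  expect_identical(e1$fold_values, e2$fold_values)
})

test_that("synergy and redundancy proxies are exact arithmetic", {
  expect_equal(synergy_proxy(0.861, 0.878, 0.655), -0.672)
  expect_equal(synergy_proxy(log(2), 0, 0), log(2))
  expect_equal(synergy_proxy(0.4, 0.4, 0), 0)
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(3)
    expect_equal(synergy_proxy(v[1], v[2], v[3]) +
                   redundancy_proxy(v[1], v[2], v[3]), 0)
  }
})

test_that("percentage of label entropy matches the reporting convention", {
  expect_equal(pct_of_entropy(0.878, 1.352), 64.9)
  expect_equal(pct_of_entropy(0, 1.2), 0)
  expect_equal(pct_of_entropy(1.2, 1.2), 100)
  expect_error(pct_of_entropy(0.5, 0), "label_entropy")
})

test_that("decomposition flags redundancy for a noisy-copy modality pair", {
  # both modalities read the same latent coordinate: redundancy-dominated
  d <- gen_latent_class(
    n = 900, n_classes = 2, class_prior = c(0.5, 0.5), latent_dim = 1,
    centroid_scale = 2,
    modalities = list(a = list(d = 1, informative = 1, snr = 2, latent_idx = 1),
                      b = list(d = 1, informative = 1, snr = 2, latent_idx = 1)),
    seed = 31)
  dec <- decompose_information(d, subsets = list("a", "b", c("a", "b")),
                               protocol = test_protocol(), seed = 5)
  expect_lt(dec$pairwise_synergy[["a,b"]], 0)
  expect_named(dec$subset_mi, c("a", "b", "a+b"))
  expect_error(decompose_information(d, subsets = list("zzz")), "unknown")
})

test_that("a pure-noise modality carries no estimated information", {
  d <- gen_latent_class(
    n = 1200, n_classes = 2, class_prior = c(0.5, 0.5), latent_dim = 1,
    modalities = list(sig = list(d = 2, informative = 2, snr = 2, latent_idx = 1),
                      nz = list(d = 2, informative = 0, snr = 0, latent_idx = 1)),
    seed = 13)
  est <- classifier_mi_bound(d$modalities$nz, d$labels,
                             protocol = test_protocol(), seed = 3)
  expect_lt(abs(est$value), 0.05)
})

test_that("masked single-model estimator shares one probe across subsets", {
  d <- gen_interaction(n = 1200, alpha = 2, seed = 17)
  dec <- decompose_information(d, subsets = list("x1", "x2", c("x1", "x2")),
                               protocol = test_protocol(), seed = 5,
                               estimator = "masked")
  expect_equal(dec$subset_mi[["x1"]]$estimator, "masked-single-model")
  # the joint subset sees strictly more than either marginal on synergy data
  expect_gt(dec$subset_mi[["x1+x2"]]$value,
            max(dec$subset_mi[["x1"]]$value, dec$subset_mi[["x2"]]$value))
})

test_that("information loss clamps at zero and recovers exact structure", {
  d <- gen_discrete_joint("copy", n = 2000, seed = 6)$data
  dec <- decompose_information(d, subsets = list("x1", "x2", c("x1", "x2")),
                               protocol = test_protocol(epochs = 200L),
                               seed = 8)
  # observed = full set
  expect_equal(as.numeric(info_loss_imiss(dec, c("x1", "x2"))), 0)
  # y = x1: observing x1 loses nothing; observing only the noise bit loses ln 2
  expect_lt(as.numeric(info_loss_imiss(dec, "x1")), 0.05)
  expect_lt(abs(as.numeric(info_loss_imiss(dec, "x2")) - log(2)), 0.12)
  expect_error(info_loss_imiss(dec, "nope"), "lacks")
})
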