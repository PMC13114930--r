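test_that("categorical entropy matches closed forms and rejects bad input", {
  expect_equal(entropy_categorical(rep(1 / 5, 5)), log(5))
  expect_equal(entropy_categorical(c(1, 0, 0)), 0)
  expect_equal(entropy_categorical(c(0.5, 0.5)), log(2))
  expect_error(entropy_categorical(c(0.5, 0.6)), "sum to 1")
  expect_error(entropy_categorical(c(-0.1, 1.1)), "non-negative")
})

test_that("categorical entropy is concave under mixing", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    p <- rexp(k); p <- p / sum(p)
    q <- rexp(k); q <- q / sum(q)
    w <- runif(1)
    expect_gte(entropy_categorical(w * p + (1 - w) * q) + 1e-12,
               w * entropy_categorical(p) + (1 - w) * entropy_categorical(q))
  }
})

test_that("diagonal-Gaussian KL matches closed forms and a quadrature oracle", {
  sn <- diag_gaussian(0, 1)
  expect_equal(kl_diag_gaussian(sn, sn), 0)
  expect_equal(kl_diag_gaussian(diag_gaussian(1, 1), sn), 0.5)
  expect_equal(kl_diag_gaussian(diag_gaussian(0, 4), sn),
               0.5 * (4 - log(4) - 1))
  set.seed(7)
  for (i in 1:100) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    v1 <- rexp(1) + 0.1; v2 <- rexp(1) + 0.1
    expect_equal(kl_diag_gaussian(diag_gaussian(m1, v1), diag_gaussian(m2, v2)),
                 kl_gaussian_quadrature(m1, v1, m2, v2), tolerance = 1e-6)
  }
  expect_error(kl_diag_gaussian(diag_gaussian(c(0, 0), c(1, 1)), sn),
               "dimension")
  expect_error(diag_gaussian(0, 0), "positive")
})

test_that("plug-in MI reproduces XOR, BSC and independence closed forms", {
  jx <- gen_discrete_joint("xor")$joint
  expect_equal(plugin_mi_discrete(jx, c("x1", "x2"), "y"), log(2),
               tolerance = 1e-12)
  m <- discrete_joint(marginalize_joint(jx, c("x1", "y")))
  expect_equal(plugin_mi_discrete(m, 1, 2), 0, tolerance = 1e-12)
  jb <- gen_discrete_joint("bsc", list(flip = 0.1))$joint
  hb <- -(0.1 * log(0.1) + 0.9 * log(0.9))
  expect_equal(plugin_mi_discrete(jb, "x1", "y"), log(2) - hb,
               tolerance = 1e-12)
  ji <- gen_discrete_joint("independent")$joint
  expect_equal(plugin_mi_discrete(ji, c("x1", "x2"), "y"), 0, tolerance = 1e-12)
  expect_error(plugin_mi_discrete(jx, "x1", "y"), "partition")
})

test_that("plug-in MI is symmetric and satisfies the chain rule exactly", {
  set.seed(11)
  for (i in 1:30) {
    j <- random_joint_3(sample(2:3, 1), sample(2:3, 1), sample(2:4, 1))
    i_ab <- plugin_mi_discrete(j, c("x1", "x2"), "y")
    expect_equal(i_ab, plugin_mi_discrete(j, "y", c("x1", "x2")),
                 tolerance = 1e-12)
    # I((x1,x2); y) = I(x1; y) + I(x2; y | x1)
    j_x1y <- discrete_joint(marginalize_joint(j, c("x1", "y")))
    i_1 <- plugin_mi_discrete(j_x1y, 1, 2)
    i_2g1 <- cond_mi_discrete(j, "x2", "y", "x1")
    expect_equal(i_ab, i_1 + i_2g1, tolerance = 1e-12)
  }
})

test_that("data-processing inequality holds on random Markov chains", {
  set.seed(13)
  for (i in 1:100) {
    ch <- random_markov_chain(sample(2:4, 1), sample(2:4, 1), sample(2:4, 1))
    i_xy <- plugin_mi_discrete(ch$yx, 1, 2)
    i_zy <- plugin_mi_discrete(ch$yz, 1, 2)
    expect_lte(i_zy, i_xy + 1e-9)
  }
})

test_that("ECE matches direct enumeration and handles degenerate cases", {
  # all predictions confident and correct
  p <- cbind(rep(1, 20), rep(0, 20))
  expect_equal(expected_calibration_error(p, rep(1L, 20)), 0)
  # single bin: confidence 0.9, half correct
  p <- cbind(rep(0.9, 10), rep(0.1, 10))
  y <- rep(c(1L, 2L), 5)
  expect_equal(expected_calibration_error(p, y), abs(0.5 - 0.9))
  # two populated bins, hand-enumerated weighted average
  p <- rbind(matrix(rep(c(0.95, 0.05), 4), 4, byrow = TRUE),
             matrix(rep(c(0.65, 0.35), 6), 6, byrow = TRUE))
  y <- c(1L, 1L, 1L, 2L, 1L, 1L, 2L, 2L, 2L, 2L)
  expect_equal(expected_calibration_error(p, y), ece_enumerate(p, y))
  # random probability matrices agree with the enumeration oracle
  set.seed(3)
  for (i in 1:20) {
    z <- matrix(rexp(30 * 3), 30)
    pr <- z / rowSums(z)
    yy <- sample(1:3, 30, replace = TRUE)
    expect_equal(expected_calibration_error(pr, yy), ece_enumerate(pr, yy))
  }
  expect_error(expected_calibration_error(p, y, n_bins = 0), "n_bins")
  expect_error(expected_calibration_error(p[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("predictive entropy matches per-row categorical entropy", {
  set.seed(5)
  z <- matrix(rexp(12), 4)
  pr <- z / rowSums(z)
  expect_equal(predictive_entropy(pr),
               apply(pr, 1, entropy_categorical))
})
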