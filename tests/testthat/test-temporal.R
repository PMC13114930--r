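test_that("closed-form AR transfer entropy matches a covariance-iteration oracle", {
  expect_equal(gaussian_ar_te_closed_form(0.7, 0, 1, 1, 0.5), 0)
  # scale invariance: common rescaling of both noise sds leaves TE unchanged
  expect_equal(gaussian_ar_te_closed_form(0.6, 0.4, 1, 0.8, 0.5),
               gaussian_ar_te_closed_form(0.6, 0.4, 3, 2.4, 0.5),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, -0.8, 0.9)
    b <- runif(1, -1, 1)
    rho <- runif(1, -0.8, 0.9)
    sx <- rexp(1) + 0.2
    sy <- rexp(1) + 0.2
    expect_equal(gaussian_ar_te_closed_form(a, b, sx, sy, rho),
                 ar_te_by_covariance_iteration(a, b, sx, sy, rho),
                 tolerance = 1e-10)
  }
  expect_error(gaussian_ar_te_closed_form(1.1, 0.5), "stationarity")
})

test_that("gaussian TE estimator recovers coupled-AR truth; white noise gives ~0", {
  d <- gen_coupled_ar(n_subjects = 1000, n_visits = 6, seed = 14)
  est <- estimate_transfer_entropy(d, "src", seed = 2)
  expect_equal(est$estimator, "gaussian-regression")
  expect_lt(abs(est$value - d$meta$te_analytic), 0.05)
  est0 <- estimate_transfer_entropy(d, "noise", seed = 2)
  expect_lt(abs(est0$value), 0.02)
  # a duplicate of the target history adds no information
  d2 <- d
  d2$records$dup <- d2$records$severity
  d2$modality_cols <- c(d2$modality_cols, "dup")
  estd <- estimate_transfer_entropy(d2, "dup", seed = 2)
  expect_lt(abs(estd$value), 0.02)
  expect_error(estimate_transfer_entropy(d, "nothere"), "unknown source")
})

test_that("classifier TE backend recovers a deterministic lag-1 copy", {
  set.seed(8)
  ns <- 250L
  tv <- 9L
  x <- matrix(rbinom(ns * tv, 1, 0.5), ns, tv)
  y <- cbind(rbinom(ns, 1, 0.5), x[, 1:(tv - 1)]) # y_t = x_{t-1}
  rec <- data.frame(subject = rep(1:ns, each = tv),
                    visit = rep(1:tv, ns),
                    src = as.vector(t(x)),
                    target = as.vector(t(y)))
  ld <- longitudinal_dataset(rec, modality_cols = "src", target_col = "target")
  est <- estimate_transfer_entropy(ld, "src", estimator = "classifier",
                                   protocol = test_protocol(), seed = 3)
  expect_equal(est$value, log(2), tolerance = 0.1)
  expect_equal(est$estimator, "classifier-bound")
})

test_that("permutation null covers the uncoupled transfer entropy", {
  d <- gen_coupled_ar(n_subjects = 250, n_visits = 6, seed = 23)
  est0 <- abs(estimate_transfer_entropy(d, "noise", seed = 4)$value)
  null_dist <- te_permutation_null(d, "src", seed = 4, n_perm = 20)
  expect_lte(est0, quantile(abs(null_dist), 0.95) + 1e-9)
  # and the genuinely coupled source clears its own null
  est_src <- estimate_transfer_entropy(d, "src", seed = 4)$value
  expect_gt(est_src, quantile(null_dist, 0.95))
})

test_that("sequential ladder gains only from genuinely informative modalities", {
  d <- gen_coupled_ar(n_subjects = 400, n_visits = 8, seed = 6)
  lad <- sequential_ladder(d, modality_sets = list("noise", "src"), seed = 2)
  base <- lad$auc[lad$step == 0]
  expect_gt(base, 0.5)
  # pure-noise modality changes nothing beyond fold noise
  expect_equal(lad$auc[lad$modalities == "noise"], base, tolerance = 0.02)
  # the coupled source adds real signal
  expect_gt(lad$auc[lad$modalities == "src"], base)
})

test_that("perfect target persistence saturates the baseline", {
  ns <- 60L
  rec <- data.frame(subject = rep(1:ns, each = 4),
                    visit = rep(1:4, ns),
                    m = rnorm(ns * 4),
                    target = rep(rep(c(0, 1), ns / 2), each = 4))
  ld <- longitudinal_dataset(rec, modality_cols = "m", target_col = "target")
  lad <- suppressWarnings(sequential_ladder(ld, modality_sets = list("m"),
                                            seed = 1))
  expect_equal(lad$auc[lad$step == 0], 1.0)
  expect_equal(lad$auc[lad$step == 1], 1.0)
})

test_that("stage-conditioned discriminability finds the designed stage markers", {
  d <- gen_coupled_ar(n_subjects = 900, n_visits = 6, seed = 10)
  tab <- stage_discriminability(d)
  # each stage marker out-discriminates the other marker at its designed stage
  auc_of <- function(st, m) tab$auc[tab$stage == st & tab$modality == m]
  expect_gt(auc_of(0, "marker_s0"), auc_of(0, "marker_s1"))
  expect_gt(auc_of(1, "marker_s1"), auc_of(1, "marker_s0"))
  # constant modality scores exactly 0.5
  d$records$flat <- 1
  d$modality_cols <- c(d$modality_cols, "flat")
  tab2 <- stage_discriminability(d)
  expect_true(all(tab2$auc[tab2$modality == "flat"] == 0.5, na.rm = TRUE))
  # swapping modality columns swaps the table rows
  d3 <- gen_coupled_ar(n_subjects = 200, n_visits = 5, seed = 3)
  t1 <- stage_discriminability(d3)
  d3$records[c("marker_s0", "marker_s1")] <-
    d3$records[c("marker_s1", "marker_s0")]
  t2 <- stage_discriminability(d3)
  expect_equal(t1$auc[t1$modality == "marker_s0"],
               t2$auc[t2$modality == "marker_s1"])
})

test_that("longitudinal containers validate their invariants", {
  rec <- data.frame(subject = c(1, 1, 2), visit = c(1, 1, 1),
                    m = rnorm(3), target = rnorm(3))
  expect_error(longitudinal_dataset(rec, "m", "target"), "strictly increasing")
  rec2 <- data.frame(subject = rep(1:5, each = 2), visit = rep(1:2, 5),
                     m = rnorm(10), target = rnorm(10))
  ld <- longitudinal_dataset(rec2, "m", "target")
  expect_error(estimate_transfer_entropy(ld, "m"), "at least 30")
  pv <- pair_view(ld, 1)
  expect_equal(nrow(pv), 5L) # one pair per subject
  expect_true(all(pv$subject == 1:5))
})
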