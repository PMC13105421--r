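test_that("estimate_distribution is a proper, floored distribution", {
  edges <- make_bin_edges(c(0, 1), n_bins = 64)
  # point mass, no smoothing: all mass in one bin up to the floor
  d0 <- estimate_distribution(rep(0.5, 10), edges, bandwidth = 0)
  expect_equal(sum(d0$probabilities), 1, tolerance = 1e-9)
  expect_gt(max(d0$probabilities), 1 - 64 * 1e-9)
  expect_true(all(d0$probabilities >= 1e-9))
  # any input sums to 1
  set.seed(2)
  d1 <- estimate_distribution(runif(100), edges, bandwidth = 1.5)
  expect_equal(sum(d1$probabilities), 1, tolerance = 1e-9)
  # values evenly spread over the binned range give near-uniform
  # probabilities at any bandwidth (the reflecting smoother is doubly
  # stochastic, so uniformity is preserved)
  full <- seq(0, 1, length.out = 65)
  for (bw in c(0, 1, 2.5)) {
    d2 <- estimate_distribution(seq(0, 1, length.out = 1e4), full,
                                bandwidth = bw)
    expect_lte(max(d2$probabilities) / min(d2$probabilities), 1.01)
  }
})

test_that("out-of-range values are clipped into end bins with a warning", {
  edges <- make_bin_edges(c(0, 1), n_bins = 8)
  expect_warning(d <- estimate_distribution(c(0.5, 50), edges, 0),
                 "clipped")
  expect_gt(d$probabilities[8], 0.4)
  expect_error(estimate_distribution(numeric(0), edges), "no values")
})

test_that("bin edges share support across classes after training", {
  fm <- tiny_feature_matrix()
  ref <- train_reference(fm[fm$modality == "SEM", ])
  a <- ref$attributes[5]
  dn <- get_distribution(ref, "normal", a)
  dm <- get_distribution(ref, "malignant", a)
  expect_identical(dn$bin_edges, dm$bin_edges)
  expect_equal(sum(dn$probabilities), 1, tolerance = 1e-9)
  expect_true(all(dn$probabilities >= 1e-9))
  expect_true(all(ref$rates > 0))
})

test_that("the exponential MLE is the reciprocal mean", {
  expect_equal(fit_exponential(c(1, 2, 3)), 0.5)
  expect_equal(fit_exponential(1), 1)
  expect_error(fit_exponential(numeric(0)), "no values")
  expect_error(fit_exponential(c(0, 0)), "non-positive")
  set.seed(9)
  expect_equal(fit_exponential(rexp(2e4, rate = 3)), 3, tolerance = 0.05)
})

test_that("class_likelihood follows the exponential log-density sum", {
  rates <- matrix(1, 3, 1, dimnames = list(
    c("normal", "benign", "malignant"), "a"))
  pooled <- matrix(0.25, 4, 1, dimnames = list(NULL, "a"))
  ref <- toy_reference(dists = NULL, pooled = pooled, rates = rates)
  expect_equal(class_likelihood(c(a = 0), ref, "normal"), 0)  # log(1) - 0
  # two identical attributes double the log-likelihood
  rates2 <- matrix(2, 3, 2, dimnames = list(
    c("normal", "benign", "malignant"), c("a", "b")))
  pooled2 <- matrix(0.25, 4, 2, dimnames = list(NULL, c("a", "b")))
  ref2 <- toy_reference(dists = NULL, pooled = pooled2, rates = rates2)
  expect_equal(class_likelihood(c(a = 0.7, b = 0.7), ref2, "benign"),
               2 * (log(2) - 2 * 0.7))
  expect_error(class_likelihood(c(zz = 1), ref, "normal"), "attributes")
})

test_that("the most likely class matches a brute-force density product", {
  set.seed(14)
  fm <- tiny_feature_matrix(seed = 14, n_per_class = 6)
  sem <- fm[fm$modality == "SEM", ]
  ref <- train_reference(sem)
  x <- as.numeric(sem[1, ref$attributes])
  names(x) <- ref$attributes
  ll <- vapply(c("normal", "benign", "malignant"), function(cl)
    class_likelihood(x, ref, cl), numeric(1))
  brute <- vapply(c("normal", "benign", "malignant"), function(cl) {
    xp <- pmax(x - ref$shift_min, 0) + ref$shift_delta
    sum(log(stats::dexp(xp, rate = ref$rates[cl, ])))
  }, numeric(1))
  expect_equal(ll, brute, tolerance = 1e-12)
  expect_equal(which.max(ll), which.max(brute))
})

test_that("stage ranges reflect class value ranges", {
  fm <- tiny_feature_matrix(n_per_class = 5)
  fm_sem <- fm[fm$modality == "SEM", ]
  # plant a perfectly separated attribute
  fm_sem$energy_CA4 <- rep(c(1, 10, 100), each = 5) +
    runif(15, 0, 0.5)
  st <- compute_stage_ranges(fm_sem)
  s <- st[st$attribute == "energy_CA4", ]
  expect_lt(s$upper[s$class == "normal"], s$lower[s$class == "benign"])
  expect_lt(s$upper[s$class == "benign"], s$lower[s$class == "malignant"])
  expect_error(compute_stage_ranges(fm_sem[fm_sem$label != "benign", ]),
               "three classes")
})
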