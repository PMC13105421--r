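test_that("divergence identities and extremes hold", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(jsd(p, p), 0)
  expect_equal(hellinger(p, p), 0)
  expect_equal(triangle(p, p), 0)
  # disjoint support saturates every measure at 1
  a <- c(1, 0); b <- c(0, 1)
  expect_equal(jsd(a, b), 1)
  expect_equal(hellinger(a, b), 1)
  expect_equal(triangle(a, b), 1)
})

test_that("divergences match direct evaluations of their formulas", {
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  m <- (p + q) / 2
  jsd_direct <- 0.5 * sum(p * log2(p / m)) + 0.5 * sum(q * log2(q / m))
  expect_equal(jsd(p, q), jsd_direct, tolerance = 1e-15)
  expect_equal(hellinger(p, q), 0.5 * sum((sqrt(p) - sqrt(q))^2),
               tolerance = 1e-15)
  expect_equal(triangle(p, q), 0.5 * (0.4^2 / 1.4 + 0.4^2 / 0.6),
               tolerance = 1e-15)
})

test_that("divergences are symmetric, bounded and definite on random pairs", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(2:32, 1)
    p <- rprob(n); q <- rprob(n)
    for (f in list(jsd, hellinger, triangle)) {
      d <- f(p, q)
      expect_equal(d, f(q, p), tolerance = 1e-12)
      expect_gte(d, 0); expect_lte(d, 1)
      expect_equal(f(p, p), 0, tolerance = 1e-14)
      expect_gt(d, 0)   # distinct random vectors separate
    }
  }
})

test_that("divergences grow monotonically along mixture paths", {
  set.seed(19)
  p <- rprob(16); r <- rprob(16)
  lam <- seq(0, 1, by = 0.1)
  for (f in list(jsd, hellinger, triangle)) {
    d <- vapply(lam, function(l) f(p, (1 - l) * p + l * r), numeric(1))
    expect_true(all(diff(d) >= -1e-12))
  }
})

test_that("invalid probability inputs are rejected", {
  expect_error(jsd(c(0.5, 0.5), c(1, 0, 0)), "equal length")
  expect_error(hellinger(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")
  expect_error(triangle(c(-0.5, 1.5), c(0.5, 0.5)), "non-negative")
})

test_that("the binary JSD variant evaluates the per-bin Bernoulli sum", {
  p <- c(0.6, 0.4); q <- c(0.3, 0.7)
  direct <- sum(p * log2(p / q) + (1 - p) * log2((1 - p) / (1 - q)))
  expect_equal(jsd(p, q, variant = "binary"), direct, tolerance = 1e-12)
})

test_that("attribute weights match a hand evaluation on a toy reference", {
  mk <- function(...) {
    m <- cbind(...)
    colnames(m) <- c("a1", "a2", "a3")
    m
  }
  dn <- mk(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25),
           c(0.4, 0.3, 0.2, 0.1))
  db <- mk(c(0.1, 0.7, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25),
           c(0.1, 0.2, 0.3, 0.4))
  dm <- mk(c(0.1, 0.1, 0.7, 0.1), c(0.25, 0.25, 0.25, 0.25),
           c(0.25, 0.25, 0.25, 0.25))
  pooled <- (dn + db + dm) / 3
  ref <- toy_reference(dists = list(normal = dn, benign = db,
                                    malignant = dm),
                       pooled = pooled)
  for (kind in c("JSD", "HD", "TD")) {
    w <- compute_weights(ref, kind)
    f <- switch(kind, JSD = jsd, HD = hellinger, TD = triangle)
    raw <- numeric(3)
    for (i in 1:3) {
      w_av <- (f(dn[, i], db[, i]) + f(dn[, i], dm[, i]) +
               f(db[, i], dm[, i])) / 3
      H <- -sum(pooled[, i] * log2(pooled[, i]))
      raw[i] <- w_av / max(H, 0.1)
    }
    expect_equal(unname(w$weights), raw / sum(raw), tolerance = 1e-12)
    expect_equal(sum(w$weights), 1, tolerance = 1e-9)
    # a2 never separates the classes: zero weight
    expect_equal(unname(w$weights["a2"]), 0, tolerance = 1e-12)
  }
})

test_that("degenerate references fall back to uniform weights", {
  u <- matrix(0.25, 4, 3, dimnames = list(NULL, c("a1", "a2", "a3")))
  ref <- toy_reference(dists = list(normal = u, benign = u, malignant = u),
                       pooled = u)
  w <- compute_weights(ref, "TD")
  expect_equal(unname(w$weights), rep(1 / 3, 3))
})

test_that("a single separating attribute takes all the weight", {
  u <- c(0.25, 0.25, 0.25, 0.25)
  sep_n <- c(0.97, 0.01, 0.01, 0.01)
  sep_m <- c(0.01, 0.01, 0.01, 0.97)
  mk <- function(v) {
    m <- cbind(v, u, u)
    colnames(m) <- c("a1", "a2", "a3")
    m
  }
  dn <- mk(sep_n); db <- mk((sep_n + sep_m) / 2); dm <- mk(sep_m)
  pooled <- (dn + db + dm) / 3
  ref <- toy_reference(dists = list(normal = dn, benign = db,
                                    malignant = dm), pooled = pooled)
  w <- compute_weights(ref, "HD")
  expect_equal(unname(w$weights["a1"]), 1, tolerance = 1e-6)
})
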