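test_that("calibration anchors class medians at 0.2 / 0.5 / 0.8", {
  raw <- c(rnorm(20, 1, 0.05), rnorm(20, 3, 0.05), rnorm(20, 6, 0.05))
  labels <- rep(c("normal", "benign", "malignant"), each = 20)
  cal <- fit_calibration(raw, labels)
  med <- tapply(raw, labels, median)[c("normal", "benign", "malignant")]
  expect_equal(unname(apply_calibration(cal, med)), c(0.2, 0.5, 0.8),
               tolerance = 1e-6)
  # monotone, clipped to [0, 1]
  grid <- seq(min(raw) - 5, max(raw) + 5, length.out = 200)
  d <- apply_calibration(cal, grid)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 0 & d <= 1))
  # degenerate, non-separated classes must not error
  cal0 <- fit_calibration(rep(1, 30), labels[1:30 * 2])
  expect_true(all(is.finite(apply_calibration(cal0, c(0.5, 1, 2)))))
})

test_that("band assignment follows the half-open 0.4 / 0.6 bands", {
  expect_equal(classify_bands(0.22), "normal")
  expect_equal(classify_bands(0.53), "benign")
  expect_equal(classify_bands(0.90), "malignant")
  expect_equal(classify_bands(c(0.4, 0.6)), c("benign", "malignant"))
  expect_equal(classify_bands(c(0, 1)), c("normal", "malignant"))
  expect_error(classify_bands(1.2), "\\[0, 1\\]")
  expect_error(classify_bands(-0.1), "\\[0, 1\\]")
})

test_that("consensus takes the band of the median score", {
  expect_equal(consensus(c(JSD = 0.23, HD = 0.19, TD = 0.12)),
               list(d = 0.19, label = "normal"))
  expect_equal(consensus(c(JSD = 0.75, HD = 0.83, TD = 0.78)),
               list(d = 0.78, label = "malignant"))
  same <- consensus(c(JSD = 0.5, HD = 0.5, TD = 0.5))
  expect_equal(same$d, 0.5)
  per <- consensus(c(JSD = 0.3, HD = 0.45, TD = 0.7),
                   policy = "per_divergence")
  expect_equal(unname(per$label), c("normal", "benign", "malignant"))
  expect_error(consensus(c(0.1, 0.2, 0.3), policy = "vote"))
})

test_that("posteriors are a stable softmax of the class likelihoods", {
  # identical class models give uniform posteriors
  rates <- matrix(2, 3, 2, dimnames = list(
    c("normal", "benign", "malignant"), c("a", "b")))
  pooled <- matrix(0.25, 4, 2, dimnames = list(NULL, c("a", "b")))
  ref <- toy_reference(dists = NULL, pooled = pooled, rates = rates)
  p <- posteriors(c(a = 0.3, b = 0.9), ref)
  expect_equal(unname(p), rep(1 / 3, 3), tolerance = 1e-12)
  # hand-set rates: direct density-ratio arithmetic
  rates2 <- matrix(c(1, 2, 4, 1, 2, 4), 3, 2, dimnames = list(
    c("normal", "benign", "malignant"), c("a", "b")))
  ref2 <- toy_reference(dists = NULL, pooled = pooled, rates = rates2)
  x <- c(a = 0.5, b = 1.5)
  dens <- vapply(c(1, 2, 4), function(l) prod(stats::dexp(x, l)),
                 numeric(1))
  p2 <- posteriors(x, ref2)
  expect_equal(unname(p2), dens / sum(dens), tolerance = 1e-12)
  expect_equal(sum(p2), 1, tolerance = 1e-9)
})

test_that("held-out d scores order the classes for every divergence", {
  r <- small_pipeline()
  res <- r$results
  for (k in c("d_JSD", "d_HD", "d_TD")) {
    m <- tapply(res[[k]], res$label, mean)
    expect_lt(m["normal"], m["benign"])
    expect_lt(m["benign"], m["malignant"])
  }
})

test_that("d_test reproduces the classify_dataset scores for one patch", {
  r <- small_pipeline()
  res <- r$results
  mod <- res$modality[1]
  mm <- r$model$modalities[[mod]]
  # rebuild the feature vector of the first test patch
  synth <- synth_config(n_per_class_per_modality = 6, image_side = 128,
                        seed = 7)
  frames <- generate_dataset(synth)
  f1 <- Filter(function(f) f$source_id == res$source_id[1] &&
                 f$modality == mod, frames)[[1]]
  patch <- split_image(f1$pixels, 64, modality = mod, label = f1$label,
                       source_id = f1$source_id)[[res$patch_index[1] + 1]]
  feats <- extract_features(dwt_decompose(patch), patch)
  d <- d_test(feats, mm$reference, mm$weights, mm$calibration)
  expect_equal(unname(d["JSD"]), res$d_JSD[1], tolerance = 1e-12)
  expect_equal(unname(d["TD"]), res$d_TD[1], tolerance = 1e-12)
})

test_that("classification is deterministic at inference", {
  r <- small_pipeline()
  synth <- synth_config(n_per_class_per_modality = 6, image_side = 128,
                        seed = 7)
  again <- run_end_to_end(seed = 7, synth = synth)
  expect_identical(r$results, again$results)
  expect_identical(r$fused, again$fused)
})

test_that("modality fusion averages d and multiplies posteriors", {
  mk <- function(modality, d, post) structure(
    list(d = d, posteriors = post, modality = modality, source_id = "s1",
         patch_index = 0L), class = "d_test_result")
  post <- c(normal = 0.7, benign = 0.2, malignant = 0.1)
  sem <- mk("SEM", c(JSD = 0.3, HD = 0.3, TD = 0.3), post)
  afm <- mk("AFM", c(JSD = 0.5, HD = 0.5, TD = 0.5), post)
  fused <- fuse_modalities(sem, afm)
  expect_equal(unname(fused$d), rep(0.4, 3))
  expect_equal(fused$assigned, "benign")
  expect_equal(sum(fused$posteriors), 1, tolerance = 1e-9)
  # identical inputs: d is unchanged and the posterior argmax is preserved
  # (the renormalized product sharpens equal vectors but cannot reorder)
  id <- fuse_modalities(sem, mk("AFM", sem$d, post))
  expect_equal(id$d, sem$d)
  expect_equal(which.max(id$posteriors), which.max(post))
  expect_equal(id$assigned, "normal")
  expect_error(fuse_modalities(sem, mk("SEM", afm$d, post)), "two SEM")
})

test_that("fuse_results pairs modalities on source and patch", {
  r <- small_pipeline()
  fused <- r$fused
  expect_true(all(fused$modality == "fused"))
  expect_equal(nrow(fused), nrow(r$results) / 2)
  expect_equal(sort(unique(paste(fused$source_id, fused$patch_index))),
               sort(unique(paste(r$results$source_id,
                                 r$results$patch_index))))
  sums <- unname(rowSums(as.matrix(fused[, c("P_Cn", "P_Cb", "P_Cm")])))
  expect_equal(sums, rep(1, nrow(fused)), tolerance = 1e-9)
})
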