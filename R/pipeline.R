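# Pipeline configuration, model training/serialization, train/test
# splitting and the seeded end-to-end run on synthetic data.

#' Pipeline configuration
#'
#' Houses every tunable of the pipeline with its default: db4 wavelet, 4
#' decomposition levels, 64 histogram bins (features and distributions),
#' smoothing bandwidth 1 bin, standard (base-2) JSD, median consensus,
#' decision bands at 0.4/0.6 and calibration anchors 0.2/0.5/0.8 on the d
#' scale, 10000 bootstrap resamples.
#'
#' @param wavelet_name,levels,entropy_bins,n_bins,bandwidth,jsd_variant
#'   See the corresponding stage functions.
#' @param consensus_policy `"median"` or `"per_divergence"`.
#' @param band_edges,calibration_anchors Strictly increasing within (0, 1).
#' @param bootstrap_n Bootstrap resamples for evaluation.
#' @param h_floor Entropy floor (bits) in the attribute weighting.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(wavelet_name = "db4", levels = 4,
                            entropy_bins = 64, n_bins = 64, bandwidth = 1.0,
                            jsd_variant = c("standard", "binary"),
                            consensus_policy = c("median", "per_divergence"),
                            band_edges = c(0.4, 0.6),
                            calibration_anchors = c(0.2, 0.5, 0.8),
                            bootstrap_n = 10000, h_floor = 0.1) {
  stopifnot(all(diff(band_edges) > 0), all(band_edges > 0 & band_edges < 1),
            all(diff(calibration_anchors) > 0),
            all(calibration_anchors > 0 & calibration_anchors < 1))
  structure(list(
    wavelet_name = wavelet_name, levels = levels,
    entropy_bins = entropy_bins, n_bins = n_bins, bandwidth = bandwidth,
    jsd_variant = match.arg(jsd_variant),
    consensus_policy = match.arg(consensus_policy),
    band_edges = band_edges, calibration_anchors = calibration_anchors,
    bootstrap_n = bootstrap_n, h_floor = h_floor),
    class = "pipeline_config")
}

#' Train the full model from a labeled feature matrix
#'
#' Shared per-attribute bin edges are computed on the pooled training values
#' (both modalities, all classes); per modality a `class_reference` is
#' trained, attribute weights are computed for each divergence kind, and the
#' d-score calibration is anchored at the class medians of the raw training
#' scores. Training is deterministic: identical data and config give an
#' identical model.
#'
#' @param fm Labeled feature matrix ([extract_feature_matrix()]) containing
#'   both modalities (or one).
#' @param config A [pipeline_config()].
#' @return A `wavediv_model`.
#' @export
train_model <- function(fm, config = pipeline_config()) {
  if (anyNA(fm$label)) stop("training patches must be labeled",
                            call. = FALSE)
  attrs <- feature_columns(fm)
  edges <- lapply(setNames(attrs, attrs),
                  function(a) make_bin_edges(fm[[a]], config$n_bins))
  mods <- intersect(wd_modalities, unique(fm$modality))
  if (!length(mods)) stop("no recognized modality in training data",
                          call. = FALSE)
  modalities <- lapply(setNames(mods, mods), function(mod) {
    sub <- fm[fm$modality == mod, , drop = FALSE]
    ref <- train_reference(sub, n_bins = config$n_bins,
                           bandwidth = config$bandwidth, bin_edges = edges)
    weights <- lapply(setNames(wd_divergences, wd_divergences), function(k)
      compute_weights(ref, k, h_floor = config$h_floor,
                      jsd_variant = config$jsd_variant))
    xs <- as.matrix(sub[, attrs, drop = FALSE])
    calibration <- lapply(weights, function(w) {
      raw <- raw_scores(xs, ref, w, config$jsd_variant)
      fit_calibration(raw, sub$label)
    })
    list(reference = ref, weights = weights, calibration = calibration)
  })
  structure(list(config = config, attributes = attrs,
                 modalities = modalities,
                 version = as.character(utils::packageVersion("wavediv"))),
            class = "wavediv_model")
}

#' @export
print.wavediv_model <- function(x, ...) {
  cat(sprintf("<wavediv_model v%s> %d attributes, modalities: %s\n",
              x$version, length(x$attributes),
              paste(names(x$modalities), collapse = ", ")))
  for (mod in names(x$modalities)) {
    w <- x$modalities[[mod]]$weights$TD$weights
    top <- sort(w, decreasing = TRUE)[1:3]
    cat(sprintf("  %s top TD weights: %s\n", mod,
                paste(sprintf("%s=%.3f", names(top), top), collapse = " ")))
  }
  invisible(x)
}

#' Serialize / deserialize a trained model as JSON
#'
#' Uses type-preserving JSON serialization so numeric precision and object
#' structure survive a round trip.
#'
#' @param model A `wavediv_model`.
#' @param path Output / input file path.
#' @return `read_model` returns the model; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  writeLines(jsonlite::serializeJSON(model, digits = NA), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Split a feature matrix into train and test halves by source frame
#'
#' All four patches of a source frame stay on the same side of the split
#' (avoiding leakage between quadrants of one frame). Within each
#' (modality, label) group, the lexicographically first half of the source
#' ids goes to training. `by = "patch"` splits at the patch level instead
#' (alternating patches within each group).
#'
#' @param fm Labeled feature matrix.
#' @param by `"source"` (default) or `"patch"`.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(fm, by = c("source", "patch")) {
  by <- match.arg(by)
  grp <- interaction(fm$modality, fm$label, drop = TRUE)
  take_train <- logical(nrow(fm))
  for (g in levels(grp)) {
    i <- which(grp == g)
    if (by == "source") {
      ids <- sort(unique(fm$source_id[i]))
      tr_ids <- ids[seq_len(floor(length(ids) / 2))]
      take_train[i] <- fm$source_id[i] %in% tr_ids
    } else {
      ord <- i[order(fm$source_id[i], fm$patch_index[i])]
      take_train[ord[seq_along(ord) %% 2L == 1L]] <- TRUE
    }
  }
  list(train = fm[take_train, , drop = FALSE],
       test = fm[!take_train, , drop = FALSE])
}

#' Run the full pipeline end to end on synthetic data
#'
#' Generates a seeded synthetic dataset, splits each frame into 4 quadrant
#' patches, extracts wavelet features, splits train/test by source frame,
#' trains the model, classifies the held-out patches, fuses the two
#' modalities and scores everything. Fully deterministic given `seed` and
#' the configs.
#'
#' @param seed Integer seed for the synthetic data (and bootstrap, if
#'   requested).
#' @param synth A [synth_config()]; defaults to the standard conditions
#'   (30 frames per class per modality, side 256, separation 1) with
#'   `seed` injected.
#' @param config A [pipeline_config()].
#' @param bootstrap If `TRUE`, attach percentile-bootstrap CIs for each
#'   divergence's held-out accuracy (using `config$bootstrap_n` resamples).
#' @return List with `results` (per-modality test classifications), `fused`,
#'   `report` ([score()] of `results`), `fused_report`, `model`, `seed`, and
#'   optionally `bootstrap`.
#' @export
run_end_to_end <- function(seed = 1, synth = NULL, config = pipeline_config(),
                           bootstrap = FALSE) {
  synth <- synth %||% synth_config(seed = seed)
  frames <- generate_dataset(synth)
  patch_side <- synth$image_side %/% 2L
  patches <- unlist(lapply(frames, function(f)
    split_image(f$pixels, patch_side, modality = f$modality,
                label = f$label, source_id = f$source_id)),
    recursive = FALSE)
  fm <- extract_feature_matrix(patches, config$wavelet_name, config$levels,
                               config$entropy_bins)
  halves <- split_train_test(fm, by = "source")
  model <- train_model(halves$train, config)
  results <- classify_dataset(halves$test, model)
  fused <- fuse_results(results)
  out <- list(results = results, fused = fused,
              report = score(results), fused_report = score(fused),
              model = model, seed = seed)
  if (isTRUE(bootstrap)) {
    out$bootstrap <- lapply(setNames(wd_divergences, wd_divergences),
                            function(k)
      bootstrap_ci(predictions = results[[paste0("assigned_", k)]],
                   truth = results$label,
                   n_resamples = config$bootstrap_n, seed = seed))
  }
  out
}
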