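# Shared fixtures, built in code at test time.

# random probability vector
rprob <- function(n) {
  x <- runif(n) + 1e-6
  x / sum(x)
}

# small end-to-end pipeline run, computed once and reused across files:
# 6 frames/class/modality at side 128 -> 144 patches of side 64,
# 72 train / 72 test.
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_end_to_end(
        seed = 7,
        synth = synth_config(n_per_class_per_modality = 6,
                             image_side = 128, seed = 7))
    cache
  }
})

# feature matrix of a tiny labeled patch set (random textures; labels
# arbitrary), for structural tests that need no class signal
tiny_feature_matrix <- function(seed = 3, n_per_class = 4, side = 64) {
  set.seed(seed)
  patches <- list()
  for (mod in c("SEM", "AFM")) for (cls in c("normal", "benign", "malignant"))
    for (i in seq_len(n_per_class))
      patches <- c(patches, list(image_patch(
        matrix(runif(side * side), side, side), modality = mod, label = cls,
        source_id = sprintf("%s%02d", substr(cls, 1, 1), i),
        patch_index = 0L)))
  extract_feature_matrix(patches)
}

# hand-built minimal class_reference for toy divergence/likelihood tests
toy_reference <- function(dists, pooled, rates = NULL, edges = NULL,
                          n_bins = nrow(pooled)) {
  attrs <- colnames(pooled)
  structure(list(
    modality = "SEM", attributes = attrs, n_bins = n_bins, bandwidth = 0,
    bin_edges = edges %||% lapply(setNames(attrs, attrs),
                                  function(a) seq(0, 1,
                                                  length.out = n_bins + 1)),
    dist = dists, pooled = pooled,
    rates = rates,
    shift_min = setNames(rep(0, length(attrs)), attrs),
    shift_delta = setNames(rep(0, length(attrs)), attrs),
    stages = NULL, n_train = 10L),
    class = "class_reference")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
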