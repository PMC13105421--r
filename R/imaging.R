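# Reading, normalizing and patch-splitting of microscopy images.

#' Construct an image patch
#'
#' An `image_patch` is the unit of classification: a square grayscale
#' intensity array with side a power of 2 (default 256), all intensities in
#' `[0, 1]`, tagged with the acquisition modality and (for training or
#' evaluation) a class label.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`; square, side a
#'   power of 2, at least 16.
#' @param modality `"SEM"` or `"AFM"`.
#' @param label Optional class label: `"normal"`, `"benign"` or
#'   `"malignant"`; `NA` for unlabeled test patches.
#' @param source_id Identifier of the source frame the patch was cut from.
#' @param patch_index Quadrant index 0-3 (row-major from top-left), or 0 for
#'   a patch that is itself a full frame.
#' @return An object of class `image_patch`.
#' @export
image_patch <- function(pixels, modality, label = NA_character_,
                        source_id = "", patch_index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  n <- nrow(pixels)
  if (ncol(pixels) != n)
    stop(sprintf("patch must be square, got %d x %d", n, ncol(pixels)),
         call. = FALSE)
  if (n < 16 || bitwAnd(n, n - 1L) != 0L)
    stop(sprintf("patch side must be a power of 2 >= 16, got %d", n),
         call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1] (normalize first)", call. = FALSE)
  modality <- match.arg(modality, wd_modalities)
  if (!is.na(label)) label <- match.arg(label, wd_classes)
  structure(
    list(pixels = pixels, modality = modality, label = label,
         source_id = as.character(source_id),
         patch_index = as.integer(patch_index)),
    class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch %s #%d> %dx%d %s label=%s\n",
              x$source_id, x$patch_index, nrow(x$pixels), ncol(x$pixels),
              x$modality, x$label))
  invisible(x)
}

#' Load a microscopy image and normalize to \code{[0, 1]}
#'
#' Reads an 8- or 16-bit PNG or TIFF (single- or 3-channel). Intensities are
#' scaled by the dtype maximum (not the observed maximum), so absolute
#' brightness differences between images survive normalization. RGB images
#' are collapsed to Rec. 709 luminance before scaling.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param modality `"SEM"` or `"AFM"` (recorded, not used for decoding).
#' @return Numeric matrix of intensities in `[0, 1]` with attribute
#'   `modality`.
#' @export
load_image <- function(path, modality = c("SEM", "AFM")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop(sprintf("cannot read image: file not found: %s", path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)),
    error = function(e)
      stop(sprintf("cannot decode image %s: %s", path, conditionMessage(e)),
           call. = FALSE))
  # readPNG/readTIFF already divide by the dtype maximum (255 or 65535)
  if (length(dim(img)) == 3) {
    nc <- dim(img)[3]
    if (nc >= 3) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img <- img[, , 1]   # gray+alpha: drop alpha
    }
  }
  img <- pmin(pmax(img, 0), 1)
  if (max(img) - min(img) == 0)
    warning(sprintf("zero-variance image: %s", path), call. = FALSE)
  attr(img, "modality") <- modality
  img
}

#' Split a square image into four quadrant patches
#'
#' The source frame is divided into four non-overlapping quadrants in
#' row-major order from the top-left (indices 0 = top-left, 1 = top-right,
#' 2 = bottom-left, 3 = bottom-right). The split is lossless: reassembling
#' the quadrants reproduces the input exactly.
#'
#' @param image Square numeric matrix with side `2 * patch_side`.
#' @param patch_side Side of each patch (power of 2, default 256).
#' @param modality,label,source_id Metadata forwarded to each patch.
#' @return List of 4 [image_patch] objects.
#' @export
split_image <- function(image, patch_side = 256, modality = "SEM",
                        label = NA_character_, source_id = "") {
  if (!is.na(attr(image, "modality") %||% NA_character_))
    modality <- attr(image, "modality")
  n <- nrow(image)
  if (ncol(image) != n || n != 2L * patch_side)
    stop(sprintf(
      "image must be square with side %d (2 x patch_side), got %d x %d",
      2L * patch_side, n, ncol(image)), call. = FALSE)
  idx <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))  # row-major quads
  lapply(seq_along(idx), function(k) {
    r <- (idx[[k]][1] - 1L) * patch_side + seq_len(patch_side)
    c <- (idx[[k]][2] - 1L) * patch_side + seq_len(patch_side)
    image_patch(image[r, c, drop = FALSE], modality = modality, label = label,
                source_id = source_id, patch_index = k - 1L)
  })
}

#' Read a dataset directory into patches
#'
#' Expects the layout `<root>/<modality>/<label>/<source_id>.png` (or
#' `.tif`). Each source frame is split into 4 quadrant patches of side
#' `patch_side`.
#'
#' @param root Dataset root directory.
#' @param patch_side Patch side; source frames must have side
#'   `2 * patch_side`.
#' @return List of [image_patch].
#' @export
read_dataset <- function(root, patch_side = 256) {
  if (!dir.exists(root)) stop("dataset directory not found: ", root,
                              call. = FALSE)
  patches <- list()
  for (mod in wd_modalities) for (lab in wd_classes) {
    d <- file.path(root, mod, lab)
    if (!dir.exists(d)) next
    for (f in sort(list.files(d, pattern = "\\.(png|tif|tiff)$",
                              full.names = TRUE))) {
      img <- load_image(f, mod)
      sid <- tools::file_path_sans_ext(basename(f))
      patches <- c(patches, split_image(img, patch_side, modality = mod,
                                        label = lab, source_id = sid))
    }
  }
  if (!length(patches)) stop("no images found under ", root, call. = FALSE)
  patches
}
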