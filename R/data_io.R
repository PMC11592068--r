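#' @useDynLib ucapsnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

CLASS_LABELS <- c("normal", "benign", "malignant")
LESION_LABELS <- c("benign", "malignant")

#' Create a labeled ultrasound image record
#'
#' The unit flowing through both pipeline stages: a grayscale image in
#' `[0, 1]`, an optional binary lesion mask of the same size, and a class
#' label (`normal`, `benign` or `malignant`).
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param mask optional binary matrix (`{0, 1}`) of the same dimensions, or
#'   `NULL` when no mask is available.
#' @param label one of `"normal"`, `"benign"`, `"malignant"`.
#' @param source_id character identifier (typically the file stem).
#' @return A `labeled_image` object.
#' @export
labeled_image <- function(pixels, mask = NULL, label, source_id = "") {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0 | pixels > 1)) stop("pixels must lie in [0, 1]")
  label <- match.arg(label, CLASS_LABELS)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(pixels)))
      stop("mask dimensions must equal pixel dimensions")
    if (!all(mask %in% c(0, 1))) stop("mask must be binary {0, 1}")
  }
  structure(list(pixels = pixels, mask = mask, label = label,
                 source_id = as.character(source_id)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("labeled_image '%s': %dx%d, label=%s, mask=%s\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$label,
              if (is.null(x$mask)) "absent" else "present"))
  invisible(x)
}

read_gray_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE],
                                        c(1, 2), mean)
  px
}

resize_bilinear <- function(px, size) {
  if (all(dim(px) == size)) return(px)
  m <- EBImage::resize(px, w = size, h = size, filter = "bilinear")
  pmin(pmax(as.matrix(m), 0), 1)
}

resize_nearest <- function(px, size) {
  if (all(dim(px) == size)) return(px)
  as.matrix(EBImage::resize(px, w = size, h = size, filter = "none"))
}

is_mask_file <- function(f) grepl("_mask", basename(f), fixed = TRUE)

mask_stem <- function(f) sub("_mask.*$", "", tools::file_path_sans_ext(basename(f)))

#' Load a BUSI-style PNG dataset
#'
#' Reads a directory with one subdirectory per class (`benign/`,
#' `malignant/`, `normal/`). Files whose names contain `_mask` are
#' ground-truth masks; a mask belongs to the image whose file stem equals the
#' mask's stem with the `_mask...` suffix removed. When an image has several
#' mask files they are combined with a pixelwise OR. Images are rescaled to
#' `[0, 1]`, bilinearly resized to `image_size`; masks are resized with
#' nearest-neighbor interpolation and binarized at 0.5.
#'
#' @param root_path dataset directory.
#' @param image_size target square size in pixels (>= 32).
#' @return A list of [labeled_image] records, one per non-mask image file.
#' @export
load_dataset <- function(root_path, image_size = 256L) {
  if (!dir.exists(root_path)) stop("dataset directory not found: ", root_path)
  stopifnot(image_size >= 32)
  records <- list()
  for (label in intersect(CLASS_LABELS, list.dirs(root_path, recursive = FALSE,
                                                  full.names = FALSE))) {
    cdir <- file.path(root_path, label)
    files <- sort(list.files(cdir, pattern = "\\.png$", ignore.case = TRUE))
    imgs <- files[!is_mask_file(files)]
    masks <- files[is_mask_file(files)]
    for (f in imgs) {
      stem <- tools::file_path_sans_ext(f)
      px <- tryCatch(read_gray_png(file.path(cdir, f)),
                     error = function(e) stop("unreadable image file: ",
                                              file.path(cdir, f), call. = FALSE))
      px <- resize_bilinear(px, image_size)
      mfiles <- masks[mask_stem(masks) == stem]
      mk <- NULL
      if (length(mfiles) > 0) {
        mk <- matrix(0, image_size, image_size)
        for (mf in mfiles) {
          m <- read_gray_png(file.path(cdir, mf))
          m <- resize_nearest((m > 0.5) * 1, image_size)
          mk <- pmax(mk, (m >= 0.5) * 1)
        }
      } else if (label %in% LESION_LABELS) {
        warning("no mask file for lesion image '", stem, "' in class ", label)
      }
      records[[length(records) + 1]] <-
        labeled_image(px, mk, label, source_id = paste0(label, "/", stem))
    }
  }
  records
}

#' Write labeled images as a BUSI-style directory
#'
#' Inverse of [load_dataset]: writes `<root>/<class>/<id>.png` plus
#' `<id>_mask.png` for records that carry a mask.
#'
#' @param records list of [labeled_image].
#' @param root_path output directory (created if missing).
#' @return `root_path`, invisibly.
#' @export
write_dataset <- function(records, root_path) {
  for (label in unique(vapply(records, `[[`, "", "label"))) {
    dir.create(file.path(root_path, label), recursive = TRUE, showWarnings = FALSE)
  }
  for (r in records) {
    id <- basename(r$source_id)
    if (id == "") stop("record without source_id cannot be written")
    png::writePNG(r$pixels, file.path(root_path, r$label, paste0(id, ".png")))
    if (!is.null(r$mask)) {
      png::writePNG(r$mask, file.path(root_path, r$label, paste0(id, "_mask.png")))
    }
  }
  invisible(root_path)
}

#' Shuffle images and labels with the same permutation
#'
#' @param images list of images (any type).
#' @param labels vector or list of the same length.
#' @param seed integer seed for the permutation.
#' @return A list with elements `images` and `labels`, both permuted by one
#'   shared random permutation.
#' @export
shuffle_paired <- function(images, labels, seed) {
  if (length(images) != length(labels))
    stop("images and labels must have the same length")
  n <- length(images)
  if (n <= 1) return(list(images = images, labels = labels))
  perm <- withr::with_seed(seed, sample.int(n))
  list(images = images[perm], labels = labels[perm])
}

#' Convert a segmentation mask into classifier input
#'
#' Downsamples a binary mask to half its size with nearest-neighbor
#' interpolation (preserving binarity) and replicates it into three identical
#' channels, matching the classifier's expected input layout. With the
#' default stage-one resolution this maps a 256x256 mask to 128x128x3.
#'
#' @param mask binary matrix of size `expected_size` x `expected_size`.
#' @param expected_size required input size (default 256).
#' @param out_size output size (default `expected_size / 2`).
#' @return Array of dim `c(out_size, out_size, 3)` with identical binary
#'   channels.
#' @export
prepare_for_classifier <- function(mask, expected_size = 256L,
                                   out_size = expected_size %/% 2L) {
  if (!is.matrix(mask) || !all(dim(mask) == expected_size))
    stop("expected a ", expected_size, "x", expected_size,
         " single-channel mask, got ", paste(dim(mask), collapse = "x"))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary {0, 1}")
  small <- (resize_nearest(mask, out_size) >= 0.5) * 1
  array(rep(small, 3), dim = c(out_size, out_size, 3))
}
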