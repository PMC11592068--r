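#' Configuration for the synthetic ultrasound phantom generator
#'
#' Phantoms emulate the gross appearance of breast ultrasound: a speckled
#' background with, for lesion classes, a single darker (hypoechoic) lesion
#' and an exact binary ground-truth mask. Benign lesions are smooth rotated
#' ellipses; malignant lesions are star-shaped polygons whose radius is
#' modulated by `r(theta) = r0 * (1 + a * |sin(k * theta / 2)|)` with `k`
#' spicules, giving the irregular, spiculated margins typical of malignancy.
#' Speckle is modeled as unit-mean gamma-distributed multiplicative noise
#' (the fully-developed-speckle approximation); images are clipped to
#' `[0, 1]`.
#'
#' @param size square image size in pixels (>= 32).
#' @param background_mean mean background echo intensity, in (0, 1).
#' @param lesion_intensity_drop fractional intensity reduction inside the
#'   lesion, in (0, 1).
#' @param speckle_shape gamma shape of the multiplicative speckle (> 0);
#'   larger values mean milder speckle. Default 4.
#' @param benign_axis_ratio_range minor/major axis ratio range for benign
#'   ellipses.
#' @param malignant_n_spicules integer range for the number of spicules.
#' @param spicule_amp_range relative amplitude range of the radial spikes.
#' @param lesion_radius_range base lesion radius range as a fraction of
#'   `size`.
#' @param seed integer master seed for [make_dataset].
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(size = 256L,
                           background_mean = 0.55,
                           lesion_intensity_drop = 0.5,
                           speckle_shape = 4,
                           benign_axis_ratio_range = c(0.6, 0.95),
                           malignant_n_spicules = c(6L, 12L),
                           spicule_amp_range = c(0.35, 0.7),
                           lesion_radius_range = c(0.12, 0.22),
                           seed = 1L) {
  stopifnot(size >= 32,
            background_mean > 0, background_mean < 1,
            lesion_intensity_drop > 0, lesion_intensity_drop < 1,
            speckle_shape > 0,
            benign_axis_ratio_range[1] <= benign_axis_ratio_range[2],
            malignant_n_spicules[1] <= malignant_n_spicules[2],
            spicule_amp_range[1] <= spicule_amp_range[2],
            lesion_radius_range[1] <= lesion_radius_range[2],
            all(lesion_radius_range > 0), all(lesion_radius_range < 1))
  structure(list(size = as.integer(size), background_mean = background_mean,
                 lesion_intensity_drop = lesion_intensity_drop,
                 speckle_shape = speckle_shape,
                 benign_axis_ratio_range = benign_axis_ratio_range,
                 malignant_n_spicules = as.integer(malignant_n_spicules),
                 spicule_amp_range = spicule_amp_range,
                 lesion_radius_range = lesion_radius_range,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate one synthetic ultrasound phantom
#'
#' @param class_label `"normal"`, `"benign"` or `"malignant"`.
#' @param config a [phantom_config].
#' @param seed integer seed; the phantom is a deterministic function of
#'   `(class_label, config, seed)`.
#' @param source_id identifier for the record.
#' @return A [labeled_image]; `normal` phantoms carry an all-zero mask.
#' @export
make_phantom <- function(class_label, config = phantom_config(), seed = 1L,
                         source_id = paste0(class_label, "_", seed)) {
  class_label <- match.arg(class_label, CLASS_LABELS)
  n <- config$size
  withr::with_seed(seed, {
    mask <- matrix(0, n, n)
    if (class_label != "normal") {
      cx <- stats::runif(1, 0.3, 0.7) * n
      cy <- stats::runif(1, 0.3, 0.7) * n
      r0 <- runif1(config$lesion_radius_range) * n
      phi <- stats::runif(1, 0, pi)
      xs <- matrix(seq_len(n) - cx, n, n)
      ys <- matrix(seq_len(n) - cy, n, n, byrow = TRUE)
      if (class_label == "benign") {
        ratio <- runif1(config$benign_axis_ratio_range)
        a <- r0
        b <- r0 * ratio
        u <- (xs * cos(phi) + ys * sin(phi)) / a
        v <- (-xs * sin(phi) + ys * cos(phi)) / b
        mask[u^2 + v^2 <= 1] <- 1
      } else {
        k <- sample(seq(config$malignant_n_spicules[1],
                        config$malignant_n_spicules[2]), 1)
        amp <- runif1(config$spicule_amp_range)
        theta <- atan2(ys, xs) - phi
        rmod <- r0 * (1 + amp * abs(sin(k * theta / 2)))
        mask[sqrt(xs^2 + ys^2) <= rmod] <- 1
      }
    }
    echo <- matrix(config$background_mean, n, n)
    echo[mask == 1] <- config$background_mean * (1 - config$lesion_intensity_drop)
    speckle <- matrix(stats::rgamma(n * n, shape = config$speckle_shape,
                                    rate = config$speckle_shape), n, n)
    px <- pmin(pmax(echo * speckle, 0), 1)
    labeled_image(px, mask, class_label, source_id = source_id)
  })
}

#' Generate a balanced synthetic phantom dataset
#'
#' Deterministic given `config$seed`: per-record seeds are drawn once from
#' the master seed, so the i-th record does not depend on how many records
#' are requested for other classes.
#'
#' @param n_per_class number of phantoms per class (>= 0).
#' @param config a [phantom_config].
#' @param classes which classes to generate (default all three).
#' @return A list of `length(classes) * n_per_class` [labeled_image] records.
#' @export
make_dataset <- function(n_per_class, config = phantom_config(),
                         classes = CLASS_LABELS) {
  stopifnot(n_per_class >= 0)
  if (n_per_class == 0) return(list())
  classes <- match.arg(classes, CLASS_LABELS, several.ok = TRUE)
  records <- list()
  for (cl in classes) {
    # independent, collision-free seed stream per class
    cl_off <- match(cl, CLASS_LABELS) * 10000000L
    seeds <- withr::with_seed(config$seed + cl_off,
                              sample.int(.Machine$integer.max %/% 2, n_per_class))
    for (i in seq_len(n_per_class)) {
      records[[length(records) + 1]] <-
        make_phantom(cl, config, seed = seeds[i],
                     source_id = sprintf("%s_%03d", cl, i))
    }
  }
  records
}

#' Boundary irregularity index of a binary mask
#'
#' Isoperimetric quotient `perimeter^2 / (4 * pi * area)` computed by pixel
#' counting: the area is the number of foreground pixels and the perimeter
#' the number of 4-neighborhood edges between foreground and background
#' (image border included). Equals ~1 for a disk and grows with boundary
#' complexity, so it separates smooth benign from spiculated malignant
#' masks.
#'
#' @param mask binary matrix.
#' @return Numeric scalar; `NA` for an empty mask.
#' @export
irregularity_index <- function(mask) {
  area <- sum(mask)
  if (area == 0) return(NA_real_)
  pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  n <- nrow(pad); m <- ncol(pad)
  perim <- sum(pad[-1, ] != pad[-n, ]) + sum(pad[, -1] != pad[, -m])
  perim^2 / (4 * pi * area)
}
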