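check_mask_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1 (perfect agreement).
#'
#' @param pred,truth binary arrays of identical shape.
#' @return Numeric in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  check_mask_pair(pred, truth)
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred * truth) / denom
}

#' Intersection over union (Jaccard index) of two binary masks
#'
#' `|A n B| / |A u B|`; two empty masks score 1. Related to Dice by
#' `dice = 2 * iou / (1 + iou)`.
#'
#' @param pred,truth binary arrays of identical shape.
#' @return Numeric in `[0, 1]`.
#' @export
iou <- function(pred, truth) {
  check_mask_pair(pred, truth)
  inter <- sum(pred * truth)
  union <- sum(pred) + sum(truth) - inter
  if (union == 0) return(1)
  inter / union
}

#' Mean IoU over a set of mask pairs
#'
#' Unweighted mean of the per-image foreground IoU (the default headline
#' variant); optionally the two-class mean that also averages in the
#' background IoU of each image.
#'
#' @param preds,truths lists of binary masks.
#' @param variant `"foreground"` (default) or `"two_class"`.
#' @return Numeric in `[0, 1]`.
#' @export
mean_iou <- function(preds, truths, variant = c("foreground", "two_class")) {
  variant <- match.arg(variant)
  stopifnot(length(preds) == length(truths))
  vals <- mapply(function(p, t) {
    fg <- iou(p, t)
    if (variant == "foreground") fg else (fg + iou(1 - p, 1 - t)) / 2
  }, preds, truths)
  mean(vals)
}

#' Pixel accuracy over a set of mask pairs
#'
#' Fraction of pixels (pooled over all images) on which prediction and truth
#' agree; the conventional reading of segmentation "accuracy".
#'
#' @param preds,truths lists of binary masks.
#' @return Numeric in `[0, 1]`.
#' @export
pixel_accuracy <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  agree <- 0
  total <- 0
  for (i in seq_along(preds)) {
    check_mask_pair(preds[[i]], truths[[i]])
    agree <- agree + sum(preds[[i]] == truths[[i]])
    total <- total + length(truths[[i]])
  }
  agree / total
}

#' Summarize segmentation quality over a test set
#'
#' @param preds,truths lists of binary masks.
#' @return List with `mean_dice`, `mean_iou` (foreground),
#'   `mean_iou_two_class`, `pixel_accuracy`, and pooled pixelwise
#'   `precision`/`recall`.
#' @export
segmentation_report <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  tp <- fp <- fn <- 0
  for (i in seq_along(preds)) {
    tp <- tp + sum(preds[[i]] * truths[[i]])
    fp <- fp + sum(preds[[i]] * (1 - truths[[i]]))
    fn <- fn + sum((1 - preds[[i]]) * truths[[i]])
  }
  list(mean_dice = mean(mapply(dice, preds, truths)),
       mean_iou = mean_iou(preds, truths),
       mean_iou_two_class = mean_iou(preds, truths, "two_class"),
       pixel_accuracy = pixel_accuracy(preds, truths),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' Classification evaluation report
#'
#' Builds the confusion matrix (rows = truth, columns = prediction) and
#' per-class precision, recall, F1 and one-vs-rest accuracy, plus overall
#' accuracy. Zero denominators yield 0 and set the `zero_division` flag.
#'
#' @param truths,preds label vectors of equal length.
#' @param classes class set (default: sorted union of observed labels).
#' @return An `eval_report` list with `confusion`, `per_class`, `accuracy`
#'   and `n`.
#' @export
classification_report <- function(truths, preds, classes = NULL) {
  truths <- as.character(truths)
  preds <- as.character(preds)
  if (length(truths) != length(preds))
    stop("truths and preds must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truths, preds)))
  if (!all(c(truths, preds) %in% classes))
    stop("labels outside the class set: ",
         paste(setdiff(unique(c(truths, preds)), classes), collapse = ", "))
  k <- length(classes)
  conf <- matrix(0L, k, k, dimnames = list(truth = classes, pred = classes))
  for (i in seq_along(truths)) {
    conf[truths[i], preds[i]] <- conf[truths[i], preds[i]] + 1L
  }
  zero_division <- FALSE
  rate <- function(num, den) {
    if (den == 0) { zero_division <<- TRUE; 0 } else num / den
  }
  per_class <- do.call(rbind, lapply(seq_len(k), function(j) {
    tp <- conf[j, j]
    fp <- sum(conf[-j, j])
    fn <- sum(conf[j, -j])
    tn <- sum(conf) - tp - fp - fn
    precision <- rate(tp, tp + fp)
    recall <- rate(tp, tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(class = classes[j], precision = precision, recall = recall,
               f1 = f1, accuracy = (tp + tn) / sum(conf))
  }))
  structure(list(confusion = conf, per_class = per_class,
                 accuracy = sum(diag(conf)) / sum(conf),
                 n = length(truths), zero_division = zero_division),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n=%d, accuracy=%.4f\n", x$n, x$accuracy))
  cat("confusion (rows=truth, cols=pred):\n")
  print(x$confusion)
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report` or a plain list of metrics.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  r <- unclass(report)
  if (!is.null(r$confusion)) r$confusion <- as.data.frame.matrix(r$confusion)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
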