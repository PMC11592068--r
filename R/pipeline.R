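#' Training configuration
#'
#' Optimizer settings for one training stage. The published defaults are 50
#' epochs with batch size 25 for both stages, learning rate 1e-5 for the
#' segmenter and 5e-3 for the classifier; small synthetic runs typically use
#' fewer epochs, smaller batches and a larger segmenter learning rate.
#'
#' @param learning_rate positive step size.
#' @param epochs number of passes over the data (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param seed integer seed controlling initialization, batch order and
#'   dropout.
#' @param optimizer only `"adam"` is available.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate, epochs = 50L, batch_size = 25L,
                         seed = 1L, optimizer = "adam") {
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified k-fold partition
#'
#' Splits indices into `k` folds, stratified by label: within each class the
#' (seeded) shuffled members are dealt round-robin, so per-class fold sizes
#' differ by at most one and every sample lands in exactly one test fold.
#'
#' @param labels label vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return List of `k` elements, each `list(train, test)` index vectors.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(k >= 2)
  if (n < k) stop("need at least k samples")
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small) > 0)
    stop("class with fewer than k members: ", paste(small, collapse = ", "))
  fold_of <- integer(n)
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      ix <- sample(which(labels == cl))
      fold_of[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Cross-validated evaluation
#'
#' Runs `k`-fold cross-validation with a user-supplied fit/predict pair and
#' pools all out-of-fold predictions into a single [classification_report].
#'
#' @param x inputs (list or vector, indexable with `[`).
#' @param labels label vector.
#' @param k number of folds.
#' @param seed integer seed for the partition.
#' @param fit_fn `function(x_train, labels_train)` returning a fitted object.
#' @param predict_fn `function(fit, x_test)` returning predicted labels.
#' @return List with `folds`, per-fold accuracies `fold_accuracy`, and the
#'   pooled `report`.
#' @export
kfold_cv <- function(x, labels, k = 5L, seed = 1L, fit_fn, predict_fn) {
  folds <- kfold_split(labels, k, seed)
  labels <- as.character(labels)
  pooled_pred <- character(length(labels))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    fit <- fit_fn(x[folds[[f]]$train], labels[folds[[f]]$train])
    pr <- as.character(predict_fn(fit, x[folds[[f]]$test]))
    pooled_pred[folds[[f]]$test] <- pr
    fold_acc[f] <- mean(pr == labels[folds[[f]]$test])
  }
  list(folds = folds, fold_accuracy = fold_acc,
       report = classification_report(labels, pooled_pred))
}

derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 7919 + k * 104729) %% 2147483646 + 1)
}

#' Run the full two-stage pipeline
#'
#' Trains the enhanced U-Net on the lesion-class training images, predicts
#' masks for every lesion image, converts the predicted masks into
#' classifier inputs ([prepare_for_classifier]), trains the capsule
#' classifier on the training portion and evaluates both stages on the
#' held-out portion. All stage seeds derive from one master seed, so two
#' runs with the same seed produce identical manifests.
#'
#' @param data list of [labeled_image] records (e.g. from [load_dataset] or
#'   [make_dataset]) sized to `seg_config$input_size`, or a dataset
#'   directory path.
#' @param seg_config a [seg_config].
#' @param caps_config a [caps_config]; its `input_size` must equal half the
#'   segmentation size.
#' @param tc_seg,tc_cls [train_config]s for the two stages (their seeds are
#'   overridden by seeds derived from `seed`).
#' @param seed master seed.
#' @param holdout_frac fraction of lesion images held out for evaluation
#'   (stratified; default 0.25).
#' @param use_ground_truth_masks train/evaluate the classifier on the
#'   ground-truth masks instead of the predicted ones (ablation flag).
#' @param out_dir optional directory for JSON reports and the manifest.
#' @return A `run_manifest` list with configs, seeds, the per-stage metric
#'   summaries (`seg_report`, `cls_report`), split bookkeeping and output
#'   paths.
#' @export
run_two_stage <- function(data, seg_config, caps_config, tc_seg, tc_cls,
                          seed = 1L, holdout_frac = 0.25,
                          use_ground_truth_masks = FALSE, out_dir = NULL) {
  if (is.character(data)) data <- load_dataset(data, seg_config$input_size)
  stopifnot(caps_config$input_size * 2 == seg_config$input_size)
  labels <- vapply(data, `[[`, "", "label")
  lesion <- which(labels %in% LESION_LABELS)
  if (length(lesion) == 0) stop("stage 1 (segmentation): no lesion images")
  ids <- vapply(data, `[[`, "", "source_id")

  # stratified holdout split of lesion images
  split_seed <- derive_seed(seed, 1L)
  test_ix <- withr::with_seed(split_seed, {
    unlist(lapply(LESION_LABELS, function(cl) {
      ix <- lesion[labels[lesion] == cl]
      ix[sample.int(length(ix), round(length(ix) * holdout_frac))]
    }))
  })
  train_ix <- setdiff(lesion, test_ix)

  tc_seg$seed <- derive_seed(seed, 2L)
  tc_cls$seed <- derive_seed(seed, 3L)

  seg_model <- tryCatch(
    train_segmenter(seg_config, data[train_ix], tc_seg),
    error = function(e) stop("stage 1 (segmentation) failed: ",
                             conditionMessage(e), call. = FALSE))

  # predicted masks for every lesion image, in batches
  n_l <- length(lesion)
  s <- seg_config$input_size
  pred_masks <- vector("list", n_l)
  names(pred_masks) <- as.character(lesion)
  for (start in seq(1, n_l, by = 25)) {
    ix <- lesion[start:min(start + 24, n_l)]
    X <- array(0, c(s, s, 1, length(ix)))
    for (i in seq_along(ix)) X[, , 1, i] <- data[[ix[i]]]$pixels
    P <- predict_masks(seg_model, X)
    for (i in seq_along(ix)) {
      pred_masks[[as.character(ix[i])]] <- matrix(P[, , 1, i], s, s)
    }
  }

  seg_report <- segmentation_report(
    pred_masks[as.character(intersect(test_ix, lesion))],
    lapply(data[intersect(test_ix, lesion)], `[[`, "mask"))

  mask_for <- function(i) {
    if (use_ground_truth_masks) data[[i]]$mask else pred_masks[[as.character(i)]]
  }
  cls_input <- function(ix) {
    lapply(ix, function(i) prepare_for_classifier(mask_for(i), s))
  }

  cls_model <- tryCatch(
    train_classifier(caps_config, cls_input(train_ix), labels[train_ix], tc_cls),
    error = function(e) stop("stage 2 (classification) failed: ",
                             conditionMessage(e), call. = FALSE))

  test_pred <- predict_class(cls_model, cls_input(test_ix))
  cls_report <- classification_report(labels[test_ix], test_pred$labels,
                                      classes = LESION_LABELS)

  manifest <- structure(list(
    seed = seed,
    stage_seeds = list(split = split_seed, segmenter = tc_seg$seed,
                       classifier = tc_cls$seed),
    seg_config = unclass(seg_config), caps_config = unclass(caps_config),
    tc_seg = unclass(tc_seg), tc_cls = unclass(tc_cls),
    use_ground_truth_masks = use_ground_truth_masks,
    train_ids = ids[train_ix], test_ids = ids[test_ix],
    seg_history = seg_model$history, cls_history = cls_model$history,
    seg_report = seg_report,
    cls_report = list(accuracy = cls_report$accuracy,
                      per_class = cls_report$per_class,
                      confusion = as.data.frame.matrix(cls_report$confusion)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    paths = list()), class = "run_manifest")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$paths <- list(
      seg_report = file.path(out_dir, "seg_report.json"),
      cls_report = file.path(out_dir, "cls_report.json"),
      manifest = file.path(out_dir, "manifest.json"))
    write_report(seg_report, manifest$paths$seg_report)
    write_report(cls_report, manifest$paths$cls_report)
    m <- manifest
    m$timestamp <- NULL # keep the on-disk manifest seed-deterministic
    jsonlite::write_json(unclass(m), manifest$paths$manifest,
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  manifest$seg_model <- seg_model
  manifest$cls_model <- cls_model
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("two-stage run manifest\n")
  cat(sprintf("  master seed: %d | train n=%d, test n=%d\n", x$seed,
              length(x$train_ids), length(x$test_ids)))
  cat(sprintf("  stage 1: mean Dice %.4f, mean IoU %.4f, pixel acc %.4f\n",
              x$seg_report$mean_dice, x$seg_report$mean_iou,
              x$seg_report$pixel_accuracy))
  cat(sprintf("  stage 2: held-out accuracy %.4f\n", x$cls_report$accuracy))
  invisible(x)
}
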