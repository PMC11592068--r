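test_that("labeled_image enforces its invariants", {
  px <- matrix(runif(16), 4, 4)
  expect_error(labeled_image(px * 2, label = "benign"), "\\[0, 1\\]")
  expect_error(labeled_image(px, mask = matrix(1, 3, 3), label = "benign"),
               "dimensions")
  expect_error(labeled_image(px, mask = matrix(0.5, 4, 4), label = "benign"),
               "binary")
  expect_error(labeled_image(px, label = "weird"))
  r <- labeled_image(px, matrix(1, 4, 4), "malignant", "m0")
  expect_s3_class(r, "labeled_image")
})

test_that("load_dataset pairs images with masks and resizes", {
  dir <- make_png_fixture()
  recs <- load_dataset(dir, image_size = 64)
  expect_length(recs, 4) # 2 benign + 1 malignant + 1 normal, masks excluded
  labs <- vapply(recs, `[[`, "", "label")
  expect_equal(sum(labs == "benign"), 2)
  expect_equal(sum(labs == "malignant"), 1)
  expect_equal(sum(labs == "normal"), 1)
  for (r in recs) {
    expect_equal(dim(r$pixels), c(64, 64))
    expect_true(all(r$pixels >= 0 & r$pixels <= 1))
    if (!is.null(r$mask)) {
      expect_equal(dim(r$mask), c(64, 64))
      expect_true(all(r$mask %in% c(0, 1)))
    }
  }
  b1 <- recs[[which(vapply(recs, `[[`, "", "source_id") == "benign/b1")]]
  expect_equal(sum(b1$mask), 21 * 21)
  expect_error(load_dataset(file.path(dir, "nope")), "not found")
})

test_that("multiple masks for one stem are OR-combined", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "benign"))
  px <- matrix(0.5, 32, 32)
  left <- matrix(0, 32, 32); left[, 1:16] <- 1
  right <- matrix(0, 32, 32); right[, 17:32] <- 1
  png::writePNG(px, file.path(dir, "benign", "x.png"))
  png::writePNG(left, file.path(dir, "benign", "x_mask.png"))
  png::writePNG(right, file.path(dir, "benign", "x_mask_1.png"))
  recs <- load_dataset(dir, image_size = 32)
  expect_length(recs, 1)
  expect_true(all(recs[[1]]$mask == 1))
})

test_that("empty class directories give an empty list, lesion images without masks warn", {
  dir <- withr::local_tempdir()
  for (cl in c("benign", "malignant", "normal")) dir.create(file.path(dir, cl))
  expect_length(load_dataset(dir, 64), 0)
  png::writePNG(matrix(0.3, 32, 32), file.path(dir, "malignant", "m.png"))
  expect_warning(recs <- load_dataset(dir, 32), "no mask")
  expect_length(recs, 1)
  expect_null(recs[[1]]$mask)
})

test_that("write_dataset then load_dataset round-trips pixels and masks", {
  set.seed(20)
  cfg <- phantom_config(size = 48, seed = 3)
  recs <- list(make_phantom("benign", cfg, 1, "b_001"),
               make_phantom("malignant", cfg, 2, "m_001"),
               make_phantom("normal", cfg, 3, "n_001"))
  dir <- withr::local_tempdir()
  write_dataset(recs, dir)
  back <- load_dataset(dir, image_size = 48)
  expect_length(back, 3)
  ids <- vapply(back, function(r) basename(r$source_id), "")
  for (r in recs) {
    b <- back[[match(r$source_id, ids)]]
    expect_equal(b$label, r$label)
    expect_lte(max(abs(b$pixels - r$pixels)), 1 / 255)
    expect_identical(b$mask, r$mask)
  }
})

test_that("shuffle_paired permutes both lists with the same permutation", {
  imgs <- as.list(letters[1:10])
  labs <- LETTERS[1:10]
  out <- shuffle_paired(imgs, labs, seed = 5)
  expect_identical(toupper(unlist(out$images)), out$labels)
  expect_setequal(unlist(out$images), letters[1:10])
  # determinism and non-triviality
  out2 <- shuffle_paired(imgs, labs, seed = 5)
  expect_identical(out, out2)
  expect_false(identical(unlist(out$images), letters[1:10]))
  # degenerate lengths unchanged
  expect_identical(shuffle_paired(list(), character(0), 1)$labels, character(0))
  expect_identical(shuffle_paired(list("x"), "X", 1)$images, list("x"))
  expect_error(shuffle_paired(imgs, labs[1:3], 1), "same length")
})

test_that("multiset of (image, label) pairs is preserved for any seed", {
  set.seed(21)
  imgs <- as.list(sprintf("img%03d", 1:100))
  labs <- sample(c("benign", "malignant"), 100, replace = TRUE)
  pairs <- sort(paste(unlist(imgs), labs))
  for (seed in c(1, 77, 1234)) {
    out <- shuffle_paired(imgs, labs, seed)
    expect_identical(sort(paste(unlist(out$images), out$labels)), pairs)
  }
})

test_that("prepare_for_classifier downsamples binarily into three identical channels", {
  z <- prepare_for_classifier(matrix(0, 256, 256))
  expect_equal(dim(z), c(128, 128, 3))
  expect_true(all(z == 0))
  expect_true(all(prepare_for_classifier(matrix(1, 256, 256)) == 1))
  m <- matrix(0, 256, 256); m[97:160, 97:160] <- 1 # centered 64x64 square
  out <- prepare_for_classifier(m)
  ref <- matrix(0, 128, 128); ref[49:80, 49:80] <- 1 # centered 32x32 square
  expect_identical(out[, , 1], ref)
  expect_identical(out[, , 1], out[, , 2])
  expect_identical(out[, , 1], out[, , 3])
  expect_error(prepare_for_classifier(matrix(0, 64, 64)), "256x256")
  # scaled variant used by small pipelines
  expect_equal(dim(prepare_for_classifier(matrix(0, 64, 64), 64)), c(32, 32, 3))
})

test_that("prepared channels are identical for arbitrary random masks", {
  set.seed(22)
  for (i in 1:5) {
    m <- matrix(rbinom(256^2, 1, runif(1, 0.1, 0.9)), 256, 256)
    out <- prepare_for_classifier(m)
    expect_identical(out[, , 1], out[, , 2])
    expect_identical(out[, , 2], out[, , 3])
    expect_true(all(out %in% c(0, 1)))
  }
})
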