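test_that("dice and iou hand cases", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(dice(a, b), 0)
  expect_equal(iou(a, b), 0)
  # |A| = |B| = 4 with overlap 2: dice 0.5, iou 1/3
  c2 <- matrix(0, 4, 4); c2[2:3, 1:2] <- 1
  expect_equal(dice(a, c2), 0.5)
  expect_equal(iou(a, c2), 1 / 3)
  # empty/empty convention
  z <- matrix(0, 4, 4)
  expect_equal(dice(z, z), 1)
  expect_equal(iou(z, z), 1)
  expect_error(dice(a, matrix(0, 3, 3)), "shapes differ")
})

test_that("dice/iou identity, symmetry and ordering on random masks", {
  set.seed(40)
  for (i in 1:1000) {
    a <- random_mask(8)
    b <- random_mask(8)
    d <- dice(a, b); j <- iou(a, b)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_identical(d, dice(b, a))
    expect_true(j <= d + 1e-15)
    expect_true(d >= 0 && d <= 1 && j >= 0 && j <= 1)
  }
})

test_that("mean_iou and pixel accuracy pool correctly", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  c2 <- matrix(0, 4, 4); c2[2:3, 1:2] <- 1
  expect_equal(mean_iou(list(a, a), list(a, c2)), (1 + 1 / 3) / 2)
  expect_equal(pixel_accuracy(list(a), list(c2)), 12 / 16)
  rep <- segmentation_report(list(a), list(c2))
  expect_equal(rep$mean_dice, 0.5)
  expect_equal(rep$precision, 0.5) # 2 of 4 predicted foreground correct
  expect_equal(rep$recall, 0.5)
})

test_that("classification_report matches the hand-computed 2x2 example", {
  r <- classification_report(c("B", "B", "M", "M"), c("B", "M", "M", "M"))
  expect_equal(r$accuracy, 0.75)
  m <- r$per_class[r$per_class$class == "M", ]
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 0.8)
  b <- r$per_class[r$per_class$class == "B", ]
  expect_equal(b$precision, 1)
  expect_equal(b$recall, 0.5)
  expect_equal(unname(r$confusion["B", ]), c(1L, 1L))
  expect_equal(unname(r$confusion["M", ]), c(0L, 2L))
  expect_equal(sum(r$confusion), r$n)
})

test_that("report metrics are invariant to sample order and relabeling is consistent", {
  set.seed(41)
  t <- sample(c("benign", "malignant"), 50, replace = TRUE)
  p <- sample(c("benign", "malignant"), 50, replace = TRUE)
  perm <- sample(50)
  r1 <- classification_report(t, p)
  r2 <- classification_report(t[perm], p[perm])
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$accuracy, sum(diag(r1$confusion)) / sum(r1$confusion))
  # swapping the class order permutes the confusion matrix consistently
  r3 <- classification_report(t, p, classes = c("malignant", "benign"))
  expect_equal(unname(r3$confusion[2:1, 2:1]), unname(r1$confusion))
})

test_that("perfect predictions give a diagonal confusion matrix and all-1 metrics", {
  t <- rep(c("a", "b", "c"), times = c(3, 4, 5))
  r <- classification_report(t, t)
  expect_true(all(r$per_class[, c("precision", "recall", "f1")] == 1))
  expect_equal(r$accuracy, 1)
  expect_equal(sum(r$confusion) - sum(diag(r$confusion)), 0)
  expect_error(classification_report(t, t, classes = c("a", "b")), "outside")
})

test_that("zero-denominator rates degrade to 0 with a flag", {
  r <- classification_report(c("a", "a"), c("b", "b"), classes = c("a", "b"))
  expect_true(r$zero_division)
  expect_equal(r$per_class$recall[r$per_class$class == "b"], 0)
})

test_that("reports serialize to JSON", {
  r <- classification_report(c("a", "b"), c("a", "b"))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(r, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$accuracy, 1)
})
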