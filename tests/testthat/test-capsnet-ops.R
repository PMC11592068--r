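# Closed-form behavior of the capsule math primitives.

test_that("squash matches closed-form values and preserves direction", {
  # zero vector stays zero (epsilon guards the 0/0)
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))
  # unit-norm input: output norm = 0.5 / (1 + 1e-7)
  s <- c(1, 0)
  expect_equal(sqrt(sum(squash(s, 1e-7)^2)), 0.5 * (1 / (1 + 1e-7)),
               tolerance = 1e-12)
  # norm-5 input (3, 4): scale (25/26) on the unit vector, hand-evaluated
  out <- squash(c(3, 4), 1e-7)
  expect_equal(out, (25 / 26) * c(0.6, 0.8), tolerance = 1e-6)
  # direction preserved and norm < 1, increasing in ||s||
  set.seed(1)
  norms <- c()
  for (len in c(0.1, 0.5, 1, 2, 10, 100)) {
    v <- c(1, 2, -2) / 3 * len
    o <- squash(v)
    expect_equal(sum(o * v) / sqrt(sum(o^2) * sum(v^2)), 1, tolerance = 1e-9)
    n <- sqrt(sum(o^2))
    expect_lt(n, 1)
    norms <- c(norms, n)
  }
  expect_true(all(diff(norms) > 0))
})

test_that("softmax closed forms, shift invariance and normalization", {
  expect_equal(softmax(rep(3.7, 5)), rep(1 / 5, 5))
  expect_equal(softmax(c(0, log(2))), c(1 / 3, 2 / 3), tolerance = 1e-12)
  set.seed(2)
  x <- rnorm(7) * 10
  expect_equal(softmax(x), softmax(x + 123.4), tolerance = 1e-12)
  expect_equal(sum(softmax(x)), 1, tolerance = 1e-12)
  expect_true(all(softmax(x) > 0))
  expect_error(softmax(numeric(0)), "empty")
  # large magnitudes do not overflow
  expect_equal(sum(softmax(c(1000, 1001))), 1, tolerance = 1e-12)
})

test_that("margin loss hand cases and monotonicity", {
  # confident-correct region: exactly zero
  expect_identical(margin_loss(c(1, 0), c(0.95, 0.05)), 0)
  # hand-evaluated: (0.9-0.3)^2 + 0.5*(0.8-0.1)^2 = 0.605
  expect_equal(margin_loss(c(1, 0), c(0.3, 0.8)), 0.36 + 0.5 * 0.49,
               tolerance = 1e-12)
  expect_error(margin_loss(c(1, 0), c(1, 0, 0)), "equal length")
  # non-increasing in the true-class activation, non-decreasing in others
  grid <- seq(0, 1, by = 0.05)
  l_true <- vapply(grid, function(g) margin_loss(c(1, 0), c(g, 0.5)), 0)
  l_false <- vapply(grid, function(g) margin_loss(c(1, 0), c(0.5, g)), 0)
  expect_true(all(diff(l_true) <= 1e-12))
  expect_true(all(diff(l_false) >= -1e-12))
  expect_true(all(l_true >= 0) && all(l_false >= 0))
  # batch form averages per-sample losses
  y <- rbind(c(1, 0), c(0, 1))
  yh <- rbind(c(0.3, 0.8), c(0.05, 0.95))
  expect_equal(margin_loss(y, yh), (0.605 + 0) / 2, tolerance = 1e-12)
})

test_that("dynamic routing matches the straight-line reference on small cases", {
  set.seed(42)
  for (case in 1:3) {
    N <- sample(2:5, 1)
    D <- sample(2:4, 1)
    K <- sample(1:3, 1)
    u <- matrix(rnorm(N * D), N, D)
    W <- array(rnorm(8 * D * N * K), c(8, D, N, K))
    got <- dynamic_routing(u, W, iterations = 3, epsilon = 1e-7)
    ref <- reference_routing(u, W, 3, 1e-7)
    expect_equal(t(got$v), ref$v, tolerance = 1e-9)
    expect_equal(got$couplings, ref$couplings, tolerance = 1e-9)
    expect_equal(got$activations, sqrt(colSums(ref$v^2)), tolerance = 1e-9)
  }
})

test_that("routing couplings are a probability distribution over classes", {
  set.seed(7)
  N <- 6; D <- 4; K <- 3
  u <- matrix(rnorm(N * D), N, D)
  W <- array(rnorm(16 * D * N * K), c(16, D, N, K))
  for (iters in 1:4) {
    r <- dynamic_routing(u, W, iterations = iters)
    expect_true(all(r$couplings >= 0))
    expect_equal(rowSums(r$couplings), rep(1, N), tolerance = 1e-9)
    expect_true(all(r$activations < 1))
  }
})

test_that("degenerate routing (one primary, one class) reduces to squash", {
  set.seed(8)
  u <- matrix(rnorm(4), 1, 4)
  W <- array(rnorm(16 * 4), c(16, 4, 1, 1))
  r <- dynamic_routing(u, W, iterations = 3)
  expect_equal(r$couplings, matrix(1, 1, 1))
  uhat <- as.numeric(matrix(W[, , 1, 1], 16, 4) %*% u[1, ])
  expect_equal(as.numeric(r$v), squash(uhat), tolerance = 1e-12)
})

test_that("primary capsules reshape and squash the feature volume", {
  set.seed(9)
  f <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  u <- primary_capsules(f, dim = 8)
  expect_equal(dim(u), c(12L, 8L)) # 96 / 8 capsules
  norms <- sqrt(rowSums(u^2))
  expect_true(all(norms < 1))
  # direction preserved per capsule relative to the raw reshape
  raw <- t(matrix(as.numeric(f), nrow = 8))
  cosine <- rowSums(u * raw) / (sqrt(rowSums(u^2) * rowSums(raw^2)))
  expect_equal(cosine, rep(1, 12), tolerance = 1e-9)
  # zero features give zero capsules; indivisible volumes are rejected
  expect_true(all(primary_capsules(array(0, c(2, 2, 4)), 4) == 0))
  expect_error(primary_capsules(array(0, c(3, 3, 3)), 8), "not divisible")
  # the full-size trace: 32x32x192 features at D = 8 -> 24,576 capsules
  expect_equal(nrow(primary_capsules(array(0, c(32, 32, 192)), 8)), 24576L)
})

test_that("routing rejects a non-positive iteration count", {
  u <- matrix(1, 2, 2)
  W <- array(1, c(4, 2, 2, 2))
  expect_error(dynamic_routing(u, W, iterations = 0), "at least one")
})
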