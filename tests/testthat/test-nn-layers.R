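# Correctness of the trainable-layer core: forward convolution against a
# naive direct-summation oracle, and analytic gradients against central
# finite differences.

naive_conv <- function(x, w, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, dim(x)[3], N))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, Co, N))
  for (n in 1:N) for (co in 1:Co) for (oi in 1:Ho) for (oj in 1:Wo) {
    patch <- xp[(oi - 1) * stride + seq_len(kh),
                (oj - 1) * stride + seq_len(kw), , n]
    y[oi, oj, co, n] <- sum(patch * w[, , , co])
  }
  y
}

test_that("compiled convolution matches the direct-summation oracle", {
  set.seed(10)
  cases <- list(list(k = 3, stride = 1, pad = 1), list(k = 3, stride = 2, pad = 0),
                list(k = 7, stride = 2, pad = 3), list(k = 1, stride = 1, pad = 0))
  for (cs in cases) {
    x <- array(rnorm(9 * 9 * 2 * 3), c(9, 9, 2, 3))
    w <- array(rnorm(cs$k^2 * 2 * 4), c(cs$k, cs$k, 2, 4))
    got <- ns$conv2d_forward_cpp(x, w, cs$stride, cs$pad)
    expect_equal(got, naive_conv(x, w, cs$stride, cs$pad), tolerance = 1e-12)
  }
})

fd_layer_check <- function(l, x, n_probes = 5, tol = 1e-3) {
  set.seed(99)
  lw <- array(rnorm(length(ns$ly_fwd(l, x, TRUE))), dim(ns$ly_fwd(l, x, TRUE)))
  loss <- function(xx) sum(ns$ly_fwd(l, xx, TRUE) * lw)
  ns$zero_grads(list(l))
  ns$ly_fwd(l, x, TRUE)
  dx <- ns$ly_bwd(l, lw)
  for (nm in names(l$params)) {
    p <- l$params[[nm]]
    for (i in sample(length(p), min(n_probes, length(p)))) {
      e <- 1e-5
      l$params[[nm]][i] <- p[i] + e; fp <- loss(x)
      l$params[[nm]][i] <- p[i] - e; fm <- loss(x)
      l$params[[nm]][i] <- p[i]
      num <- (fp - fm) / (2 * e)
      expect_equal(l$grads[[nm]][i], num, tolerance = tol,
                   label = paste(l$kind, nm, "param grad"))
    }
  }
  for (i in sample(length(x), n_probes)) {
    e <- 1e-5
    x2 <- x; x2[i] <- x[i] + e; fp <- loss(x2)
    x2[i] <- x[i] - e; fm <- loss(x2)
    num <- (fp - fm) / (2 * e)
    expect_equal(dx[i], num, tolerance = max(tol, 1e-6 * abs(num) + 1e-7),
                 label = paste(l$kind, "input grad"))
  }
}

test_that("layer backward passes agree with finite differences", {
  set.seed(11)
  fd_layer_check(ns$layer_conv(3, 3, 2, 4, pad = 1),
                 array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2)))
  fd_layer_check(ns$layer_conv(7, 7, 3, 4, stride = 2, bias = FALSE,
                               init = "glorot_normal"),
                 array(rnorm(9 * 9 * 3 * 2), c(9, 9, 3, 2)))
  fd_layer_check(ns$layer_convt(2, 3, 2),
                 array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2)))
  fd_layer_check(ns$layer_bn(3), array(rnorm(5 * 5 * 3 * 4), c(5, 5, 3, 4)))
  fd_layer_check(ns$layer_dense(4, 3), matrix(rnorm(5 * 4), 5, 4))
})

test_that("max-pool routes gradient only to the argmax positions", {
  set.seed(12)
  l <- ns$layer_maxpool(2)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  y <- ns$ly_fwd(l, x, TRUE)
  expect_equal(dim(y), c(3, 3, 2, 2))
  lw <- array(rnorm(length(y)), dim(y))
  dx <- ns$ly_bwd(l, lw)
  expect_equal(sum(dx != 0), length(y)) # distinct maxima almost surely
  expect_equal(sum(dx), sum(lw), tolerance = 1e-12)
  # perturbing a non-selected input never changes the output
  i <- which(dx == 0)[1]
  x2 <- x; x2[i] <- x2[i] - 0.5 * abs(x2[i]) - 0.1
  expect_equal(ns$ly_fwd(l, x2, TRUE), y)
})

test_that("batch norm normalizes per channel in training mode", {
  set.seed(13)
  l <- ns$layer_bn(4)
  x <- array(rnorm(8 * 8 * 4 * 5, mean = 3, sd = 2), c(8, 8, 4, 5))
  y <- ns$ly_fwd(l, x, TRUE)
  for (c in 1:4) {
    expect_equal(mean(y[, , c, ]), 0, tolerance = 1e-8)
    expect_equal(stats::sd(y[, , c, ]), 1, tolerance = 1e-2)
  }
})

test_that("Adam descends a quadratic and dropout rescales at train time", {
  l <- ns$layer_dense(2, 1)
  l$params$w <- matrix(c(5, -3), 2, 1)
  for (t in 1:300) {
    ns$zero_grads(list(l))
    l$grads$w <- 2 * l$params$w  # grad of ||w||^2
    l$grads$b <- 2 * l$params$b
    ns$adam_step(list(l), 0.05, t)
  }
  expect_lt(sum(l$params$w^2), 1e-4)
  set.seed(14)
  d <- ns$layer_dropout(0.4)
  x <- array(1, c(10, 10, 2, 3))
  y <- ns$ly_fwd(d, x, TRUE)
  expect_setequal(unique(as.numeric(y)), c(0, 1 / 0.6))
  expect_equal(mean(y), 1, tolerance = 0.1)
  expect_identical(ns$ly_fwd(d, x, FALSE), x) # inference: identity
})
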