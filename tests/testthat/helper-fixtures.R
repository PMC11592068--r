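# Shared fixtures and small oracles, all built in code at test time.

ns <- asNamespace("ucapsnet")

# write a tiny BUSI-style dataset directory and return its path
make_png_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  for (cl in c("benign", "malignant", "normal")) {
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
  }
  px <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  m1 <- matrix(0, 64, 64); m1[10:30, 10:30] <- 1
  m2 <- matrix(0, 64, 64); m2[40:60, 40:60] <- 1
  png::writePNG(px, file.path(dir, "benign", "b1.png"))
  png::writePNG(m1, file.path(dir, "benign", "b1_mask.png"))
  png::writePNG(t(px), file.path(dir, "benign", "b2.png"))
  png::writePNG(m2, file.path(dir, "benign", "b2_mask.png"))
  png::writePNG(px, file.path(dir, "malignant", "m1.png"))
  png::writePNG(m2, file.path(dir, "malignant", "m1_mask.png"))
  png::writePNG(px, file.path(dir, "normal", "n1.png"))
  dir
}

random_mask <- function(n = 16) matrix(rbinom(n * n, 1, 0.4), n, n)

# straight-line scalar-loop reference for routing by agreement, written
# independently of the package implementation (no shared helpers)
reference_routing <- function(u, W, iterations, epsilon) {
  N <- nrow(u); D <- ncol(u); Dc <- dim(W)[1]; K <- dim(W)[4]
  uhat <- array(0, c(Dc, N, K))
  for (i in 1:N) for (j in 1:K) for (m in 1:Dc) {
    acc <- 0
    for (d in 1:D) acc <- acc + W[m, d, i, j] * u[i, d]
    uhat[m, i, j] <- acc
  }
  b <- matrix(0, N, K)
  v <- matrix(0, Dc, K)
  cc <- matrix(0, N, K)
  for (it in 1:iterations) {
    for (i in 1:N) {
      mx <- max(b[i, ])
      ex <- exp(b[i, ] - mx)
      cc[i, ] <- ex / sum(ex)
    }
    for (j in 1:K) {
      s <- numeric(Dc)
      for (i in 1:N) for (m in 1:Dc) s[m] <- s[m] + cc[i, j] * uhat[m, i, j]
      n2 <- sum(s^2)
      v[, j] <- (n2 / (1 + n2)) * s / (sqrt(n2) + epsilon)
    }
    if (it < iterations) {
      for (i in 1:N) for (j in 1:K) {
        agree <- 0
        for (m in 1:Dc) agree <- agree + uhat[m, i, j] * v[m, j]
        b[i, j] <- b[i, j] + agree
      }
    }
  }
  list(v = v, couplings = cc)
}
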