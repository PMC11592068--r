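# Minimal trainable-layer framework backing both networks.
#
# Activations are 4-D arrays (H, W, C, N); kernels are (kh, kw, Cin, Cout).
# A layer is a mutable environment holding its parameters, their gradients
# (accumulated by ly_bwd), Adam moments and the forward cache. Convolutions,
# transpose convolutions and max-pooling call into compiled code; everything
# else is vectorized R.

he_normal <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))

glorot_normal <- function(n, fan_in, fan_out) {
  stats::rnorm(n, sd = sqrt(2 / (fan_in + fan_out)))
}

init_kernel <- function(dims, fan_in, fan_out, init) {
  vals <- switch(init,
    he_normal = he_normal(prod(dims), fan_in),
    glorot_normal = glorot_normal(prod(dims), fan_in, fan_out),
    stop("unknown initializer: ", init)
  )
  array(vals, dim = dims)
}

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$params)) e$params <- list()
  e$grads <- list()
  e$adam_m <- NULL
  class(e) <- c(paste0("layer_", .kind), "nn_layer")
  e
}

layer_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L,
                       bias = TRUE, init = "he_normal") {
  w <- init_kernel(c(kh, kw, cin, cout), kh * kw * cin, kh * kw * cout, init)
  params <- list(w = w)
  if (bias) params$b <- numeric(cout)
  new_layer("conv", params = params, stride = as.integer(stride),
            pad = as.integer(pad), bias = bias)
}

layer_convt <- function(k, cin, cout, stride = k, bias = TRUE,
                        init = "he_normal") {
  # fan_in per output unit of a stride-k transpose conv is cin (each output
  # pixel receives exactly one kernel tap when stride == k)
  w <- init_kernel(c(k, k, cin, cout), cin * k * k / (stride * stride),
                   cout * k * k / (stride * stride), init)
  params <- list(w = w)
  if (bias) params$b <- numeric(cout)
  new_layer("convt", params = params, stride = as.integer(stride), bias = bias)
}

layer_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  new_layer("bn",
    params = list(gamma = rep(1, c), beta = numeric(c)),
    c = as.integer(c), momentum = momentum, eps = eps,
    running_mean = numeric(c), running_var = rep(1, c))
}

layer_relu <- function() new_layer("relu")

layer_dropout <- function(rate) new_layer("dropout", rate = rate)

layer_pad <- function(p) new_layer("pad", p = as.integer(p))

layer_maxpool <- function(k, stride = k) {
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride))
}

layer_dense <- function(cin, cout, init = "glorot_normal") {
  new_layer("dense",
    params = list(w = matrix(switch(init,
        glorot_normal = glorot_normal(cin * cout, cin, cout),
        he_normal = he_normal(cin * cout, cin)), cin, cout),
      b = numeric(cout)))
}

# broadcast a per-channel vector over an (H, W, C, N) array
bc_chan <- function(v, hw) rep(v, each = hw)

chan_sums <- function(x) {
  d <- dim(x)
  m <- matrix(colSums(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
  rowSums(m)
}

ly_fwd <- function(l, x, training = TRUE) {
  switch(l$kind,
    conv = {
      l$x <- x
      y <- conv2d_forward_cpp(x, l$params$w, l$stride, l$pad)
      if (l$bias) {
        d <- dim(y)
        y <- y + bc_chan(l$params$b, d[1] * d[2])
      }
      y
    },
    convt = {
      l$x <- x
      y <- convt2d_forward_cpp(x, l$params$w, l$stride)
      if (l$bias) {
        d <- dim(y)
        y <- y + bc_chan(l$params$b, d[1] * d[2])
      }
      y
    },
    bn = {
      d <- dim(x)
      hw <- d[1] * d[2]
      m <- d[1] * d[2] * d[4]
      if (training) {
        cs <- matrix(colSums(matrix(x, nrow = hw)), d[3], d[4])
        mu <- rowSums(cs) / m
        cs2 <- matrix(colSums(matrix(x * x, nrow = hw)), d[3], d[4])
        va <- rowSums(cs2) / m - mu^2
        va <- pmax(va, 0)
        l$running_mean <- l$momentum * l$running_mean + (1 - l$momentum) * mu
        l$running_var <- l$momentum * l$running_var + (1 - l$momentum) * va
      } else {
        mu <- l$running_mean
        va <- l$running_var
      }
      inv_std <- 1 / sqrt(va + l$eps)
      xhat <- (x - bc_chan(mu, hw)) * bc_chan(inv_std, hw)
      if (training) {
        l$xhat <- xhat
        l$inv_std <- inv_std
        l$m <- m
      }
      xhat * bc_chan(l$params$gamma, hw) + bc_chan(l$params$beta, hw)
    },
    relu = {
      l$mask <- x > 0
      x * l$mask
    },
    dropout = {
      if (training && l$rate > 0) {
        l$mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
        y <- x * l$mask
        dim(y) <- dim(x)
        y
      } else x
    },
    pad = {
      d <- dim(x)
      p <- l$p
      l$d <- d
      y <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
      y[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
      y
    },
    maxpool = {
      l$xdim <- dim(x)
      r <- maxpool_forward_cpp(x, l$k, l$stride)
      l$idx <- r$idx
      r$y
    },
    dense = {
      l$x <- x # (N, cin)
      sweep(x %*% l$params$w, 2, l$params$b, "+")
    },
    stop("unknown layer kind: ", l$kind)
  )
}

acc_grad <- function(l, nm, g) {
  if (is.null(l$grads[[nm]])) l$grads[[nm]] <- g
  else l$grads[[nm]] <- l$grads[[nm]] + g
}

ly_bwd <- function(l, dy) {
  switch(l$kind,
    conv = {
      g <- conv2d_backward_cpp(l$x, l$params$w, dy, l$stride, l$pad)
      acc_grad(l, "w", g$dw)
      if (l$bias) acc_grad(l, "b", chan_sums(dy))
      g$dx
    },
    convt = {
      g <- convt2d_backward_cpp(l$x, l$params$w, dy, l$stride)
      acc_grad(l, "w", g$dw)
      if (l$bias) acc_grad(l, "b", chan_sums(dy))
      g$dx
    },
    bn = {
      d <- dim(dy)
      hw <- d[1] * d[2]
      dgamma <- chan_sums(dy * l$xhat)
      dbeta <- chan_sums(dy)
      acc_grad(l, "gamma", dgamma)
      acc_grad(l, "beta", dbeta)
      scale <- bc_chan(l$params$gamma * l$inv_std / l$m, hw)
      dx <- scale * (l$m * dy - bc_chan(dbeta, hw) - l$xhat * bc_chan(dgamma, hw))
      dim(dx) <- d
      dx
    },
    relu = dy * l$mask,
    dropout = {
      if (!is.null(l$mask)) {
        dx <- dy * l$mask
        dim(dx) <- dim(dy)
        dx
      } else dy
    },
    pad = {
      p <- l$p
      d <- l$d
      dy[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
    },
    maxpool = maxpool_backward_cpp(dy, l$idx, l$xdim),
    dense = {
      acc_grad(l, "w", crossprod(l$x, dy))
      acc_grad(l, "b", colSums(dy))
      dy %*% t(l$params$w)
    },
    stop("unknown layer kind: ", l$kind)
  )
}

zero_grads <- function(layers) {
  for (l in layers) l$grads <- list()
  invisible(NULL)
}

clear_caches <- function(layers) {
  for (l in layers) {
    l$x <- NULL; l$mask <- NULL; l$xhat <- NULL; l$idx <- NULL
  }
  invisible(NULL)
}

# One Adam update over every parameter of every layer. `t` is the global step
# counter (1-based) used for bias correction.
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (length(l$params) == 0) next
    if (is.null(l$adam_m)) {
      l$adam_m <- lapply(l$params, function(p) p * 0)
      l$adam_v <- lapply(l$params, function(p) p * 0)
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      l$adam_m[[nm]] <- beta1 * l$adam_m[[nm]] + (1 - beta1) * g
      l$adam_v[[nm]] <- beta2 * l$adam_v[[nm]] + (1 - beta2) * g * g
      mhat <- l$adam_m[[nm]] / (1 - beta1^t)
      vhat <- l$adam_v[[nm]] / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

n_params <- function(layers) {
  sum(vapply(layers, function(l) sum(lengths(l$params)), numeric(1)))
}
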