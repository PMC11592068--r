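#' Capsule classifier configuration
#'
#' Describes the mask classifier: a padded convolutional stem (7x7 stride-2
#' convolution, the only standard configuration consistent with a 9408-weight
#' first layer on three-channel input, followed by batch norm, ReLU, padding
#' and a 3x3 stride-2 max-pool), a DenseNet-style block of
#' `dense_layers` composite layers (1x1 bottleneck convolution to
#' `4 * growth_rate` channels then 3x3 convolution to `growth_rate`
#' channels, concatenated with the layer input), primary capsules of
#' dimension `primary_caps_dim` obtained by reshaping and squashing the
#' feature volume, dynamic routing by agreement to `n_classes` class
#' capsules of dimension `class_caps_dim`, and a dense softmax head on the
#' class-capsule norms. Margin-loss hyperparameters follow the usual capsule
#' network convention.
#'
#' @param input_size square input size, divisible by 4 (default 128).
#' @param stem_filters stem convolution filters (default 64).
#' @param growth_rate channels added by each composite layer (default 32).
#' @param dense_layers number of composite layers (default 4).
#' @param primary_caps_dim primary capsule dimension D (default 8).
#' @param class_caps_dim class capsule dimension (default 16).
#' @param n_classes number of output classes (default 2).
#' @param routing_iterations routing-by-agreement iterations (>= 1).
#' @param m_plus,m_minus,lambda_down margin-loss parameters, with
#'   `0 < m_minus < m_plus < 1` and `lambda_down > 0`.
#' @param epsilon numerical guard in the squash nonlinearity (default 1e-7).
#' @param dropout_rate dropout on the feature volume before capsule
#'   formation (default 0.275).
#' @param weight_init kernel initializer (Glorot normal).
#' @param use_prelu apply a trainable PReLU to the aggregated class-capsule
#'   input before squashing (default `FALSE` = classical routing).
#' @return A `caps_config` list.
#' @export
caps_config <- function(input_size = 128L, stem_filters = 64L,
                        growth_rate = 32L, dense_layers = 4L,
                        primary_caps_dim = 8L, class_caps_dim = 16L,
                        n_classes = 2L, routing_iterations = 3L,
                        m_plus = 0.9, m_minus = 0.1, lambda_down = 0.5,
                        epsilon = 1e-7, dropout_rate = 0.275,
                        weight_init = "glorot_normal", use_prelu = FALSE) {
  stopifnot(input_size %% 4 == 0, input_size >= 16,
            m_minus > 0, m_minus < m_plus, m_plus < 1, lambda_down > 0,
            epsilon > 0, routing_iterations >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  weight_init <- match.arg(weight_init, "glorot_normal")
  out_ch <- stem_filters + dense_layers * growth_rate
  vol <- (input_size / 4)^2 * out_ch
  if (vol %% primary_caps_dim != 0)
    stop("feature volume ", vol, " is not divisible by primary_caps_dim ",
         primary_caps_dim)
  structure(list(input_size = as.integer(input_size),
                 stem_filters = as.integer(stem_filters),
                 growth_rate = as.integer(growth_rate),
                 dense_layers = as.integer(dense_layers),
                 primary_caps_dim = as.integer(primary_caps_dim),
                 class_caps_dim = as.integer(class_caps_dim),
                 n_classes = as.integer(n_classes),
                 routing_iterations = as.integer(routing_iterations),
                 m_plus = m_plus, m_minus = m_minus,
                 lambda_down = lambda_down, epsilon = epsilon,
                 dropout_rate = dropout_rate, weight_init = weight_init,
                 use_prelu = use_prelu),
            class = "caps_config")
}

caps_dims <- function(config) {
  s4 <- config$input_size %/% 4L
  ch <- config$stem_filters + config$dense_layers * config$growth_rate
  list(s4 = s4, channels = ch,
       n_caps = as.integer(s4 * s4 * ch / config$primary_caps_dim))
}

#' Squash nonlinearity
#'
#' Rescales a vector's norm into `[0, 1)` while preserving its direction:
#' `squash(s) = (||s||^2 / (1 + ||s||^2)) * s / (||s|| + epsilon)`.
#'
#' @param s numeric vector (one capsule), or a matrix whose columns are
#'   capsules.
#' @param epsilon numerical guard (default 1e-7).
#' @return Object of the same shape with every capsule norm in `[0, 1)`.
#' @export
squash <- function(s, epsilon = 1e-7) {
  stopifnot(epsilon > 0)
  if (!all(is.finite(s))) stop("squash requires finite input")
  if (is.matrix(s)) return(squash_cols(s, epsilon))
  n2 <- sum(s * s)
  n <- sqrt(n2)
  s * (n2 / (1 + n2)) / (n + epsilon)
}

# columnwise squash; m is (D, N)
squash_cols <- function(m, epsilon) {
  n2 <- colSums(m * m)
  n <- sqrt(n2)
  q <- (n2 / (1 + n2)) / (n + epsilon)
  m * rep(q, each = nrow(m))
}

# columnwise backward: given input m and upstream dv, return ds.
# v = q(n) * s with q = n^2 / ((1 + n^2)(n + eps));
# ds = q * dv + q'(n)/n * (s . dv) * s
squash_cols_backward <- function(m, dv, epsilon) {
  n2 <- colSums(m * m)
  n <- sqrt(n2)
  A <- n2
  B <- (1 + n2) * (n + epsilon)
  q <- A / B
  dq <- (2 * n * B - A * (2 * n * (n + epsilon) + (1 + n2))) / (B * B)
  sdot <- colSums(m * dv)
  coef <- ifelse(n > 1e-12, dq * sdot / n, 0)
  dv * rep(q, each = nrow(m)) + m * rep(coef, each = nrow(m))
}

#' Numerically stable softmax
#'
#' @param x numeric vector, or matrix (softmax applied to each row).
#' @return Probabilities of the same shape; each vector sums to 1.
#' @export
softmax <- function(x) {
  if (length(x) == 0) stop("softmax of an empty vector")
  if (!all(is.finite(x))) stop("softmax requires finite input")
  if (is.matrix(x)) {
    z <- exp(x - apply(x, 1, max))
    return(z / rowSums(z))
  }
  z <- exp(x - max(x))
  z / sum(z)
}

#' Margin loss for capsule classification
#'
#' Per-class squared hinge loss: true classes are penalized when their
#' activation falls below `m_plus`, false classes when theirs exceeds
#' `m_minus` (down-weighted by `lambda_down`):
#' `L = sum_k y_k max(0, m+ - yhat_k)^2 +
#'      lambda sum_k (1 - y_k) max(0, yhat_k - m-)^2`.
#' For matrix input (rows = samples) the batch loss is the mean of the
#' per-sample losses.
#'
#' @param y one-hot vector (or matrix of one-hot rows).
#' @param y_hat predicted activations in `[0, 1]`, same shape as `y`.
#' @param m_plus,m_minus,lambda_down margin parameters.
#' @return Non-negative scalar.
#' @export
margin_loss <- function(y, y_hat, m_plus = 0.9, m_minus = 0.1,
                        lambda_down = 0.5) {
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  term <- y * pmax(0, m_plus - y_hat)^2 +
    lambda_down * (1 - y) * pmax(0, y_hat - m_minus)^2
  if (is.matrix(y)) mean(rowSums(term)) else sum(term)
}

# gradient of the batch margin loss w.r.t. y_hat (matrix, rows = samples)
margin_loss_grad <- function(y, y_hat, m_plus, m_minus, lambda_down) {
  (-2 * y * pmax(0, m_plus - y_hat) +
     2 * lambda_down * (1 - y) * pmax(0, y_hat - m_minus)) / nrow(y)
}

#' Build the stem architecture trace
#'
#' The entry block of the capsule classifier: zero-pad 3 per side, 7x7
#' stride-2 convolution (no bias) to `stem_filters` maps, batch norm, ReLU,
#' zero-pad 1 per side, and 3x3 stride-2 max-pooling. With the default
#' 128x128x3 input the trace is 134x134x3 -> 64x64x64 (9408 weights) ->
#' 66x66x64 -> 32x32x64.
#'
#' @param config a [caps_config].
#' @return A `network_spec` fragment.
#' @export
build_stem <- function(config = caps_config()) {
  stopifnot(inherits(config, "caps_config"))
  s <- config$input_size
  f <- config$stem_filters
  rows <- list(
    spec_row("input", "input", c(s, s, 3)),
    spec_row("stem_pad1", "zeropad3", c(s + 6, s + 6, 3)),
    spec_row("stem_conv", "conv7x7s2", c(s / 2, s / 2, f), 7 * 7 * 3 * f),
    spec_row("stem_bn", "batchnorm", c(s / 2, s / 2, f), 4 * f),
    spec_row("stem_relu", "relu", c(s / 2, s / 2, f)),
    spec_row("stem_pad2", "zeropad1", c(s / 2 + 2, s / 2 + 2, f)),
    spec_row("stem_pool", "maxpool3x3s2", c(s / 4, s / 4, f)))
  new_network_spec(do.call(rbind, rows), config)
}

dense_block_rows <- function(config) {
  s4 <- config$input_size %/% 4L
  g <- config$growth_rate
  cin <- config$stem_filters
  rows <- list()
  for (l in seq_len(config$dense_layers)) {
    rows <- c(rows, list(
      spec_row(paste0("dense", l, "_bn1"), "batchnorm", c(s4, s4, cin), 4 * cin),
      spec_row(paste0("dense", l, "_relu1"), "relu", c(s4, s4, cin)),
      spec_row(paste0("dense", l, "_conv1"), "conv1x1", c(s4, s4, 4 * g),
               cin * 4 * g),
      spec_row(paste0("dense", l, "_bn2"), "batchnorm", c(s4, s4, 4 * g),
               4 * 4 * g),
      spec_row(paste0("dense", l, "_relu2"), "relu", c(s4, s4, 4 * g)),
      spec_row(paste0("dense", l, "_conv2"), "conv3x3", c(s4, s4, g),
               3 * 3 * 4 * g * g),
      spec_row(paste0("dense", l, "_concat"), "concat", c(s4, s4, cin + g))))
    cin <- cin + g
  }
  rows
}

#' Build the full capsule classifier architecture trace
#'
#' Stem, dense block, batch norm + dropout, primary capsules, dynamic
#' routing and the dense softmax head, as a queryable [network_spec].
#'
#' @param config a [caps_config].
#' @return A `network_spec`.
#' @export
build_capsnet <- function(config = caps_config()) {
  stopifnot(inherits(config, "caps_config"))
  dm <- caps_dims(config)
  K <- config$n_classes
  D <- config$primary_caps_dim
  Dc <- config$class_caps_dim
  stem <- build_stem(config)
  rows <- lapply(seq_len(nrow(stem$layers)), function(i) stem$layers[i, ])
  rows <- c(rows, dense_block_rows(config), list(
    spec_row("caps_bn", "batchnorm", c(dm$s4, dm$s4, dm$channels),
             4 * dm$channels),
    spec_row("caps_dropout", "dropout", c(dm$s4, dm$s4, dm$channels)),
    spec_row("primary_caps", "reshape-squash", c(dm$n_caps, D)),
    spec_row("routing", "dynamic_routing", c(K, Dc),
             Dc * D * dm$n_caps * K + if (config$use_prelu) 1 else 0),
    spec_row("caps_norm", "norm", c(K)),
    spec_row("head", "dense", c(K), K * K + K),
    spec_row("softmax", "softmax", c(K))))
  new_network_spec(do.call(rbind, rows), config)
}

#' Form primary capsules from a convolutional feature volume
#'
#' Reshapes an `H x W x C` feature array (in storage order) into
#' `H*W*C / dim` capsules of dimension `dim` and applies the squash
#' nonlinearity to each, so that every capsule norm lies in `[0, 1)` and can
#' be read as an entity-presence probability.
#'
#' @param features numeric array `H x W x C` (or any array whose length is
#'   divisible by `dim`).
#' @param dim capsule dimension D.
#' @param epsilon squash guard.
#' @return Matrix `N x dim` of squashed capsule vectors (rows = capsules).
#' @export
primary_capsules <- function(features, dim = 8L, epsilon = 1e-7) {
  n <- length(features)
  if (n %% dim != 0)
    stop("feature volume of ", n, " values is not divisible by capsule ",
         "dimension ", dim)
  u <- matrix(as.numeric(features), nrow = dim)
  t(squash_cols(u, epsilon))
}

#' Dynamic routing by agreement
#'
#' Routes `N` primary capsules of dimension `D` to `K` class capsules of
#' dimension `D_out`. Prediction vectors are `u_hat[, i, j] = W[, , i, j]
#' %*% u[i, ]`; routing logits start at zero; each iteration computes
#' coupling coefficients `c_i = softmax(b_i)` over classes, aggregates
#' `s_j = sum_i c_ij u_hat_ij`, squashes `v_j = squash(s_j)`, and updates
#' the logits with the agreement `u_hat_ij . v_j`. Every row of the
#' coupling matrix sums to one at every iteration.
#'
#' @param primaries matrix of primary capsules, `N x D` (rows = capsules).
#' @param weights transformation array, dim `c(D_out, D, N, K)`.
#' @param iterations number of routing rounds (>= 1).
#' @param epsilon squash guard.
#' @param prelu_alpha optional PReLU slope applied to the aggregated input
#'   before squashing (`NULL` for classical routing).
#' @return List with `v` (`K x D_out` class capsules), `activations`
#'   (their norms, length `K`), and `couplings` (`N x K`).
#' @export
dynamic_routing <- function(primaries, weights, iterations = 3L,
                            epsilon = 1e-7, prelu_alpha = NULL) {
  if (iterations < 1) stop("routing requires at least one iteration")
  stopifnot(is.matrix(primaries), length(dim(weights)) == 4)
  r <- routing_forward(t(primaries), weights, iterations, epsilon, prelu_alpha)
  list(v = t(r$v), activations = sqrt(colSums(r$v^2)), couplings = r$c)
}

# routing iterations given precomputed prediction vectors uhat (D_out, N, K);
# returns v (D_out, K), c (N, K), s (post-PReLU), sraw.
# `agg_scale` rescales the aggregated input (the model uses 1/sqrt(N) so the
# class-capsule input stays in squash's responsive range regardless of the
# number of primaries; equivalent to rescaling the routing weights).
routing_iterate <- function(uhat, iterations, epsilon, prelu_alpha = NULL,
                            agg_scale = 1) {
  do <- dim(uhat)[1]
  N <- dim(uhat)[2]
  K <- dim(uhat)[3]
  b <- matrix(0, N, K)
  v <- matrix(0, do, K)
  s <- matrix(0, do, K)
  sraw <- matrix(0, do, K)
  cc <- NULL
  for (r in seq_len(iterations)) {
    cc <- if (K == 1) matrix(1, N, 1) else softmax(b)
    for (j in seq_len(K)) {
      sj <- (matrix(uhat[, , j], do, N) %*% cc[, j]) * agg_scale
      sraw[, j] <- sj
      if (!is.null(prelu_alpha)) sj <- pmax(sj, 0) + prelu_alpha * pmin(sj, 0)
      s[, j] <- sj
      v[, j] <- squash(as.numeric(sj), epsilon)
    }
    if (r < iterations) {
      for (j in seq_len(K)) {
        b[, j] <- b[, j] + as.numeric(crossprod(matrix(uhat[, , j], do, N),
                                                v[, j]))
      }
    }
  }
  list(v = v, c = cc, s = s, sraw = sraw)
}

# internal routing; u is (D, N); W is (D_out, D, N, K)
routing_forward <- function(u, W, iterations, epsilon, prelu_alpha = NULL) {
  uhat <- caps_uhat_cpp(W, array(u, c(dim(u), 1)))
  dim(uhat) <- dim(uhat)[1:3]
  r <- routing_iterate(uhat, iterations, epsilon, prelu_alpha)
  r$uhat <- uhat
  r
}

# Instantiate the trainable capsule classifier (consumes the RNG stream).
create_capsnet <- function(config) {
  dm <- caps_dims(config)
  g <- config$growth_rate
  init <- config$weight_init
  L <- list()
  L$stem_pad1 <- layer_pad(3)
  L$stem_conv <- layer_conv(7, 7, 3, config$stem_filters, stride = 2,
                            bias = FALSE, init = init)
  L$stem_bn <- layer_bn(config$stem_filters)
  L$stem_relu <- layer_relu()
  L$stem_pad2 <- layer_pad(1)
  L$stem_pool <- layer_maxpool(3, 2)
  cin <- config$stem_filters
  for (l in seq_len(config$dense_layers)) {
    L[[paste0("dense", l, "_bn1")]] <- layer_bn(cin)
    L[[paste0("dense", l, "_relu1")]] <- layer_relu()
    L[[paste0("dense", l, "_conv1")]] <- layer_conv(1, 1, cin, 4 * g,
                                                    bias = FALSE, init = init)
    L[[paste0("dense", l, "_bn2")]] <- layer_bn(4 * g)
    L[[paste0("dense", l, "_relu2")]] <- layer_relu()
    L[[paste0("dense", l, "_conv2")]] <- layer_conv(3, 3, 4 * g, g, pad = 1,
                                                    bias = FALSE, init = init)
    cin <- cin + g
  }
  L$caps_bn <- layer_bn(cin)
  L$caps_dropout <- layer_dropout(config$dropout_rate)
  D <- config$primary_caps_dim
  Dc <- config$class_caps_dim
  K <- config$n_classes
  routing <- new_layer("routing", params = list(
    W = array(glorot_normal(Dc * D * dm$n_caps * K, D, Dc),
              dim = c(Dc, D, dm$n_caps, K))))
  if (config$use_prelu) routing$params$alpha <- 0.25
  L$routing <- routing
  # calibration head starts at identity: probabilities initially follow the
  # class-capsule activations, and cross-entropy refines the mapping
  L$head <- layer_dense(K, K)
  L$head$params$w <- diag(K)
  structure(list(layers = L, config = config), class = "caps_model")
}

# forward through stem + dense block + bn + dropout; x is (H, W, 3, N)
caps_features <- function(model, x, training) {
  L <- model$layers
  for (nm in c("stem_pad1", "stem_conv", "stem_bn", "stem_relu",
               "stem_pad2", "stem_pool")) {
    x <- ly_fwd(L[[nm]], x, training)
  }
  for (l in seq_len(model$config$dense_layers)) {
    t <- x
    for (nm in paste0("dense", l, c("_bn1", "_relu1", "_conv1", "_bn2",
                                    "_relu2", "_conv2"))) {
      t <- ly_fwd(L[[nm]], t, training)
    }
    x <- concat_c(x, t)
  }
  x <- ly_fwd(L$caps_bn, x, training)
  ly_fwd(L$caps_dropout, x, training)
}

caps_features_backward <- function(model, dx) {
  L <- model$layers
  dx <- ly_bwd(L$caps_dropout, dx)
  dx <- ly_bwd(L$caps_bn, dx)
  g <- model$config$growth_rate
  for (l in rev(seq_len(model$config$dense_layers))) {
    cin <- model$config$stem_filters + (l - 1) * g
    dt <- dx[, , cin + seq_len(g), , drop = FALSE]
    dx <- dx[, , seq_len(cin), , drop = FALSE]
    for (nm in paste0("dense", l, c("_conv2", "_relu2", "_bn2", "_conv1",
                                    "_relu1", "_bn1"))) {
      dt <- ly_bwd(L[[nm]], dt)
    }
    dx <- dx + dt
  }
  for (nm in rev(c("stem_pad1", "stem_conv", "stem_bn", "stem_relu",
                   "stem_pad2", "stem_pool"))) {
    dx <- ly_bwd(L[[nm]], dx)
  }
  dx
}

# full forward; returns list(p, cache)
caps_forward <- function(model, x, training = TRUE) {
  cfg <- model$config
  dm <- caps_dims(cfg)
  D <- cfg$primary_caps_dim
  Dc <- cfg$class_caps_dim
  K <- cfg$n_classes
  B <- dim(x)[4]
  feat <- caps_features(model, x, training)
  fdim <- dim(feat)
  u_raw <- feat
  dim(u_raw) <- c(D, dm$n_caps, B)
  u <- u_raw
  dim(u) <- c(D, dm$n_caps * B)
  u <- squash_cols(u, cfg$epsilon)
  dim(u) <- c(D, dm$n_caps, B)
  W <- model$layers$routing$params$W
  alpha <- if (cfg$use_prelu) model$layers$routing$params$alpha else NULL
  uhat_all <- caps_uhat_cpp(W, u)
  agg_scale <- 1 / sqrt(dm$n_caps)
  a <- matrix(0, B, K)
  routs <- vector("list", B)
  for (bi in seq_len(B)) {
    r <- routing_iterate(array(uhat_all[, , , bi], dim(uhat_all)[1:3]),
                         cfg$routing_iterations, cfg$epsilon, alpha,
                         agg_scale = agg_scale)
    routs[[bi]] <- r
    a[bi, ] <- sqrt(colSums(r$v^2))
  }
  logits <- ly_fwd(model$layers$head, a, training)
  p <- softmax(logits)
  list(p = p, a = a, cache = list(u_raw = u_raw, u = u, routs = routs, a = a,
                                  fdim = fdim, B = B))
}

# backward pass; `da` is the gradient w.r.t. the class-capsule activations
# (norms) and `dlogits_head` the gradient w.r.t. the calibration head's
# logits. The head reads the activations as data (no gradient flows from the
# head back into the capsules), so the margin loss alone shapes the capsule
# geometry.
caps_backward <- function(model, cache, da, dlogits_head = NULL) {
  cfg <- model$config
  dm <- caps_dims(cfg)
  D <- cfg$primary_caps_dim
  Dc <- cfg$class_caps_dim
  K <- cfg$n_classes
  B <- cache$B
  if (!is.null(dlogits_head)) ly_bwd(model$layers$head, dlogits_head)
  W <- model$layers$routing$params$W
  routing <- model$layers$routing
  dalpha <- 0
  ds_all <- array(0, c(Dc, K, B))
  cc_all <- array(0, c(dm$n_caps, K, B))
  for (bi in seq_len(B)) {
    r <- cache$routs[[bi]]
    dv <- r$v * rep(da[bi, ] / pmax(cache$a[bi, ], 1e-12), each = Dc)
    ds <- squash_cols_backward(r$s, dv, cfg$epsilon)
    if (cfg$use_prelu) {
      alpha <- routing$params$alpha
      neg <- r$sraw < 0
      dalpha <- dalpha + sum(ds * r$sraw * neg)
      ds <- ds * ((!neg) + alpha * neg)
    }
    ds_all[, , bi] <- ds / sqrt(dm$n_caps) # chain through the 1/sqrt(N) scale
    cc_all[, , bi] <- r$c # couplings treated as constant in the backward pass
  }
  g <- caps_routing_grad_cpp(W, cache$u, ds_all, cc_all)
  acc_grad(routing, "W", g$dW)
  if (cfg$use_prelu) acc_grad(routing, "alpha", dalpha)
  du_m <- g$du
  dim(du_m) <- c(D, dm$n_caps * B)
  u_raw_m <- cache$u_raw
  dim(u_raw_m) <- c(D, dm$n_caps * B)
  dfeat <- squash_cols_backward(u_raw_m, du_m, cfg$epsilon)
  dim(dfeat) <- cache$fdim
  caps_features_backward(model, dfeat)
}

one_hot <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  y
}

as_input_array <- function(x, size) {
  if (is.list(x)) {
    B <- length(x)
    X <- array(0, c(size, size, 3, B))
    for (i in seq_len(B)) X[, , , i] <- x[[i]]
    X
  } else if (length(dim(x)) == 3) {
    array(x, c(dim(x), 1))
  } else x
}

#' Train the capsule classifier
#'
#' Minimizes the mean margin loss on the class-capsule activations (their
#' vector norms) with Adam; a dense softmax calibration head is trained
#' jointly by cross-entropy on the (detached) activations and supplies the
#' reported class probabilities. The classifier is binary (benign vs
#' malignant); `normal`-labeled inputs are rejected. Glorot initialization,
#' batch order and dropout are driven by `tc$seed`.
#'
#' @param spec a `network_spec` from [build_capsnet] (or a [caps_config]).
#' @param x classifier inputs: a list of `size x size x 3` arrays (e.g. from
#'   [prepare_for_classifier]) or a 4-D array `(size, size, 3, N)`.
#' @param labels character/factor vector in `{benign, malignant}`.
#' @param tc a [train_config].
#' @return A `caps_model` with a `history` data.frame (epoch, loss,
#'   accuracy) and the class order in `$classes`.
#' @export
train_classifier <- function(spec, x, labels, tc) {
  config <- if (inherits(spec, "network_spec")) spec$config else spec
  stopifnot(inherits(config, "caps_config"), inherits(tc, "train_config"))
  labels <- as.character(labels)
  if (any(labels == "normal"))
    stop("the classifier is binary (benign vs malignant); ",
         "'normal' labels are not accepted")
  if (!all(labels %in% LESION_LABELS)) stop("unknown labels in input")
  classes <- LESION_LABELS
  X <- as_input_array(x, config$input_size)
  n <- dim(X)[4]
  if (n != length(labels)) stop("inputs and labels must have equal length")
  if (n == 0) stop("empty training set")
  Y <- one_hot(labels, classes)
  set.seed(tc$seed)
  model <- create_capsnet(config)
  model$classes <- classes
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  t_step <- 0L
  for (ep in seq_len(tc$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    hits <- 0
    for (start in seq(1, n, by = tc$batch_size)) {
      ix <- perm[start:min(start + tc$batch_size - 1, n)]
      xb <- X[, , , ix, drop = FALSE]
      yb <- Y[ix, , drop = FALSE]
      zero_grads(model$layers)
      fw <- caps_forward(model, xb, training = TRUE)
      losses <- c(losses, margin_loss(yb, fw$a, config$m_plus,
                                      config$m_minus, config$lambda_down))
      hits <- hits + sum(max.col(fw$p, ties.method = "first") ==
                           max.col(yb, ties.method = "first"))
      da <- margin_loss_grad(yb, fw$a, config$m_plus, config$m_minus,
                             config$lambda_down)
      # calibration head: cross-entropy on the softmax probabilities
      caps_backward(model, fw$cache, da, dlogits_head = (fw$p - yb) / nrow(yb))
      t_step <- t_step + 1L
      adam_step(model$layers, tc$learning_rate, t_step)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         accuracy = hits / n))
  }
  clear_caches(model$layers)
  model$history <- history
  model
}

#' Classify a mask image
#'
#' Runs the capsule classifier in inference mode (no dropout, batch-norm
#' moving statistics) and returns the argmax label with the softmax
#' probabilities.
#'
#' @param model a trained `caps_model`.
#' @param input a `size x size x 3` array, or a 4-D batch.
#' @return For a single input, `list(label, probabilities)`; for a batch, a
#'   list with `labels` and a probability matrix.
#' @export
predict_class <- function(model, input) {
  stopifnot(inherits(model, "caps_model"))
  single <- length(dim(input)) == 3
  X <- as_input_array(input, model$config$input_size)
  if (!all(dim(X)[1:3] == c(model$config$input_size, model$config$input_size, 3)))
    stop("input must be ", model$config$input_size, "x",
         model$config$input_size, "x3")
  fw <- caps_forward(model, X, training = FALSE)
  labs <- model$classes[max.col(fw$p, ties.method = "first")]
  colnames(fw$p) <- model$classes
  if (single) list(label = labs[1], probabilities = fw$p[1, ])
  else list(labels = labs, probabilities = fw$p)
}
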