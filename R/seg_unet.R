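#' Segmentation network configuration
#'
#' Describes the enhanced U-Net: `depth` encoder blocks of paired 3x3
#' convolutions (batch normalization after the first convolution, ReLU
#' activations) each followed by 2x2 max-pooling, a two-convolution
#' bottleneck with batch normalization, and `depth` decoder blocks
#' (2x2-stride-2 transpose convolution, concatenation with the matching
#' encoder skip, two 3x3 convolutions, dropout), closed by a 1x1 sigmoid
#' output convolution. Filters start at `base_filters` and double per block.
#'
#' @param input_size square input size; must be divisible by `2^depth`.
#' @param base_filters filters in the first encoder block (default 64).
#' @param depth number of encoder/decoder blocks (default 4).
#' @param dropout_rate decoder dropout rate in `[0, 1)` (default 0.3).
#' @param weight_init kernel initializer (He normal).
#' @param threshold probability threshold for mask binarization; the `>=`
#'   convention is used.
#' @return A `seg_config` list.
#' @export
seg_config <- function(input_size = 256L, base_filters = 64L, depth = 4L,
                       dropout_rate = 0.3, weight_init = "he_normal",
                       threshold = 0.5) {
  stopifnot(base_filters >= 1, depth >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            threshold > 0, threshold < 1)
  weight_init <- match.arg(weight_init, "he_normal")
  if (input_size %% 2^depth != 0)
    stop("input_size (", input_size, ") must be divisible by 2^depth (",
         2^depth, ")")
  structure(list(input_size = as.integer(input_size),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth), dropout_rate = dropout_rate,
                 weight_init = weight_init, threshold = threshold),
            class = "seg_config")
}

#' Build the enhanced U-Net architecture trace
#'
#' Constructs the layer-by-layer [network_spec] (shapes and parameter
#' counts) without instantiating weights. Encoder block `i` uses
#' `base_filters * 2^(i-1)` filters; the bottleneck reaches
#' `base_filters * 2^depth`; output spatial shape equals input shape.
#'
#' @param config a [seg_config].
#' @return A `network_spec`.
#' @export
build_enhanced_unet <- function(config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  s <- config$input_size
  f0 <- config$base_filters
  d <- config$depth
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  rows <- list(spec_row("input", "input", c(s, s, 1)))
  cin <- 1
  for (i in seq_len(d)) {
    f <- f0 * 2^(i - 1)
    rows <- c(rows, list(
      spec_row(paste0("enc", i, "_conv1"), "conv3x3-relu", c(s, s, f),
               conv_p(3, cin, f)),
      spec_row(paste0("enc", i, "_bn"), "batchnorm", c(s, s, f), 4 * f),
      spec_row(paste0("enc", i, "_conv2"), "conv3x3-relu", c(s, s, f),
               conv_p(3, f, f)),
      spec_row(paste0("enc", i, "_pool"), "maxpool2x2", c(s / 2, s / 2, f))))
    s <- s / 2
    cin <- f
  }
  fb <- f0 * 2^d
  rows <- c(rows, list(
    spec_row("bottleneck_conv1", "conv3x3-relu", c(s, s, fb), conv_p(3, cin, fb)),
    spec_row("bottleneck_conv2", "conv3x3-relu", c(s, s, fb), conv_p(3, fb, fb)),
    spec_row("bottleneck_bn", "batchnorm", c(s, s, fb), 4 * fb)))
  cin <- fb
  for (i in rev(seq_len(d))) {
    f <- f0 * 2^(i - 1)
    s <- s * 2
    rows <- c(rows, list(
      spec_row(paste0("dec", i, "_up"), "convtranspose2x2", c(s, s, f),
               conv_p(2, cin, f)),
      spec_row(paste0("dec", i, "_concat"), "concat", c(s, s, 2 * f)),
      spec_row(paste0("dec", i, "_conv1"), "conv3x3-relu", c(s, s, f),
               conv_p(3, 2 * f, f)),
      spec_row(paste0("dec", i, "_conv2"), "conv3x3-relu", c(s, s, f),
               conv_p(3, f, f)),
      spec_row(paste0("dec", i, "_dropout"), "dropout", c(s, s, f))))
    cin <- f
  }
  rows <- c(rows, list(
    spec_row("output", "conv1x1-sigmoid", c(s, s, 1), conv_p(1, cin, 1))))
  new_network_spec(do.call(rbind, rows), config)
}

# Instantiate trainable layers for the configured U-Net. Consumes the current
# RNG stream (call under set.seed for reproducible initialization).
create_segmenter <- function(config) {
  f0 <- config$base_filters
  d <- config$depth
  L <- list()
  cin <- 1L
  for (i in seq_len(d)) {
    f <- f0 * 2^(i - 1)
    L[[paste0("enc", i, "_conv1")]] <- layer_conv(3, 3, cin, f, pad = 1)
    L[[paste0("enc", i, "_bn")]] <- layer_bn(f)
    L[[paste0("enc", i, "_relu1")]] <- layer_relu()
    L[[paste0("enc", i, "_conv2")]] <- layer_conv(3, 3, f, f, pad = 1)
    L[[paste0("enc", i, "_relu2")]] <- layer_relu()
    L[[paste0("enc", i, "_pool")]] <- layer_maxpool(2)
    cin <- f
  }
  fb <- f0 * 2^d
  L$bot_conv1 <- layer_conv(3, 3, cin, fb, pad = 1)
  L$bot_relu1 <- layer_relu()
  L$bot_conv2 <- layer_conv(3, 3, fb, fb, pad = 1)
  L$bot_relu2 <- layer_relu()
  L$bot_bn <- layer_bn(fb)
  cin <- fb
  for (i in rev(seq_len(d))) {
    f <- f0 * 2^(i - 1)
    L[[paste0("dec", i, "_up")]] <- layer_convt(2, cin, f)
    L[[paste0("dec", i, "_conv1")]] <- layer_conv(3, 3, 2 * f, f, pad = 1)
    L[[paste0("dec", i, "_relu1")]] <- layer_relu()
    L[[paste0("dec", i, "_conv2")]] <- layer_conv(3, 3, f, f, pad = 1)
    L[[paste0("dec", i, "_relu2")]] <- layer_relu()
    L[[paste0("dec", i, "_drop")]] <- layer_dropout(config$dropout_rate)
    cin <- f
  }
  L$head <- layer_conv(1, 1, cin, 1)
  structure(list(layers = L, config = config), class = "seg_model")
}

concat_c <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# forward pass to pre-sigmoid logits; x is (H, W, 1, N)
seg_forward <- function(model, x, training = TRUE) {
  L <- model$layers
  d <- model$config$depth
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    x <- ly_fwd(L[[paste0("enc", i, "_conv1")]], x, training)
    x <- ly_fwd(L[[paste0("enc", i, "_bn")]], x, training)
    x <- ly_fwd(L[[paste0("enc", i, "_relu1")]], x, training)
    x <- ly_fwd(L[[paste0("enc", i, "_conv2")]], x, training)
    x <- ly_fwd(L[[paste0("enc", i, "_relu2")]], x, training)
    skips[[i]] <- x
    x <- ly_fwd(L[[paste0("enc", i, "_pool")]], x, training)
  }
  x <- ly_fwd(L$bot_conv1, x, training)
  x <- ly_fwd(L$bot_relu1, x, training)
  x <- ly_fwd(L$bot_conv2, x, training)
  x <- ly_fwd(L$bot_relu2, x, training)
  x <- ly_fwd(L$bot_bn, x, training)
  for (i in rev(seq_len(d))) {
    x <- ly_fwd(L[[paste0("dec", i, "_up")]], x, training)
    x <- concat_c(x, skips[[i]])
    x <- ly_fwd(L[[paste0("dec", i, "_conv1")]], x, training)
    x <- ly_fwd(L[[paste0("dec", i, "_relu1")]], x, training)
    x <- ly_fwd(L[[paste0("dec", i, "_conv2")]], x, training)
    x <- ly_fwd(L[[paste0("dec", i, "_relu2")]], x, training)
    x <- ly_fwd(L[[paste0("dec", i, "_drop")]], x, training)
  }
  ly_fwd(L$head, x, training)
}

seg_backward <- function(model, dlogits) {
  L <- model$layers
  d <- model$config$depth
  f0 <- model$config$base_filters
  dskips <- vector("list", d)
  dx <- ly_bwd(L$head, dlogits)
  for (i in seq_len(d)) { # reverse of decoder execution order (d .. 1)
    dx <- ly_bwd(L[[paste0("dec", i, "_drop")]], dx)
    dx <- ly_bwd(L[[paste0("dec", i, "_relu2")]], dx)
    dx <- ly_bwd(L[[paste0("dec", i, "_conv2")]], dx)
    dx <- ly_bwd(L[[paste0("dec", i, "_relu1")]], dx)
    dx <- ly_bwd(L[[paste0("dec", i, "_conv1")]], dx)
    f <- f0 * 2^(i - 1)
    dskips[[i]] <- dx[, , f + seq_len(f), , drop = FALSE]
    dx <- ly_bwd(L[[paste0("dec", i, "_up")]],
                 dx[, , seq_len(f), , drop = FALSE])
  }
  dx <- ly_bwd(L$bot_bn, dx)
  dx <- ly_bwd(L$bot_relu2, dx)
  dx <- ly_bwd(L$bot_conv2, dx)
  dx <- ly_bwd(L$bot_relu1, dx)
  dx <- ly_bwd(L$bot_conv1, dx)
  for (i in rev(seq_len(d))) {
    dx <- ly_bwd(L[[paste0("enc", i, "_pool")]], dx)
    dx <- dx + dskips[[i]]
    dx <- ly_bwd(L[[paste0("enc", i, "_relu2")]], dx)
    dx <- ly_bwd(L[[paste0("enc", i, "_conv2")]], dx)
    dx <- ly_bwd(L[[paste0("enc", i, "_relu1")]], dx)
    dx <- ly_bwd(L[[paste0("enc", i, "_bn")]], dx)
    dx <- ly_bwd(L[[paste0("enc", i, "_conv1")]], dx)
  }
  dx
}

bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

records_to_arrays <- function(data, size) {
  n <- length(data)
  X <- array(0, c(size, size, 1, n))
  Y <- array(0, c(size, size, 1, n))
  for (i in seq_len(n)) {
    X[, , 1, i] <- data[[i]]$pixels
    if (!is.null(data[[i]]$mask)) Y[, , 1, i] <- data[[i]]$mask
  }
  list(X = X, Y = Y)
}

#' Train the enhanced U-Net segmenter
#'
#' Minimizes pixelwise binary cross-entropy with Adam. Weight initialization
#' (He normal), batch order and decoder dropout are all driven by
#' `tc$seed`, so two runs with identical inputs are bitwise identical.
#'
#' @param spec a `network_spec` from [build_enhanced_unet] (or a
#'   [seg_config]).
#' @param data list of [labeled_image] records; every record must carry a
#'   mask and be sized to the configured input size.
#' @param tc a [train_config].
#' @return A `seg_model` with a `history` data.frame (epoch, loss, dice).
#' @export
train_segmenter <- function(spec, data, tc) {
  config <- if (inherits(spec, "network_spec")) spec$config else spec
  stopifnot(inherits(config, "seg_config"), inherits(tc, "train_config"))
  if (length(data) == 0) stop("empty training set")
  no_mask <- vapply(data, function(r) is.null(r$mask), logical(1))
  if (any(no_mask))
    stop("records without masks cannot train the segmenter: ",
         paste(vapply(data[no_mask], `[[`, "", "source_id"), collapse = ", "))
  bad <- vapply(data, function(r) !all(dim(r$pixels) == config$input_size),
                logical(1))
  if (any(bad)) stop("images must be sized to input_size = ", config$input_size)

  arr <- records_to_arrays(data, config$input_size)
  n <- length(data)
  set.seed(tc$seed)
  model <- create_segmenter(config)
  history <- data.frame(epoch = integer(), loss = numeric(), dice = numeric())
  t_step <- 0L
  for (ep in seq_len(tc$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    dices <- c()
    for (start in seq(1, n, by = tc$batch_size)) {
      ix <- perm[start:min(start + tc$batch_size - 1, n)]
      xb <- arr$X[, , , ix, drop = FALSE]
      yb <- arr$Y[, , , ix, drop = FALSE]
      zero_grads(model$layers)
      z <- seg_forward(model, xb, training = TRUE)
      p <- stats::plogis(z)
      losses <- c(losses, bce_with_logits(z, yb))
      dices <- c(dices, dice((p >= config$threshold) * 1, yb))
      seg_backward(model, (p - yb) / length(yb))
      t_step <- t_step + 1L
      adam_step(model$layers, tc$learning_rate, t_step)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         dice = mean(dices)))
  }
  clear_caches(model$layers)
  model$history <- history
  model
}

#' Predict a binary lesion mask
#'
#' Runs the segmenter in inference mode (batch-norm moving statistics, no
#' dropout) and thresholds the sigmoid output at the configured threshold
#' using the `>=` convention.
#'
#' @param model a trained `seg_model`.
#' @param image numeric matrix matching the model's input size.
#' @return Binary matrix of the same size.
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "seg_model"))
  if (!is.matrix(image) || !all(dim(image) == model$config$input_size))
    stop("image must be a ", model$config$input_size, "x",
         model$config$input_size, " matrix")
  x <- array(image, c(dim(image), 1, 1))
  z <- seg_forward(model, x, training = FALSE)
  (stats::plogis(z[, , 1, 1]) >= model$config$threshold) * 1
}

# batched inference used by the pipeline; X is (H, W, 1, N)
predict_masks <- function(model, X) {
  z <- seg_forward(model, X, training = FALSE)
  p <- stats::plogis(z)
  (p >= model$config$threshold) * 1
}
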