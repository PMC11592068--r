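# Architecture traces: the stem and dense-block shapes/parameter counts the
# classifier must reproduce, and the U-Net layout.

test_that("capsule stem reproduces the printed shape and parameter trace", {
  spec <- build_stem(caps_config())
  expect_equal(spec_layer(spec, "stem_pad1")$output_shape, c(134L, 134L, 3L))
  stem <- spec_layer(spec, "stem_conv")
  expect_equal(stem$params, 9408) # 7*7*3*64, no bias
  expect_equal(stem$output_shape, c(64L, 64L, 64L))
  expect_equal(spec_layer(spec, "stem_pad2")$output_shape, c(66L, 66L, 64L))
  expect_equal(spec_layer(spec, "stem_pool")$output_shape, c(32L, 32L, 64L))
})

test_that("dense block reproduces the printed parameter counts and growth", {
  spec <- build_capsnet(caps_config())
  expect_equal(spec_layer(spec, "dense1_conv1")$params, 8192)  # 1x1, 64 -> 128
  expect_equal(spec_layer(spec, "dense1_bn2")$params, 512)     # 4 * 128
  expect_equal(spec_layer(spec, "dense1_conv2")$params, 36864) # 3x3, 128 -> 32
  expect_equal(spec_layer(spec, "dense1_conv1")$output_shape, c(32L, 32L, 128L))
  expect_equal(spec_layer(spec, "dense1_conv2")$output_shape, c(32L, 32L, 32L))
  # concatenation growth: 64 + l * 32, ending at 192 channels
  for (l in 1:4) {
    expect_equal(spec_layer(spec, paste0("dense", l, "_concat"))$output_shape,
                 c(32L, 32L, 64L + 32L * l))
  }
  expect_equal(spec_layer(spec, "dense4_concat")$output_shape[3], 192L)
})

test_that("full classifier spec has one softmax output and stable totals", {
  spec <- build_capsnet(caps_config())
  sm <- spec$layers[spec$layers$kind == "softmax", ]
  expect_equal(nrow(sm), 1)
  expect_equal(sm$dims[[1]], 2L)
  expect_equal(spec_layer(spec, "primary_caps")$output_shape,
               c(24576L, 8L)) # 32*32*192 / 8 capsules
  expect_identical(spec_total_params(spec),
                   spec_total_params(build_capsnet(caps_config())))
  expect_equal(spec_total_params(spec), sum(spec$layers$params))
  expect_error(spec_layer(spec, "nonexistent"), "no layer")
  expect_error(caps_config(input_size = 128, primary_caps_dim = 7),
               "not divisible")
})

test_that("U-Net spec ends at the input resolution with one sigmoid channel", {
  spec <- build_enhanced_unet(seg_config())
  out <- spec_layer(spec, "output")
  expect_equal(out$output_shape, c(256L, 256L, 1L))
  expect_equal(out$kind, "conv1x1-sigmoid")
  # bottleneck doubles to base_filters * 2^depth = 1024
  expect_equal(spec_layer(spec, "bottleneck_conv1")$output_shape[3], 1024L)
  # exactly depth concatenation (skip) junctions
  expect_equal(sum(spec$layers$kind == "concat"), 4)
})

test_that("encoder channels follow base_filters * 2^i for random valid configs", {
  set.seed(30)
  for (i in 1:5) {
    depth <- sample(2:4, 1)
    bf <- sample(c(4, 8, 16), 1)
    size <- 2^depth * sample(2:6, 1)
    spec <- build_enhanced_unet(seg_config(size, bf, depth))
    for (b in seq_len(depth)) {
      enc <- spec_layer(spec, paste0("enc", b, "_conv2"))
      expect_equal(enc$output_shape, c(size / 2^(b - 1), size / 2^(b - 1),
                                       bf * 2^(b - 1)))
    }
    expect_equal(spec_layer(spec, "output")$output_shape, c(size, size, 1L))
  }
  expect_error(seg_config(input_size = 100, depth = 3), "divisible")
})

test_that("spec printing renders Keras-style shape strings", {
  txt <- format(build_stem(caps_config()))
  expect_true(any(grepl("(None, 134, 134, 3)", txt, fixed = TRUE)))
  expect_true(any(grepl("9,408|9408", txt)))
  df <- as.data.frame(build_stem(caps_config()))
  expect_equal(df$output_shape[df$name == "stem_pool"], "(None, 32, 32, 64)")
})
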