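test_that("autoencoder shape chain halves then doubles the spatial size", {
  spec <- build_autoencoder(32)
  sh <- autoencoder_shapes(spec)
  expect_equal(unname(sh$encoder[, "C"]), c(64, 128, 256, 512))
  expect_equal(unname(sh$encoder[, "H"]), c(16, 8, 4, 2))
  expect_equal(unname(sh$decoder[nrow(sh$decoder), ]), c(32, 32, 3))
  sh64 <- autoencoder_shapes(build_autoencoder(64))
  expect_equal(unname(sh64$encoder[4, ]), c(4, 4, 512))
  expect_equal(unname(sh64$decoder[4, ]), c(64, 64, 3))
  expect_error(build_autoencoder(24), "multiple of 16")
  # 15-row layer sequence: 4 conv + 3 ReLU, 4 deconv + 3 ReLU + sigmoid
  expect_length(spec$encoder, 7)
  expect_length(spec$decoder, 8)
})

test_that("parameter accounting reproduces the published layer counts", {
  expect_identical(count_parameters(layer_spec_conv2d(4, 64, 4)), 4160)
  expect_identical(count_parameters(layer_spec_conv2d(64, 128, 4)), 131200)
  expect_identical(count_parameters(layer_spec_conv2d(128, 256, 4)), 524544)
  expect_identical(count_parameters(layer_spec_conv2d(256, 512, 4)), 2097664)
  expect_identical(count_parameters(layer_spec_conv2d(1, 1, 1)), 2)
  expect_identical(
    count_parameters(layer_spec_transposed_conv2d(64, 3, 4)), 3075)
  expect_identical(count_parameters(layer_spec_conv2d(2, 3, 3,
                                                      has_bias = FALSE)), 54)
  # activations count zero
  spec <- build_autoencoder(32)
  expect_identical(count_parameters(spec$encoder[[2]]), 0L)
  enc_counts <- vapply(Filter(function(l) l$kind == "conv2d", spec$encoder),
                       count_parameters, 0)
  expect_equal(enc_counts, c(4160, 131200, 524544, 2097664))
  # the instantiated engine layers carry exactly these parameter counts
  layers <- endossl:::build_encoder_layers(spec)
  expect_equal(endossl:::n_params(layers), sum(enc_counts))
})

test_that("fusion widths are computed from actual encoder shapes", {
  m1 <- build_combined("Cl", input_size = 32, seed = 1)
  expect_identical(m1$concat_width, 2048L)
  m3 <- build_combined("Cl-PPred-JigPuzz", input_size = 128, seed = 1)
  expect_identical(m3$concat_width, 98304L)
  expect_identical(m3$head[[4]]$in_dim, 512L)   # printed three-encoder head
  m2 <- build_combined("Cl-JigPuzz", input_size = 32, seed = 1)
  expect_identical(m2$head[[1]]$in_dim, 4096L)
  expect_identical(m2$head[[1]]$out_dim, 1024L) # printed two-encoder hidden
  expect_identical(m2$head[[4]]$out_dim, 3L)
  expect_error(scenario_encoders("Cl-Nope"), "unknown scenario")
})

test_that("a one-encoder scenario is a degenerate fusion", {
  m <- build_combined("PPred", input_size = 16, seed = 3)
  x <- array(stats::runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  logits <- endossl:::model_forward(m, x)
  expect_identical(dim(logits), c(3L, 2L))
  expect_true(all(is.finite(logits)))
  # identical to applying the encoder then the head by hand
  xi <- endossl:::stack_input(x, "rgb")
  f <- endossl:::seq_forward(m$encoders$patch$layers, xi)
  manual <- endossl:::seq_forward(m$head, endossl:::feats_to_matrix(f))
  expect_equal(logits, manual, tolerance = 1e-12)
})

test_that("builds are deterministic given the seed", {
  m1 <- build_combined("Cl-JigPuzz", input_size = 16, seed = 5)
  m2 <- build_combined("Cl-JigPuzz", input_size = 16, seed = 5)
  expect_identical(endossl:::snapshot_params(m1$head),
                   endossl:::snapshot_params(m2$head))
  expect_identical(
    endossl:::snapshot_params(m1$encoders$colorization$layers),
    endossl:::snapshot_params(m2$encoders$colorization$layers))
})

test_that("attention pools to a convex spatial combination", {
  m <- build_combined("Cl", input_size = 32, variant = "attention", seed = 2)
  expect_identical(m$concat_width, 512L)
  # uniform features: softmax weights are uniform, output = mean feature
  f <- array(0, dim = c(512, 2, 2, 3))
  for (n in 1:3) f[, , , n] <- stats::runif(512)   # constant across positions
  att <- m$variant_mods$colorization[[1]]
  out <- endossl:::ly_forward(att, f)
  expect_equal(out, apply(f, c(1, 4), mean), tolerance = 1e-10)
  # attention weights sum to 1 per sample
  f2 <- array(stats::runif(512 * 4 * 3), dim = c(512, 2, 2, 3))
  invisible(endossl:::ly_forward(att, f2))
  expect_equal(colSums(att$cache$a), rep(1, 3), tolerance = 1e-6)
})

test_that("the transformer block preserves the sequence shape", {
  m <- build_combined("JigPuzz", input_size = 32, variant = "transformer",
                      seed = 2)
  tb <- m$variant_mods$jigsaw[[1]]
  f <- array(stats::rnorm(512 * 4 * 2), dim = c(512, 2, 2, 2))
  out <- endossl:::ly_forward(tb, f)
  expect_identical(dim(out), dim(f))
  expect_true(all(is.finite(out)))
  # variant builders reuse the base model's encoder weights
  base <- build_combined("Cl", input_size = 16, seed = 4)
  va <- build_attention_variant(base, seed = 9)
  expect_identical(
    endossl:::snapshot_params(base$encoders$colorization$layers),
    endossl:::snapshot_params(va$encoders$colorization$layers))
  expect_identical(va$variant, "attention")
  vt <- build_transformer_variant(base, seed = 9)
  expect_identical(vt$variant, "transformer")
})

test_that("the baseline maps a 128-d embedding to the three classes", {
  b <- build_baseline("small_cnn", input_size = 32, seed = 1)
  classifier <- b$head[[length(b$head)]]
  expect_identical(classifier$in_dim, 128L)
  expect_identical(classifier$out_dim, 3L)
  x <- array(stats::runif(32 * 32 * 3), dim = c(32, 32, 3, 1))
  logits <- endossl:::model_forward(b, x)
  expect_identical(dim(logits), c(3L, 1L))
  expect_true(all(is.finite(logits)))
  expect_error(build_baseline("vgg"), "arg")
})

test_that("label smoothing at zero reduces to plain cross-entropy", {
  logits <- matrix(c(2, -1, 0.5, 0, 3, -2), nrow = 3)
  y <- c(0L, 2L)
  hand <- mean(vapply(1:2, function(n) {
    p <- exp(logits[, n]) / sum(exp(logits[, n]))
    -log(p[y[n] + 1])
  }, 0))
  expect_equal(label_smoothing_ce(logits, y, eps = 0), hand,
               tolerance = 1e-12)
  # smoothed target mixes in the uniform distribution
  eps <- 0.1
  hand_s <- mean(vapply(1:2, function(n) {
    p <- exp(logits[, n]) / sum(exp(logits[, n]))
    tgt <- rep(eps / 3, 3); tgt[y[n] + 1] <- tgt[y[n] + 1] + 1 - eps
    -sum(tgt * log(p))
  }, 0))
  expect_equal(label_smoothing_ce(logits, y, eps = eps), hand_s,
               tolerance = 1e-12)
})

test_that("resnet-50 baseline builds and runs forward", {
  b <- build_baseline("resnet50", input_size = 32, seed = 1)
  expect_identical(b$concat_width, 2048L)
  x <- array(stats::runif(32 * 32 * 3), dim = c(32, 32, 3, 1))
  logits <- endossl:::model_forward(b, x)
  expect_identical(dim(logits), c(3L, 1L))
  expect_true(all(is.finite(logits)))
})

test_that("architecture specs round-trip through YAML", {
  spec <- build_autoencoder(32, 4)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_autoencoder_yaml(spec, f)
  spec2 <- read_autoencoder_yaml(f)
  expect_identical(spec2$input_size, spec$input_size)
  expect_identical(vapply(spec2$encoder, count_parameters, 0),
                   vapply(spec$encoder, count_parameters, 0))
})
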