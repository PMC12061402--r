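# Declarative architecture specs and model builders: the shared pretext
# autoencoder (4 conv + ReLU stages doubling channels 64->512 while halving
# the spatial size, mirrored by 4 transposed-conv stages ending in a
# 3-channel sigmoid), the fusion classifier over pretrained encoders, the
# attention / transformer variants, and the contrastive-style baseline.

#' Scenario names for encoder fusion
#'
#' Labels follow the study's convention: `Cl` = colorization,
#' `PPred` = patch prediction, `JigPuzz` = jigsaw.
#' @return character vector of the 7 supported scenarios.
#' @export
scenario_names <- function() {
  c("Cl", "PPred", "JigPuzz", "Cl-PPred", "Cl-JigPuzz", "PPred-JigPuzz",
    "Cl-PPred-JigPuzz")
}

#' Encoders participating in a scenario
#' @param scenario one of [scenario_names()] (also accepts "baseline").
#' @return character vector of task names among
#'   `c("colorization", "patch", "jigsaw")`.
#' @export
scenario_encoders <- function(scenario) {
  if (!scenario %in% scenario_names())
    stop("unknown scenario '", scenario, "'; expected one of ",
         paste(scenario_names(), collapse = ", "))
  map <- c(Cl = "colorization", PPred = "patch", JigPuzz = "jigsaw")
  unname(map[strsplit(scenario, "-", fixed = TRUE)[[1L]]])
}

layer_spec <- function(kind, in_channels = NA_integer_,
                       out_channels = NA_integer_, kernel = NA_integer_,
                       stride = NA_integer_, padding = NA_integer_,
                       has_bias = TRUE, p_dropout = NA_real_,
                       in_features = NA_integer_, out_features = NA_integer_) {
  structure(list(kind = kind, in_channels = in_channels,
                 out_channels = out_channels, kernel = kernel,
                 stride = stride, padding = padding, has_bias = has_bias,
                 p_dropout = p_dropout, in_features = in_features,
                 out_features = out_features),
            class = "endo_layer_spec")
}

#' Parameter count of a single layer spec
#'
#' Convolution: `out * (in * k^2) + out` (bias); transposed convolution:
#' `in * out * k^2 + out`; linear: `out * in + out`. Activation, dropout,
#' flatten and pooling layers hold no parameters and count 0.
#'
#' @param layer an `endo_layer_spec` (e.g. one element of
#'   `build_autoencoder()$encoder`).
#' @return integer parameter count.
#' @examples
#' count_parameters(layer_spec_conv2d(4, 64, 4))  # 4160, first encoder stage
#' @export
count_parameters <- function(layer) {
  stopifnot(inherits(layer, "endo_layer_spec"))
  bias <- function(n) if (isTRUE(layer$has_bias)) n else 0L
  switch(layer$kind,
    conv2d = layer$out_channels * layer$in_channels * layer$kernel^2 +
      bias(layer$out_channels),
    transposed_conv2d = layer$in_channels * layer$out_channels *
      layer$kernel^2 + bias(layer$out_channels),
    linear = layer$out_features * layer$in_features + bias(layer$out_features),
    0L)
}

#' Convenience constructors for layer specs
#' @param in_channels,out_channels channel counts.
#' @param kernel,stride,padding convolution geometry.
#' @param has_bias whether the layer carries a bias term.
#' @return an `endo_layer_spec`.
#' @export
layer_spec_conv2d <- function(in_channels, out_channels, kernel = 4L,
                              stride = 2L, padding = 1L, has_bias = TRUE) {
  layer_spec("conv2d", in_channels = in_channels, out_channels = out_channels,
             kernel = kernel, stride = stride, padding = padding,
             has_bias = has_bias)
}

#' @rdname layer_spec_conv2d
#' @export
layer_spec_transposed_conv2d <- function(in_channels, out_channels,
                                         kernel = 4L, stride = 2L,
                                         padding = 1L, has_bias = TRUE) {
  layer_spec("transposed_conv2d", in_channels = in_channels,
             out_channels = out_channels, kernel = kernel, stride = stride,
             padding = padding, has_bias = has_bias)
}

#' Pretext autoencoder architecture
#'
#' Four conv+ReLU encoder stages (channels `in -> 64 -> 128 -> 256 -> 512`,
#' kernel 4, stride 2, padding 1, each halving the spatial size) and four
#' transposed-conv decoder stages with ReLUs and a terminal 3-channel
#' sigmoid, each doubling the spatial size back to `input_size`. The same
#' architecture serves all three pretext tasks.
#'
#' @param input_size square input side, a multiple of 16.
#' @param input_channels input channel count (default 4: RGB stacked with
#'   the luminance plane, which is what the first-stage parameter count
#'   implies).
#' @return an `endo_autoencoder_spec` with `encoder` and `decoder` layer
#'   spec lists, `input_size`, `input_channels`.
#' @export
build_autoencoder <- function(input_size = 32L, input_channels = 4L) {
  if (input_size %% 16L != 0L)
    stop("input_size must be a multiple of 16")
  widths <- c(input_channels, 64L, 128L, 256L, 512L)
  encoder <- list()
  for (i in 1:4) {
    encoder <- c(encoder, list(layer_spec_conv2d(widths[i], widths[i + 1L])),
                 list(layer_spec("relu")))
  }
  encoder <- encoder[-length(encoder)]  # Table layout: no ReLU after stage 4
  dw <- c(512L, 256L, 128L, 64L, 3L)
  decoder <- list()
  for (i in 1:4) {
    decoder <- c(decoder,
                 list(layer_spec_transposed_conv2d(dw[i], dw[i + 1L])))
    decoder <- c(decoder,
                 if (i < 4L) list(layer_spec("relu"))
                 else list(layer_spec("sigmoid")))
  }
  structure(list(encoder = encoder, decoder = decoder,
                 input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels)),
            class = "endo_autoencoder_spec")
}

#' Shape chain of an autoencoder spec
#' @param spec an `endo_autoencoder_spec`.
#' @return list with `encoder` and `decoder` matrices of (H, W, C) rows.
#' @export
autoencoder_shapes <- function(spec) {
  s <- spec$input_size
  enc <- c()
  for (ly in spec$encoder) if (ly$kind == "conv2d") {
    s <- s %/% 2L
    enc <- rbind(enc, c(H = s, W = s, C = ly$out_channels))
  }
  dec <- c()
  for (ly in spec$decoder) if (ly$kind == "transposed_conv2d") {
    s <- s * 2L
    dec <- rbind(dec, c(H = s, W = s, C = ly$out_channels))
  }
  list(encoder = enc, decoder = dec)
}

#' @export
print.endo_autoencoder_spec <- function(x, ...) {
  sh <- autoencoder_shapes(x)
  cat(sprintf("Pretext autoencoder: %dx%dx%d input\n", x$input_size,
              x$input_size, x$input_channels))
  all_specs <- c(x$encoder, x$decoder)
  shapes <- rbind(sh$encoder, sh$decoder)
  r <- 0L
  for (ly in all_specs) {
    if (ly$kind %in% c("conv2d", "transposed_conv2d")) r <- r + 1L
    shp <- if (r > 0L) sprintf("(%d, %d, %d)", shapes[r, 1L], shapes[r, 2L],
                               shapes[r, 3L]) else ""
    cat(sprintf("  %-18s %-14s %d\n", ly$kind, shp, count_parameters(ly)))
  }
  invisible(x)
}

# instantiate encoder layers (engine objects) from an autoencoder spec
build_encoder_layers <- function(spec, prefix = "enc") {
  layers <- list()
  i <- 0L
  for (ly in spec$encoder) {
    if (ly$kind == "conv2d") {
      i <- i + 1L
      layers <- c(layers, list(nn_conv2d(ly$in_channels, ly$out_channels,
                                         ly$kernel, ly$stride, ly$padding,
                                         name = sprintf("%s.conv%d", prefix, i))))
    } else if (ly$kind == "relu") {
      layers <- c(layers, list(nn_relu(sprintf("%s.relu%d", prefix, i))))
    }
  }
  layers
}

build_decoder_layers <- function(spec, prefix = "dec") {
  layers <- list()
  i <- 0L
  for (ly in spec$decoder) {
    if (ly$kind == "transposed_conv2d") {
      i <- i + 1L
      layers <- c(layers, list(nn_conv_transpose2d(
        ly$in_channels, ly$out_channels, ly$kernel, ly$stride, ly$padding,
        name = sprintf("%s.deconv%d", prefix, i))))
    } else if (ly$kind == "relu") {
      layers <- c(layers, list(nn_relu(sprintf("%s.relu%d", prefix, i))))
    } else if (ly$kind == "sigmoid") {
      layers <- c(layers, list(nn_sigmoid(sprintf("%s.sigmoid", prefix))))
    }
  }
  layers
}

# Per-task input transform: every encoder consumes a 4-channel stack.
# The colorization encoder sees only luminance information (replicated),
# the others the RGB planes stacked with their luminance.
#
# x: (H, W, 3, N) batch in [0,1]; returns (4, H, W, N)
stack_input <- function(x, transform = c("rgb", "gray")) {
  transform <- match.arg(transform)
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; N <- d[4L]
  lum <- 0.299 * x[, , 1L, , drop = FALSE] + 0.587 * x[, , 2L, , drop = FALSE] +
    0.114 * x[, , 3L, , drop = FALSE]
  out <- array(0, dim = c(4L, H, W, N))
  if (transform == "rgb") {
    for (c in 1:3) out[c, , , ] <- x[, , c, ]
  } else {
    for (c in 1:3) out[c, , , ] <- lum[, , 1L, ]
  }
  out[4L, , , ] <- lum[, , 1L, ]
  out
}

encoder_transform <- function(task) {
  if (task == "colorization") "gray" else "rgb"
}

#' Build a fusion classifier over pretrained encoders
#'
#' Forward path: each encoder (frozen feature extractor) is applied to its
#' task-appropriate input transform; bottleneck features are flattened and
#' concatenated; a linear fusion layer, ReLU, dropout and a final linear
#' layer produce 3 class logits. Head widths are computed from the actual
#' concatenated feature length; the default hidden width is 512 for one- or
#' three-encoder fusion and 1024 for two-encoder fusion.
#'
#' @param scenario one of [scenario_names()].
#' @param encoders named list of pretrained encoders
#'   (`endossl_pretext` objects or bare layer lists), with names among
#'   `colorization`, `patch`, `jigsaw`. Missing encoders are instantiated
#'   with random weights.
#' @param input_size square input side (multiple of 16).
#' @param hidden_width classifier hidden width; `NULL` picks the default.
#' @param p_dropout dropout probability in the head.
#' @param variant `"none"`, `"attention"` (spatial soft attention over each
#'   encoder's bottleneck) or `"transformer"` (one transformer encoder
#'   block over the bottleneck positions).
#' @param n_classes number of output classes.
#' @param seed seed for weight initialization.
#' @return an `endossl_model`.
#' @export
build_combined <- function(scenario, encoders = list(), input_size = 32L,
                           hidden_width = NULL, p_dropout = 0.3,
                           variant = c("none", "attention", "transformer"),
                           n_classes = 3L, seed = 1L) {
  variant <- match.arg(variant)
  tasks <- scenario_encoders(scenario)
  if (is.null(hidden_width)) hidden_width <- if (length(tasks) == 2L) 1024L else 512L
  bneck_hw <- input_size %/% 16L
  bneck_c <- 512L
  with_seed(seed, {
    enc_list <- list()
    for (task in tasks) {
      enc <- encoders[[task]]
      if (is.null(enc)) {
        spec <- build_autoencoder(input_size)
        layers <- build_encoder_layers(spec, prefix = task)
      } else {
        layers <- if (inherits(enc, "endossl_pretext")) enc$encoder else enc
        layers <- clone_layers(layers)  # never alias pretrained weights
        got <- probe_encoder_channels(layers)
        if (!identical(got, c(4L, 512L)))
          stop("encoder '", task, "' is shape-incompatible at concatenation ",
               "(expected 4 -> 512 channels, got ", got[1L], " -> ", got[2L], ")")
      }
      enc_list[[task]] <- list(task = task, layers = layers,
                               transform = encoder_transform(task))
    }
    variant_mods <- NULL
    if (variant == "attention") {
      variant_mods <- lapply(tasks, function(t)
        list(nn_attention_pool(bneck_c, name = paste0(t, ".attention"))))
      names(variant_mods) <- tasks
      feat_per_enc <- bneck_c
    } else if (variant == "transformer") {
      variant_mods <- lapply(tasks, function(t)
        list(nn_transformer_block(bneck_c, heads = 4L, ff = 1024L,
                                  name = paste0(t, ".transformer")),
             nn_flatten(paste0(t, ".flatten"))))
      names(variant_mods) <- tasks
      feat_per_enc <- bneck_c * bneck_hw * bneck_hw
    } else {
      feat_per_enc <- bneck_c * bneck_hw * bneck_hw
    }
    concat_width <- as.integer(feat_per_enc * length(tasks))
    head <- list(
      nn_linear(concat_width, hidden_width, name = "head.fc1"),
      nn_relu("head.relu"),
      nn_dropout(p_dropout, name = "head.dropout"),
      nn_linear(hidden_width, n_classes, name = "head.fc2"))
    structure(list(type = "combined", scenario = scenario,
                   input_size = as.integer(input_size),
                   encoders = enc_list, variant = variant,
                   variant_mods = variant_mods, head = head,
                   concat_width = concat_width,
                   class_names = landmark_classes(), trained = FALSE),
              class = "endossl_model")
  })
}

probe_encoder_channels <- function(layers) {
  convs <- Filter(function(l) l$kind == "conv2d", layers)
  c(convs[[1L]]$in_ch, convs[[length(convs)]]$out_ch)
}

#' Attach an attention or transformer module to a fusion model
#'
#' Returns a new model sharing the base model's (pretrained) encoders, with
#' a freshly initialized variant module and classification head.
#'
#' @param base an `endossl_model` built by [build_combined()].
#' @param seed seed for the new module/head weights.
#' @return an `endossl_model`.
#' @export
build_attention_variant <- function(base, seed = 1L) {
  rebuild_variant(base, "attention", seed)
}

#' @rdname build_attention_variant
#' @export
build_transformer_variant <- function(base, seed = 1L) {
  rebuild_variant(base, "transformer", seed)
}

rebuild_variant <- function(base, variant, seed) {
  stopifnot(inherits(base, "endossl_model"), base$type == "combined")
  encoders <- lapply(base$encoders, function(e) e$layers)
  build_combined(base$scenario, encoders = encoders,
                 input_size = base$input_size, variant = variant, seed = seed)
}

#' Build the contrastive-style supervised baseline
#'
#' A backbone encoder followed by a two-layer projection head (ReLU,
#' dropout) to a 128-dimensional embedding and a single linear classifier
#' to the three classes. Intended training protocol (see
#' [train_classifier()]): label-smoothed cross-entropy, Adam with learning
#' rate 1e-4 and weight decay 1e-5, plateau learning-rate scheduler.
#'
#' @param backbone `"small_cnn"` (the 4-stage pretext encoder) or
#'   `"resnet50"` (bottleneck-block residual network, randomly initialized;
#'   no pretrained weights are downloaded).
#' @param embed_dim embedding width (default 128).
#' @param input_size square input side.
#' @param p_dropout dropout in the projection head.
#' @param seed seed for initialization.
#' @return an `endossl_model` (type `"baseline"`).
#' @export
build_baseline <- function(backbone = c("small_cnn", "resnet50"),
                           embed_dim = 128L, input_size = 32L,
                           p_dropout = 0.3, seed = 1L) {
  backbone <- match.arg(backbone)
  with_seed(seed, {
    if (backbone == "small_cnn") {
      spec <- build_autoencoder(input_size)
      enc_layers <- build_encoder_layers(spec, prefix = "backbone")
      s0 <- input_size %/% 16L
      feat <- 512L * s0 * s0
    } else {
      enc_layers <- build_resnet50_layers()
      feat <- 2048L
    }
    head <- list(
      nn_linear(feat, 256L, name = "proj.fc1"),
      nn_relu("proj.relu"),
      nn_dropout(p_dropout, name = "proj.dropout"),
      nn_linear(256L, embed_dim, name = "proj.fc2"),
      nn_linear(embed_dim, 3L, name = "classifier"))
    structure(list(type = "baseline", scenario = "baseline",
                   input_size = as.integer(input_size), backbone = backbone,
                   encoders = list(backbone = list(task = "backbone",
                                                   layers = enc_layers,
                                                   transform = "rgb")),
                   variant = "none", variant_mods = NULL, head = head,
                   concat_width = feat, embed_dim = as.integer(embed_dim),
                   class_names = landmark_classes(), trained = FALSE),
              class = "endossl_model")
  })
}

# ResNet-50 bottleneck topology (3-4-6-3 stages); bias convolutions stand
# in for batch norm since no pretrained statistics exist here. Ends with
# global average pooling to a 2048-vector.
build_resnet50_layers <- function() {
  bottleneck <- function(in_ch, mid, out_ch, stride, name) {
    main <- list(
      nn_conv2d(in_ch, mid, 1L, 1L, 0L, name = paste0(name, ".c1")),
      nn_relu(paste0(name, ".r1")),
      nn_conv2d(mid, mid, 3L, stride, 1L, name = paste0(name, ".c2")),
      nn_relu(paste0(name, ".r2")),
      nn_conv2d(mid, out_ch, 1L, 1L, 0L, name = paste0(name, ".c3")))
    shortcut <- if (in_ch != out_ch || stride != 1L)
      list(nn_conv2d(in_ch, out_ch, 1L, stride, 0L,
                     name = paste0(name, ".proj")))
    nn_residual(main, shortcut, name = name)
  }
  layers <- list(
    nn_conv2d(4L, 64L, 7L, 2L, 3L, name = "stem.conv"),
    nn_relu("stem.relu"),
    nn_maxpool(3L, 2L, 1L, name = "stem.pool"))
  cfg <- list(list(3L, 64L, 256L, 1L), list(4L, 128L, 512L, 2L),
              list(6L, 256L, 1024L, 2L), list(3L, 512L, 2048L, 2L))
  in_ch <- 64L
  for (s in seq_along(cfg)) {
    nb <- cfg[[s]][[1L]]; mid <- cfg[[s]][[2L]]; out <- cfg[[s]][[3L]]
    stride <- cfg[[s]][[4L]]
    for (b in seq_len(nb)) {
      layers <- c(layers, list(bottleneck(in_ch, mid, out,
                                          if (b == 1L) stride else 1L,
                                          sprintf("stage%d.block%d", s, b))))
      in_ch <- out
    }
  }
  c(layers, list(nn_gap("gap")))
}

#' Label-smoothed cross-entropy over class logits
#'
#' With smoothing `eps`, the target distribution places `1 - eps + eps/K`
#' on the true class and `eps/K` elsewhere; `eps = 0` is plain
#' cross-entropy.
#'
#' @param logits K x N matrix of class logits.
#' @param labels integer vector (0-based class indices).
#' @param eps smoothing mass in \[0, 1).
#' @return mean loss (scalar).
#' @export
label_smoothing_ce <- function(logits, labels, eps = 0.1) {
  softmax_ce(as.matrix(logits), as.integer(labels) + 1L,
             label_smoothing = eps)$loss
}

#' Serialize an architecture description to YAML
#' @param spec an `endo_autoencoder_spec`.
#' @param path file path.
#' @return `read_autoencoder_yaml` returns an `endo_autoencoder_spec`.
#' @export
write_autoencoder_yaml <- function(spec, path) {
  strip <- function(ls) lapply(ls, function(l) Filter(Negate(is.na), unclass(l)))
  yaml::write_yaml(list(input_size = spec$input_size,
                        input_channels = spec$input_channels,
                        encoder = strip(spec$encoder),
                        decoder = strip(spec$decoder)), path)
  invisible(path)
}

#' @rdname write_autoencoder_yaml
#' @export
read_autoencoder_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  build_autoencoder(x$input_size, x$input_channels)
}
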