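# Grad-CAM saliency maps over any convolutional layer of a model.

# names of conv layers reachable by grad_cam
model_conv_layers <- function(model) {
  nms <- c()
  for (enc in model$encoders)
    for (ly in enc$layers)
      if (ly$kind %in% c("conv2d", "conv_transpose2d")) nms <- c(nms, ly$name)
  nms
}

bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  # align source and target pixel centers
  sy <- (seq_len(H) - 0.5) * h / H + 0.5
  sx <- (seq_len(W) - 0.5) * w / W + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    m[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

#' Grad-CAM saliency map
#'
#' Computes the gradient of the target-class logit with respect to the
#' named convolutional layer's activations, averages it spatially into
#' per-channel weights, forms `ReLU(sum_c w_c A_c)`, upsamples bilinearly
#' to the input size, and min-max normalizes to \[0, 1\]. A map with zero
#' gradient everywhere is returned as all zeros with a warning.
#'
#' @param model an `endossl_model`.
#' @param image H x W x 3 array in \[0, 1\].
#' @param target_class 0-based class index whose logit is explained.
#' @param layer_name name of a convolutional layer (see error message for
#'   the available names); default: the last convolution of the first
#'   encoder.
#' @return an `endo_heatmap`: H x W matrix in \[0, 1\] with attributes
#'   `target_class` and `layer_name`.
#' @export
grad_cam <- function(model, image, target_class, layer_name = NULL) {
  stopifnot(inherits(model, "endossl_model"), target_class %in% 0:2)
  avail <- model_conv_layers(model)
  if (is.null(layer_name)) {
    enc1 <- model$encoders[[1L]]
    convs <- Filter(function(l) l$kind == "conv2d", enc1$layers)
    layer_name <- convs[[length(convs)]]$name
  }
  if (!layer_name %in% avail)
    stop("unknown layer '", layer_name, "'; available layers: ",
         paste(avail, collapse = ", "))
  d <- dim(image)
  x <- array(image, dim = c(d, 1L))

  # forward, retaining intermediate activations of the hosting encoder
  feats <- list(); acts <- list()
  for (nm in names(model$encoders)) {
    enc <- model$encoders[[nm]]
    xi <- stack_input(x, enc$transform)
    cur <- xi
    for (ly in enc$layers) {
      cur <- ly_forward(ly, cur, training = FALSE)
      acts[[ly$name]] <- cur
    }
    feats[[nm]] <- cur
  }
  logits <- head_forward(model, feats, training = FALSE)
  dlogits <- matrix(0, nrow(logits), 1L)
  dlogits[target_class + 1L, 1L] <- 1
  g <- seq_backward(model$head, dlogits)

  # split concatenated gradient per encoder and walk each encoder backward,
  # capturing the gradient at every layer output
  per <- model$concat_width %/% length(model$encoders)
  grads <- list()
  for (i in seq_along(model$encoders)) {
    nm <- names(model$encoders)[i]
    gi <- g[(i - 1L) * per + seq_len(per), , drop = FALSE]
    if (!is.null(model$variant_mods))
      gi <- seq_backward(model$variant_mods[[nm]], gi)
    layers <- model$encoders[[nm]]$layers
    cur_g <- if (is.matrix(gi)) {
      f <- feats[[nm]]
      if (is.matrix(f)) gi else array(gi, dim = dim(f))
    } else gi
    for (j in rev(seq_along(layers))) {
      grads[[layers[[j]]$name]] <- cur_g
      cur_g <- ly_backward(layers[[j]], cur_g)
    }
  }

  A <- acts[[layer_name]]     # (C, h, w, 1)
  G <- grads[[layer_name]]
  da <- dim(A)
  wts <- rowMeans(matrix(G, nrow = da[1L]))   # spatial mean per channel
  map <- matrix(0, da[2L], da[3L])
  Am <- matrix(A, nrow = da[1L])
  raw <- colSums(Am * wts)
  map[] <- matrix(raw, da[2L], da[3L])
  map <- pmax(map, 0)
  map <- bilinear_upsample(map, d[1L], d[2L])
  if (max(map) <= 0) {
    warning("Grad-CAM map is identically zero for this input/class")
    map[] <- 0
  } else if (max(map) - min(map) < 1e-12) {
    map[] <- 1   # constant positive response
  } else {
    map <- (map - min(map)) / (max(map) - min(map))
  }
  structure(map, target_class = as.integer(target_class),
            layer_name = layer_name, class = c("endo_heatmap", "matrix"))
}

#' @export
print.endo_heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap %dx%d (layer %s, class %d), mass %.2f\n",
              nrow(x), ncol(x), attr(x, "layer_name"),
              attr(x, "target_class"), sum(x)))
  invisible(x)
}

#' Sum of heatmap values inside each image quadrant
#' @param heatmap an `endo_heatmap` or plain matrix.
#' @return named vector with quadrant masses (`tl`, `tr`, `bl`, `br`).
#' @export
heatmap_quadrant_mass <- function(heatmap) {
  H <- nrow(heatmap); W <- ncol(heatmap)
  h <- H %/% 2L; w <- W %/% 2L
  c(tl = sum(heatmap[seq_len(h), seq_len(w)]),
    tr = sum(heatmap[seq_len(h), (w + 1L):W]),
    bl = sum(heatmap[(h + 1L):H, seq_len(w)]),
    br = sum(heatmap[(h + 1L):H, (w + 1L):W]))
}

#' Overlay a heatmap on an image
#'
#' The heatmap is mapped through a perceptually uniform colormap (viridis)
#' and alpha-blended: `out = (1 - alpha) * image + alpha * cmap(h)`.
#'
#' @param heatmap H x W matrix in \[0, 1\].
#' @param image H x W x 3 array in \[0, 1\].
#' @param alpha blend weight in \[0, 1\].
#' @return H x W x 3 array in \[0, 1\].
#' @export
overlay <- function(heatmap, image, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  d <- dim(image)
  if (nrow(heatmap) != d[1L] || ncol(heatmap) != d[2L])
    stop("heatmap and image shapes differ")
  cmap <- t(grDevices::col2rgb(grDevices::hcl.colors(256L, "viridis")) / 255)
  idx <- pmin(pmax(1L + round(as.vector(heatmap) * 255), 1L), 256L)
  hm_rgb <- array(cmap[idx, ], dim = c(d[1L], d[2L], 3L))
  out <- (1 - alpha) * image[, , 1:3, drop = FALSE] + alpha * hm_rgb
  pmin(pmax(out, 0), 1)
}

#' @export
plot.endo_heatmap <- function(x, image = NULL, alpha = 0.5, ...) {
  img <- if (is.null(image)) {
    array(rep(as.vector(unclass(x)), 3L), dim = c(dim(x), 3L))
  } else overlay(x, image, alpha)
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1)
  graphics::title(sprintf("Grad-CAM (%s, class %d)", attr(x, "layer_name"),
                          attr(x, "target_class")))
  invisible(x)
}
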