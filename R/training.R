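# Pretext pretraining, SMOTE, augmentation, and downstream classifier
# training with early stopping.

#' Training configuration
#'
#' Defaults follow the pretext protocol: Adam, learning rate 1e-3, batch
#' size 32, 20 epochs. Downstream training additionally uses early
#' stopping (`patience`, minimum improvement `min_delta`, best-epoch
#' weights restored) on a validation set carved patient-wise from the
#' training side (`val_frac`).
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param min_delta minimum validation-loss improvement that resets patience.
#' @param weight_decay L2 penalty added to gradients.
#' @param label_smoothing label-smoothing mass for the cross-entropy.
#' @param lr_plateau halve the learning rate when validation loss plateaus.
#' @param lr_factor,lr_patience plateau scheduler factor and patience.
#' @param val_frac fraction of training frames carved out for validation.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 20L, patience = 5L, min_delta = 1e-4,
                         weight_decay = 0, label_smoothing = 0,
                         lr_plateau = FALSE, lr_factor = 0.5,
                         lr_patience = 2L, val_frac = 0.15, seed = 1L) {
  stopifnot(learning_rate >= 0, batch_size >= 1, patience >= 1,
            max_epochs >= 1, val_frac >= 0, val_frac < 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 weight_decay = weight_decay,
                 label_smoothing = label_smoothing,
                 lr_plateau = lr_plateau, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "train_config")
}

# ---- early stopping ----------------------------------------------------

# Incremental early-stopping rule: an epoch "improves" when val_loss is
# below best - min_delta; `patience` consecutive non-improving epochs stop
# training, and the best epoch's weights are restored by the caller.
es_init <- function(patience, min_delta) {
  list(best = Inf, best_epoch = 0L, wait = 0L, stop = FALSE,
       patience = as.integer(patience), min_delta = min_delta)
}

es_update <- function(state, val_loss, epoch) {
  if (val_loss < state$best - state$min_delta) {
    state$best <- val_loss
    state$best_epoch <- epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

# Pure trace of the rule over a loss sequence (also used by tests).
early_stop_trace <- function(val_losses, patience, min_delta = 1e-4) {
  st <- es_init(patience, min_delta)
  stopped <- length(val_losses)
  for (e in seq_along(val_losses)) {
    st <- es_update(st, val_losses[e], e)
    if (st$stop) { stopped <- e; break }
  }
  list(stopped_epoch = stopped, best_epoch = st$best_epoch)
}

# ---- tensors from manifests -------------------------------------------

# (H, W, 3, N) float batch from manifest records; 1-channel records are
# replicated, alpha channels dropped.
manifest_tensor <- function(manifest, idx = seq_along(manifest$records)) {
  r1 <- manifest$records[[idx[1L]]]$pixels
  H <- dim(r1)[1L]; W <- dim(r1)[2L]
  out <- array(0, dim = c(H, W, 3L, length(idx)))
  for (i in seq_along(idx)) {
    px <- manifest$records[[idx[i]]]$pixels
    C <- dim(px)[3L]
    out[, , , i] <- if (C == 3L) px
    else if (C == 1L) px[, , c(1L, 1L, 1L)]
    else px[, , 1:3]
  }
  out
}

new_history <- function(df, stopped_epoch, best_epoch = NA_integer_) {
  structure(df, stopped_epoch = stopped_epoch, best_epoch = best_epoch,
            class = c("endossl_history", "data.frame"))
}

#' @export
print.endossl_history <- function(x, ...) {
  cat(sprintf("Training history: %d epochs (best epoch %s)\n",
              attr(x, "stopped_epoch"),
              ifelse(is.na(attr(x, "best_epoch")), "-",
                     attr(x, "best_epoch"))))
  print.data.frame(utils::tail(as.data.frame(x), 5L))
  invisible(x)
}

#' @export
plot.endossl_history <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  graphics::matplot(x$epoch, cbind(x$train_loss, x$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss", main = "Loss per epoch")
  graphics::legend("topright", c("train", "val"), lty = 1,
                   col = c("black", "red"), bty = "n")
  if (!all(is.na(x$train_accuracy))) {
    graphics::matplot(x$epoch, cbind(x$train_accuracy, x$val_accuracy),
                      type = "l", lty = 1, col = c("black", "red"),
                      xlab = "epoch", ylab = "accuracy",
                      main = "Accuracy per epoch")
  }
  invisible(x)
}

# ---- pretext pretraining ----------------------------------------------

#' Pretrain an encoder on a pretext task
#'
#' Trains the autoencoder (colorization, patch prediction) or the
#' encoder + permutation classification head (jigsaw) on the training side
#' of `split`, minimizing the task's loss for a fixed number of epochs
#' (no early stopping during pretraining). The test side of the split is
#' used only to monitor the per-epoch validation loss.
#'
#' @param task `"colorization"`, `"patch"` or `"jigsaw"`.
#' @param manifest an `endo_manifest`.
#' @param split an `endo_split` over the manifest.
#' @param spec autoencoder architecture; default
#'   `build_autoencoder(image size)`.
#' @param config a [train_config()].
#' @param perm_set jigsaw catalog; default 2x2 grid with all 24
#'   permutations.
#' @param patch_size center-patch side for the patch task; default a
#'   quarter of the image side.
#' @param mask_fill patch mask fill value.
#' @param color_mode colorization target: `"rgb"` or `"ab"`.
#' @return an `endossl_pretext`: the trained encoder (plus task head /
#'   decoder), the architecture spec and the training history.
#' @export
pretrain_pretext <- function(task = c("colorization", "patch", "jigsaw"),
                             manifest, split, spec = NULL,
                             config = train_config(), perm_set = NULL,
                             patch_size = NULL, mask_fill = 0.5,
                             color_mode = "rgb") {
  task <- match.arg(task)
  if (length(split$train_indices) == 0L) stop("empty training split")
  img_size <- dim(manifest$records[[1L]]$pixels)[1L]
  if (is.null(spec)) spec <- build_autoencoder(img_size)
  if (task == "jigsaw" && is.null(perm_set))
    perm_set <- build_permutation_set(2L, 24L, seed = config$seed)
  if (task == "patch" && is.null(patch_size)) patch_size <- img_size %/% 4L

  encoder <- decoder <- head <- NULL
  with_seed(config$seed, {
    encoder <- build_encoder_layers(spec, prefix = task)
    if (task == "jigsaw") {
      s0 <- spec$input_size %/% 16L
      feat <- 512L * s0 * s0
      head <- list(nn_flatten(paste0(task, ".flatten")),
                   nn_linear(feat, length(perm_set$perms),
                             name = paste0(task, ".perm_head")))
    } else {
      decoder <- build_decoder_layers(spec, prefix = task)
    }
  })
  all_layers <- c(encoder, decoder, head)
  adam_init(all_layers)

  n_out <- if (identical(color_mode, "ab")) 2L else 3L
  # channel-first targets/patch masks per record, built once
  prep <- prepare_pretext_inputs(task, manifest, img_size, patch_size,
                                 mask_fill, color_mode)

  run_batch <- function(idx, labels, training, step_t) {
    x <- prep$input[, , , idx, drop = FALSE]
    N <- length(idx)
    if (task == "jigsaw") {
      # labels sampled by caller; build shuffled batch
      xs <- array(0, dim = dim(x))
      for (i in seq_len(N)) {
        img <- aperm(x[, , , i, drop = TRUE], c(2L, 3L, 1L))
        sh <- tile_and_permute(img, perm_set, labels[i])$shuffled_image
        xs[, , , i] <- aperm(sh, c(3L, 1L, 2L))
      }
      feats <- seq_forward(encoder, xs, training)
      logits <- seq_forward(head, feats, training)
      ce <- softmax_ce(logits, labels + 1L)
      acc <- mean(apply(logits, 2L, which.max) - 1L == labels)
      if (training) {
        g <- seq_backward(head, ce$dlogits)
        seq_backward(encoder, g)
        adam_step(all_layers, config$learning_rate, step_t,
                  weight_decay = config$weight_decay)
      }
      list(loss = ce$loss, acc = acc)
    } else {
      target <- prep$target[, , , idx, drop = FALSE]
      feats <- seq_forward(encoder, x, training)
      out <- seq_forward(decoder, feats, training)
      if (task == "patch") {
        box <- prep$box
        pred <- out[seq_len(n_out), box$rows, box$cols, , drop = FALSE]
        tgt <- target[, box$rows, box$cols, , drop = FALSE]
        diff <- pred - tgt
        loss <- mean(diff * diff)
        if (training) {
          g <- array(0, dim = dim(out))
          g[seq_len(n_out), box$rows, box$cols, ] <- 2 * diff / length(diff)
          gf <- seq_backward(decoder, g)
          seq_backward(encoder, gf)
          adam_step(all_layers, config$learning_rate, step_t,
                    weight_decay = config$weight_decay)
        }
        list(loss = loss, acc = NA_real_)
      } else {
        pred <- out[seq_len(n_out), , , , drop = FALSE]
        diff <- pred - target
        loss <- mean(diff * diff)
        if (training) {
          g <- array(0, dim = dim(out))
          g[seq_len(n_out), , , ] <- 2 * diff / length(diff)
          gf <- seq_backward(decoder, g)
          seq_backward(encoder, gf)
          adam_step(all_layers, config$learning_rate, step_t,
                    weight_decay = config$weight_decay)
        }
        list(loss = loss, acc = NA_real_)
      }
    }
  }

  hist_rows <- vector("list", config$max_epochs)
  with_seed(config$seed + 1L, {
    step_t <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(split$train_indices)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      losses <- accs <- c()
      for (b in batches) {
        labels <- if (task == "jigsaw")
          sample.int(length(perm_set$perms), length(b), replace = TRUE) - 1L
        step_t <- step_t + 1L
        r <- run_batch(b, labels, training = TRUE, step_t = step_t)
        losses <- c(losses, r$loss); accs <- c(accs, r$acc)
      }
      vidx <- split$test_indices
      vr <- if (length(vidx)) {
        vlab <- if (task == "jigsaw")
          sample.int(length(perm_set$perms), length(vidx), replace = TRUE) - 1L
        run_batch(vidx, vlab, training = FALSE, step_t = step_t)
      } else list(loss = NA_real_, acc = NA_real_)
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(losses), val_loss = vr$loss,
        train_accuracy = mean(accs), val_accuracy = vr$acc)
    }
  })
  history <- new_history(do.call(rbind, hist_rows), config$max_epochs)
  structure(list(task = task, encoder = encoder, decoder = decoder,
                 head = head, spec = spec, perm_set = perm_set,
                 patch_size = patch_size, color_mode = color_mode,
                 history = history, config = config),
            class = "endossl_pretext")
}

prepare_pretext_inputs <- function(task, manifest, img_size, patch_size,
                                   mask_fill, color_mode) {
  x <- manifest_tensor(manifest)
  N <- dim(x)[4L]
  if (task == "colorization") {
    input <- stack_input(x, "gray")
    n_out <- if (identical(color_mode, "ab")) 2L else 3L
    target <- array(0, dim = c(n_out, img_size, img_size, N))
    for (i in seq_len(N)) {
      samp <- make_colorization_sample(x[, , , i, drop = TRUE],
                                       mode = color_mode)
      target[, , , i] <- aperm(samp$color_target, c(3L, 1L, 2L))
    }
    list(input = input, target = target)
  } else if (task == "patch") {
    target <- array(0, dim = c(3L, img_size, img_size, N))
    ctx <- array(0, dim = dim(x))
    box <- NULL
    for (i in seq_len(N)) {
      img <- x[, , , i, drop = TRUE]
      samp <- make_patch_sample(img, patch_size = patch_size,
                                mask_fill = mask_fill)
      ctx[, , , i] <- samp$context_image
      target[, , , i] <- aperm(img, c(3L, 1L, 2L))
      if (is.null(box)) {
        rows <- samp$patch_box["row"] + seq_len(samp$patch_box["size"]) - 1L
        box <- list(rows = rows, cols = samp$patch_box["col"] +
                      seq_len(samp$patch_box["size"]) - 1L)
      }
    }
    list(input = stack_input(ctx, "rgb"), target = target, box = box)
  } else {
    list(input = stack_input(x, "rgb"))
  }
}

#' @export
print.endossl_pretext <- function(x, ...) {
  h <- x$history
  cat(sprintf("Pretext encoder (%s): %d epochs, final train loss %.4g\n",
              x$task, nrow(h), h$train_loss[nrow(h)]))
  invisible(x)
}

# ---- SMOTE -------------------------------------------------------------

#' Balance classes by synthetic minority oversampling (SMOTE)
#'
#' Each synthetic sample is `x + lambda * (x_nn - x)` with
#' `lambda ~ U(0, 1)`, where `x` is a minority-class sample and `x_nn` one
#' of its `k_neighbors` nearest same-class neighbors (Euclidean). After
#' balancing, every class has as many samples as the majority class.
#' Apply to training data only.
#'
#' @param x numeric matrix, one flattened sample per row.
#' @param labels class label per row.
#' @param k_neighbors neighborhood size.
#' @param seed integer seed.
#' @return list with `x`, `labels` and a `provenance` data frame
#'   (`base`, `neighbor`, `lambda` rows for every synthetic sample; row
#'   indices refer to the input matrix).
#' @export
smote_balance <- function(x, labels, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  counts <- table(labels)
  maj <- max(counts)
  prov <- data.frame(base = integer(), neighbor = integer(),
                     lambda = numeric(), label = labels[0])
  if (all(counts == maj))
    return(list(x = x, labels = labels, provenance = prov))
  synth <- list(); synth_lab <- list()
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- maj - counts[[cl]]
      if (need == 0L) next
      rows <- which(labels == cl)
      if (length(rows) <= k_neighbors)
        stop(sprintf(
          "class '%s' has only %d samples; choose k_neighbors < %d",
          cl, length(rows), length(rows)))
      D <- as.matrix(stats::dist(x[rows, , drop = FALSE]))
      nnv <- vapply(seq_len(nrow(D)),
                    function(i) order(D[i, ])[2:(k_neighbors + 1L)],
                    numeric(k_neighbors))
      nn <- if (is.matrix(nnv)) t(nnv) else matrix(nnv, ncol = 1L)
      base_seq <- rep(seq_along(rows), length.out = need)
      for (i in seq_len(need)) {
        b <- base_seq[i]
        nb <- nn[b, sample.int(k_neighbors, 1L)]
        lam <- stats::runif(1L)
        synth[[length(synth) + 1L]] <-
          x[rows[b], ] + lam * (x[rows[nb], ] - x[rows[b], ])
        synth_lab[[length(synth_lab) + 1L]] <- labels[rows[b]]
        prov <- rbind(prov, data.frame(base = rows[b], neighbor = rows[nb],
                                       lambda = lam,
                                       label = labels[rows[b]]))
      }
    }
  })
  list(x = rbind(x, do.call(rbind, synth)),
       labels = c(labels, unlist(synth_lab)),
       provenance = prov)
}

# ---- augmentation ------------------------------------------------------

#' Augmentation configuration
#'
#' The enabled transforms and their ranges: rotation up to `max_angle`
#' degrees, horizontal/vertical flips (each applied with probability 1/2),
#' zoom, additive brightness, and multiplicative contrast about the image
#' mean. With every transform disabled, [augment()] is the identity.
#'
#' @param rotation enable random rotation.
#' @param max_angle rotation bound in degrees.
#' @param hflip,vflip enable random flips.
#' @param zoom length-2 zoom factor range (`c(1, 1)` disables).
#' @param brightness additive intensity bound (0 disables).
#' @param contrast length-2 contrast factor range (`c(1, 1)` disables).
#' @return an `augment_config` list.
#' @export
augment_config <- function(rotation = TRUE, max_angle = 15, hflip = TRUE,
                           vflip = TRUE, zoom = c(0.9, 1.1),
                           brightness = 0.1, contrast = c(0.9, 1.1)) {
  structure(list(rotation = rotation, max_angle = max_angle, hflip = hflip,
                 vflip = vflip, zoom = zoom, brightness = brightness,
                 contrast = contrast),
            class = "augment_config")
}

#' Flip an image along one axis
#' @param image H x W x C array.
#' @param direction `"horizontal"` (mirror columns) or `"vertical"`.
#' @return flipped array (an exact involution).
#' @export
flip_image <- function(image, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  if (direction == "horizontal") image[, rev(seq_len(dim(image)[2L])), , drop = FALSE]
  else image[rev(seq_len(dim(image)[1L])), , , drop = FALSE]
}

# Inverse-affine bilinear resampling about the image center with edge
# clamping; used for rotation and zoom so output shape always equals input
# shape.
affine_sample <- function(image, angle_deg = 0, zoom = 1) {
  d <- dim(image)
  H <- d[1L]; W <- d[2L]
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H), times = W) - cy
  gx <- rep(seq_len(W), each = H) - cx
  # inverse map: rotate by -theta, scale by 1/zoom
  sy <- (cos(th) * gy - sin(th) * gx) / zoom + cy
  sx <- (sin(th) * gy + cos(th) * gx) / zoom + cx
  y0 <- pmin(pmax(floor(sy), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(sx), 1), W); x1 <- pmin(x0 + 1, W)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, dim = d)
  for (c in seq_len(d[3L])) {
    pl <- image[, , c]
    v <- (1 - fy) * (1 - fx) * pl[cbind(y0, x0)] +
      fy * (1 - fx) * pl[cbind(y1, x0)] +
      (1 - fy) * fx * pl[cbind(y0, x1)] +
      fy * fx * pl[cbind(y1, x1)]
    out[, , c] <- matrix(v, H, W)
  }
  out
}

#' Randomly augment an image
#'
#' Applies a seeded random draw of the transforms enabled in `config`;
#' output is clipped to \[0, 1\] and has the input's shape.
#'
#' @param image H x W x C array in \[0, 1\].
#' @param config an [augment_config()].
#' @param seed integer seed (same seed, same output).
#' @return augmented image array.
#' @export
augment <- function(image, config = augment_config(), seed = 1L) {
  stopifnot(min(image) >= 0, max(image) <= 1)
  with_seed(seed, {
    out <- image
    angle <- if (isTRUE(config$rotation))
      stats::runif(1L, -config$max_angle, config$max_angle) else 0
    zoom <- if (!isTRUE(all.equal(config$zoom, c(1, 1))))
      stats::runif(1L, config$zoom[1L], config$zoom[2L]) else 1
    if (angle != 0 || zoom != 1) out <- affine_sample(out, angle, zoom)
    if (isTRUE(config$hflip) && stats::runif(1L) < 0.5)
      out <- flip_image(out, "horizontal")
    if (isTRUE(config$vflip) && stats::runif(1L) < 0.5)
      out <- flip_image(out, "vertical")
    if (config$brightness > 0)
      out <- out + stats::runif(1L, -config$brightness, config$brightness)
    if (!isTRUE(all.equal(config$contrast, c(1, 1)))) {
      f <- stats::runif(1L, config$contrast[1L], config$contrast[2L])
      out <- (out - mean(out)) * f + mean(out)
    }
    pmin(pmax(out, 0), 1)
  })
}

# ---- downstream classifier --------------------------------------------

# validation indices carved patient-wise from the training side
carve_validation <- function(manifest, train_indices, val_frac, seed) {
  if (val_frac <= 0) return(list(train = train_indices, val = integer()))
  pats <- manifest_patients(manifest)[train_indices]
  upat <- unique(pats)
  if (length(upat) >= 2L) {
    counts <- table(pats)[upat]
    ord <- with_seed(seed, {
      perm <- sample(length(upat))
      perm[order(counts[perm])]            # smallest patients to validation
    })
    need <- val_frac * length(train_indices)
    cum <- cumsum(as.integer(counts[ord]))
    nval <- max(1L, which(cum >= need)[1L])
    if (is.na(nval)) nval <- 1L
    nval <- min(nval, length(upat) - 1L)
    vp <- upat[ord[seq_len(nval)]]
    list(train = train_indices[!pats %in% vp],
         val = train_indices[pats %in% vp])
  } else {
    nval <- max(1L, floor(val_frac * length(train_indices)))
    vi <- with_seed(seed, sample(seq_along(train_indices), nval))
    list(train = train_indices[-vi], val = train_indices[vi])
  }
}

feats_to_matrix <- function(f) {
  if (is.matrix(f)) f
  else {
    d <- dim(f)
    matrix(f, nrow = prod(d[-length(d)]), ncol = d[length(d)])
  }
}

# frozen-encoder features for a batch of images (H, W, 3, N)
encoder_features <- function(model, x, batch = 64L) {
  N <- dim(x)[4L]
  out <- list()
  for (nm in names(model$encoders)) {
    enc <- model$encoders[[nm]]
    chunks <- split(seq_len(N), ceiling(seq_len(N) / batch))
    f <- NULL
    for (ch in chunks) {
      xi <- stack_input(x[, , , ch, drop = FALSE], enc$transform)
      fi <- seq_forward(enc$layers, xi, training = FALSE)
      f <- if (is.null(f)) fi else abind4(f, fi)
    }
    out[[nm]] <- f
  }
  out
}

abind4 <- function(a, b) {
  if (is.matrix(a)) return(cbind(a, b))
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4L] + db[4L]))
  out[, , , seq_len(da[4L])] <- a
  out[, , , da[4L] + seq_len(db[4L])] <- b
  out
}

# fused (variant-pooled, flattened, concatenated) feature matrix
head_input_matrix <- function(model, feats, idx = NULL, training = FALSE) {
  parts <- list()
  for (nm in names(model$encoders)) {
    f <- feats[[nm]]
    if (!is.null(idx))
      f <- if (is.matrix(f)) f[, idx, drop = FALSE]
      else f[, , , idx, drop = FALSE]
    if (!is.null(model$variant_mods))
      f <- seq_forward(model$variant_mods[[nm]], f, training)
    parts[[nm]] <- feats_to_matrix(f)
  }
  do.call(rbind, parts)
}

# variant + head forward on stored encoder features; returns logits
head_forward <- function(model, feats, idx = NULL, training = FALSE) {
  seq_forward(model$head, head_input_matrix(model, feats, idx, training),
              training)
}

#' Train the downstream landmark classifier
#'
#' Trains the fusion head (and attention/transformer module, if present)
#' of a model on the training side of `split` with cross-entropy and Adam,
#' keeping pretrained encoders frozen as feature extractors. A validation
#' set is carved patient-wise from the training side; training stops early
#' when the validation loss fails to improve by at least
#' `config$min_delta` for `config$patience` consecutive epochs, and the
#' best epoch's weights are restored. SMOTE and augmentation, when
#' enabled, are applied to training frames only — never to validation or
#' test frames — and the indices they touched are recorded in
#' `$data_usage` of the result.
#'
#' @param model an `endossl_model` from [build_combined()] or
#'   [build_baseline()].
#' @param manifest an `endo_manifest`.
#' @param split an `endo_split`.
#' @param config a [train_config()].
#' @param use_smote balance training frames by [smote_balance()] on
#'   flattened pixels.
#' @param use_augment append one seeded augmented copy of each training
#'   frame.
#' @param augment_cfg an [augment_config()].
#' @param fine_tune `"last_block"` (default) additionally fine-tunes each
#'   encoder's final convolution stage during downstream training;
#'   `"none"` keeps encoders entirely frozen (pure probing).
#' @return the fitted `endossl_model`, with `$history` (an
#'   `endossl_history`) and `$data_usage`.
#' @export
train_classifier <- function(model, manifest, split, config = train_config(),
                             use_smote = FALSE, use_augment = FALSE,
                             augment_cfg = augment_config(),
                             fine_tune = c("last_block", "none")) {
  stopifnot(inherits(model, "endossl_model"))
  fine_tune <- match.arg(fine_tune)
  labels_all <- manifest_labels(manifest)
  cv <- carve_validation(manifest, split$train_indices, config$val_frac,
                         config$seed)
  y_tr <- labels_all[cv$train]
  if (length(unique(y_tr)) < 3L)
    stop("training split does not cover all 3 classes")
  x_tr <- manifest_tensor(manifest, cv$train)
  usage <- list(train_indices = cv$train, val_indices = cv$val,
                augmented_indices = integer(), smote_base_indices = integer())

  if (use_augment) {
    seeds <- with_seed(config$seed, sample.int(.Machine$integer.max %/% 2L,
                                               length(cv$train)))
    aug <- array(0, dim = dim(x_tr))
    for (i in seq_along(cv$train))
      aug[, , , i] <- augment(x_tr[, , , i, drop = TRUE], augment_cfg,
                              seed = seeds[i])
    x_tr <- abind4(x_tr, aug)
    y_tr <- c(y_tr, y_tr)
    usage$augmented_indices <- cv$train
  }
  if (use_smote) {
    d <- dim(x_tr)
    flat <- t(matrix(x_tr, nrow = prod(d[1:3])))
    bal <- smote_balance(flat, y_tr, k_neighbors = min(5L, min(table(y_tr)) - 1L),
                         seed = config$seed)
    n_new <- nrow(bal$x) - nrow(flat)
    if (n_new > 0L) {
      synth <- array(t(bal$x[nrow(flat) + seq_len(n_new), , drop = FALSE]),
                     dim = c(d[1:3], n_new))
      synth <- pmin(pmax(synth, 0), 1)
      x_tr <- abind4(x_tr, synth)
      y_tr <- bal$labels
    }
    base_pos <- bal$provenance$base
    base_pos <- ifelse(base_pos > length(cv$train),
                       base_pos - length(cv$train), base_pos)  # augmented copies
    usage$smote_base_indices <- unique(cv$train[base_pos])
  }

  # Split each encoder into a frozen prefix (features precomputed once)
  # and an optional tuned suffix (the final convolution stage), so deep
  # fine-tuning stays cheap while the representation can still adapt to
  # the classification task.
  enc_parts <- lapply(model$encoders, function(enc) {
    convs <- which(vapply(enc$layers, function(l) l$kind == "conv2d", TRUE))
    if (fine_tune == "last_block" && length(convs) > 0L) {
      k <- convs[length(convs)]
      list(frozen = enc$layers[seq_len(k - 1L)],
           tuned = enc$layers[k:length(enc$layers)])
    } else {
      list(frozen = enc$layers, tuned = list())
    }
  })
  s_hw <- model$input_size %/% 16L
  pre_feats <- function(x) {
    out <- list()
    N <- dim(x)[4L]
    for (nm in names(model$encoders)) {
      enc <- model$encoders[[nm]]
      chunks <- split(seq_len(N), ceiling(seq_len(N) / 64L))
      f <- NULL
      for (ch in chunks) {
        xi <- stack_input(x[, , , ch, drop = FALSE], enc$transform)
        fi <- seq_forward(enc_parts[[nm]]$frozen, xi, training = FALSE)
        f <- if (is.null(f)) fi else abind4(f, fi)
      }
      out[[nm]] <- f
    }
    out
  }
  fused_input <- function(pf, idx = NULL, training = FALSE) {
    parts <- list()
    for (nm in names(model$encoders)) {
      f <- pf[[nm]]
      if (!is.null(idx))
        f <- if (is.matrix(f)) f[, idx, drop = FALSE]
        else f[, , , idx, drop = FALSE]
      if (length(enc_parts[[nm]]$tuned))
        f <- seq_forward(enc_parts[[nm]]$tuned, f, training)
      if (!is.null(model$variant_mods))
        f <- seq_forward(model$variant_mods[[nm]], f, training)
      parts[[nm]] <- feats_to_matrix(f)
    }
    do.call(rbind, parts)
  }
  fused_backward <- function(dlogits) {
    g <- seq_backward(model$head, dlogits)
    per <- model$concat_width %/% length(model$encoders)
    for (i in seq_along(model$encoders)) {
      nm <- names(model$encoders)[i]
      tuned <- enc_parts[[nm]]$tuned
      if (is.null(model$variant_mods) && !length(tuned)) next
      gi <- g[(i - 1L) * per + seq_len(per), , drop = FALSE]
      gf <- if (!is.null(model$variant_mods))
        seq_backward(model$variant_mods[[nm]], gi)
      else array(gi, dim = c(512L, s_hw, s_hw, ncol(gi)))
      if (length(tuned)) seq_backward(tuned, gf)
    }
    invisible(NULL)
  }

  pf_tr <- pre_feats(x_tr)
  # Standardize the fused feature vector (training-set statistics at
  # initialization, frozen thereafter) so the head optimizes over
  # comparably scaled inputs; the layer lives in the head and is applied
  # identically at prediction time.
  if (model$head[[1L]]$kind == "standardize")
    model$head <- model$head[-1L]
  raw <- fused_input(pf_tr)
  mu <- rowMeans(raw)
  sc <- 1 / pmax(apply(raw, 1L, stats::sd), 1e-3)
  model$head <- c(list(nn_standardize(mu, sc, name = "head.standardize")),
                  model$head)
  has_val <- length(cv$val) > 0L
  if (has_val) {
    pf_val <- pre_feats(manifest_tensor(manifest, cv$val))
    y_val <- labels_all[cv$val]
  }
  trainable <- c(model$head, unlist(model$variant_mods, recursive = FALSE),
                 unlist(lapply(unname(enc_parts), function(p) p$tuned),
                        recursive = FALSE))
  adam_init(trainable)

  hist_rows <- list()
  es <- es_init(config$patience, config$min_delta)
  best_snap <- snapshot_params(trainable)
  lr <- config$learning_rate
  lr_wait <- 0L
  n_tr <- length(y_tr)
  with_seed(config$seed + 1L, {
    step_t <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      losses <- c(); correct <- 0L
      for (b in batches) {
        logits <- seq_forward(model$head, fused_input(pf_tr, idx = b,
                                                      training = TRUE),
                              training = TRUE)
        ce <- softmax_ce(logits, y_tr[b] + 1L,
                         label_smoothing = config$label_smoothing)
        correct <- correct + sum(apply(logits, 2L, which.max) - 1L == y_tr[b])
        fused_backward(ce$dlogits)
        step_t <- step_t + 1L
        adam_step(trainable, lr, step_t, weight_decay = config$weight_decay)
        losses <- c(losses, ce$loss)
      }
      if (has_val) {
        vlogits <- seq_forward(model$head, fused_input(pf_val),
                               training = FALSE)
        vce <- softmax_ce(vlogits, y_val + 1L,
                          label_smoothing = config$label_smoothing)
        vacc <- mean(apply(vlogits, 2L, which.max) - 1L == y_val)
        vloss <- vce$loss
      } else {
        vloss <- mean(losses); vacc <- NA_real_
      }
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(losses), val_loss = vloss,
        train_accuracy = correct / n_tr, val_accuracy = vacc)
      prev_best <- es$best
      es <- es_update(es, vloss, epoch)
      if (es$best_epoch == epoch) best_snap <- snapshot_params(trainable)
      if (config$lr_plateau) {
        if (vloss < prev_best - config$min_delta) lr_wait <- 0L
        else {
          lr_wait <- lr_wait + 1L
          if (lr_wait >= config$lr_patience) {
            lr <- lr * config$lr_factor
            lr_wait <- 0L
          }
        }
      }
      if (es$stop) break
    }
  })
  if (es$best_epoch > 0L) restore_params(trainable, best_snap)
  model$history <- new_history(do.call(rbind, hist_rows),
                               stopped_epoch = length(hist_rows),
                               best_epoch = max(es$best_epoch, 1L))
  model$data_usage <- usage
  model$trained <- TRUE
  model
}

# full forward pass from raw images; returns logits (3 x N)
model_forward <- function(model, x, training = FALSE) {
  feats <- encoder_features(model, x)
  head_forward(model, feats, training = training)
}

#' Predict landmark classes
#'
#' @param object a fitted `endossl_model`.
#' @param newdata an `endo_manifest`, an H x W x 3 image, or an
#'   H x W x 3 x N batch array.
#' @param type `"prob"` (softmax scores), `"class"` (0-based labels) or
#'   `"logits"`.
#' @param ... unused.
#' @return N x 3 matrix of scores, or an integer vector for
#'   `type = "class"`.
#' @export
predict.endossl_model <- function(object, newdata,
                                  type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "endo_manifest")) manifest_tensor(newdata)
  else if (length(dim(newdata)) == 3L) array(newdata, c(dim(newdata), 1L))
  else newdata
  logits <- model_forward(object, x)
  if (type == "logits") return(t(logits))
  pr <- t(softmax_cols(logits))
  colnames(pr) <- object$class_names
  if (type == "prob") pr else max.col(pr) - 1L
}

#' @export
print.endossl_model <- function(x, ...) {
  cat(sprintf("endossl %s model (scenario %s, input %dx%d)\n", x$type,
              x$scenario, x$input_size, x$input_size))
  cat("  encoders:", paste(names(x$encoders), collapse = ", "), "\n")
  if (x$variant != "none") cat("  variant:", x$variant, "\n")
  cat("  fused feature width:", x$concat_width, "\n")
  cat("  trained:", x$trained, "\n")
  invisible(x)
}

#' @export
summary.endossl_model <- function(object, ...) {
  print(object)
  n_enc <- sum(vapply(object$encoders,
                      function(e) n_params(e$layers), 0))
  n_head <- n_params(c(object$head,
                       unlist(object$variant_mods, recursive = FALSE)))
  cat(sprintf("  parameters: %d encoder + %d head/variant\n",
              n_enc, n_head))
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  best epoch %d: val loss %.4f, val accuracy %.3f\n",
                attr(h, "best_epoch"),
                h$val_loss[attr(h, "best_epoch")],
                h$val_accuracy[attr(h, "best_epoch")]))
  }
  invisible(object)
}
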