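test_that("the early-stopping rule matches a hand trace", {
  tr <- endossl:::early_stop_trace(c(1.0, 0.9, 0.9, 0.9, 0.9), patience = 3)
  expect_identical(tr$stopped_epoch, 5L)
  expect_identical(tr$best_epoch, 2L)
  # monotone improvement never stops
  tr2 <- endossl:::early_stop_trace(seq(1, 0.1, by = -0.1), patience = 3)
  expect_identical(tr2$stopped_epoch, 10L)
  expect_identical(tr2$best_epoch, 10L)
  # improvements below min_delta do not reset patience
  tr3 <- endossl:::early_stop_trace(c(1, 0.99999, 0.99998, 0.99997),
                                    patience = 2, min_delta = 1e-4)
  expect_identical(tr3$stopped_epoch, 3L)
  expect_identical(tr3$best_epoch, 1L)
  expect_error(train_config(patience = 0), "patience")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("pretext pretraining reduces its loss on a small fixture", {
  m <- tiny_manifest(c(10, 10, 10), size = 16, patients = 4, seed = 2)
  sp <- patient_wise_split(m, 0.7, seed = 2)
  cfg <- train_config(max_epochs = 5, batch_size = 16, seed = 2)
  for (task in c("colorization", "patch")) {
    enc <- pretrain_pretext(task, m, sp, config = cfg)
    h <- enc$history
    expect_identical(nrow(h), 5L)
    expect_true(all(is.finite(h$train_loss)) && all(h$train_loss >= 0))
    expect_lt(h$train_loss[5], h$train_loss[1])
    expect_true(all(is.finite(h$val_loss)))
  }
  expect_error(pretrain_pretext("patch", m, endossl:::new_split(integer(),
                                                                1:5, 1L)),
               "empty")
})

test_that("a zero learning rate leaves parameters unchanged", {
  m <- tiny_manifest(c(4, 4, 4), size = 16, patients = 3, seed = 3)
  sp <- patient_wise_split(m, 0.7, seed = 3)
  cfg0 <- train_config(learning_rate = 0, max_epochs = 1, seed = 3)
  enc <- pretrain_pretext("colorization", m, sp, config = cfg0)
  spec <- build_autoencoder(16)
  init <- endossl:::with_seed(cfg0$seed,
                              endossl:::build_encoder_layers(spec, "colorization"))
  expect_identical(endossl:::snapshot_params(enc$encoder),
                   endossl:::snapshot_params(init))
})

test_that("an easy jigsaw task is learned to high held-out accuracy", {
  m <- tiny_manifest(c(10, 10, 10), size = 16, patients = 4, seed = 4)
  sp <- patient_wise_split(m, 0.7, seed = 4)
  ps <- build_permutation_set(2, 2, seed = 4)   # identity vs a derangement
  enc <- pretrain_pretext("jigsaw", m, sp, perm_set = ps,
                          config = train_config(max_epochs = 10,
                                                batch_size = 16, seed = 4))
  expect_gt(enc$history$val_accuracy[10], 0.9)
})

test_that("SMOTE balances to the majority count by convex interpolation", {
  set.seed(5)
  x <- matrix(stats::runif(60 * 6), ncol = 6)
  y <- rep(c(0L, 1L, 2L), times = c(10, 30, 20))
  out <- smote_balance(x, y, k_neighbors = 5, seed = 5)
  expect_equal(as.vector(table(out$labels)), c(30, 30, 30))
  # provenance: each synthetic row is exactly x_b + lambda (x_n - x_b)
  pr <- out$provenance
  expect_identical(nrow(pr), 30L)
  for (i in seq_len(nrow(pr))) {
    expect_true(pr$lambda[i] >= 0 && pr$lambda[i] <= 1)
    expect_identical(y[pr$base[i]], y[pr$neighbor[i]])
    synth <- out$x[60 + i, ]
    recon <- x[pr$base[i], ] + pr$lambda[i] * (x[pr$neighbor[i], ] -
                                                 x[pr$base[i], ])
    expect_equal(synth, recon, tolerance = 1e-12)
  }
  # 1-D minority {0, 1}: synthetic values stay inside the hull
  x2 <- matrix(c(0, 1, stats::runif(20, 2, 3)), ncol = 1)
  y2 <- c(0L, 0L, rep(1L, 20))
  out2 <- smote_balance(x2, y2, k_neighbors = 1, seed = 1)
  synth2 <- out2$x[-(1:22), 1]
  expect_true(all(synth2 >= 0 & synth2 <= 1))
  # balanced input returned unchanged
  xb <- matrix(stats::runif(45), ncol = 3)
  yb <- rep(0:2, each = 5)
  outb <- smote_balance(xb, yb, seed = 1)
  expect_identical(outb$x, xb)
  expect_identical(nrow(outb$provenance), 0L)
  expect_error(smote_balance(x, y, k_neighbors = 10, seed = 1),
               "k_neighbors")
})

test_that("augmentation is seeded, shape-preserving and bounded", {
  img <- array(stats::runif(16 * 16 * 3), dim = c(16, 16, 3))
  off <- augment_config(rotation = FALSE, hflip = FALSE, vflip = FALSE,
                        zoom = c(1, 1), brightness = 0, contrast = c(1, 1))
  expect_identical(augment(img, off, seed = 1), img)
  expect_identical(flip_image(flip_image(img, "horizontal"), "horizontal"),
                   img)
  expect_identical(flip_image(flip_image(img, "vertical"), "vertical"), img)
  a1 <- augment(img, augment_config(), seed = 99)
  a2 <- augment(img, augment_config(), seed = 99)
  expect_identical(a1, a2)
  expect_false(identical(a1, augment(img, augment_config(), seed = 100)))
  expect_identical(dim(a1), dim(img))
  expect_true(min(a1) >= 0 && max(a1) <= 1)
})

test_that("classifier training obeys the early-stopping/bookkeeping contracts", {
  m <- tiny_manifest(c(12, 12, 12), size = 16, patients = 4, seed = 6)
  sp <- patient_wise_split(m, 0.75, seed = 6)
  model <- build_combined("Cl", input_size = 16, seed = 6)
  cfg <- train_config(max_epochs = 8, batch_size = 16, patience = 3,
                      seed = 6)
  fit <- train_classifier(model, m, sp, cfg, use_smote = TRUE,
                          use_augment = TRUE)
  h <- fit$history
  expect_s3_class(h, "endossl_history")
  expect_identical(nrow(h), attr(h, "stopped_epoch"))
  expect_true(all(is.finite(h$train_loss)) && all(h$train_loss >= 0))
  expect_true(all(is.finite(h$val_loss)))
  # restored weights come from an epoch whose val loss is within min_delta
  # of the overall minimum (the rule only registers improvements > min_delta)
  expect_lte(h$val_loss[attr(h, "best_epoch")] - min(h$val_loss),
             cfg$min_delta + 1e-12)
  # instrumentation: SMOTE/augment touched only training indices, and the
  # carved validation set is disjoint from them
  u <- fit$data_usage
  expect_true(all(u$augmented_indices %in% sp$train_indices))
  expect_true(all(u$smote_base_indices %in% sp$train_indices))
  expect_true(all(u$train_indices %in% sp$train_indices))
  expect_true(all(u$val_indices %in% sp$train_indices))
  expect_length(intersect(u$val_indices, u$train_indices), 0)
  expect_length(intersect(u$val_indices, u$augmented_indices), 0)
  # prediction surface
  pr <- predict(fit, m)
  expect_identical(dim(pr), c(36L, 3L))
  expect_equal(unname(rowSums(pr)), rep(1, 36), tolerance = 1e-9)
  cls <- predict(fit, m, type = "class")
  expect_true(all(cls %in% 0:2))
})

test_that("identical seeds reproduce identical training histories", {
  m <- tiny_manifest(c(8, 8, 8), size = 16, patients = 4, seed = 7)
  sp <- patient_wise_split(m, 0.75, seed = 7)
  cfg <- train_config(max_epochs = 3, batch_size = 16, seed = 7)
  f1 <- train_classifier(build_combined("JigPuzz", input_size = 16, seed = 7),
                         m, sp, cfg)
  f2 <- train_classifier(build_combined("JigPuzz", input_size = 16, seed = 7),
                         m, sp, cfg)
  expect_identical(as.data.frame(f1$history), as.data.frame(f2$history))
  p1 <- pretrain_pretext("patch", m, sp, config = cfg)
  p2 <- pretrain_pretext("patch", m, sp, config = cfg)
  expect_identical(as.data.frame(p1$history), as.data.frame(p2$history))
})

test_that("training errors on an incomplete class coverage", {
  m <- tiny_manifest(c(8, 8, 8), size = 16, patients = 4, seed = 8)
  # restrict training side to class 0 frames only
  idx0 <- which(manifest_labels(m) == 0L)
  sp <- endossl:::new_split(idx0, setdiff(seq_len(24), idx0), 1L)
  model <- build_combined("Cl", input_size = 16, seed = 8)
  expect_error(train_classifier(model, m, sp, train_config(max_epochs = 1)),
               "classes")
})
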