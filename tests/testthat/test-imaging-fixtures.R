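test_that("generate_dataset honors counts, ranges and patient coverage", {
  m <- generate_dataset(c(10, 10, 10), image_size = 16, n_patients = 5,
                        seed = 1)
  expect_s3_class(m, "endo_manifest")
  expect_length(m$records, 30)
  expect_identical(m$class_counts, c(10L, 10L, 10L))
  px <- m$records[[1]]$pixels
  expect_identical(dim(px), c(16L, 16L, 3L))
  expect_true(all(vapply(m$records, function(r)
    min(r$pixels) >= 0 && max(r$pixels) <= 1, TRUE)))
  # round-robin assignment: every patient holds frames of all classes
  df <- data.frame(p = manifest_patients(m), y = manifest_labels(m))
  cov <- tapply(df$y, df$p, function(y) length(unique(y)))
  expect_true(all(cov == 3))
  expect_error(generate_dataset(c(10, 10), n_patients = 5),
               "n_per_class")
  expect_error(generate_dataset(c(5, 5, 5), image_size = 8), "image_size")
  expect_error(generate_dataset(c(5, 5, 5), n_patients = 2), "n_patients")
})

test_that("generation is a pure function of the seed", {
  m1 <- generate_dataset(c(4, 4, 4), image_size = 16, n_patients = 3, seed = 9)
  m2 <- generate_dataset(c(4, 4, 4), image_size = 16, n_patients = 3, seed = 9)
  m3 <- generate_dataset(c(4, 4, 4), image_size = 16, n_patients = 3, seed = 10)
  expect_identical(m1$records[[5]]$pixels, m2$records[[5]]$pixels)
  expect_false(identical(m1$records[[5]]$pixels, m3$records[[5]]$pixels))
  # single-channel and 4-channel modes
  g <- generate_dataset(c(2, 2, 2), image_size = 16, n_patients = 3,
                        channels = 1, seed = 1)
  expect_identical(dim(g$records[[1]]$pixels)[3], 1L)
  a <- generate_dataset(c(2, 2, 2), image_size = 16, n_patients = 3,
                        channels = 4, seed = 1)
  expect_identical(dim(a$records[[1]]$pixels)[3], 4L)
})

test_that("generated classes separate under a pixel-mean nearest centroid", {
  m <- generate_dataset(c(20, 20, 20), image_size = 32, n_patients = 5,
                        seed = 3)
  lab <- manifest_labels(m)
  feat <- t(vapply(m$records, function(r) apply(r$pixels, 3, mean),
                   numeric(3)))
  cent <- vapply(0:2, function(c) colMeans(feat[lab == c, , drop = FALSE]),
                 numeric(3))
  pred <- apply(feat, 1, function(f) which.min(colSums((cent - f)^2)) - 1)
  expect_gt(mean(pred == lab), 0.8)
})

test_that("patient-wise split packs patients greedily and never leaks", {
  m <- stub_manifest(rep(10L, 5L))
  sp <- patient_wise_split(m, 0.8, seed = 1)
  pats <- manifest_patients(m)
  expect_length(sp$train_indices, 40)
  expect_length(intersect(pats[sp$train_indices], pats[sp$test_indices]), 0)

  # 50/30/20 frames at 0.8: verify against brute force over patient subsets
  m2 <- stub_manifest(c(50L, 30L, 20L))
  sp2 <- patient_wise_split(m2, 0.8, seed = 2)
  train_pats <- unique(manifest_patients(m2)[sp2$train_indices])
  sizes <- c(P01 = 50L, P02 = 30L, P03 = 20L)
  subsets <- list(c("P01"), c("P02"), c("P03"), c("P01", "P02"),
                  c("P01", "P03"), c("P02", "P03"))
  feasible <- Filter(function(s) sum(sizes[s]) >= 80, subsets)
  min_size <- min(lengths(feasible))
  expect_true(sum(sizes[train_pats]) >= 80)
  expect_identical(length(train_pats), min_size)

  expect_error(patient_wise_split(stub_manifest(10L), 0.8, 1), "2 distinct")
})

test_that("frame-level split follows the floor rule", {
  m <- stub_manifest(rep(361L, 10L), class_cycle = 0:2)  # 3610 frames
  m$records[[3611L]] <- m$records[[1L]]
  m <- endossl:::new_manifest(m$records)
  expect_length(m$records, 3611)
  sp <- frame_level_split(m, 0.8, seed = 1)
  expect_length(sp$train_indices, 2888)
  expect_length(sp$test_indices, 723)

  m10 <- stub_manifest(c(5L, 5L))
  expect_length(frame_level_split(m10, 0.5, 1)$train_indices, 5)
  m7 <- stub_manifest(c(4L, 3L))
  sp7 <- frame_level_split(m7, 0.8, 1)
  expect_length(sp7$train_indices, 5)
  expect_length(sp7$test_indices, 2)
  # disjoint and covering
  expect_length(intersect(sp7$train_indices, sp7$test_indices), 0)
  expect_setequal(c(sp7$train_indices, sp7$test_indices), 1:7)
})

test_that("manifest round-trips through PNG + CSV", {
  m <- tiny_manifest(c(2, 2, 2), size = 16, patients = 3)
  dir <- withr::local_tempdir()
  csv <- write_manifest(m, dir)
  m2 <- load_manifest(csv)
  expect_identical(manifest_labels(m2), manifest_labels(m))
  expect_identical(manifest_patients(m2), manifest_patients(m))
  expect_identical(m2$class_counts, m$class_counts)
  # 8-bit PNG quantizes to 1/255 steps
  expect_lt(max(abs(m2$records[[1]]$pixels - m$records[[1]]$pixels)), 1 / 254)

  # unknown label names the offending row
  df <- utils::read.csv(csv)
  df$class_label[4] <- "duodenum"
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(load_manifest(bad), "duodenum.*row 4")

  empty <- file.path(dir, "empty.csv")
  utils::write.csv(df[0, ], empty, row.names = FALSE)
  expect_error(load_manifest(empty), "empty")
  expect_error(load_manifest(file.path(dir, "nope.csv")), "not found")
})

test_that("split plans serialize to JSON and back", {
  m <- stub_manifest(c(6L, 6L, 6L))
  sp <- patient_wise_split(m, 0.6, seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_split(sp, f)
  sp2 <- read_split(f)
  expect_identical(sp2$train_indices, sp$train_indices)
  expect_identical(sp2$test_indices, sp$test_indices)
  expect_identical(sp2$seed, sp$seed)
})
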