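test_that("luminance conversion follows the Rec.601 weights", {
  white <- array(1, dim = c(8, 8, 3))
  expect_equal(make_grayscale(white), array(1, dim = c(8, 8, 1)))
  red <- array(0, dim = c(8, 8, 3)); red[, , 1] <- 1
  expect_equal(unique(as.vector(make_grayscale(red))), 0.299)
  v <- 0.37
  eq <- array(v, dim = c(4, 4, 3))
  expect_equal(make_grayscale(eq), array(v, dim = c(4, 4, 1)),
               tolerance = 1e-12)
  expect_error(make_grayscale(array(0, dim = c(8, 8, 2))), "3")
})

test_that("colorization loss is the element-count-normalized MSE", {
  t4 <- array(stats::runif(32), dim = c(4, 4, 2))
  expect_identical(colorization_loss(t4, t4), 0)
  expect_equal(colorization_loss(array(0, dim = c(3, 3, 3)),
                                 array(1, dim = c(3, 3, 3))), 1)
  target <- array(c(1, 0, 0, 1), dim = c(2, 2, 1))
  pred <- array(0.5, dim = c(2, 2, 1))
  expect_equal(colorization_loss(pred, target), 0.25)
  expect_error(colorization_loss(t4, array(0, dim = c(4, 4, 3))), "shape")
  # invariant under a common spatial shuffle of predicted and target
  a <- array(stats::runif(18), dim = c(3, 3, 2))
  b <- array(stats::runif(18), dim = c(3, 3, 2))
  p <- sample(3); q <- sample(3)
  expect_equal(colorization_loss(a, b),
               colorization_loss(a[p, q, , drop = FALSE],
                                 b[p, q, , drop = FALSE]))
})

test_that("colorization samples pair luminance with the color target", {
  img <- array(stats::runif(16 * 16 * 3), dim = c(16, 16, 3))
  s <- make_colorization_sample(img, mode = "rgb")
  expect_identical(dim(s$luminance), c(16L, 16L, 1L))
  expect_identical(s$color_target, img)
  s2 <- make_colorization_sample(img, mode = "ab")
  expect_identical(dim(s2$color_target), c(16L, 16L, 2L))
  expect_true(all(s2$color_target >= 0 & s2$color_target <= 1))
})

test_that("center-patch samples mask exactly the central tile", {
  img <- array(stats::runif(6 * 6 * 3), dim = c(6, 6, 3))
  s <- make_patch_sample(img, n = 3, mask_fill = 0.5)
  expect_identical(unname(s$patch_box), c(3L, 3L, 2L))
  expect_identical(s$true_patch, img[3:4, 3:4, , drop = FALSE])
  expect_true(all(s$context_image[3:4, 3:4, ] == 0.5))
  outside <- s$context_image; outside[3:4, 3:4, ] <- img[3:4, 3:4, ]
  expect_identical(outside, img)
  # reassembly restores the source exactly
  rec <- s$context_image
  rec[3:4, 3:4, ] <- s$true_patch
  expect_identical(rec, img)
  # constant image with matching fill leaves the context unchanged
  const <- array(0.7, dim = c(6, 6, 3))
  expect_identical(make_patch_sample(const, 3, mask_fill = 0.7)$context_image,
                   const)
  expect_error(make_patch_sample(img, n = 4), "odd")
  expect_error(make_patch_sample(array(0, dim = c(7, 7, 3)), n = 3),
               "divisible")
  # explicit patch size works on sizes no odd grid divides
  s32 <- make_patch_sample(array(0.2, dim = c(32, 32, 3)), patch_size = 8)
  expect_identical(unname(s32$patch_box), c(13L, 13L, 8L))
})

test_that("patch loss matches its hand-evaluated normalization", {
  p <- array(stats::runif(8), dim = c(2, 2, 2))
  expect_identical(patch_loss(p, p), 0)
  expect_equal(patch_loss(array(0, dim = c(2, 2, 1)),
                          array(1, dim = c(2, 2, 1))), 1)
  true <- array(c(1, 0, 0, 0), dim = c(2, 2, 1))
  expect_equal(patch_loss(array(0.5, dim = c(2, 2, 1)), true), 0.25)
})

test_that("permutation catalogs are distinct bijections with identity first", {
  ps <- build_permutation_set(2, 24, seed = 1)
  expect_length(ps$perms, 24)
  expect_identical(ps$perms[[1]], 1:4)
  keys <- vapply(ps$perms, paste, "", collapse = ",")
  expect_length(unique(keys), 24)
  for (i in seq_along(ps$perms))
    expect_identical(ps$perms[[i]][ps$inverses[[i]]], 1:4)
  # n_perms = 2: greedy pick is a derangement (Hamming distance 4),
  # verified by enumerating S4
  ps2 <- build_permutation_set(2, 2, seed = 7)
  all4 <- endossl:::enumerate_perms(4)
  maxd <- max(vapply(all4, function(p) sum(p != 1:4), 0L))
  expect_identical(sum(ps2$perms[[2]] != 1:4), maxd)
  expect_identical(maxd, 4L)
  expect_error(build_permutation_set(2, 25), "between")
  # larger grids use sampled candidates
  ps3 <- build_permutation_set(3, 10, seed = 1)
  expect_length(ps3$perms, 10)
  expect_identical(ps3$perms[[1]], 1:9)
})

test_that("permutation sets round-trip through JSON", {
  ps <- build_permutation_set(2, 6, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_permutation_set(ps, f)
  ps2 <- read_permutation_set(f)
  expect_identical(ps2$perms, lapply(ps$perms, as.integer))
  expect_identical(ps2$n, ps$n)
})

test_that("tile shuffling follows the permutation and inverts exactly", {
  ps <- build_permutation_set(2, 24, seed = 1)
  img <- array(stats::runif(8 * 8 * 3), dim = c(8, 8, 3))
  expect_identical(tile_and_permute(img, ps, 0)$shuffled_image, img)
  # constructed quadrant fixture: swap permutation exchanges quadrants
  quad <- array(0, dim = c(4, 4, 1))
  quad[1:2, 1:2, ] <- 1; quad[1:2, 3:4, ] <- 2
  quad[3:4, 1:2, ] <- 3; quad[3:4, 3:4, ] <- 4
  swap <- which(vapply(ps$perms, identical, TRUE, y = c(2L, 1L, 4L, 3L)))
  expect_length(swap, 1)
  sh <- tile_and_permute(quad, ps, swap - 1)$shuffled_image
  # row-major tiles: position 1 (top-left) receives source tile 2 (top-right)
  expect_identical(unique(as.vector(sh[1:2, 1:2, ])), 2)
  expect_identical(unique(as.vector(sh[1:2, 3:4, ])), 1)
  expect_identical(unique(as.vector(sh[3:4, 1:2, ])), 4)
  expect_error(tile_and_permute(img, ps, 24), "invalid")
  expect_error(tile_and_permute(array(0, dim = c(7, 7, 1)), ps, 1),
               "divisible")
})

test_that("jigsaw loss is clamped cross-entropy over the catalog", {
  probs <- rep(0, 24); probs[5] <- 1
  expect_identical(jigsaw_loss(probs, 4), 0)
  expect_equal(jigsaw_loss(rep(1 / 24, 24), 3), log(24))
  p0 <- c(0, 1); expect_equal(jigsaw_loss(p0, 0), -log(1e-12))
  expect_lt(jigsaw_loss(p0, 0), 30)
  expect_error(jigsaw_loss(c(0.5, 0.2), 0), "distribution")
  expect_error(jigsaw_loss(c(0.5, 0.5), 2), "label")
})

test_that("losses match independent nested-loop oracles", {
  set.seed(11)
  for (r in 1:10) {
    d <- c(sample(2:5, 1), sample(2:5, 1), sample(1:3, 1))
    a <- array(stats::runif(prod(d)), dim = d)
    b <- array(stats::runif(prod(d)), dim = d)
    expect_equal(colorization_loss(a, b), oracle_mse(a, b), tolerance = 1e-12)
    expect_equal(patch_loss(a, b), oracle_mse(a, b), tolerance = 1e-12)
    k <- sample(3:8, 1)
    pr <- stats::runif(k); pr <- pr / sum(pr)
    y <- sample(k, 1) - 1L
    expect_equal(jigsaw_loss(pr, y), oracle_cross_entropy(pr, y),
                 tolerance = 1e-12)
  }
})
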