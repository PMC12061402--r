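# Pretext-task sample construction and the three self-supervision losses:
# colorization (pixel-wise MSE from luminance), center-patch prediction
# (MSE over the masked patch), and jigsaw permutation classification
# (cross-entropy over a fixed permutation catalog).

#' Convert an RGB image to luminance
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @return H x W x 1 array.
#' @examples
#' img <- array(1, dim = c(8, 8, 3))
#' range(make_grayscale(img))  # all 1
#' @export
make_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("make_grayscale expects an H x W x 3 RGB array")
  array(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L],
        dim = c(d[1L], d[2L], 1L))
}

#' Build a colorization sample
#'
#' Pairs the luminance channel with a color target: either the full RGB
#' image (`mode = "rgb"`, matching the 3-channel sigmoid decoder) or the
#' CIE Lab chrominance channels rescaled to \[0, 1\] (`mode = "ab"`).
#'
#' @param image H x W x 3 RGB array in \[0, 1\].
#' @param mode "rgb" or "ab".
#' @return list with `luminance` (H x W x 1) and `color_target`
#'   (H x W x 3 or H x W x 2).
#' @export
make_colorization_sample <- function(image, mode = c("rgb", "ab")) {
  mode <- match.arg(mode)
  lum <- make_grayscale(image)
  if (mode == "rgb") {
    target <- image
  } else {
    d <- dim(image)
    rgbm <- matrix(c(image), ncol = 3L)
    lab <- grDevices::convertColor(rgbm, from = "sRGB", to = "Lab")
    # a, b nominally in [-110, 110]; map affinely into [0, 1]
    ab <- pmin(pmax((lab[, 2:3] + 110) / 220, 0), 1)
    target <- array(ab, dim = c(d[1L], d[2L], 2L))
  }
  list(luminance = lum, color_target = target)
}

mse_loss <- function(predicted, target, what) {
  if (!identical(dim(predicted), dim(target)))
    stop(what, ": shape mismatch between predicted and target")
  v <- mean((predicted - target)^2)
  stopifnot(is.finite(v))
  v
}

#' Colorization loss
#'
#' Pixel-wise mean squared error between predicted and target color planes,
#' normalized by the total element count `H * W * C` so the value is
#' comparable between the RGB and chrominance target modes.
#'
#' @param predicted,target arrays of identical shape.
#' @return non-negative scalar.
#' @export
colorization_loss <- function(predicted, target) {
  mse_loss(predicted, target, "colorization_loss")
}

#' Build a center-patch prediction sample
#'
#' Extracts the central patch and replaces it in the context image by a
#' constant fill. Either `n` (odd grid with H, W divisible by n; the center
#' tile is masked) or an explicit `patch_size` (centered square) selects
#' the patch.
#'
#' @param image H x W x C array in \[0, 1\].
#' @param n odd grid side >= 3; requires H and W divisible by n.
#' @param patch_size optional explicit patch side, overriding `n`.
#' @param mask_fill constant fill value for the masked region, or "mean"
#'   for the per-image mean.
#' @return list with `context_image`, `true_patch`, `patch_box`
#'   (row, col, size; 1-based top-left corner).
#' @export
make_patch_sample <- function(image, n = 3L, patch_size = NULL,
                              mask_fill = 0.5) {
  d <- dim(image)
  H <- d[1L]; W <- d[2L]
  if (is.null(patch_size)) {
    n <- as.integer(n)
    if (n < 3L || n %% 2L == 0L) stop("n must be odd and >= 3")
    if (H %% n != 0L || W %% n != 0L)
      stop(sprintf("image dimensions (%d x %d) not divisible by grid n = %d",
                   H, W, n))
    p <- H %/% n
    row <- (n %/% 2L) * p + 1L
    col <- (n %/% 2L) * (W %/% n) + 1L
    pw <- W %/% n
  } else {
    p <- as.integer(patch_size)
    if (p < 1L || p > min(H, W)) stop("patch_size out of range")
    row <- (H - p) %/% 2L + 1L
    col <- (W - p) %/% 2L + 1L
    pw <- p
  }
  fill <- if (identical(mask_fill, "mean")) mean(image) else mask_fill
  rows <- row + seq_len(p) - 1L
  cols <- col + seq_len(pw) - 1L
  true_patch <- image[rows, cols, , drop = FALSE]
  context <- image
  context[rows, cols, ] <- fill
  list(context_image = context, true_patch = true_patch,
       patch_box = c(row = as.integer(row), col = as.integer(col),
                     size = as.integer(p)))
}

#' Patch prediction loss
#'
#' Mean squared error over the `p x p x C` patch entries (the
#' `1 / (p^2 C)` normalization).
#'
#' @param predicted_patch,true_patch arrays of identical shape.
#' @return non-negative scalar.
#' @export
patch_loss <- function(predicted_patch, true_patch) {
  mse_loss(predicted_patch, true_patch, "patch_loss")
}

perm_hamming <- function(a, b) sum(a != b)

#' Build a jigsaw permutation catalog
#'
#' `perms[[1]]` is the identity; the remaining permutations of the
#' `n^2` tiles are chosen greedily from seeded random candidates to
#' maximize the minimum pairwise Hamming distance (for small `n` the full
#' symmetric group is enumerated). Inverses are precomputed.
#'
#' @param n tiles per side of the jigsaw grid.
#' @param n_perms number of permutations in the catalog.
#' @param seed integer seed.
#' @param n_candidates candidate pool size per greedy pick.
#' @return an `endo_permset`: list with `n`, `perms`, `inverses`.
#' @export
build_permutation_set <- function(n = 2L, n_perms = 24L, seed = 1L,
                                  n_candidates = 200L) {
  m <- as.integer(n) * as.integer(n)
  if (n_perms < 1L || n_perms > factorial(m))
    stop("n_perms must be between 1 and (n^2)! = ", factorial(m))
  perms <- with_seed(seed, {
    if (m <= 9L && factorial(m) <= 5000L) {
      all_perms <- enumerate_perms(m)
    } else {
      all_perms <- NULL
    }
    chosen <- list(seq_len(m))  # identity first
    if (!is.null(all_perms)) {
      pool <- all_perms[!vapply(all_perms, identical, TRUE, y = seq_len(m))]
      if (n_perms == length(all_perms)) {
        chosen <- c(chosen, pool)
      } else {
        while (length(chosen) < n_perms) {
          dmin <- vapply(pool, function(p)
            min(vapply(chosen, perm_hamming, 0L, b = p)), 0L)
          best <- which(dmin == max(dmin))
          pick <- best[sample.int(length(best), 1L)]
          chosen <- c(chosen, pool[pick])
          pool <- pool[-pick]
        }
      }
    } else {
      while (length(chosen) < n_perms) {
        cand <- replicate(n_candidates, sample(m), simplify = FALSE)
        dmin <- vapply(cand, function(p)
          min(vapply(chosen, perm_hamming, 0L, b = p)), 0L)
        pick <- which.max(dmin)
        if (any(vapply(chosen, identical, TRUE, y = cand[[pick]]))) next
        chosen <- c(chosen, cand[pick])
      }
    }
    lapply(chosen[seq_len(n_perms)], as.integer)
  })
  inverses <- lapply(perms, function(p) as.integer(order(p)))
  structure(list(n = as.integer(n), perms = perms, inverses = inverses),
            class = "endo_permset")
}

enumerate_perms <- function(m) {
  if (m == 1L) return(list(1L))
  sub <- enumerate_perms(m - 1L)
  out <- vector("list", m * length(sub))
  k <- 1L
  for (s in sub) for (pos in seq_len(m)) {
    out[[k]] <- append(s, m, after = pos - 1L)
    k <- k + 1L
  }
  out
}

#' @export
print.endo_permset <- function(x, ...) {
  cat(sprintf("Jigsaw permutation set: %d x %d grid, %d permutations\n",
              x$n, x$n, length(x$perms)))
  invisible(x)
}

#' Serialize / read a permutation set as JSON
#' @param perm_set an `endo_permset`.
#' @param path file path.
#' @return `read_permutation_set` returns an `endo_permset`.
#' @export
write_permutation_set <- function(perm_set, path) {
  jsonlite::write_json(list(n = perm_set$n,
                            perms = lapply(perm_set$perms, as.integer),
                            inverses = lapply(perm_set$inverses, as.integer)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_permutation_set
#' @export
read_permutation_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n = as.integer(x$n),
                 perms = lapply(seq_len(nrow(x$perms)), function(i)
                   as.integer(x$perms[i, ])),
                 inverses = lapply(seq_len(nrow(x$inverses)), function(i)
                   as.integer(x$inverses[i, ]))),
            class = "endo_permset")
}

tile_indices <- function(H, W, n) {
  th <- H %/% n; tw <- W %/% n
  lapply(seq_len(n * n), function(t) {
    # tiles in row-major order: tile t covers rows/cols block
    r <- (t - 1L) %/% n; c <- (t - 1L) %% n
    list(rows = r * th + seq_len(th), cols = c * tw + seq_len(tw))
  })
}

#' Shuffle an image's tiles by a catalog permutation
#'
#' Output tile position `i` receives source tile `perm[i]`. Applying the
#' stored inverse restores the source exactly.
#'
#' @param image H x W x C array; H, W divisible by `perm_set$n`.
#' @param perm_set an `endo_permset`.
#' @param label 0-based index of the permutation in the catalog.
#' @return list with `shuffled_image` and `label`.
#' @export
tile_and_permute <- function(image, perm_set, label) {
  d <- dim(image)
  n <- perm_set$n
  if (d[1L] %% n != 0L || d[2L] %% n != 0L)
    stop("image dimensions must be divisible by the jigsaw grid")
  if (label < 0L || label >= length(perm_set$perms))
    stop("invalid permutation label ", label)
  perm <- perm_set$perms[[label + 1L]]
  tiles <- tile_indices(d[1L], d[2L], n)
  out <- image
  for (i in seq_along(perm)) {
    src <- tiles[[perm[i]]]
    dst <- tiles[[i]]
    out[dst$rows, dst$cols, ] <- image[src$rows, src$cols, ]
  }
  list(shuffled_image = out, label = as.integer(label))
}

#' Jigsaw classification loss
#'
#' Cross-entropy `-log p(true permutation)` with the probability clamped
#' below at 1e-12 so degenerate predictions stay finite.
#'
#' @param predicted_probs non-negative vector summing to 1 (within 1e-6)
#'   over the permutation catalog.
#' @param label 0-based true permutation index.
#' @return non-negative scalar.
#' @export
jigsaw_loss <- function(predicted_probs, label) {
  if (any(predicted_probs < 0) || abs(sum(predicted_probs) - 1) > 1e-6)
    stop("predicted_probs must be a probability distribution")
  if (label < 0L || label >= length(predicted_probs))
    stop("invalid label ", label)
  -log(max(predicted_probs[label + 1L], 1e-12))
}
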