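# Synthetic endoscopy-like datasets, manifest I/O and leakage-free splits.

#' Anatomical landmark class names
#'
#' Class encoding is fixed: 0 = Z-line, 1 = esophageal, 2 = antrum/pylorus.
#' @return character vector of length 3.
#' @export
landmark_classes <- function() c("Z-line", "esophageal", "antrum_pylorus")

# vectorized HSV -> RGB on numeric vectors in [0,1] (h wraps)
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

new_image_record <- function(pixels, class_label, patient_id) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L,
            dim(pixels)[1L] >= 8L, dim(pixels)[2L] >= 8L,
            dim(pixels)[3L] %in% c(1L, 3L, 4L),
            min(pixels) >= 0, max(pixels) <= 1,
            class_label %in% 0:2, nzchar(patient_id))
  list(pixels = pixels, class_label = as.integer(class_label),
       patient_id = as.character(patient_id))
}

new_manifest <- function(records, class_names = landmark_classes()) {
  labels <- vapply(records, function(r) r$class_label, 0L)
  counts <- as.integer(tabulate(labels + 1L, nbins = 3L))
  m <- structure(list(records = records, class_names = class_names,
                      class_counts = counts),
                 class = "endo_manifest")
  stopifnot(sum(m$class_counts) == length(records))
  m
}

#' @export
print.endo_manifest <- function(x, ...) {
  cat("Endoscopy frame manifest:", length(x$records), "frames\n")
  for (k in 1:3)
    cat(sprintf("  class %d (%s): %d\n", k - 1L, x$class_names[k],
                x$class_counts[k]))
  cat("  patients:", length(unique(manifest_patients(x))), "\n")
  invisible(x)
}

#' Patient id per record of a manifest
#' @param manifest an `endo_manifest`.
#' @return character vector.
#' @export
manifest_patients <- function(manifest) {
  vapply(manifest$records, function(r) r$patient_id, "")
}

#' Class label (0/1/2) per record of a manifest
#' @param manifest an `endo_manifest`.
#' @return integer vector.
#' @export
manifest_labels <- function(manifest) {
  vapply(manifest$records, function(r) r$class_label, 0L)
}

# Class-specific appearance signatures (invented plumbing): each landmark
# class occupies a distinct warm hue band and differs in the number of
# bright mucosal blobs and in the spatial frequency of a sinusoidal
# texture, so a pixel-mean classifier can already separate classes.
class_signature <- function(class_label) {
  switch(as.character(class_label),
    "0" = list(hue = 0.98, blobs = 1L, freq = 2),   # Z-line: deep red, single band
    "1" = list(hue = 0.06, blobs = 3L, freq = 5),   # esophageal: pink-orange
    "2" = list(hue = 0.14, blobs = 6L, freq = 9))   # antrum/pylorus: yellow-tinged
}

render_frame <- function(class_label, image_size, channels, patient_shift) {
  sig <- class_signature(class_label)
  H <- image_size; W <- image_size
  gx <- matrix(rep(seq_len(W), each = H), H, W) / W
  gy <- matrix(rep(seq_len(H), times = W), H, W) / H
  # vignette-style radial falloff, as in endoscope optics
  rad <- sqrt((gx - 0.5)^2 + (gy - 0.5)^2)
  val <- 0.75 - 0.5 * rad^2
  for (b in seq_len(sig$blobs)) {
    cx <- stats::runif(1, 0.15, 0.85); cy <- stats::runif(1, 0.15, 0.85)
    val <- val + 0.22 * exp(-(((gx - cx)^2 + (gy - cy)^2)) / 0.02)
  }
  phase <- stats::runif(1, 0, 2 * pi)
  val <- val + 0.08 * sin(2 * pi * sig$freq * (gx + gy) + phase)
  val <- val + patient_shift["value"]
  hue <- sig$hue + patient_shift["hue"] + stats::rnorm(H * W, sd = 0.008)
  sat <- 0.75 + patient_shift["sat"] + 0.05 * sin(2 * pi * sig$freq * gy + phase)
  rgb <- hsv_to_rgb(hue, pmin(pmax(sat, 0), 1), pmin(pmax(val, 0.02), 1))
  px <- array(0, dim = c(H, W, 3L))
  px[, , 1L] <- rgb$r; px[, , 2L] <- rgb$g; px[, , 3L] <- rgb$b
  px <- px + array(stats::rnorm(H * W * 3L, sd = 0.02), dim = dim(px))
  px <- pmin(pmax(px, 0), 1)
  if (channels == 1L) {
    px <- array(0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L],
                dim = c(H, W, 1L))
  } else if (channels == 4L) {
    px <- array(c(px, rep(1, H * W)), dim = c(H, W, 4L))
  }
  px
}

#' Generate a synthetic endoscopy-like dataset
#'
#' Produces three visually separable landmark classes (distinct hue band,
#' blob geometry and texture frequency), with frames assigned round-robin
#' to patients so that every patient holds frames of all classes. The
#' output is a pure function of `seed`.
#'
#' @param n_per_class integer vector of length 3: frames for classes
#'   0 (Z-line), 1 (esophageal), 2 (antrum/pylorus).
#' @param image_size side length in pixels (square frames), >= 16.
#' @param channels 1 (luminance), 3 (RGB) or 4 (RGB + opaque alpha).
#' @param n_patients number of synthetic patients, >= 3.
#' @param seed integer seed controlling all randomness.
#' @return an `endo_manifest`.
#' @examples
#' m <- generate_dataset(c(5, 5, 5), image_size = 16, n_patients = 3, seed = 1)
#' m$class_counts
#' @export
generate_dataset <- function(n_per_class, image_size = 32L, channels = 3L,
                             n_patients = 5L, seed = 1L) {
  if (length(n_per_class) != 3L || any(n_per_class < 1))
    stop("n_per_class must be 3 integers >= 1")
  if (image_size < 16L) stop("image_size must be >= 16")
  if (n_patients < 3L) stop("n_patients must be >= 3")
  if (!channels %in% c(1L, 3L, 4L)) stop("channels must be 1, 3 or 4")
  with_seed(seed, {
    pat_ids <- sprintf("P%03d", seq_len(n_patients))
    shifts <- lapply(seq_len(n_patients), function(i)
      c(hue = stats::runif(1, -0.012, 0.012),
        sat = stats::runif(1, -0.05, 0.05),
        value = stats::runif(1, -0.05, 0.05)))
    names(shifts) <- pat_ids
    records <- vector("list", sum(n_per_class))
    pos <- 1L
    for (cl in 0:2) {
      for (j in seq_len(n_per_class[cl + 1L])) {
        pid <- pat_ids[((j - 1L) %% n_patients) + 1L]
        px <- render_frame(cl, as.integer(image_size), as.integer(channels),
                           shifts[[pid]])
        records[[pos]] <- new_image_record(px, cl, pid)
        pos <- pos + 1L
      }
    }
    new_manifest(records)
  })
}

#' Generate a fixture whose class signal lives in one quadrant
#'
#' Background is neutral noise everywhere; only the chosen quadrant carries
#' the class-specific hue patch. Used to test saliency localization.
#'
#' @param n_per_class integer vector of length 3.
#' @param image_size side length (>= 16).
#' @param quadrant one of "tl", "tr", "bl", "br".
#' @param n_patients number of patients.
#' @param seed integer seed.
#' @return an `endo_manifest`.
#' @export
generate_quadrant_dataset <- function(n_per_class, image_size = 32L,
                                      quadrant = "tl", n_patients = 4L,
                                      seed = 1L) {
  stopifnot(quadrant %in% c("tl", "tr", "bl", "br"), length(n_per_class) == 3L)
  h <- image_size %/% 2L
  rows <- if (quadrant %in% c("tl", "tr")) seq_len(h) else h + seq_len(image_size - h)
  cols <- if (quadrant %in% c("tl", "bl")) seq_len(h) else h + seq_len(image_size - h)
  with_seed(seed, {
    pat_ids <- sprintf("P%03d", seq_len(n_patients))
    records <- vector("list", sum(n_per_class))
    pos <- 1L
    for (cl in 0:2) {
      sig <- class_signature(cl)
      for (j in seq_len(n_per_class[cl + 1L])) {
        px <- array(stats::runif(image_size^2 * 3L, 0.35, 0.65),
                    dim = c(image_size, image_size, 3L))
        rgb <- hsv_to_rgb(sig$hue + stats::rnorm(length(rows) * length(cols),
                                                 sd = 0.01),
                          0.9, 0.85)
        px[rows, cols, 1L] <- rgb$r
        px[rows, cols, 2L] <- rgb$g
        px[rows, cols, 3L] <- rgb$b
        px <- pmin(pmax(px + array(stats::rnorm(length(px), sd = 0.02),
                                   dim = dim(px)), 0), 1)
        records[[pos]] <- new_image_record(px, cl,
                                           pat_ids[((j - 1L) %% n_patients) + 1L])
        pos <- pos + 1L
      }
    }
    new_manifest(records)
  })
}

new_split <- function(train_indices, test_indices, seed) {
  structure(list(train_indices = as.integer(train_indices),
                 test_indices = as.integer(test_indices),
                 seed = as.integer(seed)),
            class = "endo_split")
}

#' @export
print.endo_split <- function(x, ...) {
  cat(sprintf("Split: %d train / %d test (seed %d)\n",
              length(x$train_indices), length(x$test_indices), x$seed))
  invisible(x)
}

#' Patient-wise train/test split
#'
#' Patients (never frames) are partitioned: patients are packed greedily,
#' largest frame count first (ties broken by a seeded shuffle), into the
#' training side until it holds at least `train_frac` of all frames. No
#' patient appears on both sides, which rules out patient-level leakage.
#'
#' @param manifest an `endo_manifest`.
#' @param train_frac fraction of frames targeted for training, in (0, 1).
#' @param seed integer seed (tie-breaking among equal-sized patients).
#' @return an `endo_split`.
#' @export
patient_wise_split <- function(manifest, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  pats <- manifest_patients(manifest)
  upat <- unique(pats)
  if (length(upat) < 2L)
    stop("patient-wise split needs at least 2 distinct patients")
  counts <- table(pats)[upat]
  ord <- with_seed(seed, {
    perm <- sample(length(upat))
    perm[order(counts[perm], decreasing = TRUE)]
  })
  total <- length(pats)
  need <- train_frac * total
  cum <- cumsum(as.integer(counts[ord]))
  ntrain_pat <- which(cum >= need)[1L]
  if (is.na(ntrain_pat)) ntrain_pat <- length(upat)
  if (ntrain_pat >= length(upat)) {
    warning("train_frac unreachable without emptying the test side; ",
            "holding out the smallest patient")
    ntrain_pat <- length(upat) - 1L
  }
  train_pats <- upat[ord[seq_len(ntrain_pat)]]
  new_split(which(pats %in% train_pats), which(!pats %in% train_pats), seed)
}

#' Frame-level train/test split
#'
#' Unstratified random split at frame level with
#' `floor(train_frac * N)` training frames (so 3,611 frames at 80% give
#' the 2,888/723 partition).
#'
#' @inheritParams patient_wise_split
#' @return an `endo_split`.
#' @export
frame_level_split <- function(manifest, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  N <- length(manifest$records)
  n_train <- floor(train_frac * N)
  idx <- with_seed(seed, sample(N))
  new_split(sort(idx[seq_len(n_train)]), sort(idx[-seq_len(n_train)]), seed)
}

#' Serialize / read a split plan as JSON
#' @param split an `endo_split`.
#' @param path file path.
#' @return `read_split` returns an `endo_split`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(list(train = split$train_indices,
                            test = split$test_indices, seed = split$seed),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_split(x$train, x$test, x$seed)
}

#' Write a manifest (images + CSV) to disk
#'
#' Images are written as 8-bit PNG under `dir/images/`; the manifest CSV has
#' columns `image_path,class_label,patient_id` with class labels as strings.
#'
#' @param manifest an `endo_manifest`.
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(manifest$records)
  paths <- character(n)
  for (i in seq_len(n)) {
    rec <- manifest$records[[i]]
    paths[i] <- file.path("images", sprintf("frame_%05d.png", i))
    px <- rec$pixels
    if (dim(px)[3L] == 1L) px <- px[, , 1L]
    png::writePNG(px, file.path(dir, paths[i]))
  }
  df <- data.frame(image_path = paths,
                   class_label = manifest$class_names[manifest_labels(manifest) + 1L],
                   patient_id = manifest_patients(manifest))
  csv <- file.path(dir, "manifest.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  invisible(csv)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package")
    img <- EBImage::readImage(path)
    px <- aperm(EBImage::imageData(img), c(2L, 1L, 3L)[seq_along(dim(img))])
  } else {
    stop("unreadable image (expected PNG or JPEG): ", path)
  }
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
  px
}

#' Load a manifest from a CSV of image paths
#'
#' The CSV must have header `image_path,class_label,patient_id`; class
#' labels must be among [landmark_classes()]. Relative image paths are
#' resolved against the CSV's directory.
#'
#' @param csv_path path to the manifest CSV.
#' @return an `endo_manifest`.
#' @export
load_manifest <- function(csv_path) {
  if (!file.exists(csv_path)) stop("manifest file not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  req <- c("image_path", "class_label", "patient_id")
  if (!all(req %in% names(df)))
    stop("manifest CSV must have columns ", paste(req, collapse = ", "))
  if (nrow(df) == 0L) stop("manifest CSV is empty: ", csv_path)
  cls <- landmark_classes()
  base <- dirname(csv_path)
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    lab <- match(df$class_label[i], cls) - 1L
    if (is.na(lab))
      stop(sprintf("unknown class label '%s' in manifest row %d",
                   df$class_label[i], i))
    p <- df$image_path[i]
    if (!file.exists(p)) p <- file.path(base, df$image_path[i])
    if (!file.exists(p)) stop("image file not found: ", df$image_path[i])
    records[[i]] <- new_image_record(read_image_file(p), lab, df$patient_id[i])
  }
  new_manifest(records)
}
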