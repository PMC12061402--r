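# Shared lightweight fixtures. A "stub" manifest shares one pixel array
# across records, which keeps split/bookkeeping tests cheap.
stub_manifest <- function(frames_per_patient, class_cycle = 0:2) {
  px <- array(0.5, dim = c(8L, 8L, 1L))
  records <- list()
  k <- 0L
  for (p in seq_along(frames_per_patient)) {
    for (j in seq_len(frames_per_patient[p])) {
      k <- k + 1L
      records[[k]] <- list(pixels = px,
                           class_label = class_cycle[(k - 1L) %% length(class_cycle) + 1L],
                           patient_id = sprintf("P%02d", p))
    }
  }
  endossl:::new_manifest(records)
}

tiny_manifest <- function(n = c(8L, 8L, 8L), size = 16L, patients = 4L,
                          seed = 42L) {
  generate_dataset(n, image_size = size, n_patients = patients, seed = seed)
}

# independent nested-loop loss oracles
oracle_mse <- function(a, b) {
  s <- 0; n <- 0
  for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[2]))
    for (c in seq_len(dim(a)[3])) {
      s <- s + (a[i, j, c] - b[i, j, c])^2
      n <- n + 1
    }
  s / n
}

oracle_cross_entropy <- function(probs, y) {
  p <- probs[y + 1]
  -log(max(p, 1e-12))
}

# brute-force pairwise AUC (ties count 1/2)
oracle_auc <- function(labels, score) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  s / (length(pos) * length(neg))
}
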