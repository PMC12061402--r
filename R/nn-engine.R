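# Minimal CNN engine used by the pretext autoencoders and classifiers.
#
# Tensors are dense numeric arrays with dim (C, H, W, N) — channel-first,
# batch last. Convolutions are evaluated as im2col gathers followed by BLAS
# GEMMs; the col2im scatter (conv backward-data, transposed-conv forward)
# is a precomputed sparse matrix multiply. Everything is double precision
# and deterministic given R's RNG state.

# ---- RNG ---------------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls do not perturb the
#' caller's random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# ---- geometry cache ----------------------------------------------------

# Gather indices and scatter matrix for a conv window sweep over a padded
# (C, Hp, Wp) plane. idx is (C*k*k) x (oh*ow) into one padded sample;
# S scatters window gradients back onto the padded plane.
conv_geom_sample <- function(C, H, W, k, s, p) {
  Hp <- H + 2L * p; Wp <- W + 2L * p
  oh <- (Hp - k) %/% s + 1L; ow <- (Wp - k) %/% s + 1L  # floor sweep
  ch <- rep(seq_len(C), times = k * k)
  kh <- rep(rep(seq_len(k), each = C), times = k)
  kw <- rep(seq_len(k), each = C * k)
  wbase <- ch + C * (kh - 1L) + C * Hp * (kw - 1L)
  i0 <- rep((seq_len(oh) - 1L) * s, times = ow)
  j0 <- rep((seq_len(ow) - 1L) * s, each = oh)
  shift <- C * i0 + C * Hp * j0
  idx <- outer(as.integer(wbase), as.integer(shift), "+")
  S <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx), x = 1,
                            dims = c(C * Hp * Wp, length(idx)))
  list(idx = idx, S = S, oh = oh, ow = ow, Hp = Hp, Wp = Wp)
}

# Layer-level cache: geometry per (H, W) and batch gather index per (H, W, N).
layer_geom <- function(layer, C, H, W, N) {
  key <- paste0(H, "x", W)
  g <- layer$geom[[key]]
  if (is.null(g)) {
    g <- conv_geom_sample(C, H, W, layer$k, layer$stride, layer$pad)
    layer$geom[[key]] <- g
  }
  nkey <- paste0(key, "n", N)
  if (is.null(layer$idxN[[nkey]])) {
    offs <- (seq_len(N) - 1L) * as.integer(C * g$Hp * g$Wp)
    layer$idxN[[nkey]] <- as.vector(outer(as.vector(g$idx), offs, "+"))
  }
  list(g = g, idxN = layer$idxN[[nkey]])
}

pad_batch <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1L], d[2L] + 2L * p, d[3L] + 2L * p, d[4L]))
  xp[, p + seq_len(d[2L]), p + seq_len(d[3L]), ] <- x
  xp
}

unpad_batch <- function(xp, p, H, W) {
  if (p == 0L) return(xp)
  xp[, p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

# ---- layer constructors ------------------------------------------------

new_layer <- function(.kind, .name = .kind, ...) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- .kind
  ly$name <- .name
  ly$par <- list()
  ly$gr <- list()
  ly$opt <- NULL
  ly$geom <- list()
  ly$idxN <- list()
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = ly)
  class(ly) <- "nn_layer"
  ly
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow = nrow)
}

nn_conv2d <- function(in_ch, out_ch, k = 4L, stride = 2L, pad = 1L,
                      bias = TRUE, name = "conv") {
  ly <- new_layer("conv2d", name, in_ch = in_ch, out_ch = out_ch,
                  k = as.integer(k), stride = as.integer(stride),
                  pad = as.integer(pad), bias = bias)
  ly$par$W <- he_init(out_ch, in_ch * k * k, in_ch * k * k)
  if (bias) ly$par$b <- numeric(out_ch)
  ly
}

nn_conv_transpose2d <- function(in_ch, out_ch, k = 4L, stride = 2L, pad = 1L,
                                bias = TRUE, name = "deconv") {
  # Parameterized as the adjoint of a conv mapping out_ch -> in_ch, so the
  # weight count is in_ch * out_ch * k^2 (+ out_ch bias).
  ly <- new_layer("conv_transpose2d", name, in_ch = in_ch, out_ch = out_ch,
                  k = as.integer(k), stride = as.integer(stride),
                  pad = as.integer(pad), bias = bias)
  ly$par$W <- he_init(in_ch, out_ch * k * k, in_ch * k * k)
  if (bias) ly$par$b <- numeric(out_ch)
  ly
}

nn_linear <- function(in_dim, out_dim, bias = TRUE, name = "linear") {
  ly <- new_layer("linear", name, in_dim = in_dim, out_dim = out_dim,
                  bias = bias)
  ly$par$W <- he_init(out_dim, in_dim, in_dim)
  if (bias) ly$par$b <- numeric(out_dim)
  ly
}

nn_relu <- function(name = "relu") new_layer("relu", name)
nn_sigmoid <- function(name = "sigmoid") new_layer("sigmoid", name)
nn_flatten <- function(name = "flatten") new_layer("flatten", name)
nn_gap <- function(name = "gap") new_layer("gap", name)

nn_dropout <- function(p = 0.3, name = "dropout") {
  new_layer("dropout", name, p = p)
}

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L, name = "maxpool") {
  new_layer("maxpool", name, k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}

nn_attention_pool <- function(d, name = "attention") {
  ly <- new_layer("attention_pool", name, d = d)
  ly$par$w <- he_init(1L, d, d)
  ly$par$b <- 0
  ly
}

nn_transformer_block <- function(d, heads = 4L, ff = 1024L,
                                 name = "transformer") {
  stopifnot(d %% heads == 0L)
  ly <- new_layer("transformer_block", name, d = d, heads = as.integer(heads),
                  ff = as.integer(ff), dk = d %/% heads, eps = 1e-5)
  for (nm in c("Wq", "Wk", "Wv", "Wo")) ly$par[[nm]] <- he_init(d, d, d)
  for (nm in c("bq", "bk", "bv", "bo")) ly$par[[nm]] <- numeric(d)
  ly$par$W1 <- he_init(ff, d, d); ly$par$b1 <- numeric(ff)
  ly$par$W2 <- he_init(d, ff, ff); ly$par$b2 <- numeric(d)
  ly$par$g1 <- rep(1, d); ly$par$be1 <- numeric(d)
  ly$par$g2 <- rep(1, d); ly$par$be2 <- numeric(d)
  ly
}

nn_residual <- function(main, shortcut = NULL, name = "residual") {
  new_layer("residual", name, main = main, shortcut = shortcut)
}

# fixed (non-trainable) per-feature affine standardization x -> (x - mu) * sc
nn_standardize <- function(mu, sc, name = "standardize") {
  new_layer("standardize", name, mu = mu, sc = sc)
}

# ---- forward / backward ------------------------------------------------

ly_forward <- function(ly, x, training = FALSE) {
  switch(ly$kind,
    conv2d = {
      d <- dim(x); C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
      lg <- layer_geom(ly, C, H, W, N); g <- lg$g
      xp <- pad_batch(x, ly$pad)
      cols <- xp[lg$idxN]
      dim(cols) <- c(C * ly$k * ly$k, length(cols) %/% (C * ly$k * ly$k))
      out <- ly$par$W %*% cols
      if (ly$bias) out <- out + ly$par$b
      ly$cache <- list(cols = cols, dims = d, lg = lg)
      dim(out) <- c(ly$out_ch, g$oh, g$ow, N)
      out
    },
    conv_transpose2d = {
      d <- dim(x); H <- d[2L]; W <- d[3L]; N <- d[4L]
      H2 <- (H - 1L) * ly$stride - 2L * ly$pad + ly$k
      W2 <- (W - 1L) * ly$stride - 2L * ly$pad + ly$k
      lg <- layer_geom(ly, ly$out_ch, H2, W2, N); g <- lg$g
      stopifnot(g$oh == H, g$ow == W)
      xmat <- matrix(x, nrow = ly$in_ch)
      tmp <- crossprod(ly$par$W, xmat)          # (out*k*k, H*W*N)
      dim(tmp) <- c(length(tmp) %/% N, N)
      ya <- as.matrix(g$S %*% tmp)
      dim(ya) <- c(ly$out_ch, g$Hp, g$Wp, N)
      y <- unpad_batch(ya, ly$pad, H2, W2)
      if (ly$bias) y <- y + ly$par$b
      ly$cache <- list(xmat = xmat, dims = d, out_hw = c(H2, W2), lg = lg)
      y
    },
    linear = {
      x <- as.matrix(x)
      out <- ly$par$W %*% x
      if (ly$bias) out <- out + ly$par$b
      ly$cache <- list(x = x)
      out
    },
    relu = {
      out <- x * (x > 0)
      ly$cache <- list(mask = x > 0)
      out
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      ly$cache <- list(out = out)
      out
    },
    flatten = {
      d <- dim(x)
      ly$cache <- list(dims = d)
      matrix(x, nrow = prod(d[-length(d)]), ncol = d[length(d)])
    },
    gap = {
      d <- dim(x)
      ly$cache <- list(dims = d)
      m <- matrix(x, nrow = d[1L])
      dim(m) <- c(d[1L], d[2L] * d[3L], d[4L])
      out <- matrix(0, d[1L], d[4L])
      for (n in seq_len(d[4L])) out[, n] <- rowMeans(m[, , n, drop = FALSE])
      out
    },
    dropout = {
      if (training && ly$p > 0) {
        mask <- (stats::runif(length(x)) >= ly$p) / (1 - ly$p)
        ly$cache <- list(mask = mask)
        x * mask
      } else {
        ly$cache <- list(mask = NULL)
        x
      }
    },
    standardize = (x - ly$mu) * ly$sc,
    maxpool = maxpool_forward(ly, x),
    attention_pool = attention_pool_forward(ly, x),
    transformer_block = transformer_forward(ly, x, training),
    residual = {
      a <- seq_forward(ly$main, x, training)
      s <- if (is.null(ly$shortcut)) x else seq_forward(ly$shortcut, x, training)
      y <- a + s
      ly$cache <- list(mask = y > 0)
      y * (y > 0)
    },
    stop("unknown layer kind: ", ly$kind)
  )
}

ly_backward <- function(ly, g) {
  switch(ly$kind,
    conv2d = {
      ca <- ly$cache; d <- ca$dims; N <- d[4L]
      gmat <- matrix(g, nrow = ly$out_ch)
      ly$gr$W <- tcrossprod(gmat, ca$cols)
      if (ly$bias) ly$gr$b <- rowSums(gmat)
      gcols <- crossprod(ly$par$W, gmat)
      dim(gcols) <- c(length(gcols) %/% N, N)
      gxp <- as.matrix(ca$lg$g$S %*% gcols)
      dim(gxp) <- c(d[1L], ca$lg$g$Hp, ca$lg$g$Wp, N)
      unpad_batch(gxp, ly$pad, d[2L], d[3L])
    },
    conv_transpose2d = {
      ca <- ly$cache; d <- ca$dims; N <- d[4L]
      gyp <- pad_batch(g, ly$pad)
      nr <- ly$out_ch * ly$k * ly$k
      colsg <- gyp[ca$lg$idxN]
      dim(colsg) <- c(nr, length(colsg) %/% nr)
      ly$gr$W <- tcrossprod(ca$xmat, colsg)
      if (ly$bias) ly$gr$b <- rowSums(g, dims = 1L)
      gx <- ly$par$W %*% colsg
      array(gx, dim = d)
    },
    linear = {
      ly$gr$W <- tcrossprod(g, ly$cache$x)
      if (ly$bias) ly$gr$b <- rowSums(as.matrix(g))
      crossprod(ly$par$W, g)
    },
    relu = g * ly$cache$mask,
    sigmoid = {
      o <- ly$cache$out
      g * o * (1 - o)
    },
    flatten = array(g, dim = ly$cache$dims),
    gap = {
      d <- ly$cache$dims
      P <- d[2L] * d[3L]
      out <- array(0, dim = d)
      gm <- as.matrix(g) / P
      for (n in seq_len(d[4L])) out[, , , n] <- gm[, n]
      out
    },
    dropout = if (is.null(ly$cache$mask)) g else g * ly$cache$mask,
    standardize = g * ly$sc,
    maxpool = maxpool_backward(ly, g),
    attention_pool = attention_pool_backward(ly, g),
    transformer_block = transformer_backward(ly, g),
    residual = {
      gy <- g * ly$cache$mask
      gm <- seq_backward(ly$main, gy)
      gs <- if (is.null(ly$shortcut)) gy else seq_backward(ly$shortcut, gy)
      gm + gs
    },
    stop("unknown layer kind: ", ly$kind)
  )
}

seq_forward <- function(layers, x, training = FALSE, record = NULL) {
  for (ly in layers) {
    x <- ly_forward(ly, x, training)
    if (!is.null(record)) record[[ly$name]] <- x
  }
  if (!is.null(record)) attr(x, "record") <- record
  x
}

seq_backward <- function(layers, g) {
  for (ly in rev(layers)) g <- ly_backward(ly, g)
  g
}

# ---- maxpool -----------------------------------------------------------

maxpool_forward <- function(ly, x) {
  d <- dim(x); C <- d[1L]; N <- d[4L]
  lg <- layer_geom(ly, C, d[2L], d[3L], N); g <- lg$g
  xp <- pad_batch(x, ly$pad)   # zero padding participates in the max
  cols <- matrix(xp[lg$idxN], nrow = C * ly$k * ly$k)
  kk <- ly$k * ly$k
  arr <- array(cols, dim = c(C, kk, g$oh * g$ow * N))
  m <- arr[, 1L, ]; amax <- array(1L, dim = dim(m))
  if (kk > 1L) for (t in 2:kk) {
    cur <- arr[, t, ]
    upd <- cur > m
    m[upd] <- cur[upd]
    amax[upd] <- t
  }
  ly$cache <- list(dims = d, lg = lg, amax = amax)
  array(m, dim = c(C, g$oh, g$ow, N))
}

maxpool_backward <- function(ly, g) {
  ca <- ly$cache; d <- ca$dims; C <- d[1L]; N <- d[4L]
  lg <- ca$lg; gg <- lg$g
  kk <- ly$k * ly$k
  npos <- gg$oh * gg$ow * N
  ch <- rep(seq_len(C), times = npos)
  posn <- rep(seq_len(npos), each = C)
  flat <- ch + C * (as.vector(ca$amax) - 1L) + C * kk * (posn - 1L)
  target <- lg$idxN[flat]
  acc <- rowsum(as.vector(g), group = target)
  gxp <- numeric(C * gg$Hp * gg$Wp * N)
  gxp[as.integer(rownames(acc))] <- acc
  gxp <- array(gxp, dim = c(C, gg$Hp, gg$Wp, N))
  unpad_batch(gxp, ly$pad, d[2L], d[3L])
}

# ---- attention pooling -------------------------------------------------

# Spatial soft attention over the bottleneck: a learned scalar score per
# position, softmax-normalized; output is the attention-weighted sum of
# position features (C per sample).
attention_pool_forward <- function(ly, x) {
  d <- dim(x); C <- d[1L]; P <- d[2L] * d[3L]; N <- d[4L]
  f <- matrix(x, nrow = C)                      # (C, P*N)
  s <- matrix(as.vector(ly$par$w %*% f) + ly$par$b, nrow = P)
  s <- s - rep(apply(s, 2L, max), each = P)
  a <- exp(s); a <- a / rep(colSums(a), each = P)   # (P, N)
  f2 <- f * rep(as.vector(a), each = C)
  dim(f2) <- c(C, P, N)
  out <- apply(f2, c(1L, 3L), sum)
  ly$cache <- list(dims = d, f = f, a = a)
  out
}

attention_pool_backward <- function(ly, g) {
  ca <- ly$cache; d <- ca$dims
  C <- d[1L]; P <- d[2L] * d[3L]; N <- d[4L]
  f <- ca$f; a <- ca$a
  g <- as.matrix(g)                              # (C, N)
  # d alpha_p = g . f_p ; df_p = alpha_p * g
  grep_ <- g[, rep(seq_len(N), each = P), drop = FALSE]   # (C, P*N)
  da <- matrix(colSums(grep_ * f), nrow = P)     # (P, N)
  df <- grep_ * rep(as.vector(a), each = C)
  # softmax backward
  ds <- a * (da - rep(colSums(a * da), each = P))
  ly$gr$w <- tcrossprod(matrix(as.vector(ds), nrow = 1L), f)
  ly$gr$b <- sum(ds)
  df <- df + crossprod(ly$par$w, matrix(as.vector(ds), nrow = 1L))
  array(df, dim = d)
}

# ---- transformer block -------------------------------------------------

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

layernorm_rows <- function(X, gamma, beta, eps) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, gamma, "*") + rep(beta, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_rows_backward <- function(dy, ln, gamma) {
  dxhat <- sweep(dy, 2L, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * ln$xhat)
  dx <- (dxhat - m1 - ln$xhat * m2) * ln$inv
  list(dx = dx, dg = colSums(dy * ln$xhat), db = colSums(dy))
}

# One pre-classifier transformer encoder block over the n^2 bottleneck
# positions: multi-head self-attention + position-wise FFN, residuals and
# layer norm; sequence shape (P x d) is preserved.
transformer_forward <- function(ly, x, training = FALSE) {
  d <- dim(x); C <- d[1L]; P <- d[2L] * d[3L]; N <- d[4L]
  stopifnot(C == ly$d)
  p <- ly$par; h <- ly$heads; dk <- ly$dk
  caches <- vector("list", N)
  out <- array(0, dim = d)
  xm <- matrix(x, nrow = C)
  for (n in seq_len(N)) {
    X <- t(xm[, (n - 1L) * P + seq_len(P), drop = FALSE])   # (P, d)
    Q <- X %*% t(p$Wq) + rep(p$bq, each = P)
    K <- X %*% t(p$Wk) + rep(p$bk, each = P)
    V <- X %*% t(p$Wv) + rep(p$bv, each = P)
    A <- vector("list", h); O <- matrix(0, P, ly$d)
    for (hh in seq_len(h)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      Ah <- softmax_rows(Q[, cols, drop = FALSE] %*%
                           t(K[, cols, drop = FALSE]) / sqrt(dk))
      A[[hh]] <- Ah
      O[, cols] <- Ah %*% V[, cols, drop = FALSE]
    }
    Op <- O %*% t(p$Wo) + rep(p$bo, each = P)
    R1 <- X + Op
    ln1 <- layernorm_rows(R1, p$g1, p$be1, ly$eps)
    Z1 <- ln1$y %*% t(p$W1) + rep(p$b1, each = P)
    Hh <- Z1 * (Z1 > 0)
    F2 <- Hh %*% t(p$W2) + rep(p$b2, each = P)
    R2 <- ln1$y + F2
    ln2 <- layernorm_rows(R2, p$g2, p$be2, ly$eps)
    out[, , , n] <- t(ln2$y)
    caches[[n]] <- list(X = X, Q = Q, K = K, V = V, A = A, O = O,
                        ln1 = ln1, Z1 = Z1, Hh = Hh, ln2 = ln2)
  }
  ly$cache <- list(dims = d, P = P, caches = caches)
  out
}

transformer_backward <- function(ly, g) {
  d <- ly$cache$dims; P <- ly$cache$P; N <- d[4L]
  p <- ly$par; h <- ly$heads; dk <- ly$dk
  zero <- function(a) array(0, dim = dim(a))
  gr <- lapply(p, function(a) if (is.matrix(a)) zero(a) else numeric(length(a)))
  gx <- array(0, dim = d)
  gm <- matrix(g, nrow = d[1L])
  for (n in seq_len(N)) {
    ca <- ly$cache$caches[[n]]
    dy <- t(gm[, (n - 1L) * P + seq_len(P), drop = FALSE])  # (P, d)
    l2 <- layernorm_rows_backward(dy, ca$ln2, p$g2)
    gr$g2 <- gr$g2 + l2$dg; gr$be2 <- gr$be2 + l2$db
    dR2 <- l2$dx
    # FFN
    dF2 <- dR2
    gr$W2 <- gr$W2 + t(dF2) %*% ca$Hh
    gr$b2 <- gr$b2 + colSums(dF2)
    dH <- dF2 %*% p$W2
    dZ1 <- dH * (ca$Z1 > 0)
    gr$W1 <- gr$W1 + t(dZ1) %*% ca$ln1$y
    gr$b1 <- gr$b1 + colSums(dZ1)
    dL1 <- dR2 + dZ1 %*% p$W1
    l1 <- layernorm_rows_backward(dL1, ca$ln1, p$g1)
    gr$g1 <- gr$g1 + l1$dg; gr$be1 <- gr$be1 + l1$db
    dR1 <- l1$dx
    dX <- dR1
    dOp <- dR1
    gr$Wo <- gr$Wo + t(dOp) %*% ca$O
    gr$bo <- gr$bo + colSums(dOp)
    dO <- dOp %*% p$Wo
    dQ <- matrix(0, P, ly$d); dK <- matrix(0, P, ly$d); dV <- matrix(0, P, ly$d)
    for (hh in seq_len(h)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      Ah <- ca$A[[hh]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- ca$V[, cols, drop = FALSE]
      dAh <- dOh %*% t(Vh)
      dV[, cols] <- t(Ah) %*% dOh
      dSh <- Ah * (dAh - rowSums(dAh * Ah))
      dQ[, cols] <- dSh %*% ca$K[, cols, drop = FALSE] / sqrt(dk)
      dK[, cols] <- t(dSh) %*% ca$Q[, cols, drop = FALSE] / sqrt(dk)
    }
    gr$Wq <- gr$Wq + t(dQ) %*% ca$X; gr$bq <- gr$bq + colSums(dQ)
    gr$Wk <- gr$Wk + t(dK) %*% ca$X; gr$bk <- gr$bk + colSums(dK)
    gr$Wv <- gr$Wv + t(dV) %*% ca$X; gr$bv <- gr$bv + colSums(dV)
    dX <- dX + dQ %*% p$Wq + dK %*% p$Wk + dV %*% p$Wv
    gx[, , , n] <- t(dX)
  }
  ly$gr <- gr
  gx
}

# ---- parameter utilities ----------------------------------------------

# Deep copy of layer objects (layers are mutable environments; models that
# share pretrained encoders must not alias each other's parameters).
clone_layer <- function(ly) {
  ly2 <- new.env(parent = emptyenv())
  for (nm in ls(ly, all.names = TRUE)) assign(nm, get(nm, envir = ly), ly2)
  ly2$cache <- NULL
  ly2$gr <- list()
  ly2$opt <- NULL
  ly2$geom <- list()
  ly2$idxN <- list()
  if (identical(ly$kind, "residual")) {
    ly2$main <- clone_layers(ly$main)
    if (!is.null(ly$shortcut)) ly2$shortcut <- clone_layers(ly$shortcut)
  }
  class(ly2) <- "nn_layer"
  ly2
}

clone_layers <- function(layers) lapply(layers, clone_layer)

# Recursively collect layers holding parameters (descends into residual
# containers).
collect_param_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (ly$kind == "residual") {
      out <- c(out, collect_param_layers(ly$main))
      if (!is.null(ly$shortcut)) out <- c(out, collect_param_layers(ly$shortcut))
    } else if (length(ly$par)) {
      out <- c(out, list(ly))
    }
  }
  out
}

n_params <- function(layers) {
  sum(vapply(collect_param_layers(layers),
             function(ly) sum(vapply(ly$par, length, 0L)), 0))
}

snapshot_params <- function(layers) {
  lapply(collect_param_layers(layers), function(ly) ly$par)
}

restore_params <- function(layers, snap) {
  pls <- collect_param_layers(layers)
  stopifnot(length(pls) == length(snap))
  for (i in seq_along(pls)) pls[[i]]$par <- snap[[i]]
  invisible(NULL)
}

# ---- Adam --------------------------------------------------------------

adam_init <- function(layers) {
  for (ly in collect_param_layers(layers)) {
    ly$opt <- list(m = lapply(ly$par, function(a) a * 0),
                   v = lapply(ly$par, function(a) a * 0))
  }
  invisible(NULL)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  # bias correction folded into a scalar step size (standard reformulation)
  step <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (ly in collect_param_layers(layers)) {
    if (is.null(ly$opt)) next
    for (nm in names(ly$par)) {
      g <- ly$gr[[nm]]
      if (is.null(g)) next
      if (weight_decay > 0) g <- g + weight_decay * ly$par[[nm]]
      m <- beta1 * ly$opt$m[[nm]] + (1 - beta1) * g
      v <- beta2 * ly$opt$v[[nm]] + (1 - beta2) * g * g
      ly$opt$m[[nm]] <- m
      ly$opt$v[[nm]] <- v
      ly$par[[nm]] <- ly$par[[nm]] - step * m / (sqrt(v) + eps)
    }
    ly$gr <- list()
  }
  invisible(NULL)
}

# ---- losses ------------------------------------------------------------

# Numerically stable softmax cross-entropy with optional label smoothing.
# logits: (K, N); y: integer vector in 1..K. Returns loss and dlogits.
softmax_ce <- function(logits, y, label_smoothing = 0) {
  K <- nrow(logits); N <- ncol(logits)
  m <- apply(logits, 2L, max)
  z <- logits - rep(m, each = K)
  lse <- log(colSums(exp(z)))
  logp <- z - rep(lse, each = K)
  tgt <- matrix(label_smoothing / K, K, N)
  tgt[cbind(y, seq_len(N))] <- tgt[cbind(y, seq_len(N))] +
    (1 - label_smoothing)
  loss <- -sum(tgt * logp) / N
  dlogits <- (exp(logp) - tgt) / N
  list(loss = loss, dlogits = dlogits)
}

softmax_cols <- function(logits) {
  K <- nrow(logits)
  z <- logits - rep(apply(logits, 2L, max), each = K)
  e <- exp(z)
  e / rep(colSums(e), each = K)
}
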