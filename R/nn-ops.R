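# ---- neural-network primitives (pure R, analytic gradients) ---------------
#
# The Transformer-CNN classifier is implemented directly on double-precision
# matrices: batched token projections share one BLAS matmul across trials,
# attention is evaluated per trial and head, the CNN head uses im2col
# gathers, and every backward pass is derived analytically (verified against
# finite differences in the test suite).

# row-wise softmax, stabilized by the matrix-wide maximum (logit ranges
# within one attention matrix are far narrower than the exp() underflow
# span, so the global shift is as safe as a per-row shift and cheaper)
softmax_rows <- function(L) {
  E <- exp(L - max(L))
  E / rowSums(E)
}

# sinusoidal positional encoding, n tokens x d dims
positional_encoding <- function(n, d) {
  pos <- seq_len(n) - 1
  pe <- matrix(0, n, d)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= d) pe[, 2 * i] <- cos(pos * freq)
  }
  pe
}

# layer normalization over the feature dimension (per row)
ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  n <- nrow(X)
  Y <- xhat * rep(g, each = n) + rep(b, each = n)
  list(out = Y, xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  n <- nrow(dY)
  dxhat <- dY * rep(g, each = n)
  h1 <- rowMeans(dxhat)
  h2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - h1 - cache$xhat * h2)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

# inverted dropout; returns list(out, mask)
drop_forward <- function(X, p) {
  if (p <= 0) return(list(out = X, mask = NULL))
  m <- (matrix(stats::runif(length(X)), nrow(X)) >= p) / (1 - p)
  list(out = X * m, mask = m)
}
drop_backward <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# ---- convolution / pooling geometry ---------------------------------------

# batch-extended index tables: row-blocked stacks over B images share the
# per-image tables shifted by the image stride; cached per batch size
batch_tables <- function(geom, B) {
  key <- as.character(B)
  hit <- get0(key, envir = geom$bt_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  g1 <- geom$g1; g2 <- geom$g2; p1 <- geom$p1; p2 <- geom$p2
  n1 <- nrow(g1$P); n2 <- nrow(g2$P)
  bt <- list(
    P1 = g1$P[rep(seq_len(n1), B), ] +
      rep((seq_len(B) - 1L) * g1$in_len, each = n1),
    P2 = g2$P[rep(seq_len(n2), B), ] +
      rep((seq_len(B) - 1L) * g2$in_len, each = n2),
    c1 = lapply(p1$corners, function(ix)
      rep(ix, B) + rep((seq_len(B) - 1L) * p1$n_in, each = length(ix))),
    c2 = lapply(p2$corners, function(ix)
      rep(ix, B) + rep((seq_len(B) - 1L) * p2$n_in, each = length(ix))))
  assign(key, bt, envir = geom$bt_cache)
  bt
}

# max-pool over row-blocked stacks given (batch-extended) corner indices
pool_forward_idx <- function(X, corners) {
  cur <- X[corners[[1]], , drop = FALSE]
  nsp <- length(corners[[1]]); Cf <- ncol(X)
  src <- matrix(rep(corners[[1]], Cf), nsp, Cf)
  for (k in 2:4) {
    Vk <- X[corners[[k]], , drop = FALSE]
    sel <- Vk > cur
    cur[sel] <- Vk[sel]
    srck <- matrix(rep(corners[[k]], Cf), nsp, Cf)
    src[sel] <- srck[sel]
  }
  list(out = cur, src = src)
}

pool_backward_idx <- function(dY, src, n_rows) {
  Cf <- ncol(dY)
  dX <- matrix(0, n_rows, Cf)
  lin <- src + rep((seq_len(Cf) - 1L) * n_rows, each = nrow(src))
  dX[lin] <- dY               # pools are disjoint: plain scatter
  dX
}

# batched col2im for row-blocked stacks (P_all = batch-extended table)
col2im_add_idx <- function(dcols, P_all, len) {
  dx <- numeric(len)
  for (j in seq_len(ncol(P_all))) {
    pj <- P_all[, j]
    dx[pj] <- dx[pj] + dcols[, j]
  }
  dx
}

# im2col index table for a valid 3x3 convolution over an H x W image with
# Cin input planes stored column-major (h fastest, then w, then plane)
conv_geom <- function(H, W, Cin) {
  oH <- H - 2L; oW <- W - 2L
  if (oH < 1 || oW < 1) stop("spatial dims too small for a 3x3 convolution")
  h0 <- rep(seq_len(oH), oW)
  w0 <- rep(seq_len(oW), each = oH)
  P <- matrix(0L, oH * oW, 9L * Cin)
  j <- 0L
  for (cin in seq_len(Cin)) for (dw in 0:2) for (dh in 0:2) {
    j <- j + 1L
    P[, j] <- (cin - 1L) * H * W + (w0 + dw - 1L) * H + (h0 + dh)
  }
  list(P = P, Pvec = as.vector(P), oH = oH, oW = oW, Cin = Cin,
       in_len = H * W * Cin)
}

# 2x2 stride-2 max-pooling index table over an H x W grid (column-major)
pool_geom <- function(H, W) {
  pH <- H %/% 2L; pW <- W %/% 2L
  if (pH < 1 || pW < 1) stop("spatial dims too small for 2x2 pooling")
  ph <- rep(seq_len(pH), pW)
  pw <- rep(seq_len(pW), each = pH)
  corners <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                    function(dd) (2L * pw - 2L + dd[2]) * H + (2L * ph - 1L + dd[1]))
  list(corners = corners, pH = pH, pW = pW, n_in = H * W)
}

# conv forward for one image: x = input vector (H*W*Cin), K = (9*Cin) x Cout
conv_forward1 <- function(x, geom, K, b) {
  cols <- matrix(x[geom$Pvec], nrow(geom$P))
  A <- cols %*% K
  A <- A + rep(b, each = nrow(A))
  list(out = A, cols = cols)
}

# Glorot-uniform / He-normal initializers
glorot <- function(n_in, n_out) {
  l <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -l, l), n_in, n_out)
}
he_normal <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}
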