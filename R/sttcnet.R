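# ---- P300-STTCNet: prior-guided Transformer-CNN classifier ----------------

#' Network configuration
#'
#' Architecture hyper-parameters of the Transformer-CNN classifier: time
#' samples are the tokens, the channel vector at each sample is linearly
#' embedded into `d_model` dimensions, a 4-layer post-norm Transformer
#' encoder with prior-masked multi-head attention models temporal
#' dependencies, and a two-stage 3x3 convolution / 2x2 max-pool head with an
#' MLP produces the class logits.
#'
#' @param d_model embedding size (default 64); must be divisible by
#'   `n_heads`.
#' @param n_heads number of attention heads (default 4).
#' @param n_layers encoder depth (default 4).
#' @param ffn_dim feed-forward hidden width (default 128).
#' @param conv1_filters,conv2_filters CNN feature maps (defaults 16 and 32).
#' @param kernel convolution kernel size; the implementation realizes the
#'   3x3 case.
#' @param pool pooling size; the implementation realizes the 2x2 case.
#' @param mlp_hidden MLP hidden width (default 64).
#' @param dropout dropout probability during training (default 0.1).
#' @param n_classes number of output classes (2).
#' @return list of class `"sttcnet_config"`.
#' @export
sttcnet_config <- function(d_model = 64, n_heads = 4, n_layers = 4,
                           ffn_dim = 128, conv1_filters = 16,
                           conv2_filters = 32, kernel = 3, pool = 2,
                           mlp_hidden = 64, dropout = 0.1, n_classes = 2) {
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (kernel != 3) stop("only 3x3 convolution kernels are implemented")
  if (pool != 2) stop("only 2x2 pooling is implemented")
  if (n_layers < 1) stop("n_layers must be >= 1")
  structure(list(d_model = d_model, n_heads = n_heads, n_layers = n_layers,
                 ffn_dim = ffn_dim, conv1_filters = conv1_filters,
                 conv2_filters = conv2_filters, kernel = kernel, pool = pool,
                 mlp_hidden = mlp_hidden, dropout = dropout,
                 n_classes = n_classes),
            class = "sttcnet_config")
}

#' ERP prior specification
#'
#' Packages the two ERP priors injected into the network: per-channel
#' initial weights (higher at the fronto-central electrodes where group
#' differences concentrate) and the additive attention-mask window with its
#' logit bias. The channel weights are trainable; the mask is fixed.
#'
#' @param channels channel labels the prior must cover.
#' @param prioritized channels receiving the high initial weight
#'   (default Fz, C3, Cz, C4).
#' @param weight_high,weight_base initial weights for prioritized vs other
#'   channels (defaults 1.5 and 1.0); must be positive.
#' @param mask_window closed attention-bias window in ms
#'   (default `c(250, 450)`).
#' @param mask_magnitude dimensionless logit bias `lambda >= 0`
#'   (0 disables the prior; default 1).
#' @return list of class `"prior_spec"` with `channel_weights`,
#'   `mask_window`, `mask_magnitude`.
#' @export
prior_spec <- function(channels = default_channels(),
                       prioritized = c("Fz", "C3", "Cz", "C4"),
                       weight_high = 1.5, weight_base = 1.0,
                       mask_window = c(250, 450), mask_magnitude = 1.0) {
  if (weight_high <= 0 || weight_base <= 0) stop("weights must be positive")
  if (mask_magnitude < 0) stop("mask_magnitude must be >= 0")
  w <- stats::setNames(rep(weight_base, length(channels)), channels)
  w[intersect(prioritized, channels)] <- weight_high
  structure(list(channel_weights = w, mask_window = mask_window,
                 mask_magnitude = mask_magnitude),
            class = "prior_spec")
}

#' Scale epochs by per-channel weights
#'
#' Multiplies channel `c` of every trial by `weights[c]` — the operation the
#' network's trainable channel-prior layer applies to its input.
#'
#' @param ep an `epoch_set`.
#' @param weights named numeric vector covering every channel of `ep`.
#' @return the weighted `epoch_set`.
#' @export
apply_channel_prior <- function(ep, weights) {
  stopifnot(inherits(ep, "epoch_set"))
  miss <- setdiff(ep$channels, names(weights))
  if (length(miss))
    stop("missing channel weight(s): ", paste(miss, collapse = ", "))
  ep$data <- sweep(ep$data, 2, weights[ep$channels], "*")
  ep
}

#' Build the additive prior attention mask
#'
#' An `n x n` logit-bias matrix with entry `(i, j) = lambda` whenever token
#' `j`'s time lies inside the closed window (bias on key positions, applied
#' uniformly to all query rows), else 0. Added to the scaled dot-product
#' logits before the softmax, it raises attention toward the P300 window.
#' A constant mask (all tokens inside the window) leaves the attention
#' unchanged, by softmax shift invariance.
#'
#' @param t_axis token times in ms.
#' @param window closed window in ms (default `c(250, 450)`).
#' @param lambda nonnegative logit bias; 0 gives the zero matrix.
#' @return `n x n` numeric matrix.
#' @export
build_prior_mask <- function(t_axis, window = c(250, 450), lambda = 1) {
  if (lambda < 0) stop("lambda must be >= 0")
  key <- t_axis >= window[1] & t_axis <= window[2]
  if (!any(key))
    stop("mask window [", window[1], ", ", window[2],
         "] ms does not intersect the epoch time axis")
  n <- length(t_axis)
  M <- matrix(0, n, n)
  M[, key] <- lambda
  M
}

#' Masked scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k) + mask) V`. Every row of the attention
#' weight matrix sums to 1 for any finite mask.
#'
#' @param Q,K,V `n x d_k` matrices.
#' @param mask optional `n x n` additive logit matrix (`NULL` = no mask).
#' @return list with `output` (`n x d_k`) and `weights` (`n x n`).
#' @export
masked_attention <- function(Q, K, V, mask = NULL) {
  dk <- ncol(Q)
  if (is.null(dk) || dk < 1) stop("d_k must be >= 1")
  stopifnot(ncol(K) == dk, nrow(K) == nrow(V))
  L <- tcrossprod(Q, K) / sqrt(dk)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(L)))
    L <- L + mask
  }
  A <- softmax_rows(L)
  list(output = A %*% V, weights = A)
}

#' Multi-head attention
#'
#' Projects the input sequence into per-head queries, keys and values,
#' applies [masked_attention()] per head with a shared mask, concatenates
#' the head outputs and projects them with `Wo`.
#'
#' @param S `n x d` input sequence.
#' @param Wq,Wk,Wv,Wo `d x d` projection matrices.
#' @param n_heads number of heads; `d` must be divisible by it.
#' @param mask optional `n x n` additive logit mask.
#' @return `n x d` output with the per-head attention weights attached as
#'   attribute `"weights"` (a list).
#' @export
multi_head <- function(S, Wq, Wk, Wv, Wo, n_heads, mask = NULL) {
  d <- ncol(S)
  if (d %% n_heads != 0) stop("d must be divisible by n_heads")
  dk <- d / n_heads
  Q <- S %*% Wq; K <- S %*% Wk; V <- S %*% Wv
  H <- matrix(0, nrow(S), d)
  Ws <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cj <- ((h - 1) * dk + 1):(h * dk)
    at <- masked_attention(Q[, cj, drop = FALSE], K[, cj, drop = FALSE],
                           V[, cj, drop = FALSE], mask)
    H[, cj] <- at$output
    Ws[[h]] <- at$weights
  }
  out <- H %*% Wo
  attr(out, "weights") <- Ws
  out
}

# ---- parameter container --------------------------------------------------

nn_geom <- function(cfg, Tn) {
  g1 <- conv_geom(Tn, cfg$d_model, 1L)
  p1 <- pool_geom(g1$oH, g1$oW)
  g2 <- conv_geom(p1$pH, p1$pW, cfg$conv1_filters)
  p2 <- pool_geom(g2$oH, g2$oW)
  list(g1 = g1, p1 = p1, g2 = g2, p2 = p2,
       flat = p2$pH * p2$pW * cfg$conv2_filters,
       PE = positional_encoding(Tn, cfg$d_model), Tn = Tn,
       bt_cache = new.env(parent = emptyenv()))
}

# flat named parameter list; RNG state of the caller is used
nn_init_params <- function(cfg, n_channels, geom, channel_weights) {
  d <- cfg$d_model
  p <- list(chan_w = as.numeric(channel_weights),
            emb_W = glorot(n_channels, d),
            emb_b = numeric(d))
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("enc", l, "_")
    p[[paste0(pre, "Wq")]] <- glorot(d, d)
    p[[paste0(pre, "Wk")]] <- glorot(d, d)
    p[[paste0(pre, "Wv")]] <- glorot(d, d)
    p[[paste0(pre, "Wo")]] <- glorot(d, d)
    p[[paste0(pre, "bq")]] <- numeric(d)
    p[[paste0(pre, "bk")]] <- numeric(d)
    p[[paste0(pre, "bv")]] <- numeric(d)
    p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- glorot(d, cfg$ffn_dim)
    p[[paste0(pre, "b1")]] <- numeric(cfg$ffn_dim)
    p[[paste0(pre, "W2")]] <- glorot(cfg$ffn_dim, d)
    p[[paste0(pre, "b2")]] <- numeric(d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- numeric(d)
  }
  p$conv1_K <- he_normal(9L, cfg$conv1_filters)
  p$conv1_b <- numeric(cfg$conv1_filters)
  p$conv2_K <- he_normal(9L * cfg$conv1_filters, cfg$conv2_filters)
  p$conv2_b <- numeric(cfg$conv2_filters)
  p$mlp_W1 <- he_normal(geom$flat, cfg$mlp_hidden)
  p$mlp_b1 <- numeric(cfg$mlp_hidden)
  # down-scaled output layer: near-uniform initial class probabilities keep
  # the first optimizer steps small (guards the conv ReLUs against dying)
  p$mlp_W2 <- glorot(cfg$mlp_hidden, cfg$n_classes) * 0.1
  p$mlp_b2 <- numeric(cfg$n_classes)
  p
}

# global gradient-norm clipping
clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(grads)
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (gn > max_norm) grads <- lapply(grads, function(g) g * (max_norm / gn))
  grads
}

addb <- function(X, b) X + rep(b, each = nrow(X))

# ---- encoder stack (batched, trial-blocked token matrix) ------------------

encoder_stack <- function(S, params, cfg, mask, B, Tn, p_drop) {
  d <- cfg$d_model; nh <- cfg$n_heads; dk <- d / nh
  scl <- 1 / sqrt(dk)
  mask_t <- if (is.null(mask)) NULL
            else mask[rep(seq_len(Tn), times = B), , drop = FALSE]
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("enc", l, "_")
    P <- function(nm) params[[paste0(pre, nm)]]
    lc <- list(S_in = S)
    Qb <- addb(S %*% P("Wq"), P("bq"))
    Kb <- addb(S %*% P("Wk"), P("bk"))
    Vb <- addb(S %*% P("Wv"), P("bv"))
    Hb <- matrix(0, B * Tn, d)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cj <- ((h - 1) * dk + 1):(h * dk)
      Lg <- matrix(0, B * Tn, Tn)
      for (i in seq_len(B)) {
        ri <- ((i - 1) * Tn + 1):(i * Tn)
        Lg[ri, ] <- tcrossprod(Qb[ri, cj, drop = FALSE],
                               Kb[ri, cj, drop = FALSE])
      }
      Lg <- Lg * scl
      if (!is.null(mask_t)) Lg <- Lg + mask_t
      A <- softmax_rows(Lg)
      for (i in seq_len(B)) {
        ri <- ((i - 1) * Tn + 1):(i * Tn)
        Hb[ri, cj] <- A[ri, , drop = FALSE] %*% Vb[ri, cj, drop = FALSE]
      }
      A_heads[[h]] <- A
    }
    O <- addb(Hb %*% P("Wo"), P("bo"))
    dpa <- drop_forward(O, p_drop)
    l1 <- ln_forward(S + dpa$out, P("ln1_g"), P("ln1_b"))
    S1 <- l1$out
    H1pre <- addb(S1 %*% P("W1"), P("b1"))
    H1 <- pmax(H1pre, 0)
    F2 <- addb(H1 %*% P("W2"), P("b2"))
    dpf <- drop_forward(F2, p_drop)
    l2 <- ln_forward(S1 + dpf$out, P("ln2_g"), P("ln2_b"))
    lc$Qb <- Qb; lc$Kb <- Kb; lc$Vb <- Vb; lc$A_heads <- A_heads; lc$Hb <- Hb
    lc$dropA <- dpa$mask; lc$ln1 <- l1[c("xhat", "inv")]; lc$S1 <- S1
    lc$relu1 <- H1pre > 0; lc$H1 <- H1; lc$dropF <- dpf$mask
    lc$ln2 <- l2[c("xhat", "inv")]
    layers[[l]] <- lc
    S <- l2$out
  }
  list(out = S, layers = layers)
}

encoder_stack_backward <- function(dS, layers, params, cfg, mask, B, Tn) {
  d <- cfg$d_model; nh <- cfg$n_heads; dk <- d / nh
  scl <- 1 / sqrt(dk)
  grads <- list()
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("enc", l, "_")
    P <- function(nm) params[[paste0(pre, nm)]]
    lc <- layers[[l]]
    l2b <- ln_backward(dS, lc$ln2, P("ln2_g"))
    grads[[paste0(pre, "ln2_g")]] <- l2b$dg
    grads[[paste0(pre, "ln2_b")]] <- l2b$db
    dsum2 <- l2b$dX                        # d(S1 + dropout(F2))
    dF2 <- drop_backward(dsum2, lc$dropF)
    grads[[paste0(pre, "W2")]] <- crossprod(lc$H1, dF2)
    grads[[paste0(pre, "b2")]] <- colSums(dF2)
    dH1 <- (dF2 %*% t(P("W2"))) * lc$relu1
    grads[[paste0(pre, "W1")]] <- crossprod(lc$S1, dH1)
    grads[[paste0(pre, "b1")]] <- colSums(dH1)
    dS1 <- dsum2 + dH1 %*% t(P("W1"))
    l1b <- ln_backward(dS1, lc$ln1, P("ln1_g"))
    grads[[paste0(pre, "ln1_g")]] <- l1b$dg
    grads[[paste0(pre, "ln1_b")]] <- l1b$db
    dsum1 <- l1b$dX                        # d(S_in + dropout(O))
    dO <- drop_backward(dsum1, lc$dropA)
    grads[[paste0(pre, "Wo")]] <- crossprod(lc$Hb, dO)
    grads[[paste0(pre, "bo")]] <- colSums(dO)
    dHb <- dO %*% t(P("Wo"))
    dQb <- matrix(0, B * Tn, d); dKb <- dQb; dVb <- dQb
    for (h in seq_len(nh)) {
      cj <- ((h - 1) * dk + 1):(h * dk)
      A <- lc$A_heads[[h]]
      dA <- matrix(0, B * Tn, Tn)
      for (i in seq_len(B)) {
        ri <- ((i - 1) * Tn + 1):(i * Tn)
        dA[ri, ] <- tcrossprod(dHb[ri, cj, drop = FALSE],
                               lc$Vb[ri, cj, drop = FALSE])
      }
      dL <- A * (dA - rowSums(dA * A))
      for (i in seq_len(B)) {
        ri <- ((i - 1) * Tn + 1):(i * Tn)
        Ai <- A[ri, , drop = FALSE]
        dLi <- dL[ri, , drop = FALSE]
        dVb[ri, cj] <- crossprod(Ai, dHb[ri, cj, drop = FALSE])
        dQb[ri, cj] <- dLi %*% lc$Kb[ri, cj, drop = FALSE] * scl
        dKb[ri, cj] <- crossprod(dLi, lc$Qb[ri, cj, drop = FALSE]) * scl
      }
    }
    grads[[paste0(pre, "Wq")]] <- crossprod(lc$S_in, dQb)
    grads[[paste0(pre, "Wk")]] <- crossprod(lc$S_in, dKb)
    grads[[paste0(pre, "Wv")]] <- crossprod(lc$S_in, dVb)
    grads[[paste0(pre, "bq")]] <- colSums(dQb)
    grads[[paste0(pre, "bk")]] <- colSums(dKb)
    grads[[paste0(pre, "bv")]] <- colSums(dVb)
    dS <- dsum1 + dQb %*% t(P("Wq")) + dKb %*% t(P("Wk")) + dVb %*% t(P("Wv"))
  }
  list(dS = dS, grads = grads)
}

#' Run the Transformer encoder on a single sequence
#'
#' Applies the configured stack of (masked multi-head attention -> add &
#' layer-norm -> feed-forward -> add & layer-norm) layers to one `n x d`
#' token sequence, with the prior mask shared across layers and heads.
#' Intended for inspection and testing; training uses the batched internal
#' path with identical arithmetic.
#'
#' @param S `n x d` input sequence.
#' @param params flat named parameter list (as produced internally; see
#'   `p300sttc:::nn_init_params`), or a fitted `"sttcnet"` model.
#' @param config an [sttcnet_config()] (ignored when `params` is a model).
#' @param mask optional `n x n` additive logit mask.
#' @return `n x d` encoded representation.
#' @export
encoder_forward <- function(S, params, config = NULL, mask = NULL) {
  if (inherits(params, "sttcnet")) {
    config <- params$config
    params <- params$params
  }
  stopifnot(inherits(config, "sttcnet_config"), ncol(S) == config$d_model)
  encoder_stack(S, params, config, mask, B = 1L, Tn = nrow(S), p_drop = 0)$out
}

#' Valid 3x3 2-D convolution (single image)
#'
#' Cross-correlation of `Cin` input planes with `Cout` 3x3 kernels plus
#' bias, "valid" padding, stride 1 — the operation used by the CNN head,
#' exposed for direct testing against sliding-window oracles.
#'
#' @param image `H x W` matrix or `H x W x Cin` array.
#' @param kernels `(9 * Cin) x Cout` kernel matrix; rows ordered
#'   (kernel row, kernel column, input plane), column-major.
#' @param bias length-`Cout` bias.
#' @return `(H-2) x (W-2) x Cout` array.
#' @export
conv2d <- function(image, kernels, bias = numeric(ncol(kernels))) {
  dm <- dim(image)
  if (length(dm) == 2) dm <- c(dm, 1L)
  g <- conv_geom(dm[1], dm[2], dm[3])
  out <- conv_forward1(as.vector(image), g, kernels, bias)$out
  array(out, c(g$oH, g$oW, ncol(kernels)))
}

# Batched CNN head over the row-blocked token stack: one im2col gather and
# one BLAS matmul per convolution for the whole minibatch.
cnn_forward <- function(S, params, cfg, geom, B, Tn, p_drop) {
  d <- cfg$d_model
  bt <- batch_tables(geom, B)
  # per-image vectors (h, w-plane column-major) stacked by trial
  x1 <- as.vector(aperm(array(S, c(Tn, B, d)), c(1, 3, 2)))
  cols1 <- x1[bt$P1]
  dim(cols1) <- dim(bt$P1)
  A1 <- addb(cols1 %*% params$conv1_K, params$conv1_b)
  r1 <- pmax(A1, 0)
  pl1 <- pool_forward_idx(r1, bt$c1)
  nf1 <- cfg$conv1_filters
  pHW1 <- geom$p1$pH * geom$p1$pW
  x2 <- as.vector(aperm(array(pl1$out, c(pHW1, B, nf1)), c(1, 3, 2)))
  cols2 <- x2[bt$P2]
  dim(cols2) <- dim(bt$P2)
  A2 <- addb(cols2 %*% params$conv2_K, params$conv2_b)
  r2 <- pmax(A2, 0)
  pl2 <- pool_forward_idx(r2, bt$c2)
  nf2 <- cfg$conv2_filters
  pHW2 <- geom$p2$pH * geom$p2$pW
  flat <- t(matrix(aperm(array(pl2$out, c(pHW2, B, nf2)), c(1, 3, 2)),
                   pHW2 * nf2, B))
  list(flat = flat,
       caches = list(cols1 = cols1, m1 = A1 > 0, src1 = pl1$src,
                     cols2 = cols2, m2 = A2 > 0, src2 = pl2$src, bt = bt))
}

cnn_backward <- function(dflat, caches, params, cfg, geom, B, Tn) {
  cc <- caches
  nf1 <- cfg$conv1_filters; nf2 <- cfg$conv2_filters
  pHW1 <- geom$p1$pH * geom$p1$pW
  pHW2 <- geom$p2$pH * geom$p2$pW
  d <- cfg$d_model
  dpool2 <- matrix(aperm(array(t(dflat), c(pHW2, nf2, B)), c(1, 3, 2)),
                   B * pHW2, nf2)
  dr2 <- pool_backward_idx(dpool2, cc$src2, B * geom$p2$n_in)
  dA2 <- dr2 * cc$m2
  dK2 <- crossprod(cc$cols2, dA2)
  db2 <- colSums(dA2)
  dx2 <- col2im_add_idx(dA2 %*% t(params$conv2_K), cc$bt$P2,
                        B * geom$g2$in_len)
  dpool1 <- matrix(aperm(array(dx2, c(pHW1, nf1, B)), c(1, 3, 2)),
                   B * pHW1, nf1)
  dr1 <- pool_backward_idx(dpool1, cc$src1, B * geom$p1$n_in)
  dA1 <- dr1 * cc$m1
  dK1 <- crossprod(cc$cols1, dA1)
  db1 <- colSums(dA1)
  dx1 <- col2im_add_idx(dA1 %*% t(params$conv1_K), cc$bt$P1,
                        B * geom$g1$in_len)
  dS <- matrix(aperm(array(dx1, c(Tn, d, B)), c(1, 3, 2)), B * Tn, d)
  list(dS = dS, conv1_K = dK1, conv1_b = db1, conv2_K = dK2, conv2_b = db2)
}

#' CNN + MLP classification head
#'
#' Treats an encoded `n x d` representation as a one-plane image and applies
#' conv(16 @ 3x3) -> ReLU -> max-pool(2x2) -> conv(32 @ 3x3) -> ReLU ->
#' max-pool(2x2) -> flatten -> MLP, returning the class logits.
#'
#' @param rep `n x d` representation matrix.
#' @param params flat named parameter list or a fitted `"sttcnet"` model.
#' @param config an [sttcnet_config()] (ignored when `params` is a model).
#' @return numeric vector of `n_classes` logits.
#' @export
cnn_head <- function(rep, params, config = NULL) {
  if (inherits(params, "sttcnet")) {
    config <- params$config
    params <- params$params
  }
  stopifnot(inherits(config, "sttcnet_config"))
  geom <- nn_geom(config, nrow(rep))
  cf <- cnn_forward(rep, params, config, geom, B = 1L, Tn = nrow(rep),
                    p_drop = 0)
  h <- pmax(addb(cf$flat %*% params$mlp_W1, params$mlp_b1), 0)
  drop(addb(h %*% params$mlp_W2, params$mlp_b2))
}

# ---- full forward / backward ----------------------------------------------

nn_forward <- function(params, Xb, cfg, geom, mask = NULL, training = FALSE) {
  p_drop <- if (training) cfg$dropout else 0
  B <- dim(Xb)[1]; C <- dim(Xb)[2]; Tn <- dim(Xb)[3]
  S0 <- matrix(aperm(Xb, c(3, 1, 2)), B * Tn, C)  # rows: trial-blocked tokens
  Sw <- S0 * rep(params$chan_w, each = B * Tn)
  E <- addb(Sw %*% params$emb_W, params$emb_b)
  E <- E + geom$PE[rep(seq_len(Tn), times = B), ]
  dp0 <- drop_forward(E, p_drop)
  enc <- encoder_stack(dp0$out, params, cfg, mask, B, Tn, p_drop)
  cnn <- cnn_forward(enc$out, params, cfg, geom, B, Tn, p_drop)
  Hm_pre <- addb(cnn$flat %*% params$mlp_W1, params$mlp_b1)
  Hm <- pmax(Hm_pre, 0)
  dph <- drop_forward(Hm, p_drop)
  logits <- addb(dph$out %*% params$mlp_W2, params$mlp_b2)
  list(logits = logits,
       cache = list(B = B, Tn = Tn, S0 = S0, Sw = Sw, drop0 = dp0$mask,
                    enc = enc, cnn = cnn, relu_m = Hm_pre > 0, Hm = Hm,
                    dropH = dph$mask, Hdrop = dph$out))
}

nn_backward <- function(params, cache, dlogits, cfg, geom, mask = NULL) {
  B <- cache$B; Tn <- cache$Tn
  grads <- list()
  grads$mlp_W2 <- crossprod(cache$Hdrop, dlogits)
  grads$mlp_b2 <- colSums(dlogits)
  dHm <- drop_backward(dlogits %*% t(params$mlp_W2), cache$dropH) *
    cache$relu_m
  grads$mlp_W1 <- crossprod(cache$cnn$flat, dHm)
  grads$mlp_b1 <- colSums(dHm)
  dflat <- dHm %*% t(params$mlp_W1)
  cb <- cnn_backward(dflat, cache$cnn$caches, params, cfg, geom, B, Tn)
  grads$conv1_K <- cb$conv1_K; grads$conv1_b <- cb$conv1_b
  grads$conv2_K <- cb$conv2_K; grads$conv2_b <- cb$conv2_b
  eb <- encoder_stack_backward(cb$dS, cache$enc$layers, params, cfg, mask,
                               B, Tn)
  grads <- c(grads, eb$grads)
  dE <- drop_backward(eb$dS, cache$drop0)
  grads$emb_b <- colSums(dE)
  grads$emb_W <- crossprod(cache$Sw, dE)
  dSw <- dE %*% t(params$emb_W)
  grads$chan_w <- colSums(dSw * cache$S0)
  grads
}

# softmax cross-entropy; y is an integer class index vector (1-based)
nn_loss_grads <- function(params, Xb, y, cfg, geom, mask = NULL,
                          training = FALSE) {
  fw <- nn_forward(params, Xb, cfg, geom, mask, training)
  B <- nrow(fw$logits)
  P <- softmax_rows(fw$logits)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-12)))
  dlog <- P
  dlog[cbind(seq_len(B), y)] <- dlog[cbind(seq_len(B), y)] - 1
  dlog <- dlog / B
  grads <- nn_backward(params, fw$cache, dlog, cfg, geom, mask)
  list(loss = loss, grads = grads, probs = P, logits = fw$logits)
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z, t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

# ---- training -------------------------------------------------------------

#' Fit the P300-STTCNet classifier
#'
#' Trains the prior-guided Transformer-CNN on single-trial epochs with Adam
#' and softmax cross-entropy. Inputs are standardized per channel (training
#' statistics are stored in the model and reused at prediction). The channel
#' prior supplies the trainable per-channel input weights (higher initial
#' values at Fz/C3/Cz/C4) and the fixed 250-450 ms attention-logit bias.
#' With `val_frac > 0` a stratified trial-level split drives early stopping
#' on validation loss; the best-epoch weights are restored. Fully
#' reproducible from `seed`.
#'
#' @param x an `epoch_set` of training trials.
#' @param labels two-class factor per trial (default: trial `group`).
#' @param config an [sttcnet_config()].
#' @param prior a [prior_spec()]; default built from the epoch channels.
#' @param epochs maximum training epochs (default 60).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param val_frac fraction of trials held out for validation (default 0.2;
#'   0 disables early stopping).
#' @param patience early-stopping patience in epochs (default 30).
#' @param clip global gradient-norm clip (default 1; `Inf` disables).
#' @param seed integer seed controlling initialization, the split, batch
#'   order and dropout.
#' @param verbose print per-epoch progress.
#' @return An object of class `"sttcnet"`: `params`, `config`, `prior`,
#'   `classes`, `scale` (per-channel standardization), `history` (per-epoch
#'   train/validation loss and accuracy), `mask`, `t_axis`, `channels`,
#'   `best_epoch`, `seed`.
#' @export
sttcnet <- function(x, labels = NULL, config = sttcnet_config(),
                    prior = NULL, epochs = 60, batch_size = 32, lr = 1e-3,
                    val_frac = 0.2, patience = 30, clip = 1,
                    seed = 1, verbose = FALSE) {
  stopifnot(inherits(x, "epoch_set"), inherits(config, "sttcnet_config"))
  if (is.null(labels)) labels <- x$meta$group
  f <- factor(labels)
  if (nlevels(f) < 2) stop("training data must contain both classes")
  if (nlevels(f) != config$n_classes)
    stop("number of classes does not match config$n_classes")
  if (is.null(prior)) prior <- prior_spec(x$channels)
  stopifnot(inherits(prior, "prior_spec"))
  miss <- setdiff(x$channels, names(prior$channel_weights))
  if (length(miss))
    stop("prior lacks weight(s) for channel(s): ", paste(miss, collapse = ", "))

  Tn <- dim(x$data)[3]; C <- dim(x$data)[2]; n <- n_trials(x)
  geom <- nn_geom(config, Tn)
  mask <- if (prior$mask_magnitude > 0)
    build_prior_mask(x$t_axis, prior$mask_window, prior$mask_magnitude)
  else NULL

  mu <- apply(x$data, 2, mean)
  sdv <- pmax(apply(x$data, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(x$data, 2, mu), 2, sdv, "/")
  y <- as.integer(f)

  set.seed(seed)
  params <- nn_init_params(config, C, geom,
                           prior$channel_weights[x$channels])
  st <- adam_init(params)

  if (val_frac > 0) {
    val_idx <- unlist(lapply(levels(f), function(lv) {
      idx <- which(f == lv)
      sample(idx, max(1L, round(val_frac * length(idx))))
    }))
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    tr_idx <- seq_len(n); val_idx <- integer(0)
  }
  if (length(unique(y[tr_idx])) < 2)
    stop("training split contains a single class")

  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad <- 0L
  for (e in seq_len(epochs)) {
    ord <- sample(tr_idx)
    tl <- 0; tn <- 0L; tacc <- 0L
    for (b0 in seq(1, length(ord), by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1, length(ord))]
      Xb <- Xs[bi, , , drop = FALSE]
      lg <- nn_loss_grads(params, Xb, y[bi], config, geom, mask,
                          training = TRUE)
      up <- adam_step(params, clip_grads(lg$grads, clip), st, lr)
      params <- up$params; st <- up$state
      tl <- tl + lg$loss * length(bi); tn <- tn + length(bi)
      tacc <- tacc + sum(max.col(lg$probs, ties.method = "first") == y[bi])
    }
    vl <- NA_real_; va <- NA_real_
    if (length(val_idx)) {
      ev <- nn_eval(params, Xs[val_idx, , , drop = FALSE], y[val_idx],
                    config, geom, mask)
      vl <- ev$loss; va <- ev$acc
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, epoch = e)
        bad <- 0L
      } else bad <- bad + 1L
    }
    hist[e, ] <- list(e, tl / tn, tacc / tn, vl, va)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f/%.3f  val %s/%s", e, tl / tn,
                      tacc / tn, format(vl, digits = 4),
                      format(va, digits = 3)))
    if (length(val_idx) && bad >= patience) break
  }
  if (length(val_idx) && is.finite(best$loss)) {
    params <- best$params
  } else best$epoch <- nrow(hist)

  structure(list(params = params, config = config, prior = prior,
                 classes = levels(f),
                 scale = list(mu = mu, sd = sdv),
                 history = hist, mask = mask, t_axis = x$t_axis,
                 channels = x$channels, best_epoch = best$epoch,
                 seed = seed),
            class = "sttcnet")
}

nn_eval <- function(params, Xs, y, cfg, geom, mask, chunk = 64L) {
  n <- dim(Xs)[1]
  loss <- 0; acc <- 0L
  for (b0 in seq(1, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1, n)
    fw <- nn_forward(params, Xs[bi, , , drop = FALSE], cfg, geom, mask,
                     training = FALSE)
    P <- softmax_rows(fw$logits)
    loss <- loss - sum(log(pmax(P[cbind(seq_along(bi), y[bi])], 1e-12)))
    acc <- acc + sum(max.col(P, ties.method = "first") == y[bi])
  }
  list(loss = loss / n, acc = acc / n)
}

#' @export
print.sttcnet <- function(x, ...) {
  cfg <- x$config
  cat("P300-STTCNet: ", cfg$n_layers, "-layer encoder (d=", cfg$d_model,
      ", heads=", cfg$n_heads, "), CNN head ", cfg$conv1_filters, "/",
      cfg$conv2_filters, " filters\n", sep = "")
  cat("  classes: ", paste(x$classes, collapse = " vs "),
      " | channels: ", length(x$channels),
      " | tokens: ", length(x$t_axis), "\n", sep = "")
  cat("  prior: lambda=", x$prior$mask_magnitude, " on [",
      x$prior$mask_window[1], ", ", x$prior$mask_window[2], "] ms; ",
      "trained ", nrow(x$history), " epoch(s), best ", x$best_epoch,
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.sttcnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "cross-entropy loss",
                    main = "Training curves", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Predict from a fitted P300-STTCNet
#'
#' @param object a fitted `"sttcnet"` model.
#' @param newdata an `epoch_set` with the channels and time axis the model
#'   was trained on.
#' @param type `"class"`, `"prob"` or `"logit"`.
#' @param subject_vote if `TRUE` (with `type = "class"`), aggregate
#'   trial-level predictions to one majority-vote label per subject.
#' @param ... unused.
#' @return factor of classes, probability matrix, or logit matrix; with
#'   `subject_vote`, a named factor keyed by subject.
#' @export
predict.sttcnet <- function(object, newdata, type = c("class", "prob", "logit"),
                            subject_vote = FALSE, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "epoch_set"))
  if (!identical(newdata$channels, object$channels))
    stop("channel set differs from the training data")
  if (length(newdata$t_axis) != length(object$t_axis))
    stop("epoch length differs from the training data")
  Xs <- sweep(sweep(newdata$data, 2, object$scale$mu), 2, object$scale$sd, "/")
  geom <- nn_geom(object$config, length(object$t_axis))
  n <- dim(Xs)[1]
  logits <- matrix(0, n, object$config$n_classes)
  for (b0 in seq(1, n, by = 64L)) {
    bi <- b0:min(b0 + 63L, n)
    logits[bi, ] <- nn_forward(object$params, Xs[bi, , , drop = FALSE],
                               object$config, geom, object$mask,
                               training = FALSE)$logits
  }
  colnames(logits) <- object$classes
  if (type == "logit") return(logits)
  P <- softmax_rows(logits)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  cls <- factor(object$classes[max.col(P, ties.method = "first")], levels = object$classes)
  if (subject_vote) {
    sv <- tapply(as.character(cls), newdata$meta$subject_id, function(z) {
      tb <- sort(table(z), decreasing = TRUE)
      names(tb)[1]
    })
    return(factor(sv, levels = object$classes))
  }
  cls
}

#' Save / load a fitted network
#'
#' RDS checkpoint plus optional CSV export of the training curves and a JSON
#' export of configuration and prior.
#'
#' @param model a `"sttcnet"` object.
#' @param path output `.rds` path.
#' @param curve_csv optional CSV path for the per-epoch history.
#' @param json optional JSON path for config + prior.
#' @return `path`, invisibly.
#' @export
save_sttcnet <- function(model, path, curve_csv = NULL, json = NULL) {
  stopifnot(inherits(model, "sttcnet"))
  saveRDS(model, path)
  if (!is.null(curve_csv))
    utils::write.csv(model$history, curve_csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(config = unclass(model$config),
                              prior = list(
                                channel_weights =
                                  as.list(model$prior$channel_weights),
                                mask_window = model$prior$mask_window,
                                mask_magnitude = model$prior$mask_magnitude),
                              classes = model$classes,
                              best_epoch = model$best_epoch),
                         json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_sttcnet
#' @export
load_sttcnet <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "sttcnet"))
  m
}
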