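test_that("channel prior weighting scales channels and validates coverage", {
  set.seed(31)
  ep <- mk_noise_epochs(2, C = 3, Tn = 6)
  w <- c(ch1 = 1, ch2 = 1, ch3 = 1)
  expect_equal(apply_channel_prior(ep, w)$data, ep$data)
  w2 <- c(ch1 = 2, ch2 = 0, ch3 = 1)
  out <- apply_channel_prior(ep, w2)
  expect_equal(out$data[, 2, ], ep$data[, 2, ] * 0)
  expect_equal(out$data[, 1, ], ep$data[, 1, ] * 2)
  expect_error(apply_channel_prior(ep, c(ch1 = 1)), "missing channel")
})

test_that("prior mask biases exactly the keys inside the closed window", {
  t_axis <- seq(-100, by = 4, length.out = 175)
  M <- build_prior_mask(t_axis, c(250, 450), 1.5)
  expect_equal(dim(M), c(175L, 175L))
  key_cols <- which(colSums(M) > 0)
  expect_length(key_cols, 50L)                      # 252..448 ms at 4 ms
  expect_true(all(t_axis[key_cols] >= 250 & t_axis[key_cols] <= 450))
  expect_true(all(M[, key_cols] == 1.5))
  expect_true(all(M[, -key_cols] == 0))
  expect_equal(build_prior_mask(t_axis, lambda = 0), matrix(0, 175, 175))
  expect_error(build_prior_mask(t_axis, c(900, 1000), 1), "does not intersect")
})

test_that("masked attention matches scalar and loop oracles", {
  # zero queries/keys: uniform weights, output = column means of V
  V <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2)
  at <- masked_attention(matrix(0, 3, 2), matrix(0, 3, 2), V)
  expect_equal(at$weights, matrix(1 / 3, 3, 3))
  expect_equal(at$output, matrix(rep(colMeans(V), each = 3), 3, 2))
  # 2-token scalar oracle
  Q <- matrix(c(1, -1)); K <- matrix(c(2, 0.5)); Vv <- matrix(c(10, 20))
  at2 <- masked_attention(Q, K, Vv)
  l11 <- 1 * 2; l12 <- 1 * 0.5                      # d_k = 1, no scaling /1
  a11 <- exp(l11) / (exp(l11) + exp(l12))
  expect_equal(at2$output[1, 1], a11 * 10 + (1 - a11) * 20)
  # vectorized equals the explicit triple loop within 1e-6
  set.seed(32)
  n <- 7; dk <- 3
  Q <- matrix(rnorm(n * dk), n); K <- matrix(rnorm(n * dk), n)
  V2 <- matrix(rnorm(n * dk), n)
  mask <- matrix(rnorm(n * n), n)
  ref <- matrix(0, n, dk)
  for (i in 1:n) {
    lg <- numeric(n)
    for (j in 1:n) {
      for (m in 1:dk) lg[j] <- lg[j] + Q[i, m] * K[j, m]
      lg[j] <- lg[j] / sqrt(dk) + mask[i, j]
    }
    a <- exp(lg - max(lg)); a <- a / sum(a)
    for (j in 1:n) ref[i, ] <- ref[i, ] + a[j] * V2[j, ]
  }
  at3 <- masked_attention(Q, K, V2, mask)
  expect_equal(at3$output, ref, tolerance = 1e-6)
  expect_equal(rowSums(at3$weights), rep(1, n), tolerance = 1e-12)
})

test_that("constant and zero masks leave attention unchanged", {
  set.seed(33)
  n <- 6; dk <- 2
  Q <- matrix(rnorm(n * dk), n); K <- matrix(rnorm(n * dk), n)
  V <- matrix(rnorm(n * dk), n)
  plain <- masked_attention(Q, K, V)
  zero <- masked_attention(Q, K, V, matrix(0, n, n))
  const <- masked_attention(Q, K, V, matrix(3.7, n, n))
  expect_equal(zero$output, plain$output)
  expect_equal(const$output, plain$output, tolerance = 1e-12)
})

test_that("multi-head attention equals the per-head loop and shapes hold", {
  set.seed(34)
  n <- 9; d <- 8; h <- 2
  S <- matrix(rnorm(n * d), n)
  Wq <- matrix(rnorm(d * d), d); Wk <- matrix(rnorm(d * d), d)
  Wv <- matrix(rnorm(d * d), d); Wo <- matrix(rnorm(d * d), d)
  mask <- matrix(runif(n * n), n)
  out <- multi_head(S, Wq, Wk, Wv, Wo, h, mask)
  expect_equal(dim(out), c(n, d))
  # loop-over-heads reference
  Q <- S %*% Wq; K <- S %*% Wk; V <- S %*% Wv
  H <- matrix(0, n, d)
  for (hh in 1:h) {
    cj <- ((hh - 1) * 4 + 1):(hh * 4)
    H[, cj] <- masked_attention(Q[, cj], K[, cj], V[, cj], mask)$output
  }
  expect_equal(unclass(out), H %*% Wo, ignore_attr = TRUE)
  # single head equals masked attention composed with Wo
  out1 <- multi_head(S, Wq, Wk, Wv, Wo, 1, mask)
  ref1 <- masked_attention(S %*% Wq, S %*% Wk, S %*% Wv, mask)$output %*% Wo
  expect_equal(unclass(out1), ref1, ignore_attr = TRUE)
  expect_error(multi_head(S, Wq, Wk, Wv, Wo, 3), "divisible")
})

test_that("encoder with zeroed sublayer outputs reduces to layer-normed input", {
  set.seed(35)
  cfg <- tiny_net_config()
  Tn <- 20
  geom <- p300sttc:::nn_geom(cfg, Tn)
  params <- p300sttc:::nn_init_params(cfg, 4, geom, rep(1, 4))
  params$enc1_Wo[] <- 0; params$enc1_bo[] <- 0
  params$enc1_W2[] <- 0; params$enc1_b2[] <- 0
  S <- matrix(rnorm(Tn * cfg$d_model), Tn)
  out <- encoder_forward(S, params, cfg)
  ln <- p300sttc:::ln_forward(S, rep(1, cfg$d_model),
                              rep(0, cfg$d_model))$out
  expect_equal(out, ln, tolerance = 1e-4)   # up to the layer-norm epsilon
  # deterministic in eval mode
  expect_identical(out, encoder_forward(S, params, cfg))
})

test_that("attention mass in the prior window increases strictly with lambda", {
  set.seed(36)
  t_axis <- seq(-100, by = 4, length.out = 60)
  n <- length(t_axis)
  Q <- matrix(rnorm(n * 4), n); K <- matrix(rnorm(n * 4), n)
  V <- matrix(rnorm(n * 4), n)
  key <- t_axis >= 100 & t_axis <= 130
  mass <- vapply(c(0, 0.5, 1, 2, 4), function(lam) {
    A <- masked_attention(Q, K, V, build_prior_mask(t_axis, c(100, 130),
                                                    lam))$weights
    mean(rowSums(A[, key, drop = FALSE]))
  }, 0)
  expect_true(all(diff(mass) > 0))
})

test_that("valid 3x3 convolution matches a sliding-window oracle on a 5x5 toy", {
  set.seed(37)
  img <- matrix(rnorm(25), 5, 5)
  Kmat <- matrix(rnorm(9 * 2), 9, 2)
  bias <- c(0.3, -0.1)
  out <- conv2d(img, Kmat, bias)
  expect_equal(dim(out), c(3L, 3L, 2L))
  for (co in 1:2) {
    Kk <- matrix(Kmat[, co], 3, 3)     # (dh, dw) column-major
    for (i in 1:3) for (j in 1:3) {
      patch <- img[i:(i + 2), j:(j + 2)]
      expect_equal(out[i, j, co], sum(patch * Kk) + bias[co])
    }
  }
})

test_that("CNN head emits two logits and zero input yields the biases", {
  set.seed(38)
  cfg <- tiny_net_config()
  Tn <- 20
  geom <- p300sttc:::nn_geom(cfg, Tn)
  params <- p300sttc:::nn_init_params(cfg, 4, geom, rep(1, 4))
  rep0 <- matrix(0, Tn, cfg$d_model)
  lg0 <- cnn_head(rep0, params, cfg)
  expect_length(lg0, 2L)
  # zero input -> conv outputs = conv biases (zero-initialized) -> MLP biases
  h <- pmax(params$mlp_b1, 0)
  expect_equal(lg0, drop(h %*% params$mlp_W2 + params$mlp_b2))
  expect_error(p300sttc:::nn_geom(cfg, 5), "too small")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(39)
  cfg <- tiny_net_config(n_layers = 2)
  Tn <- 20; C <- 4; B <- 3
  geom <- p300sttc:::nn_geom(cfg, Tn)
  params <- p300sttc:::nn_init_params(cfg, C, geom, c(1.5, 1.5, 1, 1))
  X <- array(rnorm(B * C * Tn), c(B, C, Tn))
  y <- c(1L, 2L, 1L)
  t_axis <- seq(0, by = 4, length.out = Tn)
  mask <- build_prior_mask(t_axis, c(20, 40), 0.8)
  lg <- p300sttc:::nn_loss_grads(params, X, y, cfg, geom, mask)
  num_grad <- function(nm, idx, eps = 1e-5) {
    p1 <- params; p1[[nm]][idx] <- p1[[nm]][idx] + eps
    p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] - eps
    (p300sttc:::nn_loss_grads(p1, X, y, cfg, geom, mask)$loss -
       p300sttc:::nn_loss_grads(p2, X, y, cfg, geom, mask)$loss) / (2 * eps)
  }
  check <- c("chan_w", "emb_W", "enc1_Wq", "enc1_Wv", "enc2_Wo", "enc1_W1",
             "enc2_ln1_g", "conv1_K", "conv2_K", "mlp_W1", "mlp_W2")
  set.seed(40)
  for (nm in check) {
    for (k in 1:2) {
      idx <- sample(length(params[[nm]]), 1)
      a <- lg$grads[[nm]][idx]
      n <- num_grad(nm, idx)
      expect_equal(a, n, tolerance = 1e-4 * max(1, abs(n)),
                   label = paste("grad", nm))
    }
  }
})

test_that("training is deterministic, learns separable data, and exposes priors", {
  set.seed(41)
  Tn <- 24; C <- 4
  t_axis <- seq(-100, by = 25, length.out = Tn)
  n <- 20
  dat <- array(rnorm(n * C * Tn, sd = 0.5), c(n, C, Tn))
  grp <- rep(c("P", "H"), each = 10)
  for (i in which(grp == "P"))
    dat[i, 2, ] <- dat[i, 2, ] + 6 * exp(-(t_axis - 200)^2 / (2 * 80^2))
  ep <- epoch_set(dat, paste0("ch", 1:C), 40, t_axis,
                  data.frame(subject_id = rep(c("A", "B"), 10), group = grp,
                             stimulus_code = "target", trial_index = 1:n))
  cfg <- tiny_net_config(n_layers = 2, dropout = 0.1)
  pr <- prior_spec(ep$channels, prioritized = "ch2", mask_window = c(100, 300))
  net <- sttcnet(ep, config = cfg, prior = pr, epochs = 120, batch_size = 10,
                 val_frac = 0, lr = 2e-3, seed = 7)
  expect_equal(mean(predict(net, ep) == grp), 1)          # 100% on 20 trials
  expect_lt(tail(net$history$train_loss, 1), 0.1)
  # same seed reproduces identical final weights
  net2 <- sttcnet(ep, config = cfg, prior = pr, epochs = 120, batch_size = 10,
                  val_frac = 0, lr = 2e-3, seed = 7)
  expect_identical(net$params, net2$params)
  # probabilities are a proper softmax over the two classes
  p <- predict(net, ep, type = "prob")
  expect_equal(rowSums(p), rep(1, n))
  # subject-level majority vote returns one label per subject
  sv <- predict(net, ep, subject_vote = TRUE)
  expect_length(sv, 2L)
  # single-class training data is rejected
  expect_error(sttcnet(subset_epochs(ep, grp == "P"), config = cfg),
               "both classes")
})

test_that("lambda = 0 with unit channel weights is a plain transformer-CNN", {
  set.seed(42)
  cfg <- tiny_net_config()
  Tn <- 20; C <- 3
  geom <- p300sttc:::nn_geom(cfg, Tn)
  params <- p300sttc:::nn_init_params(cfg, C, geom, rep(1, C))
  X <- array(rnorm(2 * C * Tn), c(2, C, Tn))
  t_axis <- seq(0, by = 4, length.out = Tn)
  f_none <- p300sttc:::nn_forward(params, X, cfg, geom, mask = NULL)
  f_zero <- p300sttc:::nn_forward(params, X, cfg, geom,
                                  mask = build_prior_mask(t_axis, c(20, 40), 0))
  expect_equal(f_none$logits, f_zero$logits)
  # a positive lambda changes the computation
  f_pos <- p300sttc:::nn_forward(params, X, cfg, geom,
                                 mask = build_prior_mask(t_axis, c(20, 40), 2))
  expect_false(isTRUE(all.equal(f_none$logits, f_pos$logits)))
})

test_that("network checkpoints round-trip with training curves", {
  set.seed(43)
  ep <- mk_noise_epochs(6, C = 4, Tn = 20, sfreq = 50)
  cfg <- tiny_net_config()
  net <- sttcnet(ep, config = cfg, epochs = 2, batch_size = 6, val_frac = 0.3,
                 seed = 1)
  f <- tempfile(fileext = ".rds"); fc <- tempfile(fileext = ".csv")
  fj <- tempfile(fileext = ".json")
  save_sttcnet(net, f, curve_csv = fc, json = fj)
  back <- load_sttcnet(f)
  expect_identical(back$params, net$params)
  curve <- utils::read.csv(fc)
  expect_named(curve, c("epoch", "train_loss", "train_acc",
                        "val_loss", "val_acc"))
  unlink(c(f, fc, fj))
})
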