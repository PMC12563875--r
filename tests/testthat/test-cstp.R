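test_that("class covariances match an explicit per-trial loop oracle", {
  set.seed(11)
  ep <- mk_noise_epochs(3, C = 3, Tn = 8)
  V <- matrix(rnorm(8 * 2), 8, 2)
  W <- matrix(rnorm(3 * 2), 3, 2)
  for (norm in c("trial", "projected")) {
    S <- class_covariances(ep, projector = V, domain = "spatial",
                           normalize = norm)
    R <- class_covariances(ep, projector = W, domain = "temporal",
                           normalize = norm)
    f <- factor(ep$meta$group)
    for (lv in levels(f)) {
      accS <- 0; accR <- 0
      for (i in which(f == lv)) {
        X <- ep$data[i, , ]
        Zs <- X %*% V
        Zt <- t(X) %*% W %*% t(W) %*% X
        ns <- if (norm == "projected") sum(diag(Zs %*% t(Zs))) else sum(X^2)
        nt <- if (norm == "projected") sum(diag(Zt)) else sum(X^2)
        accS <- accS + (Zs %*% t(Zs)) / ns
        accR <- accR + Zt / nt
      }
      expect_equal(S[[lv]], accS / 3, tolerance = 1e-12)
      expect_equal(R[[lv]], accR / 3, tolerance = 1e-12)
    }
    # symmetric PSD
    expect_equal(S[[1]], t(S[[1]]))
    expect_gte(min(eigen(S[[1]], symmetric = TRUE)$values), -1e-12)
  }
})

test_that("covariance normalization and duplication behave as stated", {
  set.seed(12)
  ep <- mk_noise_epochs(2, C = 3, Tn = 6)
  # unprojected: trial and projected normalizers coincide, trace 1 per trial
  S <- class_covariances(ep, domain = "spatial")
  Sp <- class_covariances(ep, domain = "spatial", normalize = "projected")
  expect_equal(S, Sp)
  expect_equal(sum(diag(S[[1]])), 1)
  # duplicated trials leave the average unchanged
  ep2 <- combine_epochs(ep, ep)
  expect_equal(class_covariances(ep2, domain = "spatial")[[1]], S[[1]])
  # degenerate inputs
  epz <- ep; epz$data[1, , ] <- 0
  expect_error(class_covariances(epz, domain = "spatial"), "zero")
  expect_error(class_covariances(subset_epochs(ep, c(1, 3)),
                                 labels = c("A", "B")), "at least 2")
})

test_that("identical classes give J = 1 and generalized eigenvalues 1/2", {
  set.seed(13)
  dat <- array(rnorm(12 * 3 * 10), c(12, 3, 10))
  dat[7:12, , ] <- dat[1:6, , ]       # class B duplicates class A
  ep <- epoch_set(dat, paste0("c", 1:3), 250, seq(0, by = 4, length.out = 10),
                  data.frame(subject_id = "S1",
                             group = rep(c("A", "B"), each = 6),
                             stimulus_code = "target", trial_index = 1:12))
  fit <- cstp(ep, m_filters = 2, k_filters = 3, n_init = 1)
  expect_equal(fit$objective, 1, tolerance = 1e-9)
  expect_equal(unname(fit$lambda_spatial), rep(0.5, 2), tolerance = 1e-4)
})

test_that("a planted high-variance spatial direction is recovered", {
  set.seed(14)
  th <- pi / 5; u <- c(cos(th), sin(th))
  n <- 30; Tn <- 40
  dat <- array(0, c(2 * n, 2, Tn))
  for (i in 1:n)
    dat[i, , ] <- matrix(rnorm(2 * Tn), 2, Tn) + 3 * u %o% rnorm(Tn)
  for (i in (n + 1):(2 * n)) dat[i, , ] <- matrix(rnorm(2 * Tn), 2, Tn)
  ep <- epoch_set(dat, c("c1", "c2"), 250, seq(0, by = 4, length.out = Tn),
                  data.frame(subject_id = "S1",
                             group = rep(c("A", "B"), each = n),
                             stimulus_code = "target",
                             trial_index = seq_len(2 * n)))
  fit <- cstp(ep, m_filters = 1, k_filters = 2)
  w <- fit$W[, 1] / sqrt(sum(fit$W[, 1]^2))
  angle <- acos(min(1, abs(sum(w * u)))) * 180 / pi
  expect_lt(angle, 5)
})

test_that("objective trace is non-decreasing and class swap reciprocates", {
  set.seed(15)
  ep <- mk_erp_epochs(8, C = 4, noise_sd = 2)
  fit <- cstp(ep, m_filters = 2, k_filters = 2)
  expect_true(all(diff(fit$objective_trace) >= -1e-9))
  # swapping class labels inverts the objective direction: the swapped top
  # spatial eigenvalue equals 1 minus the original bottom eigenvalue
  swapped <- ifelse(ep$meta$group == "HC", "PTSD", "HC")
  fit2 <- cstp(ep, labels = swapped, m_filters = 2, k_filters = 2)
  expect_gt(fit$objective, 1)
  expect_lt(1 / fit2$objective, fit$objective * 1.05)
})

test_that("projection obeys Z = W'XV with bilinearity", {
  set.seed(16)
  ep <- mk_noise_epochs(2, C = 3, Tn = 5)
  fit <- list(W = diag(3), V = diag(5))
  class(fit) <- "cstp"
  expect_equal(cstp_project(fit, ep)[1, , ], ep$data[1, , ])
  # rank-1 filters give the scalar w'Xv
  w <- rnorm(3); v <- rnorm(5)
  f1 <- structure(list(W = matrix(w), V = matrix(v)), class = "cstp")
  expect_equal(drop(cstp_project(f1, ep)[2, , ]),
               drop(t(w) %*% ep$data[2, , ] %*% v))
  # bilinearity in the data
  epsum <- ep; epsum$data <- ep$data + ep$data[c(2, 1, 3, 4), , ]
  expect_equal(cstp_project(f1, epsum),
               cstp_project(f1, ep) +
                 cstp_project(f1, subset_epochs(ep, c(2, 1, 3, 4))))
  # shape mismatch
  bad <- structure(list(W = matrix(rnorm(8), 4, 2), V = diag(5)),
                   class = "cstp")
  expect_error(cstp_project(bad, ep), "do not match")
})

test_that("log-variance features satisfy the normalization identities", {
  set.seed(17)
  ep <- mk_noise_epochs(6, C = 4, Tn = 12)
  fit <- cstp(ep, m_filters = 3, k_filters = 4, n_init = 1)
  ft <- cstp_features(fit, ep)
  expect_equal(dim(ft$features), c(12L, 7L))
  expect_true(all(ft$features <= 0))
  expect_equal(rowSums(exp(ft$features[, 1:3])), rep(1, 12), tolerance = 1e-8)
  expect_equal(rowSums(exp(ft$features[, 4:7])), rep(1, 12), tolerance = 1e-8)
  # loop oracle for one trial
  Z <- cstp_project(fit, ep)[5, , ]
  rv <- apply(Z, 1, var); cv <- apply(Z, 2, var)
  expect_equal(unname(ft$features[5, ]),
               c(log(rv / sum(rv)), log(cv / sum(cv))))
  # equal row variances give log(1/M) in every spatial feature
  epc <- subset_epochs(ep, 1:4)
  fitI <- structure(list(W = diag(4)[, 1:2], V = diag(12)[, 1:2]),
                    class = "cstp")
  epc$data[1, , ] <- 0; epc$data[1, 1, 1:12] <- rep(c(-1, 1), 6)
  epc$data[1, 2, 1:12] <- rep(c(1, -1), 6)
  f2 <- cstp_features(fitI, subset_epochs(epc, 1))
  expect_equal(unname(f2$features[1, 1:2]), rep(log(0.5), 2))
})

test_that("PCA projection reports sane explained-variance ratios", {
  set.seed(18)
  X <- matrix(rnorm(4000), 2000, 2)   # isotropic
  p <- pca_project(X, 2)
  expect_equal(p$explained_variance_ratio, c(0.5, 0.5), tolerance = 0.05)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  # exactly collinear data: first ratio 1, truncation warns
  Xc <- cbind(1:20, 2 * (1:20))
  expect_warning(pc <- pca_project(Xc, 2), "rank")
  expect_equal(pc$explained_variance_ratio[1], 1)
  # full-rank reconstruction
  X3 <- matrix(rnorm(60), 20, 3)
  p3 <- pca_project(X3, 3)
  rec <- p3$scores %*% t(p3$rotation) + rep(p3$center, each = 20)
  expect_equal(rec, X3, ignore_attr = TRUE)
  expect_error(pca_project(X3[1, , drop = FALSE]), "2 samples")
})

test_that("CSTP features separate classes better than raw epochs (silhouette)", {
  set.seed(19)
  ep <- mk_erp_epochs(15, C = 10, noise_sd = 3, subjects_per_group = 5)
  fit <- cstp(ep, m_filters = 4, k_filters = 4, n_init = 1)
  ft <- cstp_features(fit, ep)$features
  sil <- function(X, g) {
    # mean silhouette over samples with euclidean distances
    D <- as.matrix(dist(X))
    s <- vapply(seq_len(nrow(X)), function(i) {
      a <- mean(D[i, g == g[i]][-match(i, which(g == g[i]))])
      b <- mean(D[i, g != g[i]])
      (b - a) / max(a, b)
    }, 0)
    mean(s)
  }
  g <- ep$meta$group
  sil_cstp <- sil(pca_project(ft, 2)$scores, g)
  sil_raw <- sil(pca_project(flatten_epochs(ep), 2)$scores, g)
  expect_gt(sil_cstp, sil_raw)
})

test_that("CSTP models round-trip through save/load", {
  set.seed(20)
  ep <- mk_noise_epochs(4, C = 3, Tn = 8)
  fit <- cstp(ep, m_filters = 2, k_filters = 2, n_init = 1)
  f <- tempfile(fileext = ".rds"); fj <- tempfile(fileext = ".json")
  save_cstp(fit, f, json = fj)
  back <- load_cstp(f)
  expect_equal(back$W, fit$W)
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(dim(j$W), dim(fit$W))
  unlink(c(f, fj))
})
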