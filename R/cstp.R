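# ---- common spatiotemporal pattern (CSTP) filtering -----------------------

# shrinkage-regularized symmetric matrix, gamma on the scaled identity
shrink_cov <- function(S, gamma) {
  p <- nrow(S)
  (1 - gamma) * S + gamma * (sum(diag(S)) / p) * diag(p)
}

# fix eigenvector sign: largest-magnitude entry positive
fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

#' Trace-normalized per-class covariance matrices
#'
#' For every trial `X` (channels x time) the spatial covariance is the
#' trace-normalized `Z Z'` with `Z = X V` (or `Z = X` when no temporal
#' projector is given), averaged over the trials of each class. The temporal
#' covariance is computed analogously on `(W' X)' (W' X)`, i.e.
#' `X' W W' X / tr(.)`. Two per-trial normalizers are available:
#' `"trial"` divides by the raw trial energy `tr(X X')` and `"projected"`
#' divides by the projected energy `tr(Z Z')`. Both make the estimates
#' invariant to per-trial amplitude scale and coincide when no projector is
#' given; the model fit uses `"trial"`, under which the spatial and temporal
#' eigen-steps provably ascend one shared objective (see the methods
#' vignette).
#'
#' @param ep an `epoch_set`.
#' @param labels two-class factor (or coercible), one entry per trial;
#'   defaults to the trial `group` metadata.
#' @param projector optional projector matrix: temporal filters `V`
#'   (time x K) for `domain = "spatial"`, spatial filters `W` (channels x M)
#'   for `domain = "temporal"`.
#' @param domain `"spatial"` (channels x channels output) or `"temporal"`
#'   (time x time output).
#' @param normalize per-trial normalizer, `"trial"` (default) or
#'   `"projected"`.
#' @return a named list with one symmetric PSD matrix per class, in factor
#'   level order.
#' @export
class_covariances <- function(ep, labels = NULL, projector = NULL,
                              domain = c("spatial", "temporal"),
                              normalize = c("trial", "projected")) {
  domain <- match.arg(domain)
  normalize <- match.arg(normalize)
  stopifnot(inherits(ep, "epoch_set"))
  if (is.null(labels)) labels <- ep$meta$group
  f <- factor(labels)
  if (nlevels(f) != 2) stop("exactly two classes are required")
  if (any(table(f) < 2)) stop("each class needs at least 2 trials")
  out <- list()
  for (lv in levels(f)) {
    idx <- which(f == lv)
    acc <- NULL
    for (i in idx) {
      X <- ep$data[i, , ]
      S <- if (domain == "spatial") {
        Z <- if (is.null(projector)) X else X %*% projector
        tcrossprod(Z)
      } else {
        Y <- if (is.null(projector)) t(X) else crossprod(X, projector)
        tcrossprod(Y)
      }
      tr <- if (normalize == "projected") sum(diag(S)) else sum(X * X)
      if (tr < .Machine$double.eps)
        stop("all-zero trial encountered (zero trace) at trial ", i)
      acc <- if (is.null(acc)) S / tr else acc + S / tr
    }
    acc <- acc / length(idx)
    out[[lv]] <- (acc + t(acc)) / 2
  }
  out
}

# generalized eigenproblem S1 w = lambda (S1 + S2) w, solved by whitening
# within the span of (S1 + S2): null-space directions (where neither class
# has variance, common when trials x filters < matrix dimension) are
# excluded, so the small-eigenvalue filters are genuine class-2-dominant
# directions rather than shrinkage artifacts that explode on unseen data.
# Returns the m filters from both ends of the in-span spectrum (CSP
# convention: ceiling(m/2) largest, floor(m/2) smallest eigenvalues).
gev_filters <- function(S1, S2, m, gamma = 1e-6) {
  St <- S1 + S2
  eS <- eigen((St + t(St)) / 2, symmetric = TRUE)
  # rank decided on the raw spectrum (shrinkage would lift the null space
  # above any fixed threshold); ridge applied within the span only
  r <- sum(eS$values > max(eS$values) * 1e-9)
  if (m > r)
    stop("requested ", m, " filters but the composite covariance has rank ",
         r)
  ridge <- gamma * max(eS$values)
  Wh <- eS$vectors[, seq_len(r), drop = FALSE] *
    rep(1 / sqrt(eS$values[seq_len(r)] + ridge), each = nrow(St))
  M <- crossprod(Wh, S1) %*% Wh
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)                # eigenvalues descending
  n_hi <- ceiling(m / 2)
  n_lo <- m - n_hi
  sel <- c(seq_len(n_hi), if (n_lo > 0) seq.int(r - n_lo + 1, r))
  W <- Wh %*% e$vectors[, sel, drop = FALSE]
  list(W = fix_signs(W), lambda = e$values[sel], all_lambda = e$values)
}

# trace-ratio objective J = tr(W' S1(V) W) / tr(W' S2(V) W)
cstp_objective <- function(ep, f, W, V) {
  S <- class_covariances(ep, f, projector = V, domain = "spatial")
  num <- sum(diag(crossprod(W, S[[1]]) %*% W))
  den <- sum(diag(crossprod(W, S[[2]]) %*% W))
  num / den
}

#' Fit common spatiotemporal pattern filters
#'
#' Learns spatial filters `W` (channels x M) and temporal filters `V`
#' (time x K) that maximize the between-class ratio of projected
#' spatiotemporal variance by alternating generalized eigendecompositions:
#' given `V`, solve `Sigma1(V) w = lambda (Sigma1(V) + Sigma2(V)) w` and keep
#' the eigenvectors from both ends of the spectrum (variance increases for
#' either class); given `W`, solve the analogous temporal problem for `V`.
#' `V` is initialized from the leading eigenvectors of `R1 + R2`; additional
#' random restarts guard against local optima of the alternating scheme. The
#' recorded objective `J = tr(W' Sigma1(V) W) / tr(W' Sigma2(V) W)` is
#' non-decreasing along the returned trace: an update that would decrease it
#' terminates the iteration at the previous (best) iterate.
#'
#' @param ep an `epoch_set`.
#' @param labels two-class factor per trial (default: trial `group`).
#' @param m_filters,k_filters number of spatial / temporal filters
#'   (defaults 6 and 6).
#' @param max_iter maximum alternating iterations (default 50).
#' @param tol relative objective-change convergence tolerance (default 1e-6).
#' @param shrinkage covariance shrinkage weight toward the scaled identity
#'   (default 1e-6), for numerical stability of the whitening step.
#' @param n_init number of initializations: three deterministic candidates
#'   (leading eigenvectors of `R1 + R2`; discriminative generalized
#'   eigenvectors of the unprojected temporal problem, from either end of
#'   the spectrum) plus random orthonormal restarts beyond 3 (default 3).
#' @param seed seed for the random restarts.
#' @return An object of class `"cstp"` with elements `W`, `V`, `sigma` and
#'   `r` (per-class spatial / temporal covariances at the solution),
#'   `lambda_spatial`, `lambda_temporal`, `objective_trace`, `objective`,
#'   `converged`, `classes`, plus the fitted dimensions.
#' @examples
#' ep <- epoch_set(array(rnorm(20 * 3 * 16), c(20, 3, 16)),
#'                 c("A", "B", "C"), 250, seq(0, 60, by = 4),
#'                 data.frame(subject_id = "S1",
#'                            group = rep(c("HC", "PTSD"), each = 10),
#'                            stimulus_code = "target", trial_index = 1:20))
#' fit <- cstp(ep, m_filters = 2, k_filters = 2)
#' fit$objective
#' @export
cstp <- function(ep, labels = NULL, m_filters = 6, k_filters = 6,
                 max_iter = 50, tol = 1e-6, shrinkage = 1e-6,
                 n_init = 3, seed = 1) {
  stopifnot(inherits(ep, "epoch_set"))
  if (is.null(labels)) labels <- ep$meta$group
  f <- factor(labels)
  if (nlevels(f) != 2) stop("exactly two classes are required")
  C <- dim(ep$data)[2]; Tn <- dim(ep$data)[3]
  if (m_filters > C) stop("m_filters may not exceed the channel count")
  if (k_filters > Tn) stop("k_filters may not exceed the sample count")

  R0 <- class_covariances(ep, f, projector = NULL, domain = "temporal")
  Rsum <- R0[[1]] + R0[[2]]
  eR <- eigen((Rsum + t(Rsum)) / 2, symmetric = TRUE)
  # initialization candidates: leading eigenvectors of R1+R2, then the
  # discriminative generalized eigenvectors of (R1, R1+R2) from either end
  # of the spectrum, then random orthonormal restarts
  gR <- gev_filters(R0[[1]], R0[[2]], k_filters, shrinkage)
  gRlo <- gev_filters(R0[[2]], R0[[1]], k_filters, shrinkage)
  inits <- list(eR$vectors[, seq_len(k_filters), drop = FALSE],
                gR$W, gRlo$W)

  set.seed(seed)
  best <- NULL
  for (init in seq_len(max(n_init, length(inits)))) {
    V <- if (init <= length(inits)) {
      inits[[init]]
    } else {
      qr.Q(qr(matrix(stats::rnorm(Tn * k_filters), Tn, k_filters)))
    }
    W <- NULL
    J_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    lam_s <- lam_t <- NULL
    for (it in seq_len(max_iter)) {
      # spatial step given V, then evaluate J at (W_new, V); an update that
      # would lower the recorded objective terminates at the previous iterate
      Sv <- class_covariances(ep, f, projector = V, domain = "spatial")
      gs <- gev_filters(Sv[[1]], Sv[[2]], m_filters, shrinkage)
      J <- cstp_objective(ep, f, gs$W, V)
      if (J < J_prev - 1e-9 * max(1, abs(J_prev))) {
        V <- V_acc                                  # keep best iterate
        break
      }
      W <- gs$W
      V_acc <- V
      lam_s <- gs$lambda
      trace <- c(trace, J)
      if (is.finite(J_prev) &&
          abs(J - J_prev) < tol * max(1, abs(J_prev))) {
        converged <- TRUE
        J_prev <- J
        break
      }
      J_prev <- J
      # temporal step given W
      Rw <- class_covariances(ep, f, projector = W, domain = "temporal")
      gt <- gev_filters(Rw[[1]], Rw[[2]], k_filters, shrinkage)
      V <- gt$W
      lam_t <- gt$lambda
    }
    if (is.null(lam_t)) {
      Rw <- class_covariances(ep, f, projector = W, domain = "temporal")
      lam_t <- gev_filters(Rw[[1]], Rw[[2]], k_filters, shrinkage)$lambda
    }
    if (is.null(best) || J_prev > best$objective) {
      best <- list(W = W, V = V, objective = J_prev, trace = trace,
                   converged = converged, lambda_s = lam_s, lambda_t = lam_t)
    }
  }

  W <- best$W; V <- best$V
  structure(list(W = W, V = V,
                 sigma = class_covariances(ep, f, V, "spatial"),
                 r = class_covariances(ep, f, W, "temporal"),
                 lambda_spatial = best$lambda_s,
                 lambda_temporal = best$lambda_t,
                 objective_trace = best$trace,
                 objective = best$objective,
                 converged = best$converged,
                 m_filters = m_filters, k_filters = k_filters,
                 classes = levels(f), channels = ep$channels,
                 t_axis = ep$t_axis, call = match.call()),
            class = "cstp")
}

#' @export
print.cstp <- function(x, ...) {
  cat("CSTP model: ", x$m_filters, " spatial x ", x$k_filters,
      " temporal filters (classes ", x$classes[1], " vs ", x$classes[2],
      ")\n", sep = "")
  cat("  objective J = ", format(x$objective, digits = 6),
      " after ", length(x$objective_trace), " iteration(s)",
      if (!x$converged) " [not converged]", "\n", sep = "")
  cat("  spatial eigenvalues: ",
      paste(format(x$lambda_spatial, digits = 3), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.cstp <- function(object, ...) list(W = object$W, V = object$V)

#' @export
plot.cstp <- function(x, ...) {
  graphics::plot(seq_along(x$objective_trace), x$objective_trace, type = "b",
                 xlab = "alternating iteration", ylab = "objective J",
                 main = "CSTP objective trace", ...)
  invisible(x)
}

#' Project epochs through fitted CSTP filters
#'
#' Applies `Z_i = W' X_i V` trial-wise.
#'
#' @param model a fitted [cstp()] model.
#' @param ep an `epoch_set` with matching channel and sample dimensions.
#' @return array `trials x M x K`.
#' @export
cstp_project <- function(model, ep) {
  stopifnot(inherits(model, "cstp"), inherits(ep, "epoch_set"))
  d <- dim(ep$data)
  if (d[2] != nrow(model$W) || d[3] != nrow(model$V))
    stop("epoch dimensions (", d[2], " x ", d[3],
         ") do not match the fitted filters (", nrow(model$W), " x ",
         nrow(model$V), ")")
  out <- array(0, c(d[1], ncol(model$W), ncol(model$V)))
  for (i in seq_len(d[1]))
    out[i, , ] <- crossprod(model$W, ep$data[i, , ]) %*% model$V
  out
}

#' Normalized log-variance features of projected epochs
#'
#' Per trial, the spatial block is
#' `f_space_m = log(var(Z[m, ]) / sum_m' var(Z[m', ]))` over the rows of the
#' projected matrix `Z = W' X V`, and the temporal block analogously over its
#' columns. By construction `sum_m exp(f_space_m) = 1` (and likewise for the
#' temporal block), and all features are <= 0.
#'
#' @param model a fitted [cstp()] model with `M >= 2` and `K >= 2`.
#' @param ep an `epoch_set`.
#' @return A list of class `"stfeatures"`: `features` (trials x (M+K) matrix
#'   with columns `space1..spaceM, time1..timeK`), `m`, `k`, and the trial
#'   `meta` carried over.
#' @export
cstp_features <- function(model, ep) {
  Z <- cstp_project(model, ep)
  M <- dim(Z)[2]; K <- dim(Z)[3]
  if (M < 2 || K < 2)
    stop("log-variance features need at least 2 spatial and 2 temporal filters")
  n <- dim(Z)[1]
  feat <- matrix(0, n, M + K)
  for (i in seq_len(n)) {
    Zi <- Z[i, , ]
    rv <- apply(Zi, 1, stats::var)
    cv <- apply(Zi, 2, stats::var)
    if (sum(rv) < .Machine$double.eps || sum(cv) < .Machine$double.eps)
      stop("zero total variance in projected trial ", i)
    feat[i, ] <- c(log(rv / sum(rv)), log(cv / sum(cv)))
  }
  colnames(feat) <- c(paste0("space", seq_len(M)), paste0("time", seq_len(K)))
  structure(list(features = feat, m = M, k = K, meta = ep$meta),
            class = "stfeatures")
}

#' @export
predict.cstp <- function(object, newdata,
                         type = c("features", "projection"), ...) {
  type <- match.arg(type)
  if (type == "projection") cstp_project(object, newdata)
  else cstp_features(object, newdata)
}

#' Column-centered SVD-based principal component analysis
#'
#' Thin wrapper around [stats::prcomp()] (no scaling) returning scores and
#' explained-variance ratios; used to visualize class separation of raw
#' (flattened) epochs versus CSTP features.
#'
#' @param X samples x features matrix (>= 2 samples).
#' @param n_components number of components to keep; silently limited by the
#'   matrix rank (with a warning when truncation occurs).
#' @return list with `scores`, `explained_variance_ratio` (non-increasing,
#'   summing to <= 1), `rotation` and `center`.
#' @export
pca_project <- function(X, n_components = 2) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-9)
  nc <- min(n_components, ncol(pr$x))
  if (n_components > rank) {
    warning("n_components (", n_components, ") exceeds rank (", rank,
            "); truncated")
    nc <- min(nc, rank)
  }
  list(scores = pr$x[, seq_len(nc), drop = FALSE],
       explained_variance_ratio = evr[seq_len(nc)],
       rotation = pr$rotation[, seq_len(nc), drop = FALSE],
       center = pr$center)
}

#' Flatten an epoch set to per-trial vectors
#'
#' Row-major per trial concatenation of channels x time, used as the "raw"
#' input for PCA visualization and the raw-feature SVM control.
#'
#' @param ep an `epoch_set`.
#' @return trials x (channels * time) matrix.
#' @export
flatten_epochs <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  d <- dim(ep$data)
  matrix(ep$data, d[1], d[2] * d[3])
}

#' Save / load a CSTP model
#'
#' RDS checkpoint plus an optional JSON export of the filters and objective
#' trace for interchange.
#'
#' @param model a `cstp` object.
#' @param path output `.rds` path.
#' @param json optional path for a JSON export.
#' @return `path`, invisibly.
#' @export
save_cstp <- function(model, path, json = NULL) {
  stopifnot(inherits(model, "cstp"))
  saveRDS(model, path)
  if (!is.null(json))
    jsonlite::write_json(list(W = model$W, V = model$V,
                              objective_trace = model$objective_trace,
                              m_filters = model$m_filters,
                              k_filters = model$k_filters,
                              classes = model$classes,
                              channels = model$channels),
                         json, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_cstp
#' @export
load_cstp <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "cstp"))
  m
}
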