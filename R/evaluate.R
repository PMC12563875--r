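# ---- subject-level cross-validation and metrics ---------------------------

#' Class-balanced subject-level fold assignment
#'
#' Shuffles subjects within each class (seeded) and deals them round-robin
#' into `k` folds, so per-fold class counts differ by at most one and every
#' subject appears in exactly one test fold.
#'
#' @param subjects character vector of unique subject ids.
#' @param groups class label per subject.
#' @param k number of folds (default 4); must be >= 2 and no larger than the
#'   size of the smallest class.
#' @param seed integer seed for the shuffle.
#' @return A data frame of class `"cv_folds"` with columns `subject_id`,
#'   `group`, `fold`.
#' @export
make_folds <- function(subjects, groups, k = 4, seed = 1) {
  if (anyDuplicated(subjects)) stop("subject ids must be unique")
  if (k < 2) stop("k must be >= 2 (no held-out rotation with k = 1)")
  f <- factor(groups)
  if (any(table(f) < k))
    stop("each class needs at least k subjects (k = ", k, ")")
  set.seed(seed)
  fold <- integer(length(subjects))
  for (lv in levels(f)) {
    idx <- which(f == lv)
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  structure(data.frame(subject_id = subjects, group = as.character(f),
                       fold = fold, stringsAsFactors = FALSE),
            class = c("cv_folds", "data.frame"))
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 for the positive class (PTSD when
#' present), trapezoidal ROC AUC from the positive-class score, and raw plus
#' row-normalized confusion matrices (rows = true class).
#'
#' @param y_true true labels (factor or coercible, 2 levels).
#' @param y_pred predicted labels on the same levels.
#' @param y_score optional numeric score for the positive class (higher =
#'   more positive); required for AUC.
#' @param positive positive-class label (default `"PTSD"` when present,
#'   otherwise the second level).
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `auc`
#'   (`NA` with a `auc_flag` note when undefined), `confusion`,
#'   `confusion_norm`, `positive`.
#' @export
classifier_metrics <- function(y_true, y_pred, y_score = NULL,
                               positive = NULL) {
  yt <- factor(y_true)
  lv <- levels(yt)
  if (length(lv) > 2) stop("binary metrics require two classes")
  if (is.null(positive))
    positive <- if ("PTSD" %in% lv) "PTSD" else lv[length(lv)]
  negative <- setdiff(lv, positive)
  if (!length(negative)) negative <- paste0("not_", positive)
  yp <- factor(as.character(y_pred), levels = c(negative, positive))
  yt <- factor(as.character(yt), levels = c(negative, positive))
  cm <- table(true = yt, pred = yp)
  TP <- cm[positive, positive]; FP <- cm[negative, positive]
  FN <- cm[positive, negative]; TN <- cm[negative, negative]
  acc <- (TP + TN) / sum(cm)
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  rec <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  auc <- NA_real_; auc_flag <- NULL
  if (!is.null(y_score)) {
    if (length(unique(as.character(yt))) < 2) {
      auc_flag <- "AUC undefined: single class in y_true"
    } else {
      r <- pROC::roc(response = yt, predictor = as.numeric(y_score),
                     levels = c(negative, positive), direction = "<",
                     quiet = TRUE)
      auc <- as.numeric(pROC::auc(r))
    }
  }
  rs <- rowSums(cm)
  cmn <- sweep(cm, 1, ifelse(rs > 0, rs, 1), "/")
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1, auc = auc,
       auc_flag = auc_flag, confusion = cm, confusion_norm = cmn,
       positive = positive)
}

#' Aggregate per-fold metrics
#'
#' Mean and normal-approximation 95% confidence interval
#' (`mean +/- 1.96 * sd / sqrt(k)`) across folds, per metric.
#'
#' @param folds list of per-fold metric records (as in a `cv_report`).
#' @param metrics metric names to aggregate.
#' @return data frame with `metric`, `mean`, `sd`, `ci_lo`, `ci_hi`.
#' @export
aggregate_metrics <- function(folds,
                              metrics = c("accuracy", "precision", "recall",
                                          "f1", "auc")) {
  if (length(folds) < 2) stop("need >= 2 folds to aggregate")
  out <- data.frame(metric = metrics, mean = NA_real_, sd = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(metrics)) {
    v <- vapply(folds, function(f) as.numeric(f[[metrics[i]]]), 0)
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v)
    hw <- 1.96 * s / sqrt(length(v))
    out[i, 2:5] <- c(m, s, m - hw, m + hw)
  }
  out
}

# oriented SVM decision values: higher = positive class
svm_scores <- function(fit, X, positive) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  nm <- strsplit(colnames(dv)[1], "/")[[1]]
  s <- as.numeric(dv[, 1])
  if (nm[1] != positive) s <- -s
  list(pred = pr, score = s)
}

#' Subject-level k-fold cross-validation of the classifiers
#'
#' Partitions subjects into class-balanced folds, then for each fold trains
#' on the remaining subjects and evaluates on the held-out subjects'
#' trials. Three classifiers are supported: the P300-STTCNet network
#' (`"sttcnet"`), an RBF-SVM on CSTP log-variance features (`"cstp_svm"`,
#' the baseline; the CSTP filters are refit inside every training fold so no
#' test-subject information leaks into feature learning), and an RBF-SVM on
#' flattened raw epochs (`"raw_svm"`, the control). In strict mode any
#' overlap between train and test subjects aborts.
#'
#' @param ep an `epoch_set` with subject and group metadata.
#' @param method `"sttcnet"`, `"cstp_svm"` or `"raw_svm"`.
#' @param k number of folds (default 4).
#' @param seed seed for fold assignment and per-fold training.
#' @param folds optional precomputed [make_folds()] assignment.
#' @param positive positive-class label (default PTSD).
#' @param cost SVM penalty parameter C (default 0.1).
#' @param m_filters,k_filters CSTP dimensions for `"cstp_svm"`.
#' @param shrinkage covariance shrinkage for the within-fold CSTP refits
#'   (default 0.2). Training folds are small relative to the temporal
#'   dimension, and with near-singular class covariances unregularized
#'   filters saturate at perfect within-fold separation that does not
#'   transfer; a sizeable ridge is the standard regularized-CSP remedy.
#' @param net_args list of arguments forwarded to [sttcnet()] (e.g.
#'   `config`, `epochs`, `batch_size`, `lr`, `val_frac`).
#' @param strict abort on any train/test subject overlap (default TRUE).
#' @param verbose print per-fold progress.
#' @return An object of class `"cv_report"`: `folds` (per-fold
#'   `test_subjects`, metrics and confusion matrices), `aggregate`,
#'   `method`, `seed`, `fold_assignment`.
#' @export
cv_classify <- function(ep, method = c("sttcnet", "cstp_svm", "raw_svm"),
                        k = 4, seed = 1, folds = NULL, positive = NULL,
                        cost = 0.1, m_filters = 6, k_filters = 6,
                        shrinkage = 0.2, net_args = list(), strict = TRUE,
                        verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(ep, "epoch_set"))
  subj <- unique(ep$meta$subject_id)
  sgrp <- ep$meta$group[match(subj, ep$meta$subject_id)]
  if (is.null(folds)) folds <- make_folds(subj, sgrp, k, seed)
  stopifnot(inherits(folds, "cv_folds"))
  if (is.null(positive))
    positive <- if ("PTSD" %in% sgrp) "PTSD" else sort(unique(sgrp))[2]
  kf <- max(folds$fold)
  fold_res <- vector("list", kf)
  for (fd in seq_len(kf)) {
    test_sub <- unique(folds$subject_id[folds$fold == fd])
    train_sub <- unique(folds$subject_id[folds$fold != fd])
    if (strict && length(intersect(train_sub, test_sub)))
      stop("leakage audit failed: train and test subjects overlap")
    tr <- subset_epochs(ep, ep$meta$subject_id %in% train_sub)
    te <- subset_epochs(ep, ep$meta$subject_id %in% test_sub)
    if (strict && length(intersect(unique(tr$meta$subject_id),
                                   unique(te$meta$subject_id))))
      stop("leakage audit failed: train and test subjects overlap")
    yte <- factor(te$meta$group)
    fold_seed <- as.integer((as.numeric(seed) * 1000 + fd) %% 2147483647)
    if (method == "sttcnet") {
      args <- c(list(x = tr, seed = fold_seed), net_args)
      net <- do.call(sttcnet, args)
      prob <- stats::predict(net, te, type = "prob")
      pred <- factor(net$classes[max.col(prob, ties.method = "first")], levels = net$classes)
      score <- prob[, positive]
    } else if (method == "cstp_svm") {
      cm <- cstp(tr, m_filters = m_filters, k_filters = k_filters,
                 shrinkage = shrinkage, seed = fold_seed)
      Ftr <- cstp_features(cm, tr)$features
      Fte <- cstp_features(cm, te)$features
      fit <- e1071::svm(Ftr, factor(tr$meta$group), kernel = "radial",
                        cost = cost, scale = TRUE)
      sc <- svm_scores(fit, Fte, positive)
      pred <- sc$pred; score <- sc$score
    } else {
      Xtr <- flatten_epochs(tr); Xte <- flatten_epochs(te)
      # gamma = 1/(p * var) on the unscaled flattened epochs
      fit <- e1071::svm(Xtr, factor(tr$meta$group), kernel = "radial",
                        cost = cost, scale = FALSE,
                        gamma = 1 / (ncol(Xtr) * stats::var(as.vector(Xtr))))
      sc <- svm_scores(fit, Xte, positive)
      pred <- sc$pred; score <- sc$score
    }
    m <- classifier_metrics(yte, pred, score, positive)
    m$test_subjects <- test_sub
    m$n_test_trials <- n_trials(te)
    fold_res[[fd]] <- m
    if (verbose)
      message(sprintf("fold %d/%d [%s]: acc %.3f auc %s", fd, kf, method,
                      m$accuracy, format(m$auc, digits = 3)))
  }
  structure(list(folds = fold_res, aggregate = aggregate_metrics(fold_res),
                 method = method, seed = seed, positive = positive,
                 fold_assignment = folds),
            class = "cv_report")
}

#' CSTP + RBF-SVM baseline under subject-level cross-validation
#'
#' Convenience wrapper around [cv_classify()] for the SVM comparisons: CSTP
#' log-variance features (refit per training fold) or flattened raw epochs,
#' classified by an RBF-kernel SVM with penalty `C = 0.1`.
#'
#' @param ep an `epoch_set`.
#' @param features `"cstp"` or `"raw"`.
#' @param ... passed to [cv_classify()] (`k`, `seed`, `folds`, `cost`, ...).
#' @return a `cv_report`.
#' @export
svm_baseline <- function(ep, features = c("cstp", "raw"), ...) {
  features <- match.arg(features)
  cv_classify(ep, method = if (features == "cstp") "cstp_svm" else "raw_svm",
              ...)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Subject-level ", length(x$folds), "-fold CV [", x$method,
      "], positive class ", x$positive, "\n", sep = "")
  ag <- x$aggregate
  for (i in seq_len(nrow(ag)))
    cat(sprintf("  %-9s %.4f  (95%% CI %.4f-%.4f)\n", ag$metric[i],
                ag$mean[i], ag$ci_lo[i], ag$ci_hi[i]))
  invisible(x)
}

#' Export a CV report
#'
#' JSON with per-fold and aggregate metrics; optional CSVs for the metric
#' table and summed confusion matrix.
#'
#' @param report a `cv_report`.
#' @param path output JSON path.
#' @param csv optional CSV path for the aggregate table.
#' @param confusion_csv optional CSV path for the pooled confusion matrix.
#' @return `path`, invisibly.
#' @export
save_cv_report <- function(report, path, csv = NULL, confusion_csv = NULL) {
  stopifnot(inherits(report, "cv_report"))
  folds <- lapply(report$folds, function(f)
    list(test_subjects = f$test_subjects, accuracy = f$accuracy,
         precision = f$precision, recall = f$recall, f1 = f$f1,
         auc = f$auc, confusion = as.vector(f$confusion)))
  jsonlite::write_json(list(method = report$method, seed = report$seed,
                            positive = report$positive, folds = folds,
                            aggregate = report$aggregate),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(csv))
    utils::write.csv(report$aggregate, csv, row.names = FALSE)
  if (!is.null(confusion_csv)) {
    cm <- Reduce(`+`, lapply(report$folds, `[[`, "confusion"))
    utils::write.csv(as.data.frame.matrix(cm), confusion_csv)
  }
  invisible(path)
}
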