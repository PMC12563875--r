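test_that("fold assignment partitions subjects with balanced classes", {
  subj <- paste0(rep(c("HC", "PTSD"), each = 12), sprintf("%02d", 1:12))
  grp <- rep(c("HC", "PTSD"), each = 12)
  f <- make_folds(subj, grp, k = 4, seed = 1)
  expect_equal(sort(unique(f$fold)), 1:4)
  # union = all subjects, pairwise disjoint, 3 + 3 per fold
  expect_setequal(f$subject_id, subj)
  expect_false(anyDuplicated(f$subject_id) > 0)
  tab <- table(f$group, f$fold)
  expect_true(all(tab == 3))
  # seeded: reproducible, different seeds differ
  expect_identical(f, make_folds(subj, grp, 4, seed = 1))
  expect_false(identical(f$fold, make_folds(subj, grp, 4, seed = 2)$fold))
  expect_error(make_folds(subj, grp, k = 1), "k = 1|>= 2")
  expect_error(make_folds(subj[c(1:3, 13:15)], grp[c(1:3, 13:15)], k = 4),
               "at least k")
})

test_that("classification metrics match hand formulas", {
  # printed toy: TP=3 FP=1 FN=2 TN=4 (positive = PTSD)
  y_true <- c(rep("PTSD", 5), rep("HC", 5))
  y_pred <- c("PTSD", "PTSD", "PTSD", "HC", "HC",
              "PTSD", "HC", "HC", "HC", "HC")
  m <- classifier_metrics(y_true, y_pred)
  expect_equal(m$positive, "PTSD")
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / (1 / 0.75 + 1 / 0.6))
  expect_equal(m$accuracy, 0.7)
  expect_equal(rowSums(m$confusion_norm), c(HC = 1, PTSD = 1))
  # perfect prediction with a separating score
  mp <- classifier_metrics(y_true, y_true, ifelse(y_true == "PTSD", 1, 0))
  expect_equal(unlist(mp[c("accuracy", "precision", "recall", "f1", "auc")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, auc = 1))
  # constant score: AUC 1/2
  mc <- classifier_metrics(y_true, y_pred, rep(0.3, 10))
  expect_equal(mc$auc, 0.5)
  # single-class truth: AUC flagged undefined
  ms <- classifier_metrics(factor(rep("PTSD", 4), levels = c("HC", "PTSD")),
                           rep("PTSD", 4), runif(4))
  expect_true(is.na(ms$auc))
  expect_match(ms$auc_flag, "single class")
})

test_that("trapezoidal AUC matches a hand-counted ranking", {
  y <- c("HC", "HC", "PTSD", "PTSD", "PTSD")
  s <- c(0.1, 0.8, 0.4, 0.9, 0.95)
  # pairs (neg, pos): 2x3 = 6; concordant: (0.1,all 3)=3, (0.8,0.9)=1,
  # (0.8,0.95)=1, discordant (0.8,0.4); AUC = 5/6
  m <- classifier_metrics(y, y, s)
  expect_equal(m$auc, 5 / 6)
})

test_that("fold aggregation applies the normal-approximation interval", {
  f1 <- list(accuracy = 0.9, precision = 1, recall = 1, f1 = 1, auc = 1)
  f2 <- list(accuracy = 1.0, precision = 1, recall = 1, f1 = 1, auc = 1)
  ag <- aggregate_metrics(list(f1, f2))
  acc <- ag[ag$metric == "accuracy", ]
  expect_equal(acc$mean, 0.95)
  hw <- 1.96 * sd(c(0.9, 1)) / sqrt(2)
  expect_equal(acc$ci_hi - acc$mean, hw)
  expect_equal(acc$mean - acc$ci_lo, hw)
  # identical folds: zero-width interval containing the mean
  agz <- aggregate_metrics(list(f1, f1))
  expect_equal(agz$ci_lo, agz$mean)
  expect_error(aggregate_metrics(list(f1)), ">= 2 folds")
})

test_that("SVM baselines are deterministic and detect separable features", {
  set.seed(51)
  ep <- mk_erp_epochs(16, C = 6, noise_sd = 0.5, subjects_per_group = 8)
  r1 <- svm_baseline(ep, "cstp", k = 4, seed = 3, m_filters = 4,
                     k_filters = 4)
  expect_gt(r1$aggregate$mean[r1$aggregate$metric == "accuracy"], 0.8)
  r2 <- svm_baseline(ep, "cstp", k = 4, seed = 3, m_filters = 4,
                     k_filters = 4)
  expect_equal(r1$aggregate, r2$aggregate)
  # every subject appears exactly once across test folds
  ts <- unlist(lapply(r1$folds, `[[`, "test_subjects"))
  expect_setequal(ts, unique(ep$meta$subject_id))
  expect_false(anyDuplicated(ts) > 0)
  # confusion counts sum to the test trial count per fold
  for (fd in r1$folds)
    expect_equal(sum(fd$confusion), fd$n_test_trials)
})

test_that("label-shuffled features drop the SVM baseline to chance", {
  set.seed(52)
  ep <- mk_erp_epochs(16, C = 6, noise_sd = 0.5, subjects_per_group = 8)
  # shuffle group labels at the subject level (keeps subject-level folds valid)
  subj <- unique(ep$meta$subject_id)
  newg <- sample(rep(c("HC", "PTSD"), length.out = length(subj)))
  ep$meta$group <- newg[match(ep$meta$subject_id, subj)]
  r <- svm_baseline(ep, "cstp", k = 4, seed = 3, m_filters = 4, k_filters = 4)
  acc <- r$aggregate$mean[r$aggregate$metric == "accuracy"]
  expect_lt(abs(acc - 0.5), 0.2)
})

test_that("the leakage audit rejects overlapping train/test subjects", {
  set.seed(53)
  ep <- mk_noise_epochs(8, C = 3, Tn = 20, n_subjects = 4, sd = 1)
  subj <- unique(ep$meta$subject_id)
  grp <- ep$meta$group[match(subj, ep$meta$subject_id)]
  folds <- make_folds(subj, grp, k = 2, seed = 1)
  # a subject assigned to two folds sits in a training and a test set at once
  bad <- rbind(folds, folds[1, ])
  bad$fold[nrow(bad)] <- setdiff(1:2, folds$fold[1])
  class(bad) <- class(folds)
  expect_error(cv_classify(ep, "raw_svm", folds = bad, strict = TRUE),
               "leakage")
  # a clean assignment passes the audit
  expect_no_error(cv_classify(ep, "raw_svm", folds = folds, strict = TRUE))
})
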