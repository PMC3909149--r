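test_that("stratified folds are balanced overall and per class", {
  y <- rep(c("benign", "malignant"), times = c(85, 149))
  f <- make_folds(y, k = 10, seed = 1)
  sizes <- tabulate(f, 10)
  expect_equal(sort(unique(sizes)), c(23, 24))
  expect_equal(sum(sizes == 24), 4)  # 234 = 4*24 + 6*23
  for (cls in c("benign", "malignant")) {
    cs <- tabulate(f[y == cls], 10)
    expect_lte(max(cs) - min(cs), 1)
  }
  # n = 20 balanced, k = 10: one of each class per fold
  y2 <- rep(c("benign", "malignant"), 10)
  f2 <- make_folds(y2, 10, seed = 2)
  for (k in 1:10) {
    expect_equal(sort(y2[f2 == k]), c("benign", "malignant"))
  }
  expect_identical(make_folds(y, 10, seed = 3), make_folds(y, 10, seed = 3))
  expect_error(make_folds(rep(c("a", "b"), times = c(5, 50)), 10), "class")
})

test_that("confusion metrics compute the standard ratios", {
  truth <- rep(c("malignant", "benign"), times = c(12, 10))
  pred <- c(rep("malignant", 10), rep("benign", 2),
            rep("benign", 8), rep("malignant", 2))
  m <- confusion_metrics(pred, truth)
  expect_equal(round(unname(m), 4), c(0.8333, 0.8, 0.8182))
  expect_equal(unname(confusion_metrics(truth, truth)), c(1, 1, 1))
  allpos <- rep("malignant", 22)
  expect_equal(unname(confusion_metrics(allpos, truth)[1:2]), c(1, 0))
})

test_that("rank-based AUC equals the all-pairs counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c("benign", "benign", "benign",
                                             "malignant", "malignant")), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c("benign", "malignant"), 5)), 0.5)
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    y <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 1))  # rounded: plenty of ties
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep("benign", 5)), "both classes")
})

test_that("univariate threshold evaluation is leakage-free and oriented", {
  # perfectly separable: accuracy 1, threshold between the groups
  y <- rep(c("benign", "malignant"), each = 3)
  x <- c(1, 2, 3, 4, 5, 6)
  folds <- c(1, 2, 3, 3, 2, 1)
  ev <- univariate_threshold_eval(x, y, folds)
  expect_equal(unname(ev$averaged["accuracy"]), 1)
  expect_gt(ev$whole_data_threshold, 3)
  expect_lt(ev$whole_data_threshold, 4)
  expect_equal(ev$direction, "greater")

  # low ADC calls malignant: orientation flips
  co <- full_cohort_features()
  ft <- co$features
  f10 <- make_folds(ft$label, 10, seed = 5)
  ev_adc <- univariate_threshold_eval(ft$adc, ft$label, f10)
  expect_equal(ev_adc$direction, "less")
  expect_gt(unname(ev_adc$averaged["accuracy"]), 0.6)

  # permuted labels: chance-level accuracy
  accs <- massdx:::with_seed(77, vapply(1:30, function(i) {
    yp <- sample(ft$label)
    fp <- make_folds(yp, 10, seed = i)
    unname(suppressWarnings(
      univariate_threshold_eval(ft$adc, yp, fp))$averaged["accuracy"])
  }, numeric(1)))
  # a Youden rule trained on permuted labels cannot systematically beat
  # the majority-class rate; its expected accuracy sits between balanced
  # chance (0.5) and the majority prevalence
  chance <- max(table(ft$label)) / nrow(ft)
  expect_lt(mean(accs), chance + 2 * sd(accs) / sqrt(30) + 0.01)
  expect_gt(mean(accs), 0.40)
})

test_that("nested cross-validation is deterministic and leakage-free", {
  co <- full_cohort_features()
  ft <- co$features
  # a feature equal to the label is classified perfectly by every model
  leak <- ft
  leak$oracle_col <- ifelse(ft$label == "malignant", 1, 0)
  for (kind in c("svm_rbf", "naive_bayes", "knn", "logistic")) {
    ev <- cross_validate(leak, "oracle_col", leak$label, model_spec(kind),
                         k = 5, inner_k = 3, seed = 2)
    expect_equal(unname(ev$averaged["accuracy"]), 1, label = kind)
  }
  # determinism
  e1 <- cross_validate(ft, c("adc", "ser"), ft$label, model_spec("svm_rbf"),
                       k = 5, inner_k = 3, seed = 9)
  e2 <- cross_validate(ft, c("adc", "ser"), ft$label, model_spec("svm_rbf"),
                       k = 5, inner_k = 3, seed = 9)
  expect_identical(e1$per_fold, e2$per_fold)
  expect_true(all(e1$per_fold[, c("sensitivity", "specificity", "accuracy",
                                  "auc")] >= 0 &
                  e1$per_fold[, c("sensitivity", "specificity", "accuracy",
                                  "auc")] <= 1))

  # rescaling a noise feature inside the would-be test folds must not
  # change anything if standardisation is fitted on training folds only
  noise <- ft
  noise$junk <- massdx:::with_seed(5, rnorm(nrow(ft)))
  ev_a <- cross_validate(noise, c("adc", "junk"), noise$label,
                         model_spec("logistic"), k = 5, inner_k = 3, seed = 4)
  expect_lt(abs(unname(ev_a$averaged["accuracy"]) -
                unname(cross_validate(noise, "adc", noise$label,
                                      model_spec("logistic"), k = 5,
                                      inner_k = 3, seed = 4)$averaged["accuracy"])),
            0.06)
})

test_that("the report aggregates models and averages correctly", {
  co <- full_cohort_features()
  ft <- co$features
  rep_ <- build_report(ft, ft$label,
                       feature_sets = list(adc = "adc",
                                           pair = c("adc", "ser")),
                       univariate = c("adc", "ser"),
                       k = 5, inner_k = 3, seed = 6)
  perf <- rep_$performance
  expect_equal(perf$model[perf$feature_set == "adc"], "univariate_threshold")
  pair <- perf[perf$feature_set == "pair", ]
  avg <- pair[pair$model == "averaged", c("sensitivity", "specificity",
                                          "accuracy", "auc")]
  man <- colMeans(pair[pair$model != "averaged", c("sensitivity", "specificity",
                                                   "accuracy", "auc")])
  expect_equal(unname(unlist(avg)), unname(man), tolerance = 1e-12)
  expect_true(all(perf$accuracy >= 0 & perf$accuracy <= 1))
  # univariate section carries Welch p-values and thresholds
  expect_true(all(c("p_value", "threshold", "cv_accuracy") %in%
                    names(rep_$univariate)))
  expect_true(all(rep_$univariate$p_value < 0.05))
})
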