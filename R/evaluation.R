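#' Stratified k-fold assignment
#'
#' Randomly partitions cases into `k` folds, stratified by class: per-class
#' fold sizes differ by at most one, and overall fold sizes differ by at
#' most one (remainders are dealt to the currently smallest folds).
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed seed for the shuffle.
#' @return integer vector of fold ids in 1..k.
#' @export
make_folds <- function(labels, k = 10, seed = 1) {
  stratified_folds(labels, k, seed = seed)
}

#' Confusion-matrix metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and overall accuracy,
#' with malignant as the positive class by default. A metric whose
#' denominator class is absent from the truth is returned as `NA`.
#'
#' @param predictions predicted labels.
#' @param truth true labels.
#' @param positive positive-class label.
#' @return named numeric vector (sensitivity, specificity, accuracy).
#' @export
confusion_metrics <- function(predictions, truth, positive = "malignant") {
  p <- as.character(predictions); t <- as.character(truth)
  if (length(p) != length(t)) stopf("confusion_metrics: length mismatch")
  pos <- t == positive
  sens <- if (any(pos)) mean(p[pos] == positive) else NA_real_
  spec <- if (any(!pos)) mean(p[!pos] != positive) else NA_real_
  c(sensitivity = sens, specificity = spec, accuracy = mean(p == t))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive case
#' outscores a random negative one, with ties counted one half (computed
#' from midranks).
#'
#' @param scores continuous scores, higher = more malignant.
#' @param truth true labels.
#' @param positive positive-class label.
#' @return AUC in [0,1].
#' @export
roc_auc <- function(scores, truth, positive = "malignant") {
  t <- as.character(truth)
  pos <- t == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("roc_auc: both classes must be present")
  if (any(!is.finite(scores))) stopf("roc_auc: scores must be finite")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Youden-optimal threshold on training data. Direction: if the training AUC
# of the raw feature is below 0.5 the orientation flips (low values call
# malignant). Candidate cutoffs are midpoints between consecutive sorted
# unique values (plus outside sentinels).
youden_threshold <- function(x, y, positive = "malignant") {
  auc_raw <- roc_auc(x, y, positive)
  direction <- if (auc_raw >= 0.5) "greater" else "less"
  s <- if (direction == "greater") x else -x
  u <- sort(unique(s))
  cuts <- if (length(u) > 1) {
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  } else c(u - 1, u + 1)
  pos <- as.character(y) == positive
  js <- vapply(cuts, function(cut) {
    call_pos <- s >= cut
    mean(call_pos[pos]) + mean(!call_pos[!pos]) - 1
  }, numeric(1))
  best_j <- max(js)
  # ties: take the center of the optimal-threshold interval, provided the
  # center itself is optimal (ties can in principle be non-contiguous)
  tied <- cuts[js >= best_j - 1e-12]
  best_cut <- mean(range(tied))
  j_center <- {
    call_pos <- s >= best_cut
    mean(call_pos[pos]) + mean(!call_pos[!pos]) - 1
  }
  if (j_center < best_j - 1e-12) best_cut <- tied[1]
  thr <- if (direction == "greater") best_cut else -best_cut
  list(threshold = thr, direction = direction, youden = best_j)
}

# Apply a trained threshold rule.
apply_threshold <- function(x, rule, positive = "malignant",
                            negative = "benign") {
  call_pos <- if (rule$direction == "greater") x >= rule$threshold else x <= rule$threshold
  ifelse(call_pos, positive, negative)
}

#' Cross-validated univariate threshold evaluation
#'
#' For a single feature: in each fold, the Youden-optimal cutoff (and its
#' orientation) is chosen on the training portion and applied to the test
#' fold. Reports per-fold sensitivity, specificity, accuracy and AUC (from
#' oriented scores), their averages, and the whole-data optimal threshold.
#'
#' @param x feature values.
#' @param labels class labels.
#' @param folds fold ids from [make_folds()].
#' @param positive positive-class label.
#' @return list of class `univariate_eval`: `per_fold` (data.frame),
#'   `averaged` (named vector), `whole_data_threshold`, `direction`.
#' @export
univariate_threshold_eval <- function(x, labels, folds, positive = "malignant") {
  y <- as.character(labels)
  neg <- setdiff(unique(y), positive)
  if (stats::sd(x) == 0) {
    warnf("univariate_threshold_eval: constant feature; chance-level report")
  }
  rows <- lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    rule <- youden_threshold(x[tr], y[tr], positive)
    pred <- apply_threshold(x[!tr], rule, positive, neg)
    m <- confusion_metrics(pred, y[!tr], positive)
    s <- if (rule$direction == "greater") x[!tr] else -x[!tr]
    auc <- tryCatch(roc_auc(s, y[!tr], positive), error = function(e) NA_real_)
    data.frame(fold = f, t(m), auc = auc, threshold = rule$threshold,
               direction = rule$direction)
  })
  per_fold <- do.call(rbind, rows)
  averaged <- colMeans(per_fold[, c("sensitivity", "specificity", "accuracy", "auc")],
                       na.rm = TRUE)
  whole <- youden_threshold(x, y, positive)
  structure(list(per_fold = per_fold, averaged = averaged,
                 whole_data_threshold = whole$threshold,
                 direction = whole$direction),
            class = "univariate_eval")
}

#' Classifier specification
#'
#' @param kind one of `svm_rbf`, `naive_bayes`, `knn`, `logistic`.
#' @param knn_k neighbours for `knn`.
#' @param cost_grid,gamma_scale_grid inner-CV tuning grid for `svm_rbf`
#'   (gamma = gamma_scale / n_features).
#' @param standardize standardise features (fitted on training folds only).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(kind = c("svm_rbf", "naive_bayes", "knn", "logistic"),
                       knn_k = 6,
                       cost_grid = c(0.1, 1, 10, 100),
                       gamma_scale_grid = c(0.01, 0.1, 1),
                       standardize = TRUE) {
  kind <- match.arg(kind)
  if (knn_k < 1) stopf("model_spec: knn_k must be >= 1")
  structure(list(kind = kind, knn_k = knn_k, cost_grid = cost_grid,
                 gamma_scale_grid = gamma_scale_grid,
                 standardize = standardize),
            class = "model_spec")
}

# Fit a model and return a closure scoring new data: list(class, score)
# where score is a continuous malignancy score.
fit_predictor <- function(xtr, ytr, spec, positive = "malignant", pars = list()) {
  y <- factor(as.character(ytr))
  neg <- setdiff(levels(y), positive)
  switch(spec$kind,
    svm_rbf = {
      fit <- e1071::svm(xtr, y, kernel = "radial", cost = pars$cost,
                        gamma = pars$gamma_scale / ncol(xtr), scale = FALSE,
                        probability = FALSE)
      function(xte) {
        pr <- stats::predict(fit, xte, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        # the column name "A/B" means positive decision values vote for A
        sgn <- if (strsplit(colnames(dv)[1], "/")[[1]][1] == positive) 1 else -1
        list(class = as.character(pr), score = sgn * as.numeric(dv))
      }
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, y)
      function(xte) {
        post <- stats::predict(fit, xte, type = "raw")
        sc <- post[, positive]
        list(class = ifelse(sc >= 0.5, positive, neg), score = sc)
      }
    },
    knn = {
      function(xte) {
        pr <- class::knn(xtr, xte, y, k = spec$knn_k, prob = TRUE)
        p <- attr(pr, "prob")
        sc <- ifelse(as.character(pr) == positive, p, 1 - p)
        list(class = as.character(pr), score = sc)
      }
    },
    logistic = {
      df <- as.data.frame(xtr)
      df$.y <- as.integer(y == positive)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      function(xte) {
        sc <- suppressWarnings(
          stats::predict(fit, newdata = as.data.frame(xte), type = "response"))
        list(class = ifelse(sc >= 0.5, positive, neg), score = as.numeric(sc))
      }
    })
}

#' Nested cross-validated evaluation of a feature subset
#'
#' Outer `k`-fold stratified CV; inside each training fold, tunable
#' hyperparameters (the SVM's C and gamma) are selected by `inner_k`-fold
#' CV over the spec's grid; standardisation is fitted on the training folds
#' only. Metrics are reported per fold and averaged; AUC is computed from
#' continuous decision scores, never from hard labels.
#'
#' @param features feature table (data.frame with registry columns).
#' @param subset feature names to use.
#' @param labels class labels.
#' @param spec a [model_spec()].
#' @param k outer folds.
#' @param inner_k inner folds for hyperparameter tuning.
#' @param seed fold-assignment seed.
#' @param positive positive-class label.
#' @return list of class `cv_eval`: `per_fold` (data.frame with
#'   sensitivity, specificity, accuracy, auc per fold), `averaged` (named
#'   vector), `model`, `subset`, `fold_assignment`, `seed`.
#' @export
cross_validate <- function(features, subset, labels, spec = model_spec(),
                           k = 10, inner_k = 5, seed = 1,
                           positive = "malignant") {
  if (!length(subset)) stopf("cross_validate: subset must be non-empty")
  X <- as.matrix(as.data.frame(features)[, subset, drop = FALSE])
  y <- as.character(labels)
  folds <- make_folds(y, k, seed)
  per_fold <- lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    xte <- X[!tr, , drop = FALSE]
    if (spec$standardize) {
      mu <- colMeans(xtr); sd_ <- apply(xtr, 2, stats::sd); sd_[sd_ == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sd_, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sd_, "/")
    }
    pars <- list()
    if (spec$kind == "svm_rbf") {
      if (min(table(ytr)) < inner_k) stopf("cross_validate: inner CV infeasible (tiny folds)")
      inner <- stratified_folds(ytr, inner_k, seed = child_seed(seed, f))
      grid <- expand.grid(cost = spec$cost_grid, gamma_scale = spec$gamma_scale_grid)
      accs <- mapply(function(co, ga) {
        mean(vapply(seq_len(inner_k), function(g) {
          itr <- inner != g
          fit <- e1071::svm(xtr[itr, , drop = FALSE], factor(ytr[itr]),
                            kernel = "radial", cost = co,
                            gamma = ga / ncol(xtr), scale = FALSE)
          mean(as.character(stats::predict(fit, xtr[!itr, , drop = FALSE])) == ytr[!itr])
        }, numeric(1)))
      }, grid$cost, grid$gamma_scale)
      best <- which.max(accs)
      pars <- list(cost = grid$cost[best], gamma_scale = grid$gamma_scale[best])
    }
    predictor <- fit_predictor(xtr, ytr, spec, positive, pars)
    with_seed(child_seed(seed, 1000 + f), {  # knn tie-breaking is random
      out <- predictor(xte)
    })
    m <- confusion_metrics(out$class, y[!tr], positive)
    auc <- tryCatch(roc_auc(out$score, y[!tr], positive), error = function(e) NA_real_)
    data.frame(fold = f, t(m), auc = auc)
  })
  per_fold <- do.call(rbind, per_fold)
  averaged <- colMeans(per_fold[, c("sensitivity", "specificity", "accuracy", "auc")],
                       na.rm = TRUE)
  structure(list(per_fold = per_fold, averaged = averaged, model = spec$kind,
                 subset = subset, fold_assignment = folds, seed = seed),
            class = "cv_eval")
}

#' Full diagnostic-performance report
#'
#' Builds the two standard result tables: a univariate section (per
#' selected feature: class means, Welch p-value, cross-validated threshold
#' performance and the whole-data optimal cutoff) and a feature-set x model
#' section. Single-feature sets are evaluated with the univariate threshold
#' model; multi-feature sets with the four classifiers, plus an "Averaged"
#' row (arithmetic mean of the four models' metrics).
#'
#' @param features feature table from [assemble_features()].
#' @param labels class labels (defaults to `features$label`).
#' @param feature_sets named list of feature-name vectors to evaluate.
#' @param univariate feature names for the univariate section.
#' @param k,inner_k,seed CV setup as in [cross_validate()].
#' @param models model kinds for multi-feature sets.
#' @return list of class `dx_report`: `univariate` (data.frame),
#'   `performance` (data.frame with columns feature_set, model,
#'   sensitivity, specificity, accuracy, auc), `seed`, `folds`.
#' @export
build_report <- function(features, labels = features$label, feature_sets,
                         univariate = NULL, k = 10, inner_k = 5, seed = 1,
                         models = c("svm_rbf", "naive_bayes", "knn", "logistic")) {
  X <- as.data.frame(features)
  y <- as.character(labels)
  folds <- make_folds(y, k, seed)
  uni_rows <- NULL
  if (length(univariate)) {
    uni_rows <- do.call(rbind, lapply(univariate, function(f) {
      v <- X[[f]]
      ev <- suppressWarnings(univariate_threshold_eval(v, y, folds))
      p <- tryCatch(stats::t.test(v ~ y)$p.value, error = function(e) NA_real_)
      data.frame(feature = f,
                 mean_benign = mean(v[y == "benign"]),
                 sd_benign = stats::sd(v[y == "benign"]),
                 mean_malignant = mean(v[y == "malignant"]),
                 sd_malignant = stats::sd(v[y == "malignant"]),
                 p_value = p,
                 cv_accuracy = unname(ev$averaged["accuracy"]),
                 threshold = ev$whole_data_threshold,
                 direction = ev$direction)
    }))
  }
  perf <- list()
  for (set_name in names(feature_sets)) {
    fs <- feature_sets[[set_name]]
    if (length(fs) == 1) {
      ev <- suppressWarnings(univariate_threshold_eval(X[[fs]], y, folds))
      perf[[length(perf) + 1]] <- data.frame(
        feature_set = set_name, model = "univariate_threshold",
        t(ev$averaged))
    } else {
      rows <- lapply(models, function(m) {
        ev <- cross_validate(X, fs, y, model_spec(m), k, inner_k, seed)
        data.frame(feature_set = set_name, model = m, t(ev$averaged))
      })
      rows <- do.call(rbind, rows)
      avg <- data.frame(feature_set = set_name, model = "averaged",
                        t(colMeans(rows[, c("sensitivity", "specificity",
                                            "accuracy", "auc")])))
      perf[[length(perf) + 1]] <- rbind(rows, avg)
    }
  }
  structure(list(univariate = uni_rows,
                 performance = do.call(rbind, perf),
                 seed = seed, folds = folds),
            class = "dx_report")
}

#' @export
print.dx_report <- function(x, ...) {
  if (!is.null(x$univariate)) {
    cat("Univariate diagnostic performance (CV threshold):\n")
    print(x$univariate, digits = 3, row.names = FALSE)
    cat("\n")
  }
  cat("Feature-set x model performance (10-fold CV):\n")
  print(x$performance, digits = 3, row.names = FALSE)
  invisible(x)
}
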