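#' Configuration for the hybrid feature-subset selection
#'
#' Step 2 filters features by two-sample Welch t-test at significance level
#' `alpha`; step 3 searches subsets of the survivors with a genetic
#' algorithm whose fitness is the cross-validated accuracy of an RBF-kernel
#' SVM; step 4 greedily ablates features whose omission costs at most
#' `ablation_epsilon` accuracy.
#'
#' @param alpha filter significance level, in (0,1).
#' @param population_size,generations,crossover_rate,mutation_rate,
#'   elitism_count,tournament_size GA hyperparameters. `generations` is a
#'   cap; the search also stops after `stagnation_limit` generations without
#'   best-fitness improvement.
#' @param fitness_cv_folds folds of the wrapper's fitness CV.
#' @param stagnation_limit early-stop patience, generations.
#' @param ablation_epsilon largest tolerated accuracy drop when a feature is
#'   omitted (absolute fraction).
#' @param cost,gamma wrapper SVM hyperparameters; `NULL` means tune once per
#'   run by `fitness_cv_folds`-fold CV over C in {0.1, 1, 10, 100} and
#'   gamma in {0.01, 0.1, 1}/d on the full filtered feature set.
#' @param seed seed for the GA and the fitness fold assignment.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, population_size = 50,
                             generations = 100, crossover_rate = 0.8,
                             mutation_rate = 0.02, elitism_count = 2,
                             tournament_size = 3, fitness_cv_folds = 5,
                             stagnation_limit = 15, ablation_epsilon = 0.005,
                             cost = NULL, gamma = NULL, seed = 1) {
  if (alpha <= 0 || alpha >= 1) stopf("selection_config: alpha must be in (0,1)")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stopf("selection_config: rates must be in [0,1]")
  }
  if (ablation_epsilon < -1) stopf("selection_config: ablation_epsilon below -1 is meaningless")
  structure(list(alpha = alpha, population_size = population_size,
                 generations = generations, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, elitism_count = elitism_count,
                 tournament_size = tournament_size,
                 fitness_cv_folds = fitness_cv_folds,
                 stagnation_limit = stagnation_limit,
                 ablation_epsilon = ablation_epsilon,
                 cost = cost, gamma = gamma, seed = seed),
            class = "selection_config")
}

#' Welch t-test filter
#'
#' Per-feature two-sample (unequal-variance, unpaired) t-test between the
#' benign and malignant groups; features with p < alpha survive.
#'
#' @param features numeric data.frame/matrix, cases x features.
#' @param labels factor/character with levels benign/malignant.
#' @param alpha significance level.
#' @return list: `surviving` (feature names, p < alpha), `p_values` (named,
#'   all features).
#' @export
ttest_filter <- function(features, labels, alpha = 0.05) {
  x <- as.data.frame(features)
  g <- as.character(labels)
  if (length(unique(g)) != 2) stopf("ttest_filter: need exactly two classes")
  if (min(table(g)) < 2) stopf("ttest_filter: each class needs >= 2 samples")
  p <- vapply(x, function(col) {
    if (any(!is.finite(col))) stopf("ttest_filter: non-finite feature values")
    tryCatch(stats::t.test(col ~ g)$p.value,
             error = function(e) {
               # constant within both groups: p = 1 if means equal, else
               # perfectly separated
               m <- tapply(col, g, mean)
               if (isTRUE(all.equal(m[1], m[2], check.attributes = FALSE))) 1 else 0
             })
  }, numeric(1))
  list(surviving = names(p)[p < alpha], p_values = p)
}

# Stratified fold assignment used by the wrapper fitness and the evaluator;
# returns integer fold ids. Remainders are dealt to the currently smallest
# folds so overall sizes differ by at most 1.
stratified_folds <- function(labels, k, seed = NULL) {
  g <- as.character(labels)
  if (any(table(g) < k)) stopf("stratified folds: every class needs >= k samples")
  fold <- integer(length(g))
  with_seed(seed, {
    totals <- integer(k)
    for (cls in sort(unique(g))) {
      idx <- sample(which(g == cls))
      n <- length(idx)
      base <- n %/% k; extra <- n %% k
      sizes <- rep(base, k)
      if (extra > 0) {
        recv <- order(totals, seq_len(k))[seq_len(extra)]
        sizes[recv] <- sizes[recv] + 1L
      }
      fid <- rep(seq_len(k), times = sizes)
      fold[idx] <- fid
      totals <- totals + sizes
    }
  })
  fold
}

# Mean CV accuracy of an RBF SVM on the given columns, with standardisation
# fitted on training folds only. Folds are fixed by the caller.
svm_cv_accuracy <- function(X, y, cols, folds, cost, gamma_scale) {
  if (!length(cols)) return(0)
  Xs <- as.matrix(X[, cols, drop = FALSE])
  acc <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    mu <- colMeans(Xs[tr, , drop = FALSE])
    sd_ <- apply(Xs[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    xtr <- sweep(sweep(Xs[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
    xte <- sweep(sweep(Xs[!tr, , drop = FALSE], 2, mu), 2, sd_, "/")
    fit <- e1071::svm(xtr, factor(y[tr]), kernel = "radial", cost = cost,
                      gamma = gamma_scale / length(cols), scale = FALSE)
    mean(as.character(stats::predict(fit, xte)) == as.character(y[!tr]))
  }, numeric(1))
  mean(acc)
}

# Tune (cost, gamma_scale) once by CV on the full candidate feature set.
tune_wrapper_svm <- function(X, y, folds) {
  grid <- expand.grid(cost = c(0.1, 1, 10, 100), gamma_scale = c(0.01, 0.1, 1))
  accs <- mapply(function(co, ga) {
    svm_cv_accuracy(X, y, colnames(X), folds, co, ga)
  }, grid$cost, grid$gamma_scale)
  best <- which.max(accs)
  list(cost = grid$cost[best], gamma_scale = grid$gamma_scale[best])
}

#' Genetic-algorithm SVM wrapper feature selection
#'
#' Chromosomes are binary inclusion masks over the candidate features;
#' fitness is the mean `fitness_cv_folds`-fold cross-validated accuracy of
#' the wrapper SVM on the encoded subset (empty chromosomes score 0).
#' Tournament selection, uniform crossover, bit-flip mutation and elitism;
#' the initial population contains every singleton chromosome (so the
#' search can never end below the best single feature) topped up with
#' random chromosomes. Fitness values are cached per chromosome; the whole
#' run is determined by `config$seed`.
#'
#' @param features cases x features table restricted to the filter
#'   survivors.
#' @param labels benign/malignant labels.
#' @param config a [selection_config()].
#' @return list: `subset` (selected feature names), `fitness_history`
#'   (best fitness per generation, non-decreasing), `best_fitness`,
#'   `n_evaluations` (distinct subsets evaluated), `wrapper` (the SVM
#'   hyperparameters used).
#' @export
ga_wrapper_select <- function(features, labels, config = selection_config()) {
  X <- as.data.frame(features)
  d <- ncol(X)
  if (d < 2) stopf("ga_wrapper_select: need >= 2 surviving features")
  y <- factor(as.character(labels))
  with_seed(config$seed, {
    folds <- stratified_folds(y, config$fitness_cv_folds, seed = NULL)
    wrapper <- if (is.null(config$cost) || is.null(config$gamma)) {
      tune_wrapper_svm(X, y, folds)
    } else list(cost = config$cost, gamma_scale = config$gamma * d)
    cache <- new.env(parent = emptyenv())
    fitness <- function(chrom) {
      key <- paste(which(chrom == 1), collapse = ",")
      if (key == "") return(0)
      hit <- get0(key, envir = cache)
      if (!is.null(hit)) return(hit)
      val <- svm_cv_accuracy(X, y, names(X)[chrom == 1], folds,
                             wrapper$cost, wrapper$gamma_scale)
      assign(key, val, envir = cache)
      val
    }
    np <- max(config$population_size, d + 3)
    # singletons (floor: never below the best single feature) plus the full
    # survivor set (the search can prune downward), topped up randomly
    pop <- rbind(diag(1L, d), rep(1L, d))
    while (nrow(pop) < np) {
      pop <- rbind(pop, matrix(stats::rbinom(d, 1, 0.5), 1))
    }
    pop <- pop[seq_len(np), , drop = FALSE]
    fit <- apply(pop, 1, fitness)
    history <- numeric(0)
    stagnant <- 0L
    for (gen in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(config$elitism_count)], , drop = FALSE]
      newpop <- matrix(0L, np, d)
      newpop[seq_len(config$elitism_count), ] <- elite
      i <- config$elitism_count
      while (i < np) {
        pick <- function() {
          cand <- sample.int(np, config$tournament_size, replace = TRUE)
          pop[cand[which.max(fit[cand])], ]
        }
        p1 <- pick(); p2 <- pick()
        if (stats::runif(1) < config$crossover_rate) {
          mix <- stats::runif(d) < 0.5
          c1 <- ifelse(mix, p1, p2)
          c2 <- ifelse(mix, p2, p1)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i >= np) break
          flip <- stats::runif(d) < config$mutation_rate
          child[flip] <- 1L - child[flip]
          i <- i + 1
          newpop[i, ] <- child
        }
      }
      if (all(rowSums(newpop) == 0)) {
        # degenerate population: re-seed with singletons
        newpop <- diag(1L, d)[rep(seq_len(d), length.out = np), , drop = FALSE]
        message("ga_wrapper_select: all-zero population re-seeded with singletons")
      }
      pop <- newpop
      fit <- apply(pop, 1, fitness)
      best <- max(fit)
      if (length(history) && best <= max(history) + 1e-12) {
        stagnant <- stagnant + 1L
      } else stagnant <- 0L
      history <- c(history, max(best, if (length(history)) max(history) else 0))
      if (stagnant >= config$stagnation_limit) break
    }
    winner <- pop[which.max(fit), ]
    # memetic polish: single-bit hill climbing from the GA optimum (the GA
    # explores globally; this recovers features whose inclusion/removal
    # improves fitness but was never sampled near convergence)
    best_fit <- fitness(winner)
    for (sweep in 1:3) {
      improved <- FALSE
      for (bit in seq_len(d)) {
        cand <- winner
        cand[bit] <- 1L - cand[bit]
        f_cand <- fitness(cand)
        if (f_cand > best_fit + 1e-12) {
          winner <- cand
          best_fit <- f_cand
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    history <- c(history, best_fit)
    list(subset = names(X)[winner == 1],
         fitness_history = history,
         best_fitness = best_fit,
         n_evaluations = length(ls(cache)),
         wrapper = wrapper)
  })
}

#' Greedy backward ablation of a feature subset
#'
#' Repeatedly finds the feature whose omission reduces the wrapper's CV
#' accuracy the least; while that reduction is at most
#' `config$ablation_epsilon` (and more than one feature remains) the
#' feature is removed. Ties are broken by removing the feature with the
#' larger filter p-value.
#'
#' @param features cases x features table (must contain `subset`).
#' @param labels benign/malignant labels.
#' @param subset feature names entering the ablation.
#' @param config a [selection_config()].
#' @param p_values optional named filter p-values for tie-breaking.
#' @param wrapper optional list(cost, gamma_scale); defaults to tuning as in
#'   [ga_wrapper_select()].
#' @return list: `subset` (final feature names, never empty), `report`
#'   (data.frame: feature examined, accuracy delta when omitted, removed
#'   flag, in removal order), `baseline_accuracy`, `final_accuracy`.
#' @export
ablation_prune <- function(features, labels, subset,
                           config = selection_config(), p_values = NULL,
                           wrapper = NULL) {
  if (!length(subset)) stopf("ablation_prune: subset must be non-empty")
  X <- as.data.frame(features)
  y <- factor(as.character(labels))
  with_seed(config$seed, {
    # accuracy deltas decide removals, so they are estimated on 3 repeated
    # fold assignments: single-split CV noise (~1-2% accuracy) would
    # otherwise dominate contributions near the epsilon threshold
    folds_list <- lapply(1:3, function(i) {
      stratified_folds(y, config$fitness_cv_folds, seed = NULL)
    })
    if (is.null(wrapper)) {
      wrapper <- if (is.null(config$cost) || is.null(config$gamma)) {
        tune_wrapper_svm(X[, subset, drop = FALSE], y, folds_list[[1]])
      } else list(cost = config$cost, gamma_scale = config$gamma * length(subset))
    }
    acc <- function(cols) {
      mean(vapply(folds_list, function(f) {
        svm_cv_accuracy(X, y, cols, f, wrapper$cost, wrapper$gamma_scale)
      }, numeric(1)))
    }
    current <- subset
    base <- acc(current)
    baseline <- base
    report <- list()
    while (length(current) > 1) {
      drops <- vapply(current, function(f) acc(setdiff(current, f)), numeric(1))
      delta <- base - drops
      best <- min(delta)
      cand <- which(delta <= best + 1e-12)
      victim <- if (length(cand) > 1 && !is.null(p_values)) {
        cand[which.max(p_values[current[cand]])]
      } else cand[1]
      if (delta[victim] <= config$ablation_epsilon) {
        report[[length(report) + 1]] <- data.frame(
          feature = current[victim], accuracy_delta = delta[victim],
          removed = TRUE)
        base <- drops[victim]
        current <- current[-victim]
      } else {
        report[[length(report) + 1]] <- data.frame(
          feature = current[victim], accuracy_delta = delta[victim],
          removed = FALSE)
        break
      }
    }
    list(subset = current,
         report = if (length(report)) do.call(rbind, report) else
           data.frame(feature = character(0), accuracy_delta = numeric(0),
                      removed = logical(0)),
         baseline_accuracy = baseline, final_accuracy = base)
  })
}

#' Run the full hybrid filter-wrapper-ablation selection
#'
#' Steps 2-4 in order: Welch t-test filter, GA-wrapped SVM subset search,
#' greedy ablation. The returned trace records the features removed at each
#' step and the final subset; the four lists partition the input feature
#' set.
#'
#' @param features cases x features numeric table (registry columns).
#' @param labels benign/malignant labels.
#' @param config a [selection_config()].
#' @return object of class `selection_trace`: `removed_step2`,
#'   `removed_step3`, `removed_step4`, `final_subset`, `p_values`,
#'   `fitness_history`, `ablation_report`, `wrapper`, `counts` (named sizes
#'   of the cascade 28 -> ... -> final).
#' @export
run_hybrid_fss <- function(features, labels, config = selection_config()) {
  X <- as.data.frame(features)
  drop_cols <- intersect(c("case_id", "label"), names(X))
  if (length(drop_cols)) X <- X[, setdiff(names(X), drop_cols), drop = FALSE]
  filt <- ttest_filter(X, labels, config$alpha)
  if (length(filt$surviving) < 2) {
    stopf("run_hybrid_fss [filter]: fewer than 2 features survive the t-test filter")
  }
  ga <- ga_wrapper_select(X[, filt$surviving, drop = FALSE], labels, config)
  ab <- ablation_prune(X, labels, ga$subset, config,
                       p_values = filt$p_values, wrapper = ga$wrapper)
  trace <- structure(list(
    removed_step2 = setdiff(names(X), filt$surviving),
    removed_step3 = setdiff(filt$surviving, ga$subset),
    removed_step4 = setdiff(ga$subset, ab$subset),
    final_subset = ab$subset,
    p_values = filt$p_values,
    fitness_history = ga$fitness_history,
    ablation_report = ab$report,
    wrapper = ga$wrapper,
    counts = c(input = ncol(X),
               after_step2 = length(filt$surviving),
               after_step3 = length(ga$subset),
               final = length(ab$subset))
  ), class = "selection_trace")
  stopifnot(setequal(c(trace$removed_step2, trace$removed_step3,
                       trace$removed_step4, trace$final_subset), names(X)))
  trace
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Hybrid feature-subset selection trace\n")
  cat(sprintf("  input features : %d\n", x$counts["input"]))
  cat(sprintf("  step 2 (t-test filter) removed %d: %s\n",
              length(x$removed_step2), paste(x$removed_step2, collapse = ", ")))
  cat(sprintf("  step 3 (GA-SVM wrapper) removed %d: %s\n",
              length(x$removed_step3), paste(x$removed_step3, collapse = ", ")))
  cat(sprintf("  step 4 (ablation) removed %d: %s\n",
              length(x$removed_step4), paste(x$removed_step4, collapse = ", ")))
  cat(sprintf("  final subset (%d): %s\n",
              length(x$final_subset), paste(x$final_subset, collapse = ", ")))
  invisible(x)
}
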