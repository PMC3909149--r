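# Stage 5: cross-validated diagnostic performance.
#
# Evaluates single-feature groups by cross-validated Youden thresholds and
# the texture group / combined final subset by four classifiers (RBF SVM
# with nested hyperparameter tuning, Gaussian naive Bayes, 6-NN, logistic
# regression) under stratified 10-fold CV, then prints the feature-set x
# model table with an "Averaged" row per multi-feature set.

source("analysis/00_config.R")

features <- read.csv(file.path(results_dir, "features.csv"),
                     stringsAsFactors = FALSE)
trace <- jsonlite::read_json(file.path(results_dir, "selection_trace.json"),
                             simplifyVector = TRUE)

groups <- feature_groups(features)
sets <- list(slope = "slope", ser = "ser", adc = "adc",
             texture = names(groups)[groups == "texture"],
             combined = trace$final_subset)

report <- build_report(features, features$label, feature_sets = sets,
                       univariate = trace$final_subset,
                       seed = evaluation_seed)
print(report)

write.csv(report$performance, file.path(results_dir, "performance.csv"),
          row.names = FALSE)
write.csv(report$univariate, file.path(results_dir, "univariate.csv"),
          row.names = FALSE)

acc <- sapply(names(sets), function(s) {
  p <- report$performance[report$performance$feature_set == s, ]
  p$accuracy[p$model %in% c("averaged", "univariate_threshold")][1]
})
cat(sprintf("\nCombined accuracy %.1f%% vs best single group %.1f%%\n",
            100 * acc[["combined"]], 100 * max(acc[names(acc) != "combined"])))
cat("Wrote", file.path(results_dir, "performance.csv"), "and univariate.csv\n")
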