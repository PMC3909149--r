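# Stage 3: extract the 28 per-lesion measurements (age; slope and SER; 11
# morphological descriptors; 13 GLCM texture statistics; mean ADC) from the
# segmented lesions, and summarise the per-class separation of a few
# representative features.

source("analysis/00_config.R")

cohort <- generate_cohort(cohort_config)
geoms <- lapply(cohort$cases, function(cs) {
  segment_lesion(cs$images$series, cs$roi_box)
})
features <- assemble_features(cohort, geoms)
write.csv(features, file.path(results_dir, "features.csv"), row.names = FALSE)

reg <- feature_registry()
jsonlite::write_json(reg, file.path(results_dir, "features_schema.json"),
                     auto_unbox = TRUE, digits = NA)

cat("Feature table:", nrow(features), "cases x", ncol(features) - 2, "features\n")
excl <- attr(features, "excluded")
if (nrow(excl)) {
  cat("Excluded cases:", paste(excl$case_id, collapse = ", "), "\n")
}
cat("Univariate separation (AUC, oriented):\n")
for (f in c("slope", "ser", "adc", "age", "heterogeneity", "entropy",
            "spiculation", "circularity")) {
  a <- roc_auc(features[[f]], features$label)
  cat(sprintf("  %-22s %.3f\n", f, max(a, 1 - a)))
}
cat("Wrote", file.path(results_dir, "features.csv"), "\n")
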