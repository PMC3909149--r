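# Stage 1: simulate the phantom cohort.
#
# Generates the default 234-case DCE-MRI/DWI phantom cohort (149 malignant,
# 85 benign, mirroring the reference clinical cohort's composition) and
# writes the ground-truth table. The per-class latent parameters (kinetics,
# ADC, texture, shape, age) are what the downstream stages will try to
# recover.

source("analysis/00_config.R")

cohort <- generate_cohort(cohort_config, render = FALSE)
truth <- cohort$truth

write.csv(truth, file.path(results_dir, "cohort_truth.csv"), row.names = FALSE)

cat("Cohort:", nrow(truth), "cases —",
    sum(truth$label == "malignant"), "malignant,",
    sum(truth$label == "benign"), "benign\n")
cat(sprintf("Mean age: %.1f y (benign %.1f, malignant %.1f)\n",
            mean(truth$age),
            mean(truth$age[truth$label == "benign"]),
            mean(truth$age[truth$label == "malignant"])))
cat(sprintf("Mean true ADC: benign %.2f, malignant %.2f (x1e-3 mm^2/s)\n",
            mean(truth$true_adc[truth$label == "benign"]),
            mean(truth$true_adc[truth$label == "malignant"])))
cat(sprintf("Mean true SER: benign %.2f, malignant %.2f\n",
            mean(truth$true_ser[truth$label == "benign"]),
            mean(truth$true_ser[truth$label == "malignant"])))
cat("Wrote", file.path(results_dir, "cohort_truth.csv"), "\n")
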