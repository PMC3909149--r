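# Shared configuration for the analysis workflow. Run every script from the
# repository root: Rscript analysis/01_simulate_cohort.R etc.
#
# Each numbered script regenerates what it needs deterministically from
# these seeds (the phantom generator is fast), so every stage can be run
# standalone and the whole chain reproduces bit-for-bit.

library(massdx)

ANALYSIS_SEED <- 20260

cohort_config <- phantom_config(seed = ANALYSIS_SEED)
selection_seed <- ANALYSIS_SEED + 1
evaluation_seed <- ANALYSIS_SEED + 2

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)
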