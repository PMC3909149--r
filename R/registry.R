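#' The fixed 28-feature registry
#'
#' Every lesion is characterised by exactly 28 measurements drawn from five
#' groups: one pathology variable (age), two enhancement-kinetic variables
#' (slope, SER), eleven morphological descriptors of the segmented contour,
#' thirteen Haralick texture statistics of the intra-lesion GLCM, and one
#' diffusion variable (mean ADC). The registry fixes canonical column names,
#' group tags and units, plus the aliases under which several features are
#' reported in the clinical literature (e.g. "Energy" for angular second
#' moment, "Inertia" for contrast, "Rectangular degree" for extent).
#'
#' @return A data.frame with columns `name`, `group`, `units`, `alias`
#'   (empty string where the canonical name is the only one in use).
#' @export
feature_registry <- function() {
  df <- rbind(
    data.frame(name = "age", group = "pathology", units = "years", alias = "Age"),
    data.frame(name = c("slope", "ser"), group = "kinetic", units = "ratio",
               alias = c("Slope", "SER")),
    data.frame(
      name = c("compactness", "spiculation", "extent", "elongation", "solidity",
               "circularity", "radial_length_entropy", "fractal_dimension",
               "heterogeneity", "area", "eccentricity"),
      group = "morphology",
      units = c(rep("dimensionless", 9), "mm^2", "dimensionless"),
      alias = c("Compactness", "Spiculation", "Rectangular degree", "Elongation",
                "Solidity", "Circularity", "Entropy of Radial Length Distribution",
                "Fractal dimension", "Heterogeneity", "Area", "Eccentricity")),
    data.frame(
      name = c("asm", "contrast", "correlation", "inverse_difference",
               "sum_average", "sum_variance", "sum_entropy", "entropy",
               "difference_average", "difference_variance", "difference_entropy",
               "info_correlation_1", "info_correlation_2"),
      group = "texture",
      units = "dimensionless",
      alias = c("Energy", "Inertia", "Correlation", "Inverse Difference",
                "Sum Average", "Sum Variance", "Sum entropy", "Entropy",
                "Difference Average", "Difference Variance", "Difference Entropy",
                "Information Correlation 1", "Information Correlation 2")),
    data.frame(name = "adc", group = "dwi", units = "1e-3 mm^2/s", alias = "ADC")
  )
  rownames(df) <- NULL
  df
}

#' Map reported feature names to canonical registry names
#'
#' Accepts canonical names or published aliases, case-insensitively.
#'
#' @param x character vector of feature names.
#' @return character vector of canonical names; unknown names raise an error.
#' @export
canonical_feature_name <- function(x) {
  reg <- feature_registry()
  lut <- c(stats::setNames(reg$name, tolower(reg$name)),
           stats::setNames(reg$name, tolower(reg$alias)))
  key <- tolower(trimws(x))
  miss <- !(key %in% names(lut))
  if (any(miss)) stopf("unknown feature name(s): %s", paste(x[miss], collapse = ", "))
  unname(lut[key])
}

#' Histopathology composition of the reference clinical cohort
#'
#' The benign/malignant counts and per-finding breakdown of the 234-lesion
#' clinical cohort whose composition the phantom generator's defaults
#' emulate (85 benign, 149 malignant). Shipped as plain CSV under
#' `extdata`; percentages are re-derivable from the counts.
#'
#' @return data.frame with columns `group`, `level` (total/subtype),
#'   `finding`, `count`, `reported_percentage`.
#' @export
reference_histopathology <- function() {
  utils::read.csv(system.file("extdata", "cohort_histopathology.csv",
                              package = "massdx"),
                  stringsAsFactors = FALSE)
}

#' Percentage composition from printed counts
#'
#' Recomputes each row's percentage of the total cohort from the raw counts,
#' rounded to two decimals as conventionally printed.
#'
#' @param counts integer vector of per-row lesion counts.
#' @param total total cohort size; defaults to the sum of the totals implied
#'   by `counts` being subtype rows, so usually pass it explicitly.
#' @return numeric vector of percentages (0-100 scale, 2 dp).
#' @export
cohort_composition <- function(counts, total = sum(counts)) {
  if (total <= 0) stopf("total must be positive")
  round(100 * counts / total, 2)
}

#' Reported feature-selection cascade of the reference study
#'
#' The published step-by-step record of the hybrid feature-subset selection
#' on the clinical cohort: which of the 28 features were removed by the
#' t-test filter (step 2), the GA-wrapped SVM search (step 3) and the
#' ablation pass (step 4), and the 7-feature final subset. One step-3 entry
#' was printed twice under the same name in the source table ("Difference
#' Average"); the second occurrence is recorded with canonical name
#' `difference_variance`, the only reading under which the four lists
#' partition the 28-feature registry.
#'
#' @return data.frame with columns `step` (step2/step3/step4/final),
#'   `reported_name`, `canonical_name`, `note`.
#' @export
reference_selection_steps <- function() {
  utils::read.csv(system.file("extdata", "reference_selection_steps.csv",
                              package = "massdx"),
                  stringsAsFactors = FALSE)
}

#' Arithmetic of a selection cascade
#'
#' Given the number of input features and the number removed at each step,
#' returns the implied size after each step and checks consistency with a
#' stated final size.
#'
#' @param n_in features entering the cascade.
#' @param removed integer vector, features removed at each successive step.
#' @return named integer vector of sizes after each step (last = final size).
#' @export
cascade_sizes <- function(n_in, removed) {
  sizes <- n_in - cumsum(removed)
  if (any(sizes < 0)) stopf("cascade removes more features than remain")
  stats::setNames(c(n_in, sizes),
                  c("input", paste0("after_step", seq_along(removed) + 1L)))
}
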