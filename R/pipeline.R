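#' Default end-to-end pipeline configuration
#'
#' A single nested configuration covering every stage: `phantom` (cohort
#' simulation; arguments of [phantom_config()]), `segmentation` (`mode`
#' "snake" for the FCM+GVF scheme or "truth" for planted geometry, plus
#' [snake_params()] fields), `selection` ([selection_config()] fields) and
#' `evaluation` (`k`, `inner_k`, `seed`, `models`). Every stochastic stage
#' carries its own named seed.
#'
#' @param seed base seed; per-stage seeds default to streams derived from
#'   it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    phantom = list(n_cases = 234, malignant_fraction = 149 / 234,
                   image_size = 128, pixel_spacing_mm = 1, b_value_high = 800,
                   seed = child_seed(seed, 1)),
    segmentation = list(mode = "snake", alpha = 0.05, beta = 0.02, gamma = 1,
                        mu = 0.05, gvf_iters = 40, snake_iters = 150,
                        convergence_tol = 0.05, n_vertices = 160, sigma = 1.0,
                        relocate_px = 2.5, relocate_sigma = 0.75),
    selection = list(alpha = 0.05, population_size = 50, generations = 100,
                     crossover_rate = 0.8, mutation_rate = 0.02,
                     elitism_count = 2, tournament_size = 3,
                     fitness_cv_folds = 5, stagnation_limit = 15,
                     ablation_epsilon = 0.005, seed = child_seed(seed, 2)),
    evaluation = list(k = 10, inner_k = 5, seed = child_seed(seed, 3),
                      models = c("svm_rbf", "naive_bayes", "knn", "logistic"))
  )
}

#' Validate a pipeline configuration
#'
#' Checks every stage's invariants and reports all violations at once
#' (never just the first). Unknown keys are errors, so typos cannot pass
#' silently. A missing seed is defaulted with a warning.
#'
#' @param config nested list, or a path to a YAML file holding one.
#' @return the validated config (with defaults filled in); errors carry the
#'   full violation list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  ref <- default_config()
  errs <- character(0)
  bad_stage <- setdiff(names(config), names(ref))
  if (length(bad_stage)) {
    errs <- c(errs, sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")))
  }
  for (stage in intersect(names(config), names(ref))) {
    bad <- setdiff(names(config[[stage]]), names(ref[[stage]]))
    if (length(bad)) {
      errs <- c(errs, sprintf("%s: unknown key(s): %s", stage, paste(bad, collapse = ", ")))
    }
    ref[[stage]] <- utils::modifyList(ref[[stage]],
                                      config[[stage]][setdiff(names(config[[stage]]), bad)])
  }
  cfg <- ref
  ph <- cfg$phantom
  if (!is_count(ph$n_cases) || ph$n_cases < 20) {
    errs <- c(errs, "phantom: n_cases must be an integer >= 20 (10-fold CV infeasible)")
  }
  if (!is_number(ph$malignant_fraction) || ph$malignant_fraction <= 0 ||
      ph$malignant_fraction >= 1) {
    errs <- c(errs, "phantom: malignant_fraction must be in (0,1)")
  }
  if (!is_count(ph$image_size) || ph$image_size < 64) {
    errs <- c(errs, "phantom: image_size must be >= 64")
  }
  sg <- cfg$segmentation
  if (!sg$mode %in% c("snake", "truth")) {
    errs <- c(errs, "segmentation: mode must be 'snake' or 'truth'")
  }
  if (sg$alpha < 0 || sg$beta < 0) errs <- c(errs, "segmentation: alpha, beta must be >= 0")
  if (sg$gamma <= 0) errs <- c(errs, "segmentation: gamma must be > 0")
  sel <- cfg$selection
  if (sel$alpha <= 0 || sel$alpha >= 1) {
    errs <- c(errs, "selection: alpha must be in (0,1) (filter confidence level)")
  }
  if (sel$crossover_rate < 0 || sel$crossover_rate > 1 ||
      sel$mutation_rate < 0 || sel$mutation_rate > 1) {
    errs <- c(errs, "selection: crossover_rate and mutation_rate must be in [0,1]")
  }
  ev <- cfg$evaluation
  if (!is_count(ev$k) || ev$k < 2) errs <- c(errs, "evaluation: k must be >= 2")
  if (!is_count(ev$inner_k) || ev$inner_k < 2) errs <- c(errs, "evaluation: inner_k must be >= 2")
  if (length(errs)) {
    stopf("invalid configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  }
  for (stage in c("phantom", "selection", "evaluation")) {
    if (!is.null(config[[stage]]) && is.null(config[[stage]]$seed)) {
      warnf("%s: no seed supplied; defaulting to %d (recorded in the manifest)",
            stage, as.integer(cfg[[stage]]$seed))
    }
  }
  cfg
}

#' Run the full simulate -> segment -> extract -> select -> evaluate chain
#'
#' Executes every stage in order, writing plain-file artifacts
#' (`features.csv` with a JSON schema sidecar, `trace.json`,
#' `report.json`) and a run manifest (config snapshot, per-stage seeds,
#' package version, file checksums) so a run can be replayed and verified.
#' Any stage failure aborts with a stage-labelled error.
#'
#' @param config nested configuration (see [default_config()]), or a YAML
#'   path.
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return list: `features`, `trace`, `report`, `manifest`, plus the paths
#'   written.
#' @export
run_all <- function(config = default_config(), out_dir = tempfile("massdx_run_"),
                    quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[simulate] generating %d-case phantom cohort (seed %d)",
      cfg$phantom$n_cases, as.integer(cfg$phantom$seed))
  cohort <- do.call(phantom_config, cfg$phantom)
  cohort <- generate_cohort(cohort)

  geometries <- NULL
  if (cfg$segmentation$mode == "snake") {
    say("[segment] FCM + GVF snake segmentation of %d cases", length(cohort$cases))
    sp <- do.call(snake_params,
                  cfg$segmentation[setdiff(names(cfg$segmentation), "mode")])
    geometries <- lapply(cohort$cases, function(cs) {
      tryCatch(segment_lesion(cs$images$series, cs$roi_box, sp),
               error = function(e) stopf("[segment] %s: %s", cs$case_id,
                                         conditionMessage(e)))
    })
  } else {
    say("[segment] using ground-truth geometry (mode = 'truth')")
  }

  say("[extract] assembling the 28-feature table")
  features <- assemble_features(cohort, geometries)
  features_path <- file.path(out_dir, "features.csv")
  utils::write.csv(features, features_path, row.names = FALSE)
  reg <- feature_registry()
  jsonlite::write_json(reg, file.path(out_dir, "features_schema.json"),
                       auto_unbox = TRUE, digits = NA)

  say("[select] hybrid t-test / GA-SVM / ablation feature selection")
  sel_cfg <- do.call(selection_config, cfg$selection)
  trace <- run_hybrid_fss(features, features$label, sel_cfg)
  trace_path <- file.path(out_dir, "trace.json")
  jsonlite::write_json(
    list(removed_step2 = trace$removed_step2,
         removed_step3 = trace$removed_step3,
         removed_step4 = trace$removed_step4,
         final_subset = trace$final_subset,
         counts = as.list(trace$counts),
         p_values = as.list(trace$p_values)),
    trace_path, auto_unbox = TRUE, digits = NA)

  say("[evaluate] cross-validated performance of feature sets")
  groups <- feature_groups(features)
  sets <- list(slope = "slope", ser = "ser", adc = "adc",
               texture = intersect(trace$final_subset,
                                   names(groups)[groups == "texture"]))
  if (length(sets$texture) < 2) sets$texture <- names(groups)[groups == "texture"]
  sets$combined <- trace$final_subset
  report <- build_report(features, features$label, feature_sets = sets,
                         univariate = trace$final_subset,
                         k = cfg$evaluation$k, inner_k = cfg$evaluation$inner_k,
                         seed = cfg$evaluation$seed,
                         models = cfg$evaluation$models)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(univariate = report$univariate, performance = report$performance,
         seed = report$seed),
    report_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  paths <- c(features = features_path, trace = trace_path, report = report_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("massdx")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = cfg,
    seeds = list(phantom = cfg$phantom$seed, selection = cfg$selection$seed,
                 evaluation = cfg$evaluation$seed),
    checksums = as.list(stats::setNames(tools::md5sum(paths), names(paths)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  say("[done] artifacts in %s", out_dir)
  list(features = features, trace = trace, report = report,
       manifest = manifest,
       paths = c(paths, manifest = manifest_path))
}
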