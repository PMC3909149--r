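# Shared fixtures, built once per test session and memoised; all seeded.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small rendered cohort for feature-level tests.
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(phantom_config(n_cases = 24, seed = 401))
  })
}

# A full-size cohort with its feature table (truth geometry), for selection
# and evaluation tests.
full_cohort_features <- function() {
  fixture("full_cohort_features", function() {
    co <- generate_cohort(phantom_config(seed = 402))
    ft <- suppressMessages(assemble_features(co))
    list(cohort = co, features = ft)
  })
}

# Full-pipeline run (simulate -> segment -> extract -> select -> evaluate)
# on the default-size cohort; shared by the end-to-end acceptance checks.
acceptance_cohort_run <- function() {
  fixture("acceptance_cohort_run", function() {
    cfg <- phantom_config(seed = 42)
    co <- generate_cohort(cfg)
    n <- cfg$image_size
    geoms <- lapply(co$cases, function(cs) {
      segment_lesion(cs$images$series, cs$roi_box)
    })
    dices <- mapply(function(g, cs) {
      dice_coefficient(g$mask, massdx:::rasterize_polygon(cs$true_contour, c(n, n)))
    }, geoms, co$cases)
    ft <- suppressMessages(assemble_features(co, geoms))
    tr <- run_hybrid_fss(ft, ft$label, selection_config(seed = 43))
    groups <- feature_groups(ft)
    sets <- list(slope = "slope", ser = "ser", adc = "adc",
                 texture = names(groups)[groups == "texture"],
                 combined = tr$final_subset)
    rep_ <- build_report(ft, ft$label, sets, univariate = tr$final_subset,
                         seed = 44)
    perf <- rep_$performance
    acc <- vapply(names(sets), function(s) {
      p <- perf[perf$feature_set == s, ]
      p$accuracy[p$model %in% c("averaged", "univariate_threshold")][1]
    }, numeric(1))
    list(features = ft, trace = tr, report = rep_,
         set_accuracy = acc, dice_median = median(dices))
  })
}

# Noiseless disk phantom: polygon, mask and images, for closed-form checks.
disk_case <- function(radius = 20, n = 96, si = c(100, 250, 175),
                      s0 = 1000, adc = 1.5) {
  theta <- seq(0, 2 * pi, length.out = 129)[-129]
  ctr <- n / 2 - 0.5
  poly <- cbind(r = ctr + radius * sin(theta), c = ctr + radius * cos(theta))
  mask <- massdx:::rasterize_polygon(poly, c(n, n))
  frame <- function(inside, outside = 100) {
    img <- matrix(outside, n, n); img[mask] <- inside; img
  }
  b <- 800
  list(poly = poly, mask = mask,
       series = list(pre = frame(si[1]), first = frame(si[2]), last = frame(si[3])),
       dwi = list(b0 = frame(s0, 300),
                  bhigh = frame(s0, 300) * exp(-b * 1e-3 * frame(adc, 2.2)),
                  b_value = b),
       roi_box = c(r0 = 2, c0 = 2, r1 = n - 3, c1 = n - 3))
}
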