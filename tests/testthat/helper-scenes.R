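# Shared fixtures, built once per test run. The "demo" scene is noiseless
# and cloud-free (the separable fixture world); tests that need noise or
# clouds build their own small scenes.

.fixtures <- new.env(parent = emptyenv())

demo_scene <- function() {
  if (is.null(.fixtures$scene)) {
    .fixtures$scene <- simulate_scene(
      rows = 50, cols = 50, n_municipalities = 8, n_biomes = 2,
      n_ecoregions = 3, n_samples = 80,
      phenology = default_phenology(noise_sd = 0, cloud_prob = 0),
      seed = 11
    )
  }
  .fixtures$scene
}

demo_classification <- function() {
  if (is.null(.fixtures$classified)) {
    .fixtures$classified <- run_classification(
      demo_scene(), classifier_config(n_trees = 499), seed = 11
    )
  }
  .fixtures$classified
}

# truth maps grouped to the 5-class integer codes
truth_map5 <- function(cover) {
  apply(cover$labels, 2, function(l) {
    class5_code(group_to_five(cover_classes8()[l]))
  })
}

# named percent vector helper
pct <- function(...) {
  v <- c(...)
  full <- stats::setNames(numeric(7), pct_categories())
  full[names(v)] <- v
  full
}

# one interpretation row (list form) for consensus()
interp <- function(sample_id, year, ...) {
  p <- pct(...)
  c(list(sample_id = sample_id, year = year),
    stats::setNames(as.list(p), paste0("pct_", names(p))))
}

# brute-force oracle for window statistics: filter then compute naively
oracle_window_stats <- function(values, flags) {
  v <- values[flags != 3]
  if (length(v) < 3) return(stats::setNames(rep(NA_real_, 5),
                                            c("mean", "sd", "min", "max", "range")))
  c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
    range = max(v) - min(v))
}
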