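# Shared fixtures. Everything is generated in code; the expensive planted
# cohort (46/55 subjects, 180 s) is built once per session and memoized for
# the acceptance-level experiments.

.fixture_cache <- new.env(parent = emptyenv())

planted_feature_names <- function() {
  c("F3-C3_alpha", "P4-T6_alpha", "F3-F4_theta", "C3-C4_theta", "P3-P4_delta")
}

planted_cohort_features <- function() {
  if (is.null(.fixture_cache$planted_feats)) {
    spec <- cohort_spec(seed = 101)  # defaults: 46/55, 180 s, 0.6 vs 0.2
    cohort <- generate_cohort(spec)
    .fixture_cache$planted_feats <- build_feature_matrix(cohort)
  }
  .fixture_cache$planted_feats
}

# Gaussian feature matrix with a planted mean shift on selected columns:
# cheap stand-in for search-behaviour tests that do not need EEG structure.
make_planted_matrix <- function(n1 = 30, n2 = 30, n_features = 48,
                                informative = 1:5, delta = 2, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  X <- matrix(rnorm(n * n_features), n, n_features)
  labels <- rep(c("A", "B"), c(n1, n2))
  X[labels == "A", informative] <- X[labels == "A", informative] + delta
  colnames(X) <- paste0("f", seq_len(n_features))
  as_coherence_features(X, labels)
}

# Fast evaluator for search unit tests: nearest-class-centroid accuracy on a
# fixed stratified holdout. Orders of magnitude cheaper than an SVM fit.
make_centroid_evaluator <- function(X, y, seed = 1) {
  y <- factor(y)
  folds <- stratified_folds(y, 5, seed = seed)
  val <- folds[[1]]
  tr <- setdiff(seq_len(nrow(X)), val)
  Xtr <- X[tr, , drop = FALSE]
  Xval <- X[val, , drop = FALSE]
  ytr <- y[tr]
  yval <- y[val]
  lv <- levels(y)
  function(subset, ...) {
    a <- Xtr[, subset, drop = FALSE]
    b <- Xval[, subset, drop = FALSE]
    m1 <- colMeans(a[ytr == lv[1], , drop = FALSE])
    m2 <- colMeans(a[ytr == lv[2], , drop = FALSE])
    d1 <- rowSums(sweep(b, 2, m1)^2)
    d2 <- rowSums(sweep(b, 2, m2)^2)
    mean(ifelse(d1 < d2, lv[1], lv[2]) == as.character(yval))
  }
}

# One-effect cohort spec for coherence-oracle checks.
one_effect_spec <- function(target, band = "alpha", pair = c("F3", "C3"),
                            duration_s = 180, noise_sd = 1, seed = 1) {
  em <- if (target > 0)
    list(list(pair = pair, band = band,
              target = c(BD = target, MDD = target)))
  else list()
  cohort_spec(n_per_class = c(1, 1), duration_s = duration_s,
              effect_map = em, noise_sd = noise_sd, seed = seed)
}

# Band MSC of one generated pair, through the package's estimator chain.
generated_band_msc <- function(spec, pair = c("F3", "C3"), band = "alpha",
                               seed = 1, label = "BD") {
  rec <- eeg_bandpass(synthesize_recording(spec, label, seed))
  wx <- segment_windows(rec$data[pair[1], ], rec$fs)
  wy <- segment_windows(rec$data[pair[2], ], rec$fs)
  cs <- magnitude_squared_coherence(spectral_estimates(wx, wy, rec$fs))
  band_coherence(cs, default_bands()[[band]])
}

# Small, fast nested-CV configuration for structural tests.
tiny_cv_config <- function(seed = 1, outer_k = 3, inner_k = 3,
                           k_range = c(2, 6)) {
  cv_config(outer_k = outer_k, inner_k = inner_k,
            colony = colony_config(n_ants = 5, n_iter = 5,
                                   subset_size_range = k_range),
            ga = ga_config(pop_size = 6, n_iter = 5),
            pso = pso_config(n_particles = 6, n_iter = 5),
            seed = seed)
}
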