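# Shared small-scale synthetic world and lazily trained models.
#
# Unit tests run on a 300-channel grid with 30 spectra per bag so that the
# scorer networks train in seconds; the acceptance tests use the full
# desk-scale world (900 channels, 100 spectra per bag).

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env))
    assign(key, force(expr), envir = fixture_env)
  get(key, envir = fixture_env)
}

small_cohort_config <- function(n_per_class, spectra = 30L, seed = 101L,
                                class_amplitude = 150, witness_rate = 0.5,
                                noise_sd = 15, intensity_cv = 0.06,
                                anomaly_rate = 0.02, spike_rate = 0.03,
                                channels = 300L) {
  cohort_config(
    n_per_class = n_per_class, spectra_per_sample = spectra,
    grid = c(600, 1800, channels),
    anomaly_rate = anomaly_rate, spike_rate = spike_rate, seed = seed,
    signatures = default_signatures(class_amplitude = class_amplitude,
                                    witness_rate = witness_rate,
                                    noise_sd = noise_sd,
                                    intensity_cv = intensity_cv))
}

# A noise-free, jitter-free signature for closed-form checks.
exact_signature <- function(class_name = "HC",
                            common_peaks = peaks_df(numeric(0), numeric(0),
                                                    numeric(0)),
                            class_peaks = peaks_df(numeric(0), numeric(0),
                                                   numeric(0)),
                            witness_rate = 0, b0 = 0) {
  class_signature(
    class_name, common_peaks, class_peaks, witness_rate = witness_rate,
    baseline_params = list(b0 = b0, slope = 0, hump_center = 1100,
                           hump_width = 300, hump_amp = 0, jitter = 0),
    noise_sd = 0, intensity_cv = 0)
}

peaks_df <- function(center, width, amplitude) {
  data.frame(center = center, width = width, amplitude = amplitude)
}

# Bare bag from an intensity matrix (for scorer-level tests).
make_bag <- function(mat, wavenumbers, class = "HC", id = "toy",
                     split = "train") {
  structure(
    list(sample_id = id, true_class = class,
         stage = if (class == "HC") "none" else "advanced", split = split,
         wavenumbers = wavenumbers, intensities = mat,
         spot_index = seq_len(nrow(mat)), witness = rep(FALSE, nrow(mat)),
         spike = rep(FALSE, nrow(mat)), anomalous = rep(FALSE, nrow(mat))),
    class = "sample_bag")
}

# Strong-effect small world: 7 classes x 16 bags (8 train / 8 test),
# preprocessed with a training-derived threshold.
small_world <- function() memo("small_world", {
  cfg <- small_cohort_config(
    n_per_class = stats::setNames(rep(16L, 7L), all_classes()))
  bags <- generate_cohort(cfg)
  cls <- vapply(bags, function(b) b$true_class, "")
  for (cl in unique(cls)) {
    ix <- which(cls == cl)
    for (i in ix[1:8]) bags[[i]]$split <- "train"
    for (i in ix[9:16]) bags[[i]]$split <- "test"
  }
  pp <- preprocess_cohort(bags, preprocess_config())
  list(cfg = cfg, bags = pp$bags, reports = pp$reports,
       threshold = pp$threshold,
       train = pp$bags[vapply(pp$bags, function(b) b$split, "") == "train"],
       test = pp$bags[vapply(pp$bags, function(b) b$split, "") == "test"])
})

small_presence <- function() memo("small_presence", {
  w <- small_world()
  m <- build_presence_classifier(arch_config(), n_channels = 300L, seed = 7L)
  train_presence(m, w$train, train_config(epochs = 4L, seed = 7L))
})

small_too <- function() memo("small_too", {
  w <- small_world()
  cancer <- w$train[vapply(w$train, function(b) b$true_class, "") != "HC"]
  train_one_vs_rest(cancer, arch_config(),
                    train_config(epochs = 3L, seed = 11L))
})
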