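# Condition every spectrum (despike, baseline, denoise), set the anomaly
# threshold from the training split, filter and normalize; then compute the
# cancer-minus-control difference spectrum on the training split.
#
# Outputs: results/qc_summary.csv, results/difference_spectrum.csv.

source("analysis/00_config.R")

bags <- readRDS(cache_path("cohort_raw"))
pp <- preprocess_cohort(bags, cfg$preprocess)

qc <- data.frame(
  n_input = sum(vapply(pp$reports, function(r) r$n_input, 0)),
  n_removed_anomalous = sum(vapply(pp$reports,
                                   function(r) r$n_removed_anomalous, 0)),
  n_despiked = sum(vapply(pp$reports, function(r) r$n_despiked, 0)),
  threshold = pp$threshold)
write.csv(qc, "results/qc_summary.csv", row.names = FALSE)
saveRDS(pp, cache_path("cohort_preprocessed"))

cat(sprintf("QC: %d spectra in, %d anomalous removed, %d despiked (thr %.1f)\n",
            qc$n_input, qc$n_removed_anomalous, qc$n_despiked, qc$threshold))

# Difference spectrum (mean cancer minus mean HC, training split): its
# positive excursions localize the cancer-common Raman bands.
train <- pp$bags[vapply(pp$bags, function(b) b$split, "") == "train"]
is_hc <- vapply(train, function(b) b$true_class, "") == "HC"
mat_of <- function(bl) do.call(rbind, lapply(bl, function(b) b$intensities))
d <- difference_spectrum(mat_of(train[!is_hc]), mat_of(train[is_hc]),
                         wavenumbers = train[[1]]$wavenumbers)
write.csv(data.frame(wavenumber = d$wavenumbers,
                     difference = d$intensities),
          "results/difference_spectrum.csv", row.names = FALSE)
top <- order(d$intensities, decreasing = TRUE)[1:8]
cat("strongest cancer-minus-HC bands near:",
    paste(round(sort(d$wavenumbers[top])), collapse = ", "), "cm^-1\n")
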