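# Signal conditioning: despiking, baseline, denoising, QC filtering.

grid300 <- seq(600, 1800, length.out = 300)

clean_peaks <- function(grid) {
  1000 / (1 + ((grid - 860) / 18)^2) + 400 / (1 + ((grid - 1283) / 22)^2) +
    150 / (1 + ((grid - 1001) / 8)^2)
}

test_that("despiking removes delta spikes and is idempotent", {
  cfg <- preprocess_config()
  clean <- raman_spectrum(grid300, clean_peaks(grid300))
  # spike-free smooth spectrum passes through unchanged
  expect_equal(despike(clean, cfg)$intensities, clean$intensities)

  # 50x local-level delta spike: restored near the clean value, neighbours
  # untouched
  spiked <- clean
  ch <- 140L
  spiked$intensities[ch] <- 50 * spiked$intensities[ch]
  fixed <- despike(spiked, cfg)
  local_sd <- sd(clean$intensities[(ch - 10):(ch + 10)])
  expect_lt(abs(fixed$intensities[ch] - clean$intensities[ch]), 3 * local_sd)
  expect_identical(fixed$intensities[-ch], spiked$intensities[-ch])

  # idempotence, channel-wise
  expect_identical(despike(fixed, cfg)$intensities, fixed$intensities)

  # window must fit
  short <- raman_spectrum(1:5, rep(1, 5))
  expect_error(despike(short, preprocess_config(despike_window = 7L)),
               "window")
})

test_that("baseline correction removes smooth backgrounds, keeps peaks", {
  cfg <- preprocess_config()
  peaks <- clean_peaks(grid300)

  # nothing to remove: output within 1 % of max amplitude
  out <- correct_baseline(raman_spectrum(grid300, peaks), cfg)
  expect_lt(max(abs(out$intensities - peaks)), 0.01 * max(peaks) + 25)

  # known linear baseline: residual background < 5 % of max peak amplitude
  base <- 200 + 0.3 * (grid300 - 600)
  out <- correct_baseline(raman_spectrum(grid300, peaks + base), cfg)
  resid <- out$intensities - peaks
  expect_lt(max(abs(resid)), 0.05 * max(peaks))
  # peak position unchanged
  expect_equal(which.max(out$intensities), which.max(peaks))

  # flat constant spectrum -> ~0 everywhere
  out <- correct_baseline(raman_spectrum(grid300, rep(300, 300)), cfg)
  expect_lt(max(abs(out$intensities)), 1e-6 * 300)

  bad <- raman_spectrum(grid300, c(rep(1, 299), NA))
  expect_error(correct_baseline(bad, cfg), "finite")
})

test_that("Savitzky-Golay denoising reproduces low-order polynomials and
           reduces noise", {
  cfg <- preprocess_config(denoise_window = 9L, denoise_polyorder = 3L)
  x <- seq_len(300)
  quad <- raman_spectrum(grid300, 3 + 0.2 * x + 0.01 * x^2)
  expect_equal(denoise(quad, cfg)$intensities, quad$intensities,
               tolerance = 1e-9)

  flat <- raman_spectrum(grid300, rep(7, 300))
  expect_equal(denoise(flat, cfg)$intensities, flat$intensities,
               tolerance = 1e-12)

  clean <- clean_peaks(grid300)
  set.seed(8)
  noisy <- raman_spectrum(grid300, clean + rnorm(300, 0, 20))
  sm <- denoise(noisy, cfg)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(sm$intensities - clean), rms(noisy$intensities - clean))

  expect_error(preprocess_config(denoise_window = 5L, denoise_polyorder = 5L),
               "polyorder")
})

test_that("band intensity is the windowed maximum", {
  flat <- raman_spectrum(grid300, rep(42, 300))
  expect_equal(band_intensity(flat, 860, 15), 42)

  peak <- raman_spectrum(grid300, 90 / (1 + ((grid300 - 860) / 15)^2))
  expect_lt(abs(band_intensity(peak, 860, 15) - 90), 0.01 * 90)
  # off-peak window sees only the tail
  expect_lt(band_intensity(peak, 1700, 15), 2)

  expect_error(band_intensity(flat, 5000, 10), "intersect")
})

test_that("anomaly filtering partitions the bag and recovers injected flags", {
  cfg <- small_cohort_config(c(lung = 1), spectra = 100L,
                             anomaly_rate = 0.08, spike_rate = 0)
  set.seed(21)
  bag <- generate_sample_bag("lung", "early", cfg, "l1")
  pcfg <- preprocess_config()
  b <- sersmil:::band_intensity_rows(bag$intensities, bag$wavenumbers,
                                     860, 15)
  stopifnot(sum(bag$anomalous) > 0)
  # threshold in the gap between anomalous and normal band levels
  thr <- (max(b[bag$anomalous]) + min(b[!bag$anomalous])) / 2
  res <- filter_anomalies(bag, thr, pcfg)
  expect_equal(n_spectra(res$bag) + res$report$n_removed_anomalous,
               res$report$n_input)
  # recall and precision both 1 against generator ground truth
  removed <- setdiff(bag$spot_index, res$bag$spot_index)
  expect_setequal(removed, bag$spot_index[bag$anomalous])

  # boundary cases
  expect_equal(filter_anomalies(bag, 0, pcfg)$report$n_removed_anomalous, 0L)
  allgone <- filter_anomalies(bag, max(b) + 1, pcfg)
  expect_equal(n_spectra(allgone$bag), 0L)
  expect_error(filter_anomalies(allgone$bag, 0, pcfg), "empty")
  # strict inequality: a spectrum exactly at the threshold is removed
  at <- filter_anomalies(bag, max(b), pcfg)
  expect_equal(n_spectra(at$bag), 0L)
})

test_that("preprocess_bag applies the full pipeline in order with true QC
           counts", {
  cfg <- small_cohort_config(c(breast = 1), spectra = 60L,
                             anomaly_rate = 0.1, spike_rate = 0.1)
  set.seed(33)
  bag <- generate_sample_bag("breast", "early", cfg, "b1")
  # a 25th-percentile threshold sits safely above the ~10 % anomalous
  # low-signal cluster, so every injected anomaly must be removed
  pcfg <- preprocess_config(qc_threshold_percentile = 25)
  res <- preprocess_bag(bag, pcfg)
  # unit-vector normalization holds exactly
  expect_equal(sqrt(rowSums(res$bag$intensities^2)),
               rep(1, n_spectra(res$bag)), tolerance = 1e-9)
  # every generator-injected anomaly is removed (the 5th-percentile default
  # threshold may additionally clip weak normal spectra; recall must be 1)
  kept <- res$bag$spot_index
  expect_length(intersect(kept, bag$spot_index[bag$anomalous]), 0L)
  # all spiked spectra were repaired
  expect_gte(res$report$n_despiked, sum(bag$spike & !bag$anomalous))
  expect_equal(res$report$n_input, 60L)

  # determinism
  res2 <- preprocess_bag(bag, pcfg)
  expect_identical(res$bag$intensities, res2$bag$intensities)
})

test_that("difference spectra localize the injected cancer bands", {
  grid <- seq(600, 1800, length.out = 400)
  sigs <- default_signatures(noise_sd = 0)
  set.seed(2)
  hc <- lapply(1:5, function(i) generate_spectrum(sigs$HC, grid))
  ca <- lapply(1:5, function(i)
    generate_spectrum(sigs$stomach, grid, carry_class_peaks = TRUE))
  d <- difference_spectrum(ca, hc)
  # positive excursions at the stomach-specific band centres
  for (ctr in c(1378, 1432))
    expect_gt(d$intensities[which.min(abs(grid - ctr))], 50)

  # identical groups cancel exactly
  z <- difference_spectrum(hc, hc)
  expect_equal(z$intensities, rep(0, 400))

  # two singleton groups equal element-wise subtraction
  d2 <- difference_spectrum(ca[1], hc[1])
  expect_equal(d2$intensities, ca[[1]]$intensities - hc[[1]]$intensities)

  other <- raman_spectrum(seq(600, 1800, length.out = 401), rep(1, 401))
  expect_error(difference_spectrum(list(other), hc), "grid")
})
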