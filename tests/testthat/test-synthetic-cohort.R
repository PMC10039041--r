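# Synthetic SERS cohort generator.

test_that("spectrum generation matches the closed-form line-shape model", {
  grid <- seq(600, 1800, length.out = 300)
  # no components: constant trace at the flat baseline level
  set.seed(1)
  sp <- generate_spectrum(exact_signature(b0 = 120), grid)
  expect_equal(sp$intensities, rep(120, 300))

  # a single Lorentzian peak, zero baseline/noise: closed form on the grid
  sig <- exact_signature(common_peaks = peaks_df(1000, 12, 80))
  set.seed(1)
  sp <- generate_spectrum(sig, grid)
  oracle <- 80 / (1 + ((grid - 1000) / 12)^2)
  expect_equal(sp$intensities, oracle, tolerance = 1e-12)
  # the channel nearest the centre reaches the amplitude up to the
  # discretization bound a * (delta/2w)^2 of the Lorentzian
  ch <- which.min(abs(grid - 1000))
  delta <- (grid[2] - grid[1]) / 2
  expect_lt(abs(sp$intensities[ch] - 80), 80 * (delta / 12)^2 + 1e-9)

  # every default class carries the strong 860 band above nearby background
  sigs <- default_signatures(noise_sd = 0)
  for (cls in all_classes()) {
    set.seed(2)
    sp <- generate_spectrum(sigs[[cls]], grid, carry_class_peaks = TRUE)
    expect_gt(band_intensity(sp, 860, 10),
              band_intensity(sp, 790, 10))
  }

  # peak outside the grid is a configuration error
  bad <- exact_signature(common_peaks = peaks_df(200, 10, 5))
  expect_error(generate_spectrum(bad, grid), "outside")
})

test_that("sample bags respect witness draws, rates and seeded determinism", {
  cfg <- small_cohort_config(c(HC = 1, lung = 1), spectra = 25L)
  set.seed(5)
  hc <- generate_sample_bag("HC", "none", cfg, "h1")
  expect_false(any(hc$witness))
  expect_equal(n_spectra(hc), 25L)

  # witness_rate 1: every spectrum carries class peaks; same seed, same bag
  cfg1 <- small_cohort_config(c(lung = 1), witness_rate = 1)
  set.seed(9); b1 <- generate_sample_bag("lung", "early", cfg1, "l1")
  set.seed(9); b2 <- generate_sample_bag("lung", "early", cfg1, "l1")
  expect_true(all(b1$witness))
  expect_identical(b1$intensities, b2$intensities)

  # flag draws reproduce the seeded Bernoulli stream (witness, spike, anomaly)
  cfg2 <- small_cohort_config(c(lung = 1), spectra = 100L,
                              anomaly_rate = 0.05, spike_rate = 0.03)
  set.seed(31)
  wit <- runif(100) < 0.5
  spk <- runif(100) < 0.03
  ano <- runif(100) < 0.05
  set.seed(31)
  b <- generate_sample_bag("lung", "advanced", cfg2, "l2")
  expect_identical(b$witness, wit)
  expect_identical(b$spike, spk)
  expect_identical(b$anomalous, ano)
  expect_equal(sum(b$anomalous), sum(ano))

  cfg3 <- small_cohort_config(c(lung = 1), anomaly_rate = 0)
  set.seed(3)
  expect_false(any(generate_sample_bag("lung", "early", cfg3)$anomalous))

  expect_error(generate_sample_bag("oesophageal", "early", cfg),
               "unknown class")
  expect_error(generate_sample_bag("lung", "none", cfg), "stage")
})

test_that("anomaly injection suppresses the 860 band below normal levels", {
  grid <- seq(600, 1800, length.out = 300)
  sigs <- default_signatures()
  set.seed(4)
  sp <- generate_spectrum(sigs$HC, grid)
  normal_level <- band_intensity(sp, 860)
  set.seed(4)
  bad <- inject_anomaly(sp)
  expect_lt(band_intensity(bad, 860), 0.1 * normal_level)
  expect_true("anomalous_low_signal" %in% bad$qc_flags)
})

test_that("cohorts have exact class counts, stages and byte-level determinism", {
  # the study-shaped test split: 160 HC + 100+70+70+40+40+40 cancer = 520 bags
  counts <- c(HC = 160L, lung = 100L, breast = 70L, colorectal = 70L,
              liver = 40L, pancreatic = 40L, stomach = 40L)
  cfg <- small_cohort_config(counts, spectra = 2L, channels = 200L,
                             seed = 77L)
  bags <- generate_cohort(cfg)
  expect_length(bags, 520L)
  cls <- vapply(bags, function(b) b$true_class, "")
  expect_equal(as.list(table(cls))[names(counts)], as.list(as.integer(counts)),
               ignore_attr = TRUE)
  # early_fraction of each cancer class's bags labelled early
  stage <- vapply(bags, function(b) b$stage, "")
  expect_equal(sum(stage == "early" & cls == "lung"), round(0.5 * 100))
  expect_true(all(stage[cls == "HC"] == "none"))

  expect_identical(generate_cohort(cfg), bags)

  # empty cohort
  cfg0 <- small_cohort_config(c(HC = 0L, lung = 0L))
  expect_length(generate_cohort(cfg0), 0L)
})

test_that("witness rate and intensity CV are recovered from generated bags", {
  # witness fraction over many bags within 3 binomial standard errors
  cfg <- small_cohort_config(c(lung = 1), spectra = 50L, witness_rate = 0.5)
  set.seed(12)
  fr <- replicate(40, mean(generate_sample_bag("lung", "early", cfg)$witness))
  se <- sqrt(0.5 * 0.5 / (50 * 40))
  expect_lt(abs(mean(fr) - 0.5), 3 * se)

  # with zero additive noise, the 860-band CV across a bag ~ intensity_cv
  cfg_cv <- small_cohort_config(c(HC = 1), spectra = 200L, noise_sd = 0,
                                intensity_cv = 0.06, anomaly_rate = 0,
                                spike_rate = 0)
  set.seed(13)
  b <- generate_sample_bag("HC", "none", cfg_cv)
  cv <- coefficient_of_variation(
    sersmil:::band_intensity_rows(b$intensities, b$wavenumbers, 860, 15))
  expect_lt(abs(cv - 6), 1.5)
})

test_that("cohort CSV round-trip preserves spectra and the manifest", {
  cfg <- small_cohort_config(c(HC = 2, liver = 1), spectra = 5L,
                             channels = 40L, seed = 3L)
  # 40-channel grid stops at 1800 but signature peaks fit inside 600..1800
  bags <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(bags, dir)
  back <- read_cohort(dir)
  expect_length(back, 3L)
  expect_equal(back[[3]]$true_class, "liver")
  expect_equal(back[[1]]$intensities, bags[[1]]$intensities,
               tolerance = 1e-8)
  expect_equal(back[[2]]$wavenumbers, bags[[2]]$wavenumbers,
               tolerance = 1e-8)
})
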