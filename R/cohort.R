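# Synthetic SERS cohort generator: seeded bags of spectra with ground truth.

#' Cohort configuration
#'
#' @param n_per_class Named integer vector of bag counts per class; names must
#'   be a subset of [all_classes()].
#' @param spectra_per_sample Spectra acquired per sample (default 100, the
#'   10 x 10 acquisition grid).
#' @param grid `c(min_wavenumber, max_wavenumber, n_channels)`; default
#'   600-1800 cm^-1 over 900 channels.
#' @param anomaly_rate Fraction of spectra replaced by low-signal anomalies.
#' @param spike_rate Fraction of spectra receiving one cosmic-ray spike.
#' @param early_fraction Fraction of each cancer class's bags labelled
#'   early-stage.
#' @param seed Integer seed; the whole cohort is a pure function of the config.
#' @param signatures Named list of [class_signature()] objects registering the
#'   generative phenotype of every class in `n_per_class`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(HC = 30, breast = 30,
                                          colorectal = 30, liver = 30,
                                          lung = 30, pancreatic = 30,
                                          stomach = 30),
                          spectra_per_sample = 100L,
                          grid = c(600, 1800, 900),
                          anomaly_rate = 0.02,
                          spike_rate = 0.03,
                          early_fraction = 0.5,
                          seed = 1L,
                          signatures = default_signatures()) {
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% all_classes()))
    stop("n_per_class must be named by classes in all_classes()")
  if (any(n_per_class < 0)) stop("bag counts must be >= 0")
  if (spectra_per_sample < 1) stop("need at least one spectrum per sample")
  if (length(grid) != 3 || grid[1] >= grid[2] || grid[3] < 2)
    stop("grid must be c(min, max, n_channels) with min < max, n >= 2")
  for (r in c(anomaly_rate, spike_rate, early_fraction))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  cfg <- structure(
    list(n_per_class = n_per_class,
         spectra_per_sample = as.integer(spectra_per_sample),
         grid = grid,
         anomaly_rate = anomaly_rate,
         spike_rate = spike_rate,
         early_fraction = early_fraction,
         seed = as.integer(seed),
         signatures = signatures),
    class = "cohort_config")
  # Grid closure: every configured peak centre must lie inside the grid.
  w <- cohort_grid(cfg)
  for (cls in names(n_per_class)) {
    if (n_per_class[[cls]] == 0) next
    sig <- signatures[[cls]]
    if (is.null(sig)) stop("no registered signature for class ", cls)
    ctrs <- c(sig$common_peaks$center, sig$class_peaks$center)
    if (length(ctrs) && (any(ctrs < min(w)) || any(ctrs > max(w))))
      stop("peak center outside the wavenumber grid for class ", cls)
  }
  cfg
}

#' @rdname cohort_config
#' @export
cohort_grid <- function(config) {
  seq(config$grid[1], config$grid[2], length.out = config$grid[3])
}

lorentzian <- function(w, center, width, amplitude) {
  amplitude / (1 + ((w - center) / width)^2)
}

# Sum of Lorentzian profiles over the grid.
peak_profile <- function(w, peaks) {
  y <- numeric(length(w))
  if (!nrow(peaks)) return(y)
  for (i in seq_len(nrow(peaks)))
    y <- y + lorentzian(w, peaks$center[i], peaks$width[i], peaks$amplitude[i])
  y
}

baseline_profile <- function(w, bp, jitter_draws = c(0, 0, 0)) {
  span <- diff(range(w))
  x <- (w - min(w)) / span
  b0 <- bp$b0 * (1 + bp$jitter * jitter_draws[1])
  slope <- bp$slope * (1 + bp$jitter * jitter_draws[2])
  hump <- bp$hump_amp * (1 + bp$jitter * jitter_draws[3])
  b0 + slope * x + hump * exp(-0.5 * ((w - bp$hump_center) / bp$hump_width)^2)
}

#' Generate a single synthetic spectrum
#'
#' Intensities are `(baseline + sum of Lorentzian peaks) * scale + noise`,
#' clipped at zero. `class_peaks` are included iff `carry_class_peaks`.
#' Draws come from the current R random stream; seed upstream for determinism.
#'
#' @param signature A [class_signature()].
#' @param grid Numeric wavenumber grid (strictly increasing).
#' @param carry_class_peaks Logical: is this a witness spectrum?
#' @param sample_id,spot_index Metadata forwarded to the spectrum.
#' @return A [raman_spectrum()].
#' @export
generate_spectrum <- function(signature, grid, carry_class_peaks = FALSE,
                              sample_id = NA_character_,
                              spot_index = NA_integer_) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  pk <- signature$common_peaks
  if (carry_class_peaks) pk <- rbind(pk, signature$class_peaks)
  if (nrow(pk) && (any(pk$center < min(grid)) || any(pk$center > max(grid))))
    stop("peak center outside the wavenumber grid")
  jit <- runif(3, -1, 1)
  base <- baseline_profile(grid, signature$baseline_params, jit)
  scale <- max(rnorm(1, 1, signature$intensity_cv), 0.05)
  y <- (base + peak_profile(grid, pk)) * scale
  if (signature$noise_sd > 0) y <- y + rnorm(length(grid), 0, signature$noise_sd)
  raman_spectrum(grid, pmax(y, 0), sample_id = sample_id,
                 spot_index = spot_index)
}

#' Suppress a spectrum into a low-signal anomaly
#'
#' Rescales the trace so the 860 cm^-1 common band falls far below any sane
#' quality-control threshold, and flags it `anomalous_low_signal`. These are
#' the failures the anomaly filter must catch.
#'
#' @param spectrum A [raman_spectrum()].
#' @return The suppressed, flagged spectrum.
#' @export
inject_anomaly <- function(spectrum) {
  f <- runif(1, 0.01, 0.05)
  spectrum$intensities <- spectrum$intensities * f
  spectrum$qc_flags <- union(spectrum$qc_flags, "anomalous_low_signal")
  spectrum
}

inject_spike <- function(spectrum) {
  n <- length(spectrum$intensities)
  ch <- sample.int(n, 1L)
  amp <- runif(1, 10, 30) * max(1, median(spectrum$intensities))
  spectrum$intensities[ch] <- spectrum$intensities[ch] + amp
  spectrum$qc_flags <- union(spectrum$qc_flags, "spike_detected")
  spectrum
}

#' Generate one sample bag
#'
#' A bag is one plasma sample: `spectra_per_sample` spectra sharing a grid,
#' with per-spectrum Bernoulli(witness_rate) witness draws for cancer classes,
#' then spike and anomaly injection at the configured rates. Ground-truth
#' witness and QC flags are kept for testing.
#'
#' @param class One of [all_classes()], registered in `config$signatures`.
#' @param stage `"none"` (HC only), `"early"` or `"advanced"`.
#' @param config A [cohort_config()].
#' @param sample_id Identifier.
#' @return An object of class `sample_bag` with fields `wavenumbers`,
#'   `intensities` (matrix spectra x channels), `witness`, `spike`,
#'   `anomalous`, `spot_index`, `true_class`, `stage`, `split`.
#' @export
generate_sample_bag <- function(class, stage = if (class == "HC") "none"
                                else "advanced",
                                config, sample_id = class) {
  sig <- config$signatures[[class]]
  if (is.null(sig)) stop("unknown class: ", class)
  if ((class == "HC") != (stage == "none"))
    stop("stage must be 'none' iff the class is HC")
  w <- cohort_grid(config)
  n <- config$spectra_per_sample
  witness <- if (sig$witness_rate > 0)
    runif(n) < sig$witness_rate else rep(FALSE, n)
  spike <- runif(n) < config$spike_rate
  anom <- runif(n) < config$anomaly_rate
  mat <- matrix(0, n, length(w))
  for (i in seq_len(n)) {
    sp <- generate_spectrum(sig, w, carry_class_peaks = witness[i],
                            sample_id = sample_id, spot_index = i)
    if (spike[i]) sp <- inject_spike(sp)
    if (anom[i]) sp <- inject_anomaly(sp)
    mat[i, ] <- sp$intensities
  }
  structure(
    list(sample_id = sample_id, true_class = class, stage = stage,
         split = "unassigned", wavenumbers = w, intensities = mat,
         spot_index = seq_len(n), witness = witness, spike = spike,
         anomalous = anom),
    class = "sample_bag")
}

#' @export
print.sample_bag <- function(x, ...) {
  cat(sprintf("<sample_bag> %s: %s (%s), %d spectra x %d channels [%s]\n",
              x$sample_id, x$true_class, x$stage, nrow(x$intensities),
              ncol(x$intensities), x$split))
  invisible(x)
}

#' Number of spectra currently in a bag
#' @param bag A `sample_bag`.
#' @export
n_spectra <- function(bag) nrow(bag$intensities)

#' Extract spectra from a bag as `raman_spectrum` objects
#' @param bag A `sample_bag`.
#' @param i Spectrum indices (default all).
#' @return A list of [raman_spectrum()] objects.
#' @export
bag_spectra <- function(bag, i = seq_len(n_spectra(bag))) {
  lapply(i, function(k) {
    fl <- c(if (bag$spike[k]) "spike_detected",
            if (bag$anomalous[k]) "anomalous_low_signal")
    raman_spectrum(bag$wavenumbers, bag$intensities[k, ],
                   sample_id = bag$sample_id, spot_index = bag$spot_index[k],
                   qc_flags = as.character(fl))
  })
}

#' Generate a full synthetic cohort
#'
#' Deterministic under `config$seed`: class counts exactly match
#' `n_per_class`; `early_fraction` of each cancer class's bags (rounded) are
#' labelled early-stage.
#'
#' @param config A [cohort_config()].
#' @return List of `sample_bag` objects.
#' @export
generate_cohort <- function(config) {
  set.seed(config$seed)
  bags <- list()
  idx <- 0L
  for (cls in names(config$n_per_class)) {
    k <- config$n_per_class[[cls]]
    if (k == 0) next
    n_early <- if (cls == "HC") 0L else round(config$early_fraction * k)
    for (j in seq_len(k)) {
      idx <- idx + 1L
      stage <- if (cls == "HC") "none"
               else if (j <= n_early) "early" else "advanced"
      bags[[idx]] <- generate_sample_bag(
        cls, stage, config, sample_id = sprintf("s%04d_%s", idx, cls))
    }
  }
  bags
}

# cohort IO -------------------------------------------------------------------

#' Write / read a cohort as plain-text CSV
#'
#' One directory per cohort: `manifest.csv` (sample_id, class, stage, split)
#' plus one wide CSV per sample (first column `wavenumber`, then one intensity
#' column per spot).
#'
#' @param bags List of `sample_bag` objects.
#' @param dir Output directory (created if missing).
#' @return `write_cohort` the directory, invisibly; `read_cohort` a list of
#'   `sample_bag` objects (ground-truth witness/QC flags are not persisted).
#' @export
write_cohort <- function(bags, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(
    sample_id = vapply(bags, `[[`, "", "sample_id"),
    class = vapply(bags, `[[`, "", "true_class"),
    stage = vapply(bags, `[[`, "", "stage"),
    split = vapply(bags, `[[`, "", "split"))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (b in bags) {
    df <- data.frame(wavenumber = b$wavenumbers,
                     t(b$intensities))
    names(df)[-1] <- sprintf("spot%03d", b$spot_index)
    write.csv(df, file.path(dir, paste0(b$sample_id, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    df <- read.csv(file.path(dir, paste0(man$sample_id[i], ".csv")))
    mat <- t(as.matrix(df[, -1, drop = FALSE]))
    n <- nrow(mat)
    structure(
      list(sample_id = man$sample_id[i], true_class = man$class[i],
           stage = man$stage[i], split = man$split[i],
           wavenumbers = df$wavenumber, intensities = unname(mat),
           spot_index = seq_len(n), witness = rep(NA, n),
           spike = rep(NA, n), anomalous = rep(NA, n)),
      class = "sample_bag")
  })
}
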