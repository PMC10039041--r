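# Signal conditioning: despiking, baseline correction, denoising, QC filter,
# normalization, difference spectra.

#' Preprocessing configuration
#'
#' @param despike_window Odd sliding-window width (channels) for the
#'   modified-z cosmic-ray filter.
#' @param despike_z Modified-z threshold above which a channel is replaced by
#'   its local median.
#' @param baseline_smoothness Penalty weight (lambda) of the asymmetric
#'   penalized least-squares background estimate.
#' @param baseline_asymmetry Asymmetry parameter p in (0, 1): weight given to
#'   channels above the running background.
#' @param denoise_window Odd Savitzky-Golay window (channels).
#' @param denoise_polyorder Polynomial order (< `denoise_window`).
#' @param qc_band_center,qc_band_halfwidth Band (cm^-1) whose intensity gates
#'   anomalous low-signal spectra; default the common 860 cm^-1 band +/- 15.
#' @param qc_threshold_percentile Percentile of training-set band intensities
#'   used as the anomaly threshold (a reproducible stand-in for a manually
#'   chosen instrument threshold).
#' @param normalize One of `"unit_vector"`, `"max_band"`, `"none"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(despike_window = 11L, despike_z = 8,
                              baseline_smoothness = 1e6,
                              baseline_asymmetry = 0.01,
                              denoise_window = 9L, denoise_polyorder = 3L,
                              qc_band_center = 860, qc_band_halfwidth = 15,
                              qc_threshold_percentile = 5,
                              normalize = c("unit_vector", "max_band",
                                            "none")) {
  normalize <- match.arg(normalize)
  for (w in c(despike_window, denoise_window))
    if (w < 3L || w %% 2L == 0L) stop("windows must be odd and >= 3")
  if (denoise_polyorder >= denoise_window)
    stop("denoise_polyorder must be smaller than denoise_window")
  if (qc_threshold_percentile <= 0 || qc_threshold_percentile >= 100)
    stop("qc_threshold_percentile must lie in (0, 100)")
  if (baseline_asymmetry <= 0 || baseline_asymmetry >= 1)
    stop("baseline_asymmetry must lie in (0, 1)")
  structure(
    list(despike_window = as.integer(despike_window), despike_z = despike_z,
         baseline_smoothness = baseline_smoothness,
         baseline_asymmetry = baseline_asymmetry,
         denoise_window = as.integer(denoise_window),
         denoise_polyorder = as.integer(denoise_polyorder),
         qc_band_center = qc_band_center,
         qc_band_halfwidth = qc_band_halfwidth,
         qc_threshold_percentile = qc_threshold_percentile,
         normalize = normalize),
    class = "preprocess_config")
}

# vector kernels --------------------------------------------------------------

despike_vec <- function(y, window, zmax) {
  n <- length(y)
  if (window > n) stop("despike window larger than the spectrum")
  med <- stats::runmed(y, window, endrule = "median")
  r <- y - med
  sig <- 1.4826 * stats::runmed(abs(r), window, endrule = "median")
  # Floor keeps flat / noise-free regions from producing infinite z-scores,
  # protects sharp genuine peaks (whose apex deviates from the running
  # median by a few percent of the dynamic range) and makes the filter
  # idempotent in practice. Cosmic-ray spikes are an order of magnitude
  # above the trace, so they stay far beyond the threshold.
  floor_sig <- 0.05 * diff(range(y))
  sig <- pmax(sig, floor_sig, 1e-12)
  hit <- abs(r) / sig > zmax
  y[hit] <- med[hit]
  list(y = y, n_replaced = sum(hit))
}

sg_matrices <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  x <- (-h):h
  V <- outer(x, 0:polyorder, `^`)
  # Projection onto degree-<=polyorder polynomials within the window.
  P <- V %*% solve(crossprod(V), t(V))
  list(h = h, center = P[h + 1L, ], head = P[1:h, , drop = FALSE],
       tail = P[(h + 2L):window, , drop = FALSE])
}

sgolay_vec <- function(y, window, polyorder) {
  n <- length(y)
  if (window > n) stop("denoise window larger than the spectrum")
  m <- sg_matrices(window, polyorder)
  out <- stats::filter(y, rev(m$center), sides = 2)
  out <- as.numeric(out)
  out[1:m$h] <- as.numeric(m$head %*% y[1:window])
  out[(n - m$h + 1L):n] <- as.numeric(m$tail %*% y[(n - window + 1L):n])
  out
}

#' Remove single-channel cosmic-ray spikes
#'
#' Channels whose modified-z score against a running local median exceeds
#' `despike_z` are replaced by that median; all other channels are unchanged.
#' Idempotent on its own output for well-behaved spectra.
#'
#' @param spectrum A [raman_spectrum()].
#' @param config A [preprocess_config()].
#' @return The despiked spectrum.
#' @export
despike <- function(spectrum, config = preprocess_config()) {
  res <- despike_vec(spectrum$intensities, config$despike_window,
                     config$despike_z)
  spectrum$intensities <- res$y
  spectrum
}

#' Subtract the smooth spectral background
#'
#' Asymmetric penalized least squares (Whittaker smoother with asymmetric
#' weights): the estimated background hugs the lower envelope of the trace and
#' is subtracted, leaving peaks on a flat base. Peak positions are unchanged.
#'
#' @inheritParams despike
#' @return The baseline-corrected spectrum.
#' @export
correct_baseline <- function(spectrum, config = preprocess_config()) {
  y <- spectrum$intensities
  if (any(!is.finite(y))) stop("non-finite intensities")
  z <- als_baseline_cpp(y, config$baseline_smoothness,
                        config$baseline_asymmetry, 20L)
  spectrum$intensities <- y - z
  spectrum
}

#' Savitzky-Golay denoising
#'
#' Local least-squares polynomial smoothing; reproduces any polynomial of
#' degree `<= denoise_polyorder` exactly (edges handled by one-sided fits).
#'
#' @inheritParams despike
#' @return The smoothed spectrum.
#' @export
denoise <- function(spectrum, config = preprocess_config()) {
  spectrum$intensities <- sgolay_vec(spectrum$intensities,
                                     config$denoise_window,
                                     config$denoise_polyorder)
  spectrum
}

normalize_rows <- function(mat, how, wavenumbers, config) {
  switch(how,
    none = mat,
    unit_vector = {
      nrm <- sqrt(rowSums(mat^2))
      nrm[nrm == 0] <- 1
      mat / nrm
    },
    max_band = {
      b <- band_intensity_rows(mat, wavenumbers, config$qc_band_center,
                               config$qc_band_halfwidth)
      b[b == 0] <- 1
      mat / b
    })
}

# QC report constructor (serializable via jsonlite).
qc_report <- function(n_input, n_removed_anomalous, n_despiked,
                      threshold_used, removed_ids = character()) {
  stopifnot(n_removed_anomalous <= n_input, n_input >= 0, n_despiked >= 0)
  structure(list(n_input = n_input,
                 n_removed_anomalous = n_removed_anomalous,
                 n_despiked = n_despiked,
                 threshold_used = threshold_used,
                 removed_ids = removed_ids),
            class = "qc_report")
}

#' Drop anomalous low-signal spectra from a bag
#'
#' A spectrum is retained iff its quality-control band intensity strictly
#' exceeds `threshold` ("did not exceed" means removal). Retained and removed
#' sets partition the bag.
#'
#' @param bag A `sample_bag`.
#' @param threshold Non-negative intensity threshold.
#' @param config A [preprocess_config()] (band definition).
#' @return `list(bag = filtered bag, report = qc_report)`.
#' @export
filter_anomalies <- function(bag, threshold, config = preprocess_config()) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (n_spectra(bag) == 0L) stop("empty bag")
  b <- band_intensity_rows(bag$intensities, bag$wavenumbers,
                           config$qc_band_center, config$qc_band_halfwidth)
  keep <- b > threshold
  report <- qc_report(
    n_input = length(keep),
    n_removed_anomalous = sum(!keep),
    n_despiked = 0L,
    threshold_used = threshold,
    removed_ids = sprintf("%s#%d", bag$sample_id, bag$spot_index[!keep]))
  list(bag = subset_bag(bag, keep), report = report)
}

subset_bag <- function(bag, keep) {
  bag$intensities <- bag$intensities[keep, , drop = FALSE]
  bag$spot_index <- bag$spot_index[keep]
  bag$witness <- bag$witness[keep]
  bag$spike <- bag$spike[keep]
  bag$anomalous <- bag$anomalous[keep]
  bag
}

#' Full per-bag preprocessing pipeline
#'
#' Applies, in this fixed order: despike -> baseline correction -> denoise ->
#' anomaly filtering -> normalization. Deterministic: a pure function of
#' `(bag, config, threshold)`.
#'
#' @param bag A `sample_bag`.
#' @param config A [preprocess_config()].
#' @param threshold Anomaly threshold; if `NULL`, the configured percentile of
#'   this bag's own band intensities (cohort pipelines pass a training-set
#'   threshold instead, see [preprocess_cohort()]).
#' @return `list(bag, report)` as in [filter_anomalies()].
#' @export
preprocess_bag <- function(bag, config = preprocess_config(),
                           threshold = NULL) {
  bag <- condition_bag(bag, config)
  thr <- if (is.null(threshold)) {
    b <- band_intensity_rows(bag$intensities, bag$wavenumbers,
                             config$qc_band_center, config$qc_band_halfwidth)
    as.numeric(quantile(b, config$qc_threshold_percentile / 100))
  } else threshold
  res <- filter_anomalies(bag, thr, config)
  res$report$n_despiked <- attr(bag, "n_despiked")
  res$bag$intensities <- normalize_rows(res$bag$intensities, config$normalize,
                                        res$bag$wavenumbers, config)
  res
}

# despike + baseline + denoise on every spectrum of a bag (no filtering).
condition_bag <- function(bag, config) {
  mat <- bag$intensities
  n_despiked <- 0L
  for (i in seq_len(nrow(mat))) {
    d <- despike_vec(mat[i, ], config$despike_window, config$despike_z)
    if (d$n_replaced > 0L) n_despiked <- n_despiked + 1L
    y <- d$y - als_baseline_cpp(d$y, config$baseline_smoothness,
                                config$baseline_asymmetry, 20L)
    mat[i, ] <- sgolay_vec(y, config$denoise_window, config$denoise_polyorder)
  }
  bag$intensities <- mat
  attr(bag, "n_despiked") <- n_despiked
  bag
}

#' Preprocess a whole cohort with a training-derived QC threshold
#'
#' Conditions every bag (despike, baseline, denoise), sets the anomaly
#' threshold as the configured percentile of the *training-split* band
#' intensities, then filters and normalizes every bag with that single
#' threshold, mirroring a fixed instrument-level QC rule.
#'
#' @param bags List of `sample_bag` objects with `split` assigned.
#' @param config A [preprocess_config()].
#' @return `list(bags, reports, threshold)`.
#' @export
preprocess_cohort <- function(bags, config = preprocess_config()) {
  conditioned <- lapply(bags, condition_bag, config = config)
  train_idx <- which(vapply(bags, `[[`, "", "split") == "train")
  if (!length(train_idx)) train_idx <- seq_along(bags)
  b_train <- unlist(lapply(conditioned[train_idx], function(b)
    band_intensity_rows(b$intensities, b$wavenumbers, config$qc_band_center,
                        config$qc_band_halfwidth)))
  thr <- as.numeric(quantile(b_train, config$qc_threshold_percentile / 100))
  out <- vector("list", length(bags))
  reports <- vector("list", length(bags))
  for (i in seq_along(conditioned)) {
    res <- filter_anomalies(conditioned[[i]], thr, config)
    res$report$n_despiked <- attr(conditioned[[i]], "n_despiked")
    res$bag$intensities <- normalize_rows(res$bag$intensities,
                                          config$normalize,
                                          res$bag$wavenumbers, config)
    out[[i]] <- res$bag
    reports[[i]] <- res$report
  }
  list(bags = out, reports = reports, threshold = thr)
}
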