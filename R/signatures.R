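# Spectral phenotypes: per-class peak catalogues and noise parameters.

peak_table <- function(center, width, amplitude) {
  stopifnot(length(center) == length(width),
            length(center) == length(amplitude))
  if (any(width <= 0)) stop("peak widths must be positive")
  if (any(amplitude < 0)) stop("peak amplitudes must be non-negative")
  data.frame(center = center, width = width, amplitude = amplitude)
}

#' Define a class spectral signature
#'
#' A signature is the generative phenotype of one diagnostic class: the common
#' exosome bands every spectrum carries, the class-specific bands that only
#' "witness" spectra carry, the witness rate, and baseline/noise parameters.
#'
#' @param class_name One of [all_classes()].
#' @param common_peaks,class_peaks Data frames with columns `center` (cm^-1),
#'   `width` (Lorentzian half-width at half-maximum, cm^-1) and `amplitude`
#'   (counts); build them with column-wise vectors via `peak_table()` semantics
#'   (any data frame with those columns is accepted).
#' @param witness_rate Fraction in `[0, 1]` of a bag's spectra that carry
#'   `class_peaks`. Must be 0 for `"HC"`.
#' @param baseline_params List with elements `b0`, `slope`, `hump_center`,
#'   `hump_width`, `hump_amp`, `jitter` describing the smooth background.
#' @param noise_sd Additive Gaussian noise scale (counts).
#' @param intensity_cv Coefficient of variation of the per-spectrum
#'   multiplicative scale (acquisition non-uniformity), e.g. 0.06 for 6 %.
#' @return An object of class `class_signature`.
#' @export
class_signature <- function(class_name,
                            common_peaks,
                            class_peaks = peak_table(numeric(0), numeric(0),
                                                     numeric(0)),
                            witness_rate = 0,
                            baseline_params = default_baseline_params(),
                            noise_sd = 15,
                            intensity_cv = 0.06) {
  class_name <- match.arg(class_name, all_classes())
  stopifnot(is.data.frame(common_peaks), is.data.frame(class_peaks))
  req <- c("center", "width", "amplitude")
  if (!all(req %in% names(common_peaks)) || !all(req %in% names(class_peaks)))
    stop("peak tables need columns center, width, amplitude")
  if (witness_rate < 0 || witness_rate > 1)
    stop("witness_rate must lie in [0, 1]")
  if (class_name == "HC" && witness_rate != 0)
    stop("HC witness_rate is fixed at 0")
  for (tab in list(common_peaks, class_peaks)) {
    if (any(tab$width <= 0)) stop("peak widths must be positive")
    if (any(tab$amplitude < 0)) stop("peak amplitudes must be non-negative")
  }
  structure(
    list(class_name = class_name,
         common_peaks = common_peaks[req],
         class_peaks = class_peaks[req],
         witness_rate = witness_rate,
         baseline_params = baseline_params,
         noise_sd = noise_sd,
         intensity_cv = intensity_cv),
    class = "class_signature")
}

#' @rdname class_signature
#' @export
default_baseline_params <- function() {
  list(b0 = 150, slope = 80, hump_center = 1100, hump_width = 350,
       hump_amp = 180, jitter = 0.15)
}

# Wavenumbers of the shared strong exosome bands and of the subtle
# protein/lipid variation bands reported for plasma-exosome SERS spectra.
common_band_centers <- function() c(860, 1283, 1597)
subtle_band_centers <- function() {
  c(638, 668, 707, 733, 978, 1001, 1049, 1123, 1162, 1358, 1378, 1394, 1432)
}
cancer_common_band_centers <- function() {
  c(691, 826, 938, 961, 993, 1144, 1245, 1527)
}

#' Default class signatures
#'
#' The stated synthetic world: every class shares three strong bands near 860,
#' 1283 and 1597 cm^-1; the six cancer classes additionally carry, in their
#' witness spectra, a shared set of cancer-common difference bands plus two
#' organ-specific bands drawn from the subtle-variation band list.
#'
#' @param class_amplitude Amplitude (counts) of the organ-specific bands;
#'   cancer-common bands use 60 % of it. Set 0 for a null (no-signal) world.
#' @param witness_rate Witness rate for the six cancer classes (HC is 0).
#' @param noise_sd Additive noise scale in counts.
#' @param intensity_cv Per-spectrum multiplicative scale CV.
#' @return Named list of `class_signature` objects, one per class.
#' @export
default_signatures <- function(class_amplitude = 150, witness_rate = 0.5,
                               noise_sd = 15, intensity_cv = 0.06) {
  common <- peak_table(common_band_centers(),
                       width = c(18, 22, 16),
                       amplitude = c(1000, 750, 850))
  specific <- list(
    breast     = c(638, 1001),
    colorectal = c(668, 1049),
    liver      = c(707, 1123),
    lung       = c(733, 1162),
    pancreatic = c(978, 1358),
    stomach    = c(1378, 1432))
  sigs <- list(HC = class_signature("HC", common, witness_rate = 0,
                                    noise_sd = noise_sd,
                                    intensity_cv = intensity_cv))
  cc <- cancer_common_band_centers()
  for (cls in cancer_types()) {
    cp <- peak_table(
      center = c(cc, specific[[cls]]),
      width = c(rep(10, length(cc)), 8, 8),
      amplitude = c(rep(0.6 * class_amplitude, length(cc)),
                    class_amplitude, class_amplitude))
    sigs[[cls]] <- class_signature(cls, common, cp,
                                   witness_rate = witness_rate,
                                   noise_sd = noise_sd,
                                   intensity_cv = intensity_cv)
  }
  sigs
}
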