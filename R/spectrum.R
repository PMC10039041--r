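# Raman spectrum container and channel-level utilities.

#' Construct a single Raman spectrum
#'
#' A spectrum is one wavenumber-indexed intensity trace acquired at one spot of
#' the 10 x 10 acquisition grid, plus quality-control flags.
#'
#' @param wavenumbers Strictly increasing numeric grid in cm^-1 (length >= 2).
#' @param intensities Numeric counts, one per channel.
#' @param sample_id Identifier of the plasma sample the spectrum belongs to.
#' @param spot_index Integer position on the acquisition grid.
#' @param qc_flags Character subset of
#'   `c("spike_detected", "anomalous_low_signal")`.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, sample_id = NA_character_,
                           spot_index = NA_integer_, qc_flags = character()) {
  if (!is.numeric(wavenumbers) || !is.numeric(intensities))
    stop("wavenumbers and intensities must be numeric")
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least two channels")
  if (length(wavenumbers) != length(intensities))
    stop("intensities must have one value per wavenumber channel")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  bad <- setdiff(qc_flags, c("spike_detected", "anomalous_low_signal"))
  if (length(bad)) stop("unknown qc flag: ", paste(bad, collapse = ", "))
  structure(
    list(wavenumbers = as.numeric(wavenumbers),
         intensities = as.numeric(intensities),
         sample_id = sample_id,
         spot_index = as.integer(spot_index),
         qc_flags = qc_flags),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d channels, %.1f-%.1f cm^-1",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$qc_flags)) cat(" [", paste(x$qc_flags, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

is_raman_spectrum <- function(x) inherits(x, "raman_spectrum")

# Coerce a spectrum / list of spectra / matrix to an n x channels matrix.
spectra_matrix <- function(spectra) {
  if (is.matrix(spectra)) return(spectra)
  if (is_raman_spectrum(spectra)) {
    return(matrix(spectra$intensities, nrow = 1L))
  }
  if (is.list(spectra)) {
    if (!length(spectra)) return(matrix(numeric(0), nrow = 0L, ncol = 0L))
    n <- lengths(lapply(spectra, `[[`, "intensities"))
    if (length(unique(n)) != 1L) stop("spectra do not share one grid")
    return(do.call(rbind, lapply(spectra, `[[`, "intensities")))
  }
  stop("cannot interpret 'spectra' input")
}

#' Band intensity of a spectrum
#'
#' Maximum intensity over the channels within `center +/- halfwidth`, the
#' statistic used for the 860 cm^-1 common-band quality-control filter.
#'
#' @param spectrum A `raman_spectrum`, or a numeric intensity vector when
#'   `wavenumbers` is supplied.
#' @param center Band centre in cm^-1.
#' @param halfwidth Half-width of the band window in cm^-1 (default 15).
#' @param wavenumbers Grid for a bare numeric `spectrum`.
#' @return Scalar band intensity.
#' @export
band_intensity <- function(spectrum, center, halfwidth = 15,
                           wavenumbers = NULL) {
  if (is_raman_spectrum(spectrum)) {
    wavenumbers <- spectrum$wavenumbers
    y <- spectrum$intensities
  } else {
    y <- spectrum
    if (is.null(wavenumbers)) stop("supply wavenumbers for a bare vector")
  }
  sel <- abs(wavenumbers - center) <= halfwidth
  if (!any(sel)) stop("band window does not intersect the wavenumber grid")
  max(y[sel])
}

# Vectorised band intensity over the rows of an intensity matrix.
band_intensity_rows <- function(mat, wavenumbers, center, halfwidth = 15) {
  sel <- abs(wavenumbers - center) <= halfwidth
  if (!any(sel)) stop("band window does not intersect the wavenumber grid")
  sub <- mat[, sel, drop = FALSE]
  do.call(pmax, c(as.data.frame(sub), na.rm = FALSE))
}

#' Channel-wise group difference spectrum
#'
#' Mean spectrum of group A minus mean spectrum of group B, used to locate
#' cancer-common Raman bands between patient and control spectra.
#'
#' @param group_a,group_b Non-empty lists of `raman_spectrum` objects (or
#'   intensity matrices) sharing one wavenumber grid.
#' @param wavenumbers Grid, required when matrices are supplied.
#' @return A `raman_spectrum` holding the difference trace.
#' @export
difference_spectrum <- function(group_a, group_b, wavenumbers = NULL) {
  grid_of <- function(g) {
    if (is.list(g) && length(g) && is_raman_spectrum(g[[1L]]))
      g[[1L]]$wavenumbers
    else wavenumbers
  }
  ga <- spectra_matrix(group_a)
  gb <- spectra_matrix(group_b)
  if (!nrow(ga) || !nrow(gb)) stop("both groups must be non-empty")
  wa <- grid_of(group_a); wb <- grid_of(group_b)
  if (is.null(wa) || is.null(wb)) stop("supply wavenumbers for matrix input")
  if (length(wa) != length(wb) || any(wa != wb) ||
      ncol(ga) != length(wa) || ncol(gb) != length(wb))
    stop("groups do not share one wavenumber grid")
  raman_spectrum(wa, colMeans(ga) - colMeans(gb), sample_id = "difference")
}
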