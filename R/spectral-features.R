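#' Canonical frequency-band definitions
#'
#' The four analysis bands used throughout: delta-theta (2-7 Hz), alpha
#' (8-12 Hz), beta (13-35 Hz), and broadband (1-35 Hz). Band edges are
#' inclusive on both sides.
#'
#' @return A data.frame with columns `band`, `lo_hz`, `hi_hz`.
#' @export
band_definitions <- function() {
  data.frame(
    band = c("delta_theta", "alpha", "beta", "broadband"),
    lo_hz = c(2, 8, 13, 1),
    hi_hz = c(7, 12, 35, 35),
    stringsAsFactors = FALSE
  )
}

#' Regional power spectrum container
#'
#' One subject-by-ROI power spectrum in dB over a frequency grid.
#'
#' @param grid Frequencies in Hz (strictly increasing, positive).
#' @param psd_db Power spectral density in dB, one finite value per
#'   frequency.
#' @param subject_id,roi Optional identifiers carried through fitting and
#'   cohort tables.
#' @return An object of class `regional_spectrum`.
#' @export
regional_spectrum <- function(grid, psd_db, subject_id = NA_character_,
                              roi = NA_character_) {
  grid <- freq_grid(grid)
  psd_db <- as.numeric(psd_db)
  if (length(psd_db) != length(grid))
    stop("'psd_db' and 'grid' must have equal length", call. = FALSE)
  if (any(!is.finite(psd_db)))
    stop("'psd_db' must be finite everywhere", call. = FALSE)
  structure(list(subject_id = subject_id, roi = roi,
                 grid = as.numeric(grid), psd_db = psd_db),
            class = "regional_spectrum")
}

#' @export
print.regional_spectrum <- function(x, ...) {
  cat(sprintf("Regional spectrum [%s / %s]: %d bins, %.3g-%.3g Hz\n",
              x$subject_id, x$roi, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
plot.regional_spectrum <- function(x, ..., xlab = "Frequency (Hz)",
                                   ylab = "PSD (dB)", type = "l") {
  graphics::plot(x$grid, x$psd_db, type = type, xlab = xlab, ylab = ylab, ...)
}

#' Welch power spectral density in dB
#'
#' Welch-averaged periodogram of a sampled signal: the trace is split into
#' Hann-windowed segments of `window_s` seconds overlapping by
#' `overlap_frac`, segment periodograms are averaged, and the average is
#' converted to dB as `10 log10(power)`. The returned grid is restricted
#' to `[fmin, fmax]` (default the 1-35 Hz analysis band).
#'
#' @param trace Numeric vector of samples (finite; at least two windows
#'   long).
#' @param sample_rate Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 2, giving 0.5 Hz
#'   resolution).
#' @param overlap_frac Fractional overlap between consecutive segments in
#'   `[0, 1)` (default 0.5).
#' @param fmin,fmax Analysis band edges in Hz.
#' @inheritParams regional_spectrum
#' @return A [regional_spectrum()].
#' @export
compute_psd_db <- function(trace, sample_rate, window_s = 2,
                           overlap_frac = 0.5, fmin = 1, fmax = 35,
                           subject_id = NA_character_, roi = NA_character_) {
  if (inherits(trace, "nmm_realization")) {
    sample_rate <- trace$sample_rate
    trace <- trace$x_e + trace$x_i
  }
  trace <- as.numeric(trace)
  if (any(!is.finite(trace)))
    stop("trace contains non-finite samples", call. = FALSE)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("'overlap_frac' must be in [0, 1)", call. = FALSE)
  nwin <- round(window_s * sample_rate)
  if (length(trace) < 2 * nwin)
    stop(sprintf("trace too short: need >= %d samples (two windows), got %d",
                 2 * nwin, length(trace)), call. = FALSE)
  hop <- max(1L, round(nwin * (1 - overlap_frac)))
  starts <- seq(1L, length(trace) - nwin + 1L, by = hop)
  w <- signal::hanning(nwin)
  u <- sum(w^2)                       # window power normalization
  nf <- nwin %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- trace[s:(s + nwin - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * sample_rate * u)
  # one-sided: double everything except DC and (even nwin) Nyquist
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (nwin %% 2L == 0L) dbl[nf] <- 1
  pxx <- pxx * dbl
  f <- (seq_len(nf) - 1L) * sample_rate / nwin
  keep <- f >= fmin & f <= fmax
  if (!any(keep)) stop("no frequency bins inside [fmin, fmax]", call. = FALSE)
  regional_spectrum(f[keep], 10 * log10(pxx[keep]),
                    subject_id = subject_id, roi = roi)
}

#' Mean band power of a dB spectrum
#'
#' Arithmetic mean of the dB values over the bins falling inside a band,
#' edges inclusive. Averaging is done on the dB scale (mean-of-dB, not
#' dB-of-mean), matching how dB-scale spectra are compared across groups.
#'
#' @param spec A [regional_spectrum()] or `nmm_spectrum`.
#' @param band Band name from [band_definitions()], or a numeric
#'   `c(lo_hz, hi_hz)` pair.
#' @return Scalar band power in dB.
#' @export
band_power_db <- function(spec, band = "broadband") {
  if (is.character(band)) {
    defs <- band_definitions()
    i <- match(band, defs$band)
    if (is.na(i)) stop(sprintf("unknown band '%s'", band), call. = FALSE)
    lo <- defs$lo_hz[i]; hi <- defs$hi_hz[i]
  } else {
    if (length(band) != 2 || band[1] >= band[2])
      stop("numeric 'band' must be c(lo_hz, hi_hz) with lo < hi",
           call. = FALSE)
    lo <- band[1]; hi <- band[2]
  }
  keep <- spec$grid >= lo & spec$grid <= hi
  if (!any(keep))
    stop(sprintf("band [%g, %g] Hz does not overlap the grid", lo, hi),
         call. = FALSE)
  mean(spec$psd_db[keep])
}

#' Band-power table for a collection of spectra
#'
#' @param spectra A list of [regional_spectrum()] objects.
#' @param bands Character vector of band names (default all four).
#' @return Long data.frame: `subject_id`, `roi`, `band`, `power_db`.
#' @export
band_power_table <- function(spectra, bands = band_definitions()$band) {
  rows <- lapply(spectra, function(sp) {
    data.frame(subject_id = sp$subject_id, roi = sp$roi, band = bands,
               power_db = vapply(bands, function(b) band_power_db(sp, b),
                                 numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
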