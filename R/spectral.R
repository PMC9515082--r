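#' Frequency band for spectral summation
#'
#' A narrow band over which spectral magnitudes are summed, defined by its
#' center and half-width. The two bands of interest are the stable
#' cavitation (SC) band at the fourth harmonic of the drive (2 MHz for a
#' 500 kHz drive) and the inertial cavitation (IC) band at 2.1 MHz, both
#' with a +/- 0.02 MHz half-width.
#'
#' @param center Band center in Hz.
#' @param half_width Band half-width in Hz. Must satisfy
#'   `center > half_width > 0`.
#' @return An object of class `band`.
#' @export
band <- function(center, half_width = 2e4) {
  if (!(center > half_width && half_width > 0))
    stop("band requires center > half_width > 0", call. = FALSE)
  structure(list(center = center, half_width = half_width), class = "band")
}

#' @rdname band
#' @param f0 Drive frequency in Hz (the SC band sits at its 4th harmonic).
#' @export
sc_band <- function(f0 = 5e5, half_width = 2e4) band(4 * f0, half_width)

#' @rdname band
#' @export
ic_band <- function(half_width = 2e4) band(2.1e6, half_width)

#' One-sided magnitude spectrum of a PCD trace
#'
#' Computes the FFT of the full trace (rectangular window, no zero
#' padding) and returns the one-sided magnitude spectrum with frequency
#' resolution `fs / N`. Magnitudes are unscaled DFT magnitudes: a unit
#' cosine at an exact bin frequency yields a single bin of magnitude N/2.
#'
#' An optional analysis sub-window (`start`, `length`, in seconds) is
#' provided for users matching time-of-flight gating; the default is the
#' full trace.
#'
#' @param trace Numeric voltage trace.
#' @param fs Sampling rate in Hz.
#' @param start Offset of the analysis window, seconds. Default 0.
#' @param length Length of the analysis window, seconds. Default full trace.
#' @return A data.frame with columns `freq` (Hz) and `mag` (a.u.).
#' @export
compute_spectrum <- function(trace, fs, start = 0, length = NULL) {
  if (length(trace) < 2) stop("trace must have at least 2 samples", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  i0 <- round(start * fs) + 1L
  i1 <- if (is.null(length)) base::length(trace) else i0 + round(length * fs) - 1L
  if (i0 < 1L || i1 > base::length(trace) || i1 - i0 + 1L < 2L)
    stop("analysis window outside trace", call. = FALSE)
  x <- trace[i0:i1]
  n <- base::length(x)
  half <- n %/% 2L + 1L
  mag <- Mod(stats::fft(x))[seq_len(half)]
  data.frame(freq = (seq_len(half) - 1) * fs / n, mag = mag)
}

#' Summed spectral magnitude within a band
#'
#' Sums the one-sided spectrum magnitudes over all bins whose frequency f
#' satisfies `center - half_width <= f <= center + half_width` (closed
#' interval; both edge bins included). This is the linear SC/IC "level".
#'
#' @param spectrum A data.frame with `freq` and `mag` columns, as returned
#'   by [compute_spectrum()].
#' @param band A [band()] object. Must lie inside `[0, fs/2]`.
#' @return The summed magnitude (linear, arbitrary units).
#' @export
band_level <- function(spectrum, band) {
  stopifnot(inherits(band, "band"))
  nyq <- max(spectrum$freq)
  if (band$center + band$half_width > nyq || band$center - band$half_width < 0)
    stop("band extends outside the Nyquist range [0, fs/2]", call. = FALSE)
  sel <- spectrum$freq >= band$center - band$half_width &
    spectrum$freq <= band$center + band$half_width
  sum(spectrum$mag[sel])
}

#' Baseline calibration from dummy-sonication pulses
#'
#' Averages the per-pulse linear SC and IC band levels over the dummy
#' pulses (five by default in a session). Averaging is performed in linear
#' units, never in dB, so that the mean dummy pulse maps to 0 dB.
#'
#' @param traces List of numeric traces, all of the same length.
#' @param fs Sampling rate in Hz.
#' @param sc SC [band()]. Default: 4th harmonic of 500 kHz.
#' @param ic IC [band()]. Default: 2.1 MHz.
#' @return An object of class `baseline_calibration` with fields
#'   `sc_base`, `ic_base` (linear a.u.) and `n_pulses`.
#' @export
calibrate_baseline <- function(traces, fs, sc = sc_band(), ic = ic_band()) {
  if (!is.list(traces) || length(traces) < 1)
    stop("need at least one trace", call. = FALSE)
  lens <- vapply(traces, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("all traces must have the same length", call. = FALSE)
  lv <- vapply(traces, function(tr) {
    sp <- compute_spectrum(tr, fs)
    c(band_level(sp, sc), band_level(sp, ic))
  }, numeric(2))
  cal <- structure(list(sc_base = mean(lv[1, ]), ic_base = mean(lv[2, ]),
                        n_pulses = length(traces)),
                   class = "baseline_calibration")
  if (cal$sc_base <= 0 || cal$ic_base <= 0)
    stop("baseline levels must be positive (dB undefined otherwise)",
         call. = FALSE)
  cal
}

#' Linear level to dB relative to a baseline
#'
#' Converts a linear band level to dB re the baseline level. Band levels
#' are summed spectral magnitudes (an amplitude-like quantity), so the
#' default convention is `20 * log10(level / base)`; a power convention
#' (`10 * log10`) is selectable.
#'
#' @param level_linear Linear level, must be positive.
#' @param base_linear Baseline linear level, must be positive.
#' @param convention `"amplitude"` (20 log10, default) or `"power"`
#'   (10 log10).
#' @return Level in dB re baseline.
#' @export
to_db <- function(level_linear, base_linear,
                  convention = c("amplitude", "power")) {
  convention <- match.arg(convention)
  if (any(level_linear <= 0) || any(base_linear <= 0))
    stop("dB conversion requires positive linear levels", call. = FALSE)
  k <- if (convention == "amplitude") 20 else 10
  k * log10(level_linear / base_linear)
}

#' Per-pulse SC/IC levels of a trace
#'
#' Convenience wrapper computing the linear SC and IC band levels of one
#' trace and, when a calibration is supplied, their dB values re baseline.
#'
#' @param trace Numeric voltage trace.
#' @param fs Sampling rate in Hz.
#' @param calibration Optional `baseline_calibration`.
#' @param sc,ic SC and IC [band()]s.
#' @param convention dB convention passed to [to_db()].
#' @return A list with `sc_linear`, `ic_linear` and (if calibrated)
#'   `sc_db`, `ic_db`.
#' @export
pulse_levels <- function(trace, fs, calibration = NULL,
                         sc = sc_band(), ic = ic_band(),
                         convention = "amplitude") {
  sp <- compute_spectrum(trace, fs)
  out <- list(sc_linear = band_level(sp, sc), ic_linear = band_level(sp, ic),
              sc_db = NA_real_, ic_db = NA_real_)
  if (!is.null(calibration)) {
    out$sc_db <- to_db(out$sc_linear, calibration$sc_base, convention)
    out$ic_db <- to_db(out$ic_linear, calibration$ic_base, convention)
  }
  out
}

#' @export
print.baseline_calibration <- function(x, ...) {
  cat(sprintf("Baseline calibration from %d dummy pulse(s)\n", x$n_pulses))
  cat(sprintf("  SC baseline: %.6g a.u.\n  IC baseline: %.6g a.u.\n",
              x$sc_base, x$ic_base))
  invisible(x)
}
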