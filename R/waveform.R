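#' Sampled waveform
#'
#' Container for a single-channel sampled signal with its sampling rate and the
#' role it plays in a trial. Acoustic roles (`prestimulus`, `startle`) hold
#' dimensionless amplitudes where 1.0 is digital full scale; the `trigger` role
#' is a two-valued \{0, 1\} TTL-style channel.
#'
#' Note that under the default [level_calibration()] (unit RMS = 100 dB SPL) a
#' loud startle burst has RMS above 1: digital amplitudes are allowed to exceed
#' full scale, and clipping is reported where a signal leaves the package
#' (WAV export, [apply_equalizer()]) rather than rejected at construction.
#'
#' @param samples numeric vector of sample values.
#' @param rate sampling rate in Hz (> 0).
#' @param role one of `"prestimulus"`, `"startle"`, `"trigger"`.
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, rate,
                     role = c("prestimulus", "startle", "trigger")) {
  role <- match.arg(role)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!(length(rate) == 1L && is.finite(rate) && rate > 0)) {
    stop("rate must be a single positive finite number")
  }
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("samples must not contain NA")
  if (role == "trigger" && length(samples) &&
    !all(samples == 0 | samples == 1)) {
    stop("trigger waveforms must be two-valued {0, 1}")
  }
  structure(list(samples = samples, rate = rate, role = role),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform: %s, %d samples @ %g Hz (%.4g s), peak %.4g, RMS %.4g>\n",
    x$role, length(x$samples), x$rate, length(x$samples) / x$rate,
    if (length(x$samples)) max(abs(x$samples)) else 0, wav_rms(x)
  ))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param w a [waveform()].
#' @return duration in seconds.
#' @export
wav_duration <- function(w) length(w$samples) / w$rate

#' Root-mean-square amplitude of a waveform
#' @param w a [waveform()] or numeric vector.
#' @return RMS value (0 for an empty waveform).
#' @export
wav_rms <- function(w) {
  x <- if (inherits(w, "waveform")) w$samples else as.numeric(w)
  if (!length(x)) return(0)
  sqrt(mean(x^2))
}

#' Level calibration: mapping between digital amplitude and dB SPL
#'
#' A single reference point: the sound pressure level, in dB SPL, produced by a
#' unit-RMS digital signal after the (equalized) playback chain. All stimulus
#' levels in the package are specified in dB SPL and converted through this
#' reference. No physical microphone is involved; on real hardware the
#' reference would be measured once with a calibrated microphone.
#'
#' @param ref_dbspl dB SPL produced by a unit-RMS signal (default 100).
#' @return an object of class `level_calibration`.
#' @export
level_calibration <- function(ref_dbspl = 100.0) {
  if (!(length(ref_dbspl) == 1L && is.finite(ref_dbspl) && ref_dbspl > 0)) {
    stop("ref_dbspl must be a single positive finite number")
  }
  structure(list(ref_dbspl = as.numeric(ref_dbspl)),
    class = "level_calibration"
  )
}

#' Convert a sound pressure level to a digital amplitude scale factor
#'
#' Returns `10^((level_dbspl - ref_dbspl) / 20)`; multiplying a unit-RMS
#' waveform by this factor yields the requested level under `cal`.
#'
#' @param level_dbspl target level in dB SPL.
#' @param cal a [level_calibration()].
#' @return scalar amplitude factor.
#' @export
dbspl_to_amplitude <- function(level_dbspl, cal = level_calibration()) {
  stopifnot(inherits(cal, "level_calibration"))
  if (!all(is.finite(level_dbspl))) stop("level_dbspl must be finite")
  10^((level_dbspl - cal$ref_dbspl) / 20)
}

#' Convert a digital RMS amplitude back to dB SPL
#' @param amplitude RMS amplitude (> 0).
#' @param cal a [level_calibration()].
#' @return level in dB SPL.
#' @export
amplitude_to_dbspl <- function(amplitude, cal = level_calibration()) {
  stopifnot(inherits(cal, "level_calibration"))
  if (any(amplitude <= 0)) stop("amplitude must be positive")
  cal$ref_dbspl + 20 * log10(amplitude)
}
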