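#' 3-axis acceleration recording of one trial
#'
#' @param ax,ay,az numeric acceleration traces (sensor units, equal length).
#' @param trigger two-valued \{0, 1\} trigger trace of the same length.
#' @param rate sampling rate in Hz.
#' @param t0 1-based sample index of the startle onset (trigger rising edge),
#'   or `NA` before alignment.
#' @return an object of class `accel_recording`.
#' @export
accel_recording <- function(ax, ay, az, trigger, rate, t0 = NA_integer_) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n || length(trigger) != n) {
    stop("ax, ay, az and trigger must have equal length")
  }
  stopifnot(length(rate) == 1L, rate > 0)
  if (n && !all(trigger == 0 | trigger == 1)) {
    stop("trigger must be two-valued {0, 1}")
  }
  structure(
    list(
      ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
      trigger = as.numeric(trigger), rate = rate, t0 = t0
    ),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf(
    "<accel_recording: %d samples @ %g Hz, t0 %s>\n",
    length(x$ax), x$rate, if (is.na(x$t0)) "unaligned" else x$t0
  ))
  invisible(x)
}

#' Per-axis sensitivity calibration factors
#'
#' Multiplicative factors applied to the raw axis signals so that the same
#' force produces the same calibrated acceleration on every axis.
#'
#' @param cx,cy,cz positive factors (conventionally normalized to `cx = 1`).
#' @return an object of class `axis_calibration`.
#' @export
axis_calibration <- function(cx = 1, cy = 1, cz = 1) {
  if (any(c(cx, cy, cz) <= 0) || !all(is.finite(c(cx, cy, cz)))) {
    stop("calibration factors must be positive and finite")
  }
  structure(list(cx = cx, cy = cy, cz = cz), class = "axis_calibration")
}

find_rising_edges <- function(x, threshold_frac = 0.5) {
  thr <- threshold_frac * max(x)
  above <- x >= thr
  which(above & !c(FALSE, above[-length(above)]))
}

#' Align a recording to its trigger rising edge
#'
#' Sets the recording's time origin (`t0`) to the first crossing of
#' `threshold_frac * max(trigger)`, i.e. the startle stimulus onset.
#' Pre-trigger samples are retained (they carry negative times). The recording
#' must contain exactly one rising edge.
#'
#' @param rec an [accel_recording()].
#' @param threshold_frac edge threshold as a fraction of the trigger maximum.
#' @return the recording with `t0` set.
#' @export
align_to_trigger <- function(rec, threshold_frac = 0.5) {
  stopifnot(inherits(rec, "accel_recording"))
  if (max(rec$trigger) <= 0) stop("trigger channel is flat; no edge to align to")
  edges <- find_rising_edges(rec$trigger, threshold_frac)
  if (length(edges) != 1L) {
    stop(sprintf(
      "expected exactly one trigger rising edge, found %d (at samples %s)",
      length(edges), paste(utils::head(edges, 5), collapse = ", ")
    ))
  }
  rec$t0 <- edges
  rec
}

#' Sample times of an aligned recording
#' @param rec an aligned [accel_recording()].
#' @return numeric vector of times in seconds (0 at the trigger edge).
#' @export
recording_times <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  if (is.na(rec$t0)) stop("recording is not aligned; call align_to_trigger()")
  (seq_along(rec$ax) - rec$t0) / rec$rate
}

#' Calibrated acceleration magnitude trace
#'
#' Each axis is low-pass filtered (4th-order Butterworth applied
#' forward-backward, i.e. zero phase), scaled by its calibration factor, and
#' the three axes are combined into the Euclidean magnitude
#' \eqn{a(t) = \sqrt{(c_x a_x)^2 + (c_y a_y)^2 + (c_z a_z)^2}}.
#'
#' @param rec an [accel_recording()].
#' @param cal an [axis_calibration()].
#' @param lowpass_hz low-pass cutoff in Hz (default 40); `NULL` disables
#'   filtering.
#' @return numeric magnitude trace, same length and alignment as `rec`.
#' @export
magnitude_trace <- function(rec, cal = axis_calibration(), lowpass_hz = 40) {
  stopifnot(inherits(rec, "accel_recording"), inherits(cal, "axis_calibration"))
  axes <- list(rec$ax, rec$ay, rec$az)
  if (!is.null(lowpass_hz)) {
    if (lowpass_hz >= rec$rate / 2) {
      stop("lowpass_hz must be below the Nyquist frequency")
    }
    bf <- signal::butter(4, lowpass_hz / (rec$rate / 2), type = "low")
    axes <- lapply(axes, function(a) signal::filtfilt(bf, a))
  }
  sqrt((cal$cx * axes[[1]])^2 + (cal$cy * axes[[2]])^2 +
    (cal$cz * axes[[3]])^2)
}

#' Acoustic startle reflex amplitude
#'
#' The ASR amplitude is the maximum of the calibrated acceleration magnitude
#' within the window `[0, window_s]` after startle onset (endpoints
#' inclusive); ties are broken toward the earliest time.
#'
#' @param a_t numeric magnitude trace starting at startle onset (t = 0).
#' @param rate sampling rate in Hz.
#' @param window_s analysis window length in seconds (default 150 ms).
#' @return an object of class `asr_amplitude` with fields `value` and
#'   `peak_time_s`.
#' @export
asr_amplitude <- function(a_t, rate, window_s = 0.150) {
  n_win <- floor(window_s * rate) + 1L
  if (length(a_t) < n_win) {
    stop(sprintf(
      "trace (%d samples) does not cover the %g s window (%d samples)",
      length(a_t), window_s, n_win
    ))
  }
  win <- a_t[seq_len(n_win)]
  idx <- which.max(win) # first index wins ties
  structure(
    list(value = win[idx], peak_time_s = (idx - 1) / rate),
    class = "asr_amplitude"
  )
}

#' @export
print.asr_amplitude <- function(x, ...) {
  cat(sprintf(
    "<asr_amplitude: %.6g at %.1f ms>\n", x$value, 1000 * x$peak_time_s
  ))
  invisible(x)
}

#' Extract the ASR amplitude from a raw recording
#'
#' Convenience pipeline: [align_to_trigger()], [magnitude_trace()], then
#' [asr_amplitude()] on the post-onset part of the trace.
#'
#' @param rec an [accel_recording()] (aligned or not).
#' @param cal an [axis_calibration()].
#' @param lowpass_hz low-pass cutoff (default 40 Hz).
#' @param window_s analysis window (default 150 ms).
#' @return an `asr_amplitude`.
#' @export
extract_asr <- function(rec, cal = axis_calibration(), lowpass_hz = 40,
                        window_s = 0.150) {
  if (is.na(rec$t0)) rec <- align_to_trigger(rec)
  a <- magnitude_trace(rec, cal, lowpass_hz)
  asr_amplitude(a[rec$t0:length(a)], rec$rate, window_s)
}

#' Calibrate per-axis sensitivities from reference recordings
#'
#' Given one recording per axis, each taken under the same reference force
#' applied along that axis, returns factors proportional to the inverse of the
#' per-axis peak response, normalized so `cx = 1` — so that the same force
#' yields the same calibrated acceleration on every axis.
#'
#' @param reference_recs list of three [accel_recording()]s: force along x, y,
#'   z respectively.
#' @return an [axis_calibration()].
#' @export
calibrate_axes <- function(reference_recs) {
  if (length(reference_recs) != 3L) {
    stop("need exactly three reference recordings (x, y, z)")
  }
  peaks <- vapply(seq_len(3L), function(i) {
    rec <- reference_recs[[i]]
    stopifnot(inherits(rec, "accel_recording"))
    max(abs(list(rec$ax, rec$ay, rec$az)[[i]]))
  }, numeric(1))
  if (any(peaks == 0)) {
    stop("zero response on axis ", paste(c("x", "y", "z")[peaks == 0],
      collapse = ", "
    ))
  }
  axis_calibration(1, peaks[1] / peaks[2], peaks[1] / peaks[3])
}
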