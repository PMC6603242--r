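#' Finite impulse response system
#' @param coefficients numeric impulse response (nonempty, finite).
#' @param rate sampling rate in Hz.
#' @return an object of class `fir_system`.
#' @export
fir_system <- function(coefficients, rate) {
  coefficients <- as.numeric(coefficients)
  if (!length(coefficients) || !all(is.finite(coefficients))) {
    stop("coefficients must be a nonempty finite numeric vector")
  }
  stopifnot(length(rate) == 1L, rate > 0)
  structure(list(coefficients = coefficients, rate = rate),
    class = "fir_system"
  )
}

#' @export
print.fir_system <- function(x, ...) {
  cat(sprintf(
    "<fir_system: %d taps @ %g Hz>\n", length(x$coefficients), x$rate
  ))
  invisible(x)
}

#' Equalizer filter with its design band
#' @param coefficients numeric FIR taps.
#' @param rate sampling rate in Hz.
#' @param band_hz length-2 vector `(f_lo, f_hi)` within (0, rate/2).
#' @return an object of class `equalizer_filter` (also a `fir_system`).
#' @export
equalizer_filter <- function(coefficients, rate, band_hz) {
  obj <- fir_system(coefficients, rate)
  if (!(length(band_hz) == 2L && band_hz[1] > 0 && band_hz[2] > band_hz[1] &&
    band_hz[2] < rate / 2)) {
    stop("band_hz must be (f_lo, f_hi) with 0 < f_lo < f_hi < rate/2")
  }
  obj$band_hz <- as.numeric(band_hz)
  class(obj) <- c("equalizer_filter", "fir_system")
  obj
}

#' NLMS configuration
#' @param filter_length number of adaptive taps (default 2048).
#' @param step_size NLMS step size mu in (0, 2); default 0.5.
#' @param regularization small positive constant delta added to the excitation
#'   norm (default 1e-6).
#' @param passes number of passes over the data (default 2).
#' @return an object of class `nlms_config`.
#' @export
nlms_config <- function(filter_length = 2048, step_size = 0.5,
                        regularization = 1e-6, passes = 2) {
  if (!(step_size >= 0 && step_size < 2)) stop("step_size must be in [0, 2)")
  if (regularization <= 0) stop("regularization must be > 0")
  if (filter_length < 1 || passes < 1) stop("filter_length and passes must be >= 1")
  structure(
    list(
      filter_length = as.integer(filter_length), step_size = step_size,
      regularization = regularization, passes = as.integer(passes)
    ),
    class = "nlms_config"
  )
}

# Primitive LFSR feedback taps (Fibonacci form), one per register length.
mls_taps <- list(
  `2` = c(2, 1), `3` = c(3, 2), `4` = c(4, 3), `5` = c(5, 3), `6` = c(6, 5),
  `7` = c(7, 6), `8` = c(8, 6, 5, 4), `9` = c(9, 5), `10` = c(10, 7),
  `11` = c(11, 9), `12` = c(12, 11, 10, 4), `13` = c(13, 12, 11, 8),
  `14` = c(14, 13, 12, 2), `15` = c(15, 14), `16` = c(16, 15, 13, 4),
  `17` = c(17, 14), `18` = c(18, 11), `19` = c(19, 18, 17, 14),
  `20` = c(20, 17)
)

#' Generate an excitation signal for system identification
#'
#' Either seeded Gaussian white noise (RMS exactly 0.5) or a bipolar
#' maximum-length sequence (MLS) of length `2^mls_order - 1` from a primitive
#' linear-feedback shift register. Both have the constant power spectral
#' density needed to identify the system at all frequencies of interest; the
#' MLS has the additional property that its periodic autocorrelation is
#' `N` at lag 0 and exactly `-1` at all other lags.
#'
#' @param kind `"white"` or `"mls"`.
#' @param duration_s duration in seconds (white noise).
#' @param mls_order LFSR register length, 2..20 (MLS).
#' @param rate sampling rate in Hz.
#' @param seed integer seed (white noise).
#' @return a [waveform()] with role `"prestimulus"`.
#' @export
generate_excitation <- function(kind = c("white", "mls"), duration_s = NULL,
                                mls_order = NULL, rate = 96000, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "white") {
    if (is.null(duration_s)) stop("white excitation needs duration_s")
    n <- round(duration_s * rate)
    x <- with_seed(seed, rnorm(n))
    x <- x / wav_rms(x) * 0.5
    return(waveform(x, rate, "prestimulus"))
  }
  if (is.null(mls_order) || mls_order < 2 || mls_order > 20) {
    stop("mls_order must be in [2, 20]")
  }
  taps <- mls_taps[[as.character(as.integer(mls_order))]]
  m <- as.integer(mls_order)
  n <- 2L^m - 1L
  reg <- rep(1L, m)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- reg[m]
    fb <- 0L
    for (tp in taps) fb <- bitwXor(fb, reg[tp])
    reg <- c(fb, reg[-m])
  }
  waveform(ifelse(out == 1L, 1, -1), rate, "prestimulus")
}

#' Identify an FIR system with the NLMS adaptive algorithm
#'
#' Iteratively minimizes the power of the error between the adaptive filter
#' output and the observed signal for a known excitation, yielding an FIR
#' estimate of the unknown (loudspeaker-enclosure-microphone) system.
#'
#' @param excitation [waveform()] or numeric vector: the known driving signal.
#' @param observed [waveform()] or numeric vector of the same rate and length:
#'   the recorded response.
#' @param cfg an [nlms_config()].
#' @param rate sampling rate in Hz; required when both inputs are bare
#'   vectors.
#' @return list with `estimate` (an [fir_system()]) and `error_power`
#'   (per-sample squared error over all passes).
#' @export
nlms_identify <- function(excitation, observed, cfg = nlms_config(),
                          rate = NULL) {
  get_samp <- function(w) if (inherits(w, "waveform")) w$samples else as.numeric(w)
  get_rate <- function(w) if (inherits(w, "waveform")) w$rate else NULL
  x <- get_samp(excitation)
  y <- get_samp(observed)
  rx <- get_rate(excitation) %||% rate
  ry <- get_rate(observed) %||% rate
  if (is.null(rx) || is.null(ry)) stop("rate must be given for bare vectors")
  if (rx != ry) stop("excitation and observed must share the sampling rate")
  if (length(x) != length(y)) stop("excitation and observed must be equal length")
  if (length(x) < cfg$filter_length) {
    stop("signals must be at least filter_length samples long")
  }
  if (sum(x^2) == 0) stop("excitation is silent; cannot identify the system")
  res <- .nlms_core(
    x, y, cfg$filter_length, cfg$step_size,
    cfg$regularization, cfg$passes
  )
  list(
    estimate = fir_system(res$w, rx),
    error_power = as.numeric(res$err2)
  )
}

# Minimum-phase impulse response (length n_fft) with the given full-circle
# magnitude spectrum, via the real cepstrum.
minphase_ir_from_mag <- function(mag) {
  n_fft <- length(mag)
  ceps <- Re(fft(log(mag), inverse = TRUE)) / n_fft
  fold <- numeric(n_fft)
  fold[1] <- ceps[1]
  half <- floor(n_fft / 2)
  fold[2:half] <- 2 * ceps[2:half]
  if (n_fft %% 2 == 0) fold[half + 1] <- ceps[half + 1]
  Re(fft(exp(fft(fold)), inverse = TRUE)) / n_fft
}

#' Minimum-phase component of an FIR system
#'
#' Real-cepstrum method: the log-magnitude spectrum is folded into a causal
#' cepstrum and exponentiated back, giving a system with the same magnitude
#' response (up to FFT-grid tolerance) and all zeros inside the unit circle.
#' Spectral magnitudes below a floor of -100 dB relative to the spectral peak
#' are raised to the floor (with a warning) to keep the logarithm bounded.
#'
#' @param h an [fir_system()] or numeric impulse response.
#' @param n_fft FFT length, at least `4 * length(h)`; default
#'   `max(4 * length(h), 4096)` rounded up to a power of two.
#' @param rate sampling rate when `h` is a bare vector.
#' @return an [fir_system()] of the same length as `h`.
#' @export
minimum_phase <- function(h, n_fft = NULL, rate = NULL) {
  if (!inherits(h, "fir_system")) h <- fir_system(h, rate %||% 1)
  co <- h$coefficients
  if (all(co == 0)) stop("cannot take the minimum phase of an all-zero system")
  n <- length(co)
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(max(4 * n, 4096)))
  if (n_fft < 4 * n) stop("n_fft must be at least 4 * length(h)")
  H <- fft(c(co, numeric(n_fft - n)))
  mag <- Mod(H)
  floor_mag <- max(mag) * 10^(-100 / 20)
  if (any(mag < floor_mag)) {
    warning("spectral magnitudes below -100 dB floored for cepstrum stability")
    mag <- pmax(mag, floor_mag)
  }
  hmp <- minphase_ir_from_mag(mag)
  fir_system(hmp[seq_len(n)], h$rate)
}

# Raised-cosine in-band weight with 1/6-octave transitions placed just
# outside the band, so the band itself is fully inverted (1 inside the band,
# 0 beyond the transitions).
band_weight <- function(f, band_hz) {
  lo1 <- band_hz[1] * 2^(-1 / 6)
  hi2 <- band_hz[2] * 2^(+1 / 6)
  w <- numeric(length(f))
  w[f >= band_hz[1] & f <= band_hz[2]] <- 1
  ri <- f > lo1 & f < band_hz[1]
  w[ri] <- sin(pi / 2 * (log2(f[ri] / lo1)) / (1 / 6))^2
  fa <- f > band_hz[2] & f < hi2
  w[fa] <- cos(pi / 2 * (log2(f[fa] / band_hz[2])) / (1 / 6))^2
  w
}

#' Invert (the minimum-phase component of) a transfer function over a band
#'
#' Frequency bin-wise Tikhonov-regularized inversion
#' \eqn{G(f) = H^*(f) / (|H(f)|^2 + \epsilon)} inside the band, unity gain
#' outside it, blended in the log-magnitude domain through raised-cosine
#' transitions of 1/6 octave placed just outside the band. The equalizer is
#' realized as the minimum-phase FIR with that magnitude (causal, near-zero
#' delay), obtained by inverse FFT and truncated to `n_taps` with a cosine
#' fade on the final quarter.
#'
#' @param h_mp minimum-phase [fir_system()] to invert.
#' @param band_hz length-2 band `(f_lo, f_hi)` in Hz, within (0, rate/2).
#' @param n_taps number of equalizer taps (>= 8; default 1024).
#' @param regularization Tikhonov epsilon relative to the peak of `|H|^2`
#'   (default 1e-4).
#' @return an [equalizer_filter()].
#' @export
invert_transfer <- function(h_mp, band_hz = c(2000, 20000), n_taps = 1024,
                            regularization = 1e-4) {
  stopifnot(inherits(h_mp, "fir_system"))
  if (n_taps < 8) stop("n_taps must be at least 8")
  rate <- h_mp$rate
  if (!(band_hz[1] > 0 && band_hz[2] > band_hz[1] && band_hz[2] < rate / 2)) {
    stop("band_hz must lie within (0, rate/2)")
  }
  n_fft <- 2^ceiling(log2(max(8 * n_taps, 4 * length(h_mp$coefficients), 1024)))
  H <- fft(c(h_mp$coefficients, numeric(n_fft - length(h_mp$coefficients))))
  eps <- regularization * max(Mod(H)^2)
  mag_inv <- Mod(H) / (Mod(H)^2 + eps) # magnitude of H* / (|H|^2 + eps)
  k <- 0:(n_fft / 2)
  fk <- k * rate / n_fft
  w_half <- band_weight(fk, band_hz)
  w <- c(w_half, rev(w_half[2:(n_fft / 2)]))
  log_mag <- w * log(pmax(mag_inv, 1e-12)) # unity (log 0) outside the band
  g <- minphase_ir_from_mag(exp(log_mag))
  taps <- g[seq_len(n_taps)]
  fade_n <- floor(n_taps / 4)
  if (fade_n > 0) {
    fade <- cos(pi / 2 * seq_len(fade_n) / fade_n)^2
    taps[n_taps - fade_n + seq_len(fade_n)] <-
      taps[n_taps - fade_n + seq_len(fade_n)] * fade
  }
  equalizer_filter(taps, rate, band_hz)
}

#' Design a loudspeaker equalizer from an excitation/recording pair
#'
#' Composition of [nlms_identify()], [minimum_phase()] and
#' [invert_transfer()]: identifies the loudspeaker-enclosure-microphone system
#' driven by a known excitation, inverts the minimum-phase component of the
#' identified transfer function over the requested band, and reports the
#' flatness of the equalized cascade.
#'
#' @param excitation known driving signal ([waveform()] or numeric).
#' @param recording observed response, same rate and length.
#' @param cfg an [nlms_config()].
#' @param band_hz equalization band; default 2-20 kHz.
#' @param n_taps equalizer length (default 1024).
#' @param regularization Tikhonov epsilon (relative; default 1e-4).
#' @param rate sampling rate for bare-vector inputs.
#' @return list with `filter` (an [equalizer_filter()]), `system` (the
#'   identified [fir_system()]), and `flatness_db` (max absolute in-band
#'   deviation of the equalized cascade from its mean level, in dB).
#' @export
design_equalizer <- function(excitation, recording, cfg = nlms_config(),
                             band_hz = c(2000, 20000), n_taps = 1024,
                             regularization = 1e-4, rate = NULL) {
  ident <- nlms_identify(excitation, recording, cfg, rate = rate)
  h_mp <- minimum_phase(ident$estimate)
  eq <- invert_transfer(h_mp, band_hz, n_taps, regularization)
  list(
    filter = eq,
    system = ident$estimate,
    flatness_db = cascade_flatness_db(eq, ident$estimate, band_hz)
  )
}

#' In-band flatness of an equalizer/system cascade
#'
#' Maximum absolute deviation (dB) of `|G(f) H(f)|` from its in-band mean.
#'
#' @param eq an [equalizer_filter()] (or `fir_system`).
#' @param h an [fir_system()].
#' @param band_hz evaluation band in Hz.
#' @param n_fft FFT grid (default 16384).
#' @return scalar deviation in dB.
#' @export
cascade_flatness_db <- function(eq, h, band_hz = eq$band_hz, n_fft = 16384) {
  casc <- convolve(eq$coefficients, rev(h$coefficients), type = "open")
  n_fft <- max(n_fft, 2^ceiling(log2(length(casc))))
  C <- fft(c(casc, numeric(n_fft - length(casc))))
  fk <- (0:(n_fft - 1)) * eq$rate / n_fft
  sel <- fk >= band_hz[1] & fk <= band_hz[2]
  db <- 20 * log10(Mod(C[sel]))
  max(abs(db - mean(db)))
}

#' Apply an equalizer filter to a waveform
#'
#' Linear (FFT-based) convolution of the waveform with the equalizer taps.
#' `output = "full"` returns all `length(w) + n_taps - 1` samples;
#' `output = "same"` returns the first `length(w)` samples, which for the
#' near-zero-delay minimum-phase equalizers designed here is the aligned
#' equalized signal. A warning reports clipping when the result exceeds
#' digital full scale.
#'
#' @param w a [waveform()].
#' @param eq an [equalizer_filter()] of matching rate.
#' @param output `"full"` or `"same"`.
#' @return a [waveform()]; attribute `clipped` flags full-scale overrun.
#' @export
apply_equalizer <- function(w, eq, output = c("full", "same")) {
  output <- match.arg(output)
  stopifnot(inherits(w, "waveform"), inherits(eq, "fir_system"))
  if (w$rate != eq$rate) stop("waveform and equalizer rates differ")
  y <- convolve(w$samples, rev(eq$coefficients), type = "open")
  if (output == "same") y <- y[seq_along(w$samples)]
  out <- waveform(y, w$rate, w$role)
  clipped <- any(abs(y) > 1)
  if (clipped && w$role != "trigger") {
    warning(sprintf(
      "equalized signal exceeds full scale (peak %.3f); reduce level or ref_dbspl",
      max(abs(y))
    ))
  }
  attr(out, "clipped") <- clipped
  out
}

#' Measure inter-channel latencies from recorded trigger pulses
#'
#' Each channel must contain exactly one rising edge above
#' `threshold_frac * max(channel)`; the offset of that edge relative to the
#' first channel's edge is returned, in samples.
#'
#' @param recorded_pulses list of [waveform()]s or numeric vectors, one per
#'   channel.
#' @param threshold_frac edge-detection threshold as a fraction of the channel
#'   maximum (default 0.5).
#' @return integer vector of per-channel offsets in samples (first channel 0).
#' @export
measure_latency <- function(recorded_pulses, threshold_frac = 0.5) {
  stopifnot(length(recorded_pulses) >= 1)
  edges <- vapply(seq_along(recorded_pulses), function(i) {
    x <- recorded_pulses[[i]]
    if (inherits(x, "waveform")) x <- x$samples
    if (max(x) <= 0) {
      stop(sprintf("channel %d: no pulse (no rising edge above threshold)", i))
    }
    thr <- threshold_frac * max(x)
    above <- x >= thr
    rising <- which(above & !c(FALSE, above[-length(above)]))
    if (length(rising) == 0) {
      stop(sprintf("channel %d: no rising edge above threshold", i))
    }
    if (length(rising) > 1) {
      stop(sprintf("channel %d: %d rising edges found, expected exactly one",
        i, length(rising)))
    }
    rising
  }, integer(1))
  edges - edges[1]
}
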