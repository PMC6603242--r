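# Shared fixture builders for the test suite. Everything is generated in code
# at test time; no stored data.

# Recording with a clean rectangular trigger and per-axis contents supplied by
# the caller (defaults to zeros).
make_recording <- function(n = 2000, rate = 1000, edge = 500,
                           ax = numeric(n), ay = numeric(n), az = numeric(n),
                           trig_len = 10) {
  trig <- numeric(n)
  trig[edge:(edge + trig_len - 1)] <- 1
  accel_recording(ax, ay, az, trig, rate = rate)
}

# Brute-force oracle for the ASR amplitude: direct evaluation of
# max over [0, window] of sqrt(sum (c_i a_i)^2), no filtering.
brute_force_asr <- function(ax, ay, az, cal, rate, window_s = 0.150) {
  a <- sqrt((cal$cx * ax)^2 + (cal$cy * ay)^2 + (cal$cz * az)^2)
  n_win <- floor(window_s * rate) + 1
  max(a[seq_len(n_win)])
}

# Magnitude response of an FIR on a dense grid restricted to a band.
fir_band_response_db <- function(coefficients, rate, band, n_fft = 16384) {
  H <- stats::fft(c(coefficients, numeric(n_fft - length(coefficients))))
  fk <- (0:(n_fft - 1)) * rate / n_fft
  sel <- fk >= band[1] & fk <= band[2]
  20 * log10(Mod(H[sel]))
}

# Small GPIAS protocol + simulated session used by several tests.
quick_gpias_session <- function(seed = 1, gpias_true = 0.5, n_repeats = 15,
                                rate = 2000, noise_rms = 0.002) {
  p <- build_gpias_protocol(8000, 0.5, n_repeats = n_repeats, seed = seed)
  an <- virtual_animal(gpias_true = gpias_true, seed = seed)
  pl <- virtual_platform(rate = rate, noise_rms = noise_rms)
  simulate_session(p, an, pl, trial_length_s = 0.8, trigger_onset_s = 0.4)
}
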