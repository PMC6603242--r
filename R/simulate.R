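#' Virtual animal: a generative model of startle behavior
#'
#' Startle amplitudes are log-normally distributed; a perceived pre-stimulus
#' inhibits the response multiplicatively. Gap trials are inhibited by the
#' fixed fraction `gpias_true`; tone trials follow a hard-sigmoid
#' stimulus-response function of pre-stimulus level (zero below
#' `threshold_dbspl`, rising with `slope` per dB, saturating at
#' `saturation`). Defaults emulate a normal-hearing gerbil-like responder:
#' log-amplitude scale 0.4 (amplitudes spread over roughly a factor 2-3, as
#' startle data typically are), a clear gap inhibition of 0.5, and a
#' threshold at 10 dB SPL with saturation 0.8.
#'
#' @param baseline_mu,baseline_sigma location and scale of the log startle
#'   amplitude (sensor units are arbitrary but consistent).
#' @param gpias_true fractional inhibition on gap trials, in \[0, 1\].
#' @param threshold_dbspl,slope,saturation hard-sigmoid PPI parameters.
#' @param seed integer seed; all per-trial draws derive from it.
#' @return an object of class `virtual_animal`.
#' @export
virtual_animal <- function(baseline_mu = 0, baseline_sigma = 0.4,
                           gpias_true = 0.5, threshold_dbspl = 10,
                           slope = 0.05, saturation = 0.8, seed = 1) {
  if (baseline_sigma <= 0) stop("baseline_sigma must be > 0")
  if (gpias_true < 0 || gpias_true > 1) stop("gpias_true must be in [0, 1]")
  if (saturation > 1 || saturation <= 0) stop("saturation must be in (0, 1]")
  structure(
    list(
      baseline_mu = baseline_mu, baseline_sigma = baseline_sigma,
      gpias_true = gpias_true, threshold_dbspl = threshold_dbspl,
      slope = slope, saturation = saturation, seed = as.integer(seed)
    ),
    class = "virtual_animal"
  )
}

#' Virtual sensor platform: spring-mounted plate with a 3-axis accelerometer
#'
#' The plate is modelled as one damped second-order mode per axis (springs
#' plus foam damping): a startle twitch excites a damped sinusoid
#' \eqn{g_{axis}\, e^{-\zeta \omega t} \sin(\omega_d t)} with per-axis gains,
#' on top of Gaussian sensor noise. Defaults: 15 Hz resonance (soft spring
#' suspension), damping ratio 0.3, mildly unequal axis gains, and a noise
#' floor about 40 dB below a unit-amplitude response.
#'
#' @param resonance_hz undamped resonance frequency of the plate (Hz).
#' @param damping_ratio damping ratio in (0, 1).
#' @param gains length-3 positive per-axis sensitivities (x, y, z).
#' @param noise_rms Gaussian sensor noise RMS per axis (sensor units).
#' @param rate acquisition sampling rate in Hz.
#' @return an object of class `virtual_platform`.
#' @export
virtual_platform <- function(resonance_hz = 15, damping_ratio = 0.3,
                             gains = c(1, 0.8, 1.2), noise_rms = 0.005,
                             rate = 10000) {
  if (!(damping_ratio > 0 && damping_ratio < 1)) {
    stop("damping_ratio must be in (0, 1)")
  }
  if (length(gains) != 3 || any(gains <= 0)) {
    stop("gains must be three positive values")
  }
  structure(
    list(
      resonance_hz = resonance_hz, damping_ratio = damping_ratio,
      gains = as.numeric(gains), noise_rms = noise_rms, rate = rate
    ),
    class = "virtual_platform"
  )
}

#' True inhibition fraction implied by the animal model for one trial
#' @param animal a [virtual_animal()].
#' @param spec a [trial_spec()].
#' @return inhibition fraction in \[0, 1\].
#' @export
true_inhibition <- function(animal, spec) {
  switch(spec$kind,
    gap = animal$gpias_true,
    tone = hard_sigmoid(
      spec$tone_level_dbspl, animal$threshold_dbspl,
      animal$slope, animal$saturation
    ),
    0
  )
}

#' Draw one trial's true startle amplitude
#'
#' `amplitude = exp(N(baseline_mu, baseline_sigma^2)) * (1 - I)` where `I` is
#' the trial's inhibition fraction ([true_inhibition()]). Deterministic per
#' (animal seed, trial index).
#'
#' @param animal a [virtual_animal()].
#' @param spec a [trial_spec()].
#' @param index trial index within the session (drives the per-trial seed).
#' @return positive amplitude.
#' @export
draw_trial_amplitude <- function(animal, spec, index = 1) {
  stopifnot(inherits(animal, "virtual_animal"), inherits(spec, "trial_spec"))
  z <- with_seed(trial_seed(animal$seed, index), rnorm(1))
  exp(animal$baseline_mu + animal$baseline_sigma * z) *
    (1 - true_inhibition(animal, spec))
}

#' Render a startle twitch into a synthetic 3-axis acceleration trace
#'
#' Each axis carries the platform's damped-sinusoid mode scaled by the axis
#' gain, starting `latency_s` after the trigger rising edge, plus Gaussian
#' sensor noise; the trigger channel is a 10 ms rectangular pulse at
#' `trigger_onset_s`. The mode shape is normalized so that, with the correct
#' [axis_calibration()] (and an x-gain of 1), the extracted ASR amplitude
#' equals `amplitude` up to the (sub-percent) attenuation of the 40 Hz
#' low-pass.
#'
#' @param amplitude true response amplitude (>= 0).
#' @param platform a [virtual_platform()].
#' @param trial_length_s total recording length in seconds.
#' @param trigger_onset_s trigger edge time in seconds.
#' @param seed integer seed for the sensor noise.
#' @param latency_s motor latency from trigger to movement onset (default
#'   20 ms).
#' @return an [accel_recording()] (unaligned).
#' @export
render_accel_trace <- function(amplitude, platform, trial_length_s = 1,
                               trigger_onset_s = 0.5, seed = 1,
                               latency_s = 0.020) {
  stopifnot(inherits(platform, "virtual_platform"))
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (trigger_onset_s + 0.2 > trial_length_s) {
    stop("trial too short: need at least 0.2 s after trigger onset")
  }
  rate <- platform$rate
  n <- round(trial_length_s * rate)
  t <- (seq_len(n) - 1) / rate
  tau <- t - (trigger_onset_s + latency_s)
  om <- 2 * pi * platform$resonance_hz
  zeta <- platform$damping_ratio
  omd <- om * sqrt(1 - zeta^2)
  s <- ifelse(tau >= 0, exp(-zeta * om * pmax(tau, 0)) * sin(omd * pmax(tau, 0)), 0)
  pk <- max(abs(s))
  if (pk > 0) s <- s / pk
  if (platform$noise_rms > amplitude / sqrt(3) && amplitude > 0) {
    warning("sensor noise RMS exceeds the per-axis signal scale")
  }
  noise <- with_seed(seed, matrix(rnorm(3 * n), ncol = 3)) * platform$noise_rms
  g <- platform$gains
  ax <- g[1] * amplitude / sqrt(3) * s + noise[, 1]
  ay <- g[2] * amplitude / sqrt(3) * s + noise[, 2]
  az <- g[3] * amplitude / sqrt(3) * s + noise[, 3]
  trig <- numeric(n)
  i0 <- round(trigger_onset_s * rate)
  trig[i0 + seq_len(min(round(0.010 * rate), n - i0))] <- 1
  accel_recording(ax, ay, az, trig, rate)
}

#' Axis calibration matching a virtual platform
#'
#' The exact calibration factors for a [virtual_platform()]'s gains,
#' normalized so `cx = 1`.
#' @param platform a [virtual_platform()].
#' @return an [axis_calibration()].
#' @export
platform_calibration <- function(platform) {
  g <- platform$gains
  axis_calibration(1, g[1] / g[2], g[1] / g[3])
}

#' Simulate a complete measurement session
#'
#' Draws a true amplitude for every trial of the protocol (habituation trials
#' carry zero inhibition) and renders it through the virtual platform into an
#' acceleration recording, producing raw data plus a ground-truth table for
#' recovery tests.
#'
#' @param protocol an [asr_protocol()].
#' @param animal a [virtual_animal()].
#' @param platform a [virtual_platform()].
#' @param trial_length_s recording length per trial (default 1 s).
#' @param trigger_onset_s trigger time within each trial (default 0.5 s).
#' @return list of class `simulated_session`: `recordings` (list of
#'   [accel_recording()]), `truth` (data frame: `trial`, `kind`, `freq`,
#'   `level`, `inhibition`, `amplitude`, `habituation`), `protocol`,
#'   `animal`, `platform`.
#' @export
simulate_session <- function(protocol, animal = virtual_animal(),
                             platform = virtual_platform(),
                             trial_length_s = 1, trigger_onset_s = 0.5) {
  stopifnot(inherits(protocol, "asr_protocol"))
  n <- length(protocol$trials)
  hab <- validate_protocol(protocol)$habituation_n
  recs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- protocol$trials[[i]]
    amp <- draw_trial_amplitude(animal, sp, i)
    recs[[i]] <- render_accel_trace(
      amp, platform, trial_length_s, trigger_onset_s,
      seed = trial_seed(animal$seed, 500000L + i)
    )
    rows[[i]] <- data.frame(
      trial = i, kind = sp$kind,
      freq = if (sp$kind %in% c("gap", "nogap")) sp$center_freq_hz else sp$tone_freq_hz,
      level = sp$tone_level_dbspl,
      inhibition = true_inhibition(animal, sp),
      amplitude = amp, habituation = i <= hab
    )
  }
  structure(
    list(
      recordings = recs, truth = do.call(rbind, rows),
      protocol = protocol, animal = animal, platform = platform
    ),
    class = "simulated_session"
  )
}

#' Extract per-trial ASR amplitudes from a simulated session
#'
#' Runs the full measurement pipeline ([extract_asr()]) on every recording and
#' returns the amplitude table expected by [analyze_gpias()] /
#' [analyze_threshold()].
#'
#' @param session a [simulate_session()] result.
#' @param cal an [axis_calibration()]; defaults to the platform's exact
#'   calibration.
#' @param lowpass_hz low-pass cutoff (default 40 Hz).
#' @param window_s ASR window (default 150 ms).
#' @return data frame: `trial`, `kind`, `freq`, `level`, `amplitude`,
#'   `habituation`.
#' @export
extract_session_amplitudes <- function(session,
                                       cal = platform_calibration(session$platform),
                                       lowpass_hz = 40, window_s = 0.150) {
  stopifnot(inherits(session, "simulated_session"))
  amps <- vapply(session$recordings, function(rec) {
    extract_asr(rec, cal, lowpass_hz, window_s)$value
  }, numeric(1))
  out <- session$truth[, c("trial", "kind", "freq", "level", "habituation")]
  out$amplitude <- amps
  out
}

#' Simulate a colored minimum-phase loudspeaker-enclosure-microphone system
#'
#' Builds a random smooth log-magnitude response (a sum of Gaussian bumps on a
#' log-frequency axis across 2-20 kHz, tapered to flat outside the band),
#' scaled so the largest in-band deviation is `+/- coloration_db`, then
#' reconstructs the minimum-phase FIR with that magnitude via the real
#' cepstrum. Deterministic per seed.
#'
#' @param rate sampling rate in Hz (default 48 kHz).
#' @param n_taps FIR length (default 256).
#' @param coloration_db maximum absolute in-band magnitude deviation in dB
#'   (>= 0); 0 gives a flat (near-delta) system.
#' @param seed integer seed.
#' @return an [fir_system()].
#' @export
simulate_lems <- function(rate = 48000, n_taps = 256, coloration_db = 6,
                          seed = 1) {
  if (coloration_db < 0) stop("coloration_db must be >= 0")
  n_fft <- 2^ceiling(log2(max(16 * n_taps, 4096)))
  k <- 0:(n_fft / 2)
  fk <- k * rate / n_fft
  band <- c(2000, 20000)
  dev <- numeric(length(fk))
  if (coloration_db > 0) {
    bumps <- with_seed(seed, {
      data.frame(
        center = 2^runif(8, log2(band[1]), log2(band[2])),
        width = runif(8, 0.3, 0.8), amp = rnorm(8)
      )
    })
    lf <- log2(pmax(fk, 1))
    for (b in seq_len(nrow(bumps))) {
      dev <- dev + bumps$amp[b] *
        exp(-0.5 * ((lf - log2(bumps$center[b])) / bumps$width[b])^2)
    }
    inb <- fk >= band[1] & fk <= band[2]
    dev <- dev - mean(range(dev[inb]))
    dev <- dev * coloration_db / max(abs(dev[inb]))
    # taper the coloration to zero towards DC and Nyquist
    taper <- band_weight(fk, c(band[1] / 2, min(band[2] * 1.5, rate / 2 / 1.1)))
    dev <- dev * taper
  }
  mag_half <- 10^(dev / 20)
  mag <- c(mag_half, rev(mag_half[2:(n_fft / 2)]))
  # zero-phase prototype -> minimum-phase via the real cepstrum
  ceps <- Re(fft(log(mag), inverse = TRUE)) / n_fft
  fold <- numeric(n_fft)
  fold[1] <- ceps[1]
  half <- n_fft / 2
  fold[2:half] <- 2 * ceps[2:half]
  fold[half + 1] <- ceps[half + 1]
  h <- Re(fft(exp(fft(fold)), inverse = TRUE)) / n_fft
  fir_system(h[seq_len(n_taps)], rate)
}
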