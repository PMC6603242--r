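#' Synthesize a pure tone with sin^2 on/off ramps
#'
#' The tone plateau (the part outside the ramps) has RMS exactly equal to
#' `dbspl_to_amplitude(level_dbspl, cal)`, so the reported level refers to the
#' steady-state portion of the tone.
#'
#' @param freq_hz tone frequency in Hz, strictly below Nyquist.
#' @param duration_s total tone duration in seconds (ramps included).
#' @param level_dbspl tone level in dB SPL.
#' @param ramp_s duration of each sin^2 ramp (default 5 ms).
#' @param rate sampling rate in Hz (default 96 kHz).
#' @param cal a [level_calibration()].
#' @return a [waveform()] with role `"prestimulus"`.
#' @export
synth_pure_tone <- function(freq_hz, duration_s, level_dbspl,
                            ramp_s = 0.005, rate = 96000,
                            cal = level_calibration()) {
  if (!(freq_hz > 0 && freq_hz < rate / 2)) {
    stop(sprintf(
      "freq_hz must lie in (0, %g) Hz (Nyquist) at rate %g Hz",
      rate / 2, rate
    ))
  }
  if (duration_s < 0 || ramp_s < 0) stop("durations must be non-negative")
  n <- round(duration_s * rate)
  if (n == 0) return(waveform(numeric(0), rate, "prestimulus"))
  if (2 * ramp_s > duration_s) stop("ramps (2 * ramp_s) exceed tone duration")
  t <- (seq_len(n) - 1) / rate
  x <- sin(2 * pi * freq_hz * t)
  nr <- round(ramp_s * rate)
  env <- rep(1, n)
  if (nr > 0) {
    r <- sin(pi / 2 * (seq_len(nr) - 0.5) / nr)^2
    env[seq_len(nr)] <- r
    env[n - nr + seq_len(nr)] <- rev(r)
  }
  plateau <- if (nr > 0 && n > 2 * nr) (nr + 1):(n - nr) else seq_len(n)
  amp <- dbspl_to_amplitude(level_dbspl, cal)
  x <- x / wav_rms(x[plateau]) * amp
  waveform(x * env, rate, "prestimulus")
}

#' Synthesize band-limited noise by frequency-domain construction
#'
#' Uniform spectral magnitude with independent uniform random phases inside
#' the band \eqn{[f_c 2^{-w}, f_c 2^{+w}]} and exactly zero outside (brick-wall
#' band edges), inverse-transformed to the time domain and RMS-scaled to the
#' requested level. Deterministic given `seed`.
#'
#' @param center_freq_hz band center frequency in Hz.
#' @param half_width_octaves half bandwidth in octaves (band edges at
#'   `center_freq_hz * 2^(+/- half_width_octaves)`).
#' @param duration_s duration in seconds.
#' @param level_dbspl noise level (RMS) in dB SPL.
#' @param rate sampling rate in Hz.
#' @param seed integer seed for the random phases.
#' @param cal a [level_calibration()].
#' @return a [waveform()] with role `"prestimulus"`.
#' @export
synth_band_noise <- function(center_freq_hz, half_width_octaves, duration_s,
                             level_dbspl, rate = 96000, seed = 1,
                             cal = level_calibration()) {
  f_lo <- center_freq_hz * 2^(-half_width_octaves)
  f_hi <- center_freq_hz * 2^(+half_width_octaves)
  if (!(f_lo > 0 && f_hi < rate / 2)) {
    stop(sprintf(
      "noise band [%.1f, %.1f] Hz must lie within (0, %g) Hz",
      f_lo, f_hi, rate / 2
    ))
  }
  n <- round(duration_s * rate)
  if (n == 0) return(waveform(numeric(0), rate, "prestimulus"))
  # positive-frequency bins strictly inside (0, Nyquist)
  kmax <- ceiling(n / 2) - 1
  k <- seq_len(kmax)
  fk <- k * rate / n
  inband <- k[fk >= f_lo & fk <= f_hi]
  if (!length(inband)) stop("noise band contains no frequency bin; increase duration")
  spec <- complex(length.out = n)
  phases <- with_seed(seed, runif(length(inband), 0, 2 * pi))
  spec[inband + 1] <- exp(1i * phases)
  spec[n - inband + 1] <- Conj(spec[inband + 1])
  x <- Re(fft(spec, inverse = TRUE)) / n
  amp <- dbspl_to_amplitude(level_dbspl, cal)
  x <- x / wav_rms(x) * amp
  waveform(x, rate, "prestimulus")
}

#' Insert a sin^2-ramped gap of silence into a waveform
#'
#' The envelope is multiplied by a notch that falls to zero with a sin^2 ramp,
#' stays at zero, and recovers with a mirrored ramp. The gap duration is
#' measured between the half-amplitude points of the two ramps, which conserves
#' the nominal gap length under ramping: the fully silent plateau lasts
#' `gap_duration_s - ramp_s` and the whole notch spans
#' `gap_duration_s + ramp_s`.
#'
#' @param w a [waveform()].
#' @param gap_center_offset_s time of the gap center from waveform start (s).
#' @param gap_duration_s gap duration between half-amplitude points (default
#'   50 ms). A zero-duration gap leaves the waveform unchanged.
#' @param ramp_s sin^2 ramp duration (default 20 ms); must not exceed
#'   `gap_duration_s`.
#' @return a [waveform()] of the same length, role preserved.
#' @export
insert_gap <- function(w, gap_center_offset_s, gap_duration_s = 0.050,
                       ramp_s = 0.020) {
  stopifnot(inherits(w, "waveform"))
  if (gap_duration_s < 0 || ramp_s < 0) stop("durations must be non-negative")
  if (gap_duration_s == 0) return(w)
  if (ramp_s > gap_duration_s) stop("ramp_s must not exceed gap_duration_s")
  dur <- wav_duration(w)
  t_start <- gap_center_offset_s - gap_duration_s / 2 - ramp_s / 2
  t_end <- gap_center_offset_s + gap_duration_s / 2 + ramp_s / 2
  if (t_start < 0 || t_end > dur) {
    stop(sprintf(
      "gap [%.4f, %.4f] s extends past the waveform [0, %.4f] s",
      t_start, t_end, dur
    ))
  }
  t <- (seq_along(w$samples) - 1) / w$rate
  env <- rep(1, length(t))
  if (ramp_s > 0) {
    dn <- t >= t_start & t < t_start + ramp_s
    env[dn] <- cos(pi / 2 * (t[dn] - t_start) / ramp_s)^2
    up0 <- t_end - ramp_s
    up <- t >= up0 & t < t_end
    env[up] <- sin(pi / 2 * (t[up] - up0) / ramp_s)^2
  }
  env[t >= t_start + ramp_s & t < t_end - ramp_s] <- 0
  waveform(w$samples * env, w$rate, w$role)
}

#' Synthesize a broadband white-noise startle burst
#'
#' Gaussian white noise rescaled to an RMS of exactly
#' `dbspl_to_amplitude(level_dbspl, cal)`; deterministic given `seed`.
#'
#' @param duration_s burst duration in seconds (default 20 ms).
#' @param level_dbspl burst level in dB SPL (default 115).
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @param cal a [level_calibration()].
#' @return a [waveform()] with role `"startle"`.
#' @export
synth_startle_burst <- function(duration_s = 0.020, level_dbspl = 115,
                                rate = 96000, seed = 1,
                                cal = level_calibration()) {
  n <- round(duration_s * rate)
  if (n == 0) return(waveform(numeric(0), rate, "startle"))
  x <- with_seed(seed, rnorm(n))
  amp <- dbspl_to_amplitude(level_dbspl, cal)
  waveform(x / wav_rms(x) * amp, rate, "startle")
}

#' Specification of a single trial
#'
#' Declarative description of one trial of a startle paradigm. `kind` selects
#' the pre-stimulus condition: a silent gap in background band noise (`gap`),
#' the same noise without a gap (`nogap`), a pure-tone pre-pulse (`tone`), the
#' matching silent baseline (`notone`), or a bare startle pulse
#' (`startle_only`, used for habituation).
#'
#' @param kind trial kind; see above.
#' @param center_freq_hz background-noise center frequency (gap/nogap trials).
#' @param half_width_octaves background-noise half bandwidth in octaves.
#' @param noise_level_dbspl background-noise level (gap/nogap; default 60).
#' @param tone_freq_hz pre-pulse tone frequency (tone trials).
#' @param tone_level_dbspl pre-pulse tone level (tone trials).
#' @param gap_duration_s gap duration, half-amplitude to half-amplitude
#'   (default 50 ms).
#' @param gap_ramp_s gap sin^2 ramp duration (default 20 ms).
#' @param tone_duration_s pre-pulse tone duration (default 40 ms).
#' @param lead_interval_s pre-stimulus lead interval (default 100 ms): tone
#'   onset to startle onset for tone trials, gap end to startle onset for gap
#'   trials.
#' @param startle_duration_s startle burst duration (default 20 ms).
#' @param startle_level_dbspl startle burst level (default 115 dB SPL).
#' @param noise_seed integer seed for all stochastic stimulus components of
#'   this trial.
#' @return an object of class `trial_spec`.
#' @export
trial_spec <- function(kind = c("gap", "nogap", "tone", "notone", "startle_only"),
                       center_freq_hz = 8000, half_width_octaves = 0.5,
                       noise_level_dbspl = 60,
                       tone_freq_hz = NA_real_, tone_level_dbspl = NA_real_,
                       gap_duration_s = 0.050, gap_ramp_s = 0.020,
                       tone_duration_s = 0.040, lead_interval_s = 0.100,
                       startle_duration_s = 0.020, startle_level_dbspl = 115,
                       noise_seed = 1L) {
  kind <- match.arg(kind)
  durs <- c(
    gap_duration_s, gap_ramp_s, tone_duration_s, lead_interval_s,
    startle_duration_s
  )
  if (any(durs < 0)) stop("durations must be non-negative")
  if (gap_ramp_s > gap_duration_s && gap_duration_s > 0) {
    stop("gap_ramp_s must not exceed gap_duration_s")
  }
  if (kind == "tone") {
    if (!is.finite(tone_freq_hz) || !is.finite(tone_level_dbspl)) {
      stop("tone trials need tone_freq_hz and tone_level_dbspl")
    }
    if (lead_interval_s < tone_duration_s) {
      stop("lead_interval_s must be >= tone_duration_s for tone trials")
    }
  }
  structure(
    list(
      kind = kind, center_freq_hz = center_freq_hz,
      half_width_octaves = half_width_octaves,
      noise_level_dbspl = noise_level_dbspl,
      tone_freq_hz = tone_freq_hz, tone_level_dbspl = tone_level_dbspl,
      gap_duration_s = gap_duration_s, gap_ramp_s = gap_ramp_s,
      tone_duration_s = tone_duration_s, lead_interval_s = lead_interval_s,
      startle_duration_s = startle_duration_s,
      startle_level_dbspl = startle_level_dbspl,
      noise_seed = as.integer(noise_seed)
    ),
    class = "trial_spec"
  )
}

#' Assemble the three output channels of one trial
#'
#' Renders a [trial_spec()] into three sample-aligned, equal-length channels:
#' the pre-stimulus channel (background noise with or without a gap, a tone
#' pre-pulse, or silence), the startle channel (noise burst at
#' `startle_onset_s`), and the trigger channel (a rectangular pulse whose
#' rising edge coincides with startle onset).
#'
#' Timing conventions: tone onset precedes startle onset by
#' `lead_interval_s`; the gap *ends* (half-amplitude point of the recovery
#' ramp) `lead_interval_s` before startle onset.
#'
#' @param spec a [trial_spec()].
#' @param rate sampling rate in Hz (default 96 kHz).
#' @param cal a [level_calibration()].
#' @param startle_onset_s startle onset time within the trial (default 0.6 s).
#' @param total_duration_s total trial duration (default 1 s).
#' @param trigger_duration_s trigger pulse duration (default 10 ms).
#' @return named list of three [waveform()]s: `prestimulus`, `startle`,
#'   `trigger`.
#' @export
assemble_trial <- function(spec, rate = 96000, cal = level_calibration(),
                           startle_onset_s = 0.6, total_duration_s = 1.0,
                           trigger_duration_s = 0.010) {
  stopifnot(inherits(spec, "trial_spec"))
  n <- round(total_duration_s * rate)
  i_onset <- round(startle_onset_s * rate) # 0-based sample of startle onset
  if (i_onset < 0 || i_onset >= n) stop("startle onset outside the trial")
  if (startle_onset_s + spec$startle_duration_s > total_duration_s) {
    stop("startle burst extends past the end of the trial")
  }

  burst <- synth_startle_burst(
    spec$startle_duration_s, spec$startle_level_dbspl, rate,
    seed = trial_seed(spec$noise_seed, 2L), cal = cal
  )
  startle <- numeric(n)
  if (length(burst$samples)) {
    startle[i_onset + seq_along(burst$samples)] <- burst$samples
  }

  trigger <- numeric(n)
  n_trig <- max(1L, round(trigger_duration_s * rate))
  trigger[i_onset + seq_len(min(n_trig, n - i_onset))] <- 1

  pre <- numeric(n)
  if (spec$kind %in% c("gap", "nogap")) {
    noise <- synth_band_noise(
      spec$center_freq_hz, spec$half_width_octaves, total_duration_s,
      spec$noise_level_dbspl, rate,
      seed = trial_seed(spec$noise_seed, 1L), cal = cal
    )
    w <- noise
    if (spec$kind == "gap" && spec$gap_duration_s > 0) {
      gap_end <- startle_onset_s - spec$lead_interval_s
      gc <- gap_end - spec$gap_duration_s / 2
      w <- insert_gap(noise, gc, spec$gap_duration_s, spec$gap_ramp_s)
    }
    pre <- w$samples
  } else if (spec$kind == "tone") {
    tone <- synth_pure_tone(
      spec$tone_freq_hz, spec$tone_duration_s, spec$tone_level_dbspl,
      rate = rate, cal = cal
    )
    t_on <- startle_onset_s - spec$lead_interval_s
    i_on <- round(t_on * rate)
    if (i_on < 0) stop("tone onset precedes trial start; increase startle_onset_s")
    pre[i_on + seq_along(tone$samples)] <- tone$samples
  } # notone / startle_only: silence

  list(
    prestimulus = waveform(pre, rate, "prestimulus"),
    startle = waveform(startle, rate, "startle"),
    trigger = waveform(trigger, rate, "trigger")
  )
}
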