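test_that("MLS excitation has the maximum-length autocorrelation property", {
  for (order in c(4, 7, 10)) {
    m <- generate_excitation("mls", mls_order = order, rate = 48000)
    n <- 2^order - 1
    expect_length(m$samples, n)
    expect_setequal(unique(m$samples), c(-1, 1))
    # brute-force periodic autocorrelation: peak N, off-peak exactly -1
    x <- m$samples
    ac <- vapply(0:(n - 1), function(lag) {
      sum(x * x[(seq_len(n) + lag - 1) %% n + 1])
    }, numeric(1))
    expect_equal(ac[1], n)
    expect_true(all(ac[-1] == -1))
  }
  expect_error(generate_excitation("mls", mls_order = 25), "mls_order")
})

test_that("white excitation is seeded and RMS-0.5", {
  w1 <- generate_excitation("white", duration_s = 0.1, rate = 48000, seed = 3)
  w2 <- generate_excitation("white", duration_s = 0.1, rate = 48000, seed = 3)
  expect_identical(w1$samples, w2$samples)
  expect_equal(wav_rms(w1), 0.5, tolerance = 1e-12)
})

test_that("NLMS identifies known FIR systems", {
  # one-tap system, noiseless
  x <- generate_excitation("white", duration_s = 0.05, rate = 8000, seed = 1)
  y <- waveform(0.5 * x$samples, 8000, "prestimulus")
  res <- nlms_identify(x, y, nlms_config(filter_length = 1, passes = 1))
  expect_equal(res$estimate$coefficients, 0.5, tolerance = 1e-6)

  # random 64-tap FIR, white excitation, 2 s at 48 kHz, noiseless:
  # relative misalignment below 1e-3
  h <- with_seed(21, rnorm(64)) * exp(-(0:63) / 16)
  x2 <- generate_excitation("white", duration_s = 2, rate = 48000, seed = 2)
  y2 <- waveform(
    stats::convolve(x2$samples, rev(h), type = "open")[seq_along(x2$samples)],
    48000, "prestimulus"
  )
  res2 <- nlms_identify(x2, y2, nlms_config(filter_length = 64, passes = 2))
  mis <- sqrt(sum((res2$estimate$coefficients - h)^2) / sum(h^2))
  expect_lt(mis, 1e-3)

  # zero step size: no update from the zero initialization
  res3 <- nlms_identify(x, y, nlms_config(filter_length = 8, step_size = 0))
  expect_equal(res3$estimate$coefficients, numeric(8))

  # silent excitation rejected
  expect_error(
    nlms_identify(
      waveform(numeric(100), 8000, "prestimulus"),
      waveform(numeric(100), 8000, "prestimulus"),
      nlms_config(filter_length = 4)
    ),
    "silent"
  )
})

test_that("NLMS error power trends downward on stationary white excitation", {
  h <- c(1, -0.4, 0.2, 0.1)
  x <- generate_excitation("white", duration_s = 0.5, rate = 8000, seed = 9)
  y <- stats::convolve(x$samples, rev(h), type = "open")[seq_along(x$samples)]
  res <- nlms_identify(x, y, nlms_config(filter_length = 8, passes = 1),
    rate = 8000
  )
  e2 <- res$error_power
  blocks <- split(e2, cut(seq_along(e2), 8, labels = FALSE))
  sm <- vapply(blocks, mean, numeric(1))
  # monotone downward trend of the smoothed error power (small wiggles at the
  # numerical floor tolerated), with large overall decay
  expect_true(all(diff(log10(sm)) <= 0.5))
  expect_lt(sm[8], sm[1] * 1e-6)
})

test_that("minimum-phase extraction preserves the magnitude spectrum", {
  # already minimum-phase: recovered
  h1 <- fir_system(c(1, 0.5), 48000)
  mp1 <- minimum_phase(h1)
  expect_equal(mp1$coefficients, c(1, 0.5), tolerance = 1e-6)

  # maximum-phase input: same magnitude, zeros reflected inside
  h2 <- fir_system(c(0.5, 1), 48000)
  mp2 <- minimum_phase(h2)
  n_fft <- 4096
  mag_in <- Mod(stats::fft(c(h2$coefficients, numeric(n_fft - 2))))
  mag_out <- Mod(stats::fft(c(mp2$coefficients, numeric(n_fft - 2))))
  expect_equal(20 * log10(mag_out), 20 * log10(mag_in), tolerance = 1e-6)
  expect_lt(Mod(polyroot(rev(mp2$coefficients))), 1)

  # impulse maps to impulse
  expect_equal(minimum_phase(fir_system(c(1), 48000))$coefficients, 1,
    tolerance = 1e-9
  )

  # magnitude preservation on a realistic colored system: < 0.01 dB binwise
  lems <- simulate_lems(48000, n_taps = 256, coloration_db = 6, seed = 4)
  mp <- minimum_phase(lems)
  n_fft <- 8192
  pad <- function(co) Mod(stats::fft(c(co, numeric(n_fft - length(co)))))
  fk <- (0:(n_fft - 1)) * 48000 / n_fft
  sel <- fk >= 500 & fk <= 23000
  d_db <- 20 * log10(pad(mp$coefficients)[sel] / pad(lems$coefficients)[sel])
  expect_lt(max(abs(d_db)), 0.01)
})

test_that("band-limited inversion flattens a delay+gain system", {
  rate <- 48000
  h <- fir_system(c(numeric(10), 2), rate) # 10-sample delay, gain 2
  hmp <- minimum_phase(h)
  eq <- invert_transfer(hmp, c(2000, 20000), n_taps = 512)
  flat <- cascade_flatness_db(eq, h)
  expect_lt(flat, 0.1)

  # heavy regularization drives the in-band equalizer gain towards zero
  eq_reg <- invert_transfer(hmp, c(2000, 20000), n_taps = 512,
    regularization = 1e6)
  resp <- fir_band_response_db(eq_reg$coefficients, rate, c(4000, 10000))
  expect_true(all(resp < -40))

  expect_error(invert_transfer(hmp, c(2000, 20000), n_taps = 4), "n_taps")
  expect_error(invert_transfer(hmp, c(2000, 30000), n_taps = 64), "band")
})

test_that("design_equalizer flattens a colored LEMS to within 1 dB", {
  rate <- 48000
  lems <- simulate_lems(rate, n_taps = 256, coloration_db = 6, seed = 12)
  x <- generate_excitation("white", duration_s = 2, rate = rate, seed = 5)
  y <- stats::convolve(x$samples, rev(lems$coefficients),
    type = "open"
  )[seq_along(x$samples)]
  des <- design_equalizer(x, y,
    nlms_config(filter_length = 384, passes = 2),
    band_hz = c(2000, 20000), n_taps = 1024, rate = rate
  )
  expect_equal(des$filter$band_hz, c(2000, 20000))
  # before equalization the cascade deviation is the coloration itself
  raw_db <- fir_band_response_db(lems$coefficients, rate, c(2000, 20000))
  expect_gt(max(abs(raw_db - mean(raw_db))), 2)
  expect_lt(des$flatness_db, 1)

  # identity system gives a near-delta equalizer
  y_id <- x$samples
  des_id <- design_equalizer(x, y_id, nlms_config(filter_length = 64),
    n_taps = 256, rate = rate
  )
  expect_lt(des_id$flatness_db, 0.1)
})

test_that("apply_equalizer is a linear convolution with clipping report", {
  rate <- 48000
  w <- synth_band_noise(8000, 0.5, 0.01, 90, rate = rate, seed = 6)
  # unit impulse equalizer: identity
  eq1 <- equalizer_filter(c(1, numeric(15)), rate, c(2000, 20000))
  out <- apply_equalizer(w, eq1, output = "same")
  expect_equal(out$samples, w$samples, tolerance = 1e-12)
  # linearity
  eqr <- equalizer_filter(with_seed(8, rnorm(16)) / 8, rate, c(2000, 20000))
  o1 <- apply_equalizer(w, eqr)
  w2 <- waveform(2.5 * w$samples, rate, w$role)
  o2 <- suppressWarnings(apply_equalizer(w2, eqr))
  expect_equal(o2$samples, 2.5 * o1$samples, tolerance = 1e-9)
  # matches the direct O(N*M) convolution sum
  xs <- with_seed(9, rnorm(30))
  ws <- waveform(xs / max(abs(xs)) / 2, rate, "prestimulus")
  direct <- numeric(30 + 16 - 1)
  for (i in seq_len(30)) {
    for (j in seq_len(16)) direct[i + j - 1] <- direct[i + j - 1] +
        ws$samples[i] * eqr$coefficients[j]
  }
  expect_equal(apply_equalizer(ws, eqr)$samples, direct, tolerance = 1e-12)
  # rate mismatch rejected
  expect_error(
    apply_equalizer(waveform(xs, 96000, "prestimulus"), eqr),
    "rate"
  )
  # clipping reported
  loud <- waveform(rep(0.9, 100), rate, "prestimulus")
  eq_gain <- equalizer_filter(c(2), rate, c(2000, 20000))
  expect_warning(res <- apply_equalizer(loud, eq_gain), "full scale")
  expect_true(attr(res, "clipped"))
})

test_that("latency measurement recovers constructed channel offsets", {
  pulse <- function(delay, n = 400) {
    x <- numeric(n)
    x[delay + 50:80] <- 1
    x
  }
  expect_equal(measure_latency(list(pulse(0), pulse(0), pulse(0))), c(0, 0, 0))
  expect_equal(measure_latency(list(pulse(0), pulse(10))), c(0, 10))
  shifts <- c(0, 17, 3)
  expect_equal(measure_latency(lapply(shifts, pulse)), shifts - shifts[1])
  expect_error(measure_latency(list(pulse(0), numeric(100))), "rising")
})
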