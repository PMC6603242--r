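---
title: "Models and methods behind the gpias package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the gpias package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpias)
```

# Scope

`gpias` is a hardware-free reimplementation of the measurement and analysis
stack of an open acoustic-startle-reflex (ASR) setup for rodent behavioral
audiometry: gap-prepulse inhibition of the acoustic startle (GPIAS, used for
tinnitus screening) and prepulse inhibition with tone pre-pulses of varying
level (hearing-threshold estimation). The package covers stimulus synthesis,
session protocols, loudspeaker equalization, startle-amplitude extraction
from a 3-axis accelerometer, the ratio/threshold statistics, and a synthetic
animal/platform simulator that stands in for the hardware so that the entire
pipeline can be exercised and validated in software. Sound-card and
data-acquisition drivers, GUIs, and live-animal concerns are out of scope.

# The measurement model

## Startle amplitude

A startle trial produces a 3-axis acceleration recording of the spring-mounted
sensor platform, plus a TTL trigger whose rising edge marks startle-stimulus
onset. The ASR amplitude is

$$A = \max_{0 \le t \le 150\,\mathrm{ms}} a(t), \qquad
a(t) = \sqrt{(c_x a_x(t))^2 + (c_y a_y(t))^2 + (c_z a_z(t))^2},$$

where $c_x, c_y, c_z$ are per-axis calibration factors chosen so that the same
force yields the same calibrated acceleration on every axis (normalized to
$c_x = 1$, estimated from one reference recording per axis as the inverse
peak response). Each axis is low-pass filtered before the vector magnitude is
taken — a 4th-order Butterworth at 40 Hz applied forward–backward
(zero-phase), so the peak is not displaced in time. Filtering the *axes*
(rather than the magnitude) preserves sign information through the filter;
with a zero-phase filter and band-limited platform motion the two orders of
operations agree closely, but the axis-first order is the one implemented and
tested. The 150 ms window is endpoint-inclusive and ties resolve to the
earliest peak.

## Inhibition statistics

Let $A^{pre}_1..A^{pre}_n$ be amplitudes from trials with a pre-stimulus (a
silent gap in background noise, or a tone pre-pulse) and $A^{base}_1..A^{base}_m$
from baseline trials. The package forms the *full combinatorial* ratio set
$\{A^{pre}_i / A^{base}_j\}$ ($n \cdot m$ values) and defines the inhibition
statistic

$$\mathrm{PPI} \;(\text{or GPIAS}) = 1 - \mathrm{median}\left(A^{pre}_i / A^{base}_j\right).$$

Startle amplitudes are well described as log-normal, hence the ratios are
log-normal too and the log-ratios Gaussian; `fit_lognormal()` (closed-form
maximum likelihood) and `lognormality_check()` (Shapiro–Wilk on log ratios
plus QQ deviations) make both statements checkable on data. The standard
error of the median-based statistic comes from a bootstrap: both amplitude
groups are resampled independently with replacement (resampling amplitudes
rather than ratios preserves the two-sample structure), the full-combinatorial
median is recomputed per replicate, and the SE is the standard deviation of
the replicate statistics (default 100,000 replicates; tests and examples use
fewer). Group contrasts (e.g. species with vs. without gap inhibition) use a
two-sided Mann–Whitney U rank-sum test — exact enumeration of the permutation
distribution for combined $n \le 12$ (midranks, so ties are handled), the
tie-corrected normal approximation above that.

## Hearing thresholds

In the threshold paradigm the PPI as a function of pre-pulse level has a
saturating sigmoid shape and is fitted with a *hard sigmoid*

$$f(x) = \mathrm{clip}\big(m (x - \theta),\, 0,\, s\big),$$

with the lower asymptote fixed at zero: below the sensory threshold the
pre-pulse is not perceived and the startle is uninhibited. The breakpoint
$\theta$ — where $f$ diverges from zero — is the estimated threshold. The fit
is least squares (optionally inverse-variance weighted by bootstrap SEs):
a 0.1 dB grid over $\theta$ (well below the 2 dB level step of a typical
protocol) with slope/saturation profiled per grid point, then continuous
joint refinement under box constraints ($m > 0$, $0 < s \le 1$). On noiseless
sigmoid data the refinement recovers the generating parameters to ~1e-6; an
all-zero PPI profile is reported as `no_threshold` rather than a fabricated
breakpoint.

# Stimuli and protocols

Stimulus constants default to the printed operating point of the original
setup: 96 kHz sampling, 20 ms broadband startle bursts at 115 dB SPL, 40 ms
tone pre-pulses, 100 ms lead interval, background band noise interrupted by a
50 ms gap smoothed with 20 ms $\sin^2$ ramps. Decisions the printed numbers
leave open, fixed here once:

* **Gap-duration convention.** The 50 ms gap is measured between the
  half-amplitude points of the falling and rising ramps. This conserves the
  nominal gap length under ramping; the fully silent plateau is
  `gap - ramp` = 30 ms and the whole notch spans `gap + ramp` = 70 ms.
* **Gap position.** The gap *ends* (half-amplitude of the recovery ramp) one
  lead interval — 100 ms by default, mirroring the tone paradigm — before
  startle onset. Configurable per trial.
* **Lead interval** is onset-to-onset for tone trials.
* **Level calibration.** Digital amplitude maps to dB SPL through a single
  reference (`level_calibration()`, default: unit RMS = 100 dB SPL). No
  physical microphone exists in this scope, so with the default reference a
  115 dB startle has digital RMS ≈ 5.6 — above nominal full scale. Amplitudes
  are therefore allowed to exceed 1.0 in the digital domain; clipping is
  *reported* where a signal leaves the package (WAV export, equalized
  playback). On real hardware one would choose `ref_dbspl` so the loudest
  stimulus fits the DAC.
* **Background-noise level** for GPIAS trials is not a printed constant; the
  trial specification carries it explicitly (default 60 dB SPL, a typical
  GPIAS background).
* **Band noise** is synthesized in the frequency domain: uniform magnitude and
  independent uniform phases strictly inside the band, zero outside. Band
  edges are exact (testable to periodogram precision) instead of the sloped
  skirts a time-domain filter would produce.
* **Trigger pulse**: amplitude 1.0, 10 ms, rising edge coincident with
  startle onset.

Protocols start with five startle-only habituation trials (presented to damp
adaptation; excluded from all statistics), followed by a seeded Fisher–Yates
permutation of the balanced condition multiset — equal numbers of gap and
no-gap trials per center frequency (GPIAS), or of tone trials per
(frequency × level) condition and pooled no-tone baselines (threshold). The
RNG is pinned (Mersenne-Twister, inversion normals) through `with_seed()`, so
the same seed reproduces the same order on any platform, and the same order
can be reused across animals. No anti-repetition constraints are imposed
beyond the shuffle. Whether multiple center frequencies are randomized
jointly or blockwise is selectable (`interleave`, default joint); no-tone
baselines are pooled across the session, matching how the full-combinatorial
statistic uses them.

# Loudspeaker equalization

Loudspeakers are not flat; the package identifies the
loudspeaker-enclosure-microphone system (LEMS) and pre-equalizes the driving
signals:

1. **Identification** — NLMS adaptive FIR: per sample,
   $w \leftarrow w + \mu\, e_n x_n / (\lVert x_n \rVert^2 + \delta)$ with
   $e_n = y_n - w^\top x_n$, implemented in C++ (the update is inherently
   sequential). Defaults $\mu = 0.5$, $\delta = 10^{-6}$, 2048 taps, two
   passes: stable convergence for desk-scale fixtures; the original system
   prints no hyperparameters, so these are engineering choices. Excitations
   with flat spectra are provided: seeded Gaussian white noise (RMS 0.5) and
   bipolar maximum-length sequences from primitive LFSRs (orders 2–20),
   whose periodic autocorrelation ($N$ at lag 0, $-1$ elsewhere) is asserted
   in tests.
2. **Minimum-phase extraction** — real-cepstrum method on an FFT grid of at
   least 4× the filter length, magnitudes floored at −100 dB relative to the
   spectral peak (with a warning) to keep the log bounded. Magnitude is
   preserved to well under 0.01 dB for well-conditioned inputs.
3. **Band-limited inversion** — Tikhonov-regularized bin-wise inverse
   $|H|/(|H|^2 + \epsilon)$ (default $\epsilon$ = 1e-4 of the peak
   $|H|^2$) inside the band (default 2–20 kHz), unity outside, blended in the
   log-magnitude domain through raised-cosine transitions of 1/6 octave placed
   just outside the band, then realized as the minimum-phase FIR with that
   magnitude. A zero-phase realization was rejected: half of its impulse
   response is anticausal, and truncating it measurably distorts the in-band
   gain, whereas the minimum-phase realization is causal with near-zero
   delay and truncates benignly (cosine fade over the final quarter of the
   taps).

Channel timing offsets are calibrated from recorded TTL pulses; the rising
edge is the first crossing of 50 % of the channel maximum (the edge criterion
is not quantified in the original description).

On the standard synthetic LEMS fixture (minimum-phase FIR whose in-band
magnitude deviates by ±6 dB, built from random smooth log-spectral bumps and
cepstrum-reconstructed), the identified-equalized cascade is flat within
±1 dB across 2–20 kHz — the property the acceptance suite asserts.

# The simulator: what it emulates, and what it does not

`virtual_animal()` draws per-trial amplitudes
$A = e^{\mathcal{N}(\mu, \sigma^2)} (1 - I)$ with $I$ the inhibition fraction:
`gpias_true` on gap trials, the hard sigmoid of the tone level on tone
trials, 0 otherwise. Inhibition multiplies rather than adds — that is what
makes the ratio statistic well-posed and keeps amplitudes log-normal within
condition. Defaults ($\sigma = 0.4$, GPIAS 0.5, threshold 10 dB SPL, slope
0.05/dB, saturation 0.8) describe a clearly-responding, normal-hearing
animal with the amplitude spread startle data typically show.
`virtual_platform()` renders an amplitude as one damped second-order mode per
axis (15 Hz resonance, damping ratio 0.3 — a soft spring suspension, safely
below the 40 Hz analysis low-pass), with per-axis gains, a 20 ms motor
latency after the trigger (any latency below ~130 ms leaves $A$ unchanged),
and Gaussian sensor noise (default RMS 0.005, ≈ 40 dB below a unit response).
Rendering is normalized so extraction round-trips the true amplitude within
2 % in the noiseless case.

The simulator deliberately does *not* model habituation or sensitization
across trials, movement artifacts, nonlinear loudspeaker behavior, or
inter-animal variance structure. Passing closure tests therefore demonstrate
that the pipeline's own transformations are faithful (no estimator bias, no
timing or calibration errors), not that real animals satisfy the generative
assumptions.

# Numerical choices and problem sizes

* Tones scale the *plateau* RMS exactly to the requested level; noise signals
  scale total RMS exactly, so levels are exact by construction.
* `asr_amplitude` uses `which.max`, i.e. earliest-tie resolution; the window
  endpoint is inclusive.
* Bootstrap, shuffles, noise seeds: every random quantity flows through an
  explicit integer seed; per-trial seeds are derived linearly and kept below
  $2^{31}$.
* Exact-vs-approximate cutover of the rank-sum test at combined $n = 12$
  (924 enumerated assignments at the cutover).
* Validation problem sizes: the end-to-end closure suite uses 500 simulated
  GPIAS sessions (15 gap / 15 no-gap, platform rate 2 kHz, 300 bootstrap
  replicates) and 50 threshold sessions (13 levels × 50 repeats); the
  equalizer fixture runs 2 s of white excitation at 48 kHz against a 256-tap
  LEMS. These sizes make the whole suite run in minutes on one CPU while
  leaving the statistical assertions sharp; the bootstrap default of 100,000
  replicates is retained for real analyses.

# Known limitations

* The hard-sigmoid parameterization matches the clip form described for the
  stimulus–response fits; the cited methodological lineage was not available
  to restate exact slope/saturation bounds, so the package constrains only
  $m > 0$, $0 < s \le 1$.
* The bootstrap SE of a median from ~15 trials per group is itself noisy
  (≈ 25 % across datasets); its *calibration* — mean SE versus the true
  sampling SD — is what the tests pin down to 10 %.
* Minimum-phase truncation to a finite tap count slightly perturbs the
  magnitude near sharp spectral features; fixtures keep features ≥ 1/3 octave
  wide, as physical loudspeaker responses do.
* `magnitude_trace` applies `filtfilt`, whose edge transients make the first
  ~100 ms of a trace untrustworthy; recordings should (and in this package
  do) include ample pre-trigger context.
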