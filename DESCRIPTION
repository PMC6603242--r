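Package: gpias
Title: Acoustic Startle Reflex Measurement Stack for GPIAS and PPI Audiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Hardware-free toolkit for gap-prepulse inhibition of the acoustic
    startle reflex (GPIAS) and prepulse-inhibition (PPI) hearing-threshold
    paradigms in rodents. Synthesizes calibrated stimuli (pure tones, band
    noise with sin^2-ramped silent gaps, broadband startle bursts) and seeded
    pseudo-randomized measurement protocols; identifies and equalizes a
    loudspeaker-enclosure-microphone system via NLMS adaptive filtering and
    minimum-phase inversion; extracts startle amplitudes from 3-axis
    accelerometer traces aligned to a TTL trigger; computes full-combinatorial
    amplitude-ratio statistics with bootstrap standard errors, log-normal
    maximum-likelihood fits, hard-sigmoid hearing-threshold estimation, and
    rank-sum group comparisons. A synthetic animal/platform simulator provides
    ground-truth sessions so the entire pipeline is testable without hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
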