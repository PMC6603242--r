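#' Measurement protocol: an ordered, seeded session of trials
#'
#' @param trials list of [trial_spec()] objects in presentation order.
#' @param seed integer seed the randomized order was derived from.
#' @param paradigm `"gpias"` or `"threshold"`.
#' @param metadata named list of free-text metadata (experimenter, animal,
#'   treatment, ...).
#' @return an object of class `asr_protocol`.
#' @export
asr_protocol <- function(trials, seed, paradigm = c("gpias", "threshold"),
                         metadata = list()) {
  paradigm <- match.arg(paradigm)
  stopifnot(is.list(trials), all(vapply(trials, inherits, TRUE, "trial_spec")))
  structure(
    list(
      trials = trials, seed = as.integer(seed), paradigm = paradigm,
      metadata = metadata
    ),
    class = "asr_protocol"
  )
}

#' @export
print.asr_protocol <- function(x, ...) {
  kinds <- vapply(x$trials, `[[`, "", "kind")
  cat(sprintf(
    "<asr_protocol: %s, %d trials (%s), seed %d>\n",
    x$paradigm, length(kinds),
    paste(sprintf("%s=%d", names(table(kinds)), table(kinds)), collapse = ", "),
    x$seed
  ))
  invisible(x)
}

# Seeded Fisher-Yates shuffle of trial indices; Mersenne-Twister pinned by
# with_seed so the order is reproducible across platforms ("the same pseudo
# random order is used for all animals").
shuffle_indices <- function(n, seed) with_seed(seed, sample.int(n))

habituation_block <- function(template, seed) {
  lapply(seq_len(5L), function(i) {
    sp <- template
    sp$kind <- "startle_only"
    sp$noise_seed <- trial_seed(seed, 1000L + i)
    sp
  })
}

#' Build a GPIAS measurement protocol
#'
#' Five startle-only habituation trials (presented first, to prevent
#' adaptation effects; excluded from all downstream statistics), followed by a
#' seeded pseudo-random permutation of `n_repeats` gap and `n_repeats` no-gap
#' trials per background-noise center frequency. Gap and no-gap trial counts
#' are equal by construction. The same seed reproduces the identical order.
#'
#' @param center_freqs_hz vector of background-noise center frequencies (Hz).
#' @param half_width_octaves background-noise half bandwidth in octaves.
#' @param n_repeats repetitions per condition per frequency (>= 1).
#' @param seed integer seed for the trial order.
#' @param metadata named metadata list.
#' @param interleave if `TRUE` (default) all frequencies are randomized within
#'   one block; if `FALSE` each frequency forms its own randomized block.
#' @param ... further [trial_spec()] fields applied to every trial (e.g.
#'   `noise_level_dbspl`).
#' @return an [asr_protocol()].
#' @export
build_gpias_protocol <- function(center_freqs_hz, half_width_octaves = 0.5,
                                 n_repeats = 15, seed = 1, metadata = list(),
                                 interleave = TRUE, ...) {
  if (!length(center_freqs_hz)) stop("center_freqs_hz must not be empty")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  cond <- expand.grid(
    kind = c("gap", "nogap"), freq = center_freqs_hz,
    rep = seq_len(n_repeats), stringsAsFactors = FALSE
  )
  make_trial <- function(kind, freq, idx) {
    trial_spec(
      kind = kind, center_freq_hz = freq,
      half_width_octaves = half_width_octaves,
      noise_seed = trial_seed(seed, idx), ...
    )
  }
  if (interleave) {
    ord <- shuffle_indices(nrow(cond), seed)
    cond <- cond[ord, ]
  } else {
    blocks <- lapply(seq_along(center_freqs_hz), function(b) {
      sub <- cond[cond$freq == center_freqs_hz[b], ]
      sub[shuffle_indices(nrow(sub), trial_seed(seed, b)), ]
    })
    cond <- do.call(rbind, blocks)
  }
  trials <- Map(make_trial, cond$kind, cond$freq, seq_len(nrow(cond)))
  template <- trial_spec("startle_only",
    center_freq_hz = center_freqs_hz[1],
    half_width_octaves = half_width_octaves, ...
  )
  asr_protocol(
    c(habituation_block(template, seed), unname(trials)),
    seed, "gpias", metadata
  )
}

#' Build a PPI hearing-threshold protocol
#'
#' Five startle-only habituation trials, then a seeded pseudo-random
#' permutation of tone-pre-pulse trials over a frequency range (octave, 1/2- or
#' 1/4-octave steps) crossed with a sound-pressure-level range, `n_repeats`
#' per condition, mixed with an equal total number of no-tone baseline trials.
#'
#' @param freq_lo_hz,freq_hi_hz tone frequency range in Hz.
#' @param octave_step frequency step: 1, 1/2 or 1/4 octave.
#' @param level_lo_dbspl,level_hi_dbspl tone level range in dB SPL.
#' @param level_step_db level step in dB (> 0).
#' @param n_repeats repetitions per (frequency, level) condition.
#' @param seed integer seed for the trial order.
#' @param metadata named metadata list.
#' @param ... further [trial_spec()] fields applied to every trial.
#' @return an [asr_protocol()].
#' @export
build_threshold_protocol <- function(freq_lo_hz, freq_hi_hz,
                                     octave_step = c(1, 1 / 2, 1 / 4),
                                     level_lo_dbspl, level_hi_dbspl,
                                     level_step_db = 2, n_repeats = 50,
                                     seed = 1, metadata = list(), ...) {
  if (is.character(octave_step)) octave_step <- as.numeric(octave_step)
  if (length(octave_step) > 1) octave_step <- octave_step[1]
  if (!octave_step %in% c(1, 1 / 2, 1 / 4)) {
    stop("octave_step must be 1, 1/2 or 1/4")
  }
  if (freq_hi_hz < freq_lo_hz) stop("freq_hi_hz must be >= freq_lo_hz")
  if (level_hi_dbspl < level_lo_dbspl) {
    stop("level_hi_dbspl must be >= level_lo_dbspl")
  }
  if (level_step_db <= 0) stop("level_step_db must be > 0")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  n_oct <- log2(freq_hi_hz / freq_lo_hz)
  freqs <- freq_lo_hz * 2^(seq(0, n_oct + 1e-9, by = octave_step))
  freqs <- freqs[freqs <= freq_hi_hz * (1 + 1e-9)]
  levels <- seq(level_lo_dbspl, level_hi_dbspl, by = level_step_db)
  cond <- expand.grid(
    freq = freqs, level = levels, rep = seq_len(n_repeats),
    stringsAsFactors = FALSE
  )
  n_tone <- nrow(cond)
  kinds <- c(rep("tone", n_tone), rep("notone", n_tone))
  freq_all <- c(cond$freq, rep(NA_real_, n_tone))
  level_all <- c(cond$level, rep(NA_real_, n_tone))
  ord <- shuffle_indices(2L * n_tone, seed)
  trials <- lapply(seq_along(ord), function(i) {
    j <- ord[i]
    if (kinds[j] == "tone") {
      trial_spec("tone",
        tone_freq_hz = freq_all[j], tone_level_dbspl = level_all[j],
        noise_seed = trial_seed(seed, i), ...
      )
    } else {
      trial_spec("notone", noise_seed = trial_seed(seed, i), ...)
    }
  })
  template <- trial_spec("startle_only", ...)
  asr_protocol(
    c(habituation_block(template, seed), trials),
    seed, "threshold", metadata
  )
}

#' Validate a protocol and summarize its composition
#'
#' Checks the structural rules a session must obey — five leading startle-only
#' habituation trials, equal numbers of gap/no-gap (GPIAS) or tone/no-tone
#' (threshold) trials — and tabulates per-condition counts. Never modifies the
#' protocol.
#'
#' @param p an [asr_protocol()].
#' @return a list of class `protocol_validation` with elements
#'   `habituation_n`, `counts` (data frame), `balanced`, `violations`
#'   (character vector, empty when valid) and `valid`.
#' @export
validate_protocol <- function(p) {
  stopifnot(inherits(p, "asr_protocol"))
  kinds <- vapply(p$trials, `[[`, "", "kind")
  hab_n <- 0L
  while (hab_n < length(kinds) && kinds[hab_n + 1L] == "startle_only") {
    hab_n <- hab_n + 1L
  }
  hab_n <- min(hab_n, 5L)
  main <- kinds[-seq_len(hab_n)]
  violations <- character(0)
  if (hab_n != 5L) {
    violations <- c(violations, sprintf(
      "expected 5 leading startle_only habituation trials, found %d", hab_n
    ))
  }
  freq_of <- function(tr) {
    if (tr$kind %in% c("gap", "nogap")) tr$center_freq_hz else tr$tone_freq_hz
  }
  main_trials <- p$trials[-seq_len(hab_n)]
  tab <- data.frame(
    kind = vapply(main_trials, `[[`, "", "kind"),
    freq = vapply(main_trials, freq_of, 0),
    level = vapply(main_trials, `[[`, 0, "tone_level_dbspl")
  )
  counts <- as.data.frame(table(kind = tab$kind), stringsAsFactors = FALSE)
  names(counts) <- c("kind", "n")
  balanced <- if (p$paradigm == "gpias") {
    sum(main == "gap") == sum(main == "nogap")
  } else {
    sum(main == "tone") == sum(main == "notone")
  }
  if (!balanced) {
    violations <- c(
      violations,
      "pre-stimulus and baseline trial counts are not equal"
    )
  }
  structure(
    list(
      habituation_n = hab_n, counts = counts, balanced = balanced,
      per_condition = as.data.frame(table(
        kind = tab$kind, freq = tab$freq,
        useNA = "ifany"
      )),
      violations = violations, valid = length(violations) == 0L
    ),
    class = "protocol_validation"
  )
}

#' @export
print.protocol_validation <- function(x, ...) {
  cat(sprintf(
    "<protocol validation: %s; habituation %d; balanced %s>\n",
    if (x$valid) "OK" else "VIOLATIONS", x$habituation_n, x$balanced
  ))
  if (length(x$violations)) cat(paste(" -", x$violations, collapse = "\n"), "\n")
  print(x$counts)
  invisible(x)
}

#' Save a protocol as JSON
#' @param p an [asr_protocol()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(p, path) {
  stopifnot(inherits(p, "asr_protocol"))
  trials <- do.call(rbind, lapply(p$trials, function(tr) {
    as.data.frame(unclass(tr), stringsAsFactors = FALSE)
  }))
  obj <- list(
    format = "gpias-protocol", version = 1L, paradigm = p$paradigm,
    seed = p$seed, metadata = p$metadata, trials = trials
  )
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Load a protocol from JSON
#' @param path JSON file written by [write_protocol()].
#' @return an [asr_protocol()].
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gpias-protocol")) {
    stop("not a gpias protocol file: ", path)
  }
  trials <- lapply(seq_len(nrow(obj$trials)), function(i) {
    row <- as.list(obj$trials[i, ])
    for (f in setdiff(names(row), "kind")) {
      row[[f]] <- if (is.null(row[[f]])) NA_real_ else as.numeric(row[[f]])
    }
    do.call(trial_spec, row)
  })
  asr_protocol(trials, obj$seed, obj$paradigm, as.list(obj$metadata))
}
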