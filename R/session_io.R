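#' Create a measurement session on disk
#'
#' Lays out the storage for one session under
#' `<root>/<experimenter>/<animal>/<treatment>/<session_id>/`, writes the
#' protocol and a metadata sidecar, and returns a handle used by
#' [save_trial()], [load_trial()] and [export_ascii()].
#'
#' @param root storage root directory.
#' @param experimenter,animal free-text metadata (used as path components).
#' @param treatment optional treatment label (default `"none"`).
#' @param protocol an [asr_protocol()].
#' @param session_id session directory name; default a UTC timestamp.
#' @return an object of class `session_record`.
#' @export
start_session <- function(root, experimenter, animal, treatment = "none",
                          protocol, session_id = NULL) {
  stopifnot(inherits(protocol, "asr_protocol"))
  clean <- function(s) gsub("[^A-Za-z0-9_.-]", "_", s)
  session_id <- session_id %||%
    format(Sys.time(), "session_%Y%m%dT%H%M%SZ", tz = "UTC")
  dir <- file.path(
    root, clean(experimenter), clean(animal), clean(treatment),
    clean(session_id)
  )
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_protocol(protocol, file.path(dir, "protocol.json"))
  meta <- list(
    format = "gpias-session", version = 1L,
    experimenter = experimenter, animal = animal, treatment = treatment,
    session_id = session_id,
    created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    n_trials = length(protocol$trials)
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  structure(
    list(dir = dir, metadata = meta, protocol = protocol),
    class = "session_record"
  )
}

#' Open an existing session directory
#' @param dir session directory created by [start_session()].
#' @return a `session_record`.
#' @export
open_session <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) stop("not a session directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  protocol <- read_protocol(file.path(dir, "protocol.json"))
  structure(
    list(dir = dir, metadata = meta, protocol = protocol),
    class = "session_record"
  )
}

trial_paths <- function(session, trial_index) {
  base <- file.path(session$dir, sprintf("trial_%04d", trial_index))
  list(csv = paste0(base, ".csv"), json = paste0(base, ".json"))
}

#' Save one trial's raw recording
#'
#' Writes the 3-axis acceleration and trigger traces as a 4-column CSV
#' (`ax, ay, az, trigger`; the sample index is implicit) with a JSON sidecar
#' carrying the sampling rate and alignment. The write is atomic (temp file +
#' rename); an existing trial is only replaced with `overwrite = TRUE`. Raw
#' trial files are never modified after creation.
#'
#' @param session a `session_record`.
#' @param trial_index 1-based trial index within the protocol.
#' @param rec an [accel_recording()].
#' @param overwrite replace an existing trial file (default `FALSE`).
#' @return the CSV path, invisibly.
#' @export
save_trial <- function(session, trial_index, rec, overwrite = FALSE) {
  stopifnot(inherits(session, "session_record"), inherits(rec, "accel_recording"))
  n_trials <- length(session$protocol$trials)
  if (trial_index < 1 || trial_index > n_trials) {
    stop(sprintf("trial_index %d outside protocol (1..%d)", trial_index, n_trials))
  }
  paths <- trial_paths(session, trial_index)
  if (file.exists(paths$csv) && !overwrite) {
    stop("trial ", trial_index, " already saved; use overwrite = TRUE")
  }
  # 17 significant digits round-trip IEEE doubles exactly
  cols <- lapply(
    list(rec$ax, rec$ay, rec$az, rec$trigger),
    function(v) formatC(v, digits = 17, format = "g")
  )
  tmp <- paste0(paths$csv, ".tmp")
  writeLines(
    c(
      "ax,ay,az,trigger",
      paste(cols[[1]], cols[[2]], cols[[3]], cols[[4]], sep = ",")
    ),
    tmp
  )
  file.rename(tmp, paths$csv)
  side <- list(rate = rec$rate, n_samples = length(rec$ax))
  if (length(rec$t0) == 1 && !is.na(rec$t0)) side$t0 <- rec$t0
  tmpj <- paste0(paths$json, ".tmp")
  jsonlite::write_json(side, tmpj, auto_unbox = TRUE, digits = NA)
  file.rename(tmpj, paths$json)
  invisible(paths$csv)
}

#' Load one trial's raw recording
#' @param session a `session_record`.
#' @param trial_index 1-based trial index.
#' @return an [accel_recording()].
#' @export
load_trial <- function(session, trial_index) {
  paths <- trial_paths(session, trial_index)
  if (!file.exists(paths$csv)) stop("trial ", trial_index, " not saved")
  df <- read.csv(paths$csv)
  side <- jsonlite::read_json(paths$json, simplifyVector = TRUE)
  t0 <- side$t0
  if (is.null(t0) || !length(t0)) t0 <- NA_integer_
  accel_recording(df$ax, df$ay, df$az, df$trigger, rate = side$rate, t0 = t0)
}

#' Indices of trials already saved in a session
#' @param session a `session_record`.
#' @return integer vector of saved trial indices.
#' @export
saved_trials <- function(session) {
  files <- list.files(session$dir, pattern = "^trial_[0-9]{4}\\.csv$")
  sort(as.integer(sub("^trial_([0-9]{4})\\.csv$", "\\1", files)))
}

#' Save all recordings of a simulated session
#'
#' @param session a `session_record`.
#' @param sim a [simulate_session()] result for the same protocol.
#' @param overwrite passed to [save_trial()].
#' @return the session, invisibly.
#' @export
save_simulated_session <- function(session, sim, overwrite = FALSE) {
  stopifnot(inherits(sim, "simulated_session"))
  for (i in seq_along(sim$recordings)) {
    save_trial(session, i, sim$recordings[[i]], overwrite = overwrite)
  }
  invisible(session)
}

#' Export a session as a tab-delimited ASCII table
#'
#' One row per protocol trial, carrying the session metadata, the trial
#' condition, and the extracted ASR amplitude. Trials without a saved
#' recording are kept and flagged in the `status` column (`missing`), never
#' silently dropped. The file is tab-delimited with a header line, `.` as the
#' decimal separator, and amplitudes printed to 9 significant digits.
#'
#' Columns, in order: `trial`, `experimenter`, `animal`, `treatment`, `kind`,
#' `freq_hz`, `level_dbspl`, `habituation`, `amplitude`, `peak_time_s`,
#' `status`.
#'
#' @param session a `session_record` with at least one saved trial.
#' @param out_path output text file path.
#' @param cal an [axis_calibration()] for amplitude extraction.
#' @param lowpass_hz,window_s extraction parameters (see [extract_asr()]).
#' @return the exported data frame, invisibly.
#' @export
export_ascii <- function(session, out_path, cal = axis_calibration(),
                         lowpass_hz = 40, window_s = 0.150) {
  stopifnot(inherits(session, "session_record"))
  if (!length(saved_trials(session))) stop("session has no saved trials")
  trials <- session$protocol$trials
  hab_n <- validate_protocol(session$protocol)$habituation_n
  meta <- session$metadata
  rows <- lapply(seq_along(trials), function(i) {
    sp <- trials[[i]]
    freq <- if (sp$kind %in% c("gap", "nogap")) sp$center_freq_hz else sp$tone_freq_hz
    row <- data.frame(
      trial = i, experimenter = meta$experimenter, animal = meta$animal,
      treatment = meta$treatment, kind = sp$kind, freq_hz = freq,
      level_dbspl = sp$tone_level_dbspl, habituation = i <= hab_n,
      amplitude = NA_real_, peak_time_s = NA_real_, status = "missing",
      stringsAsFactors = FALSE
    )
    if (file.exists(trial_paths(session, i)$csv)) {
      rec <- load_trial(session, i)
      asr <- extract_asr(rec, cal, lowpass_hz, window_s)
      row$amplitude <- asr$value
      row$peak_time_s <- asr$peak_time_s
      row$status <- "ok"
    }
    row
  })
  df <- do.call(rbind, rows)
  out <- df
  for (col in c("amplitude", "peak_time_s")) {
    out[[col]] <- ifelse(is.na(df[[col]]), "NA",
      formatC(df[[col]], digits = 9, format = "g")
    )
  }
  write.table(out, out_path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    dec = "."
  )
  invisible(df)
}
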