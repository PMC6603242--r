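#' Default configuration constants
#'
#' One document holding the package-wide defaults for every operating
#' constant of the measurement stack: sampling rate, stimulus durations and
#' levels, analysis filter and window, equalization band, and bootstrap
#' count. [read_config()] validates a user-supplied JSON document against
#' this schema; the CLI accepts it via the global `--config` flag.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    rate_hz = 96000,
    ref_dbspl = 100,
    startle_duration_s = 0.020,
    startle_level_dbspl = 115,
    tone_duration_s = 0.040,
    lead_interval_s = 0.100,
    gap_duration_s = 0.050,
    gap_ramp_s = 0.020,
    noise_level_dbspl = 60,
    lowpass_hz = 40,
    window_s = 0.150,
    band_hz = c(2000, 20000),
    n_bootstrap = 100000
  )
}

#' Read and validate a configuration document
#'
#' Loads a JSON configuration, rejects unknown or non-numeric fields, and
#' fills every omitted field with its default from [default_config()].
#'
#' @param path JSON file path, or `NULL` for the pure defaults.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  for (f in names(user)) {
    v <- user[[f]]
    if (!is.numeric(v) || anyNA(v)) stop("configuration field ", f, " must be numeric")
    if (f == "band_hz") {
      if (length(v) != 2 || v[1] <= 0 || v[2] <= v[1]) {
        stop("band_hz must be (f_lo, f_hi) with 0 < f_lo < f_hi")
      }
    } else {
      if (length(v) != 1 || v < 0) stop("configuration field ", f, " must be a single non-negative number")
    }
    cfg[[f]] <- v
  }
  cfg
}
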