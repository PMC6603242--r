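#' Write waveforms to a RIFF/WAVE file
#'
#' Minimal WAV writer supporting IEEE float32 (format 3, default — exact for
#' signals that may exceed full scale) and 16-bit PCM (format 1, values
#' clipped to full scale). Channels are interleaved in the order given.
#'
#' @param channels a [waveform()], numeric vector, or list/matrix of equal
#'   length channels.
#' @param path output file path.
#' @param rate sampling rate in Hz; taken from the first waveform if omitted.
#' @param format `"float32"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(channels, path, rate = NULL,
                      format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(channels, "waveform")) {
    rate <- rate %||% channels$rate
    channels <- list(channels$samples)
  } else if (is.numeric(channels) && is.null(dim(channels))) {
    channels <- list(as.numeric(channels))
  } else if (is.matrix(channels)) {
    channels <- lapply(seq_len(ncol(channels)), function(j) channels[, j])
  } else if (is.list(channels)) {
    rates <- unlist(lapply(channels, function(ch) {
      if (inherits(ch, "waveform")) ch$rate else NULL
    }))
    if (length(rates)) {
      if (length(unique(rates)) > 1) stop("channel rates differ")
      rate <- rate %||% rates[1]
    }
    channels <- lapply(channels, function(ch) {
      if (inherits(ch, "waveform")) ch$samples else as.numeric(ch)
    })
  } else {
    stop("unsupported channels argument")
  }
  if (is.null(rate)) stop("rate must be given")
  n <- unique(vapply(channels, length, integer(1)))
  if (length(n) != 1) stop("all channels must have equal length")
  nch <- length(channels)
  # nch x n matrix flattened column-major = frame-interleaved samples
  inter <- as.numeric(do.call(rbind, lapply(channels, as.numeric)))

  bits <- if (format == "float32") 32L else 16L
  fmt_code <- if (format == "float32") 3L else 1L
  block <- nch * bits / 8L
  data_bytes <- n * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    pcm <- as.integer(round(pmin(pmax(inter, -1), 1) * 32767))
    writeBin(pcm, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a RIFF/WAVE file
#'
#' Supports the formats written by [write_wav()]: IEEE float32 and 16-bit
#' PCM, any channel count.
#'
#' @param path WAV file path.
#' @return list with `samples` (matrix, one column per channel) and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt_code <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("data chunk before fmt chunk in ", path)
      n_tot <- size / (bits / 8)
      x <- if (fmt_code == 3L && bits == 32L) {
        readBin(con, numeric(), n = n_tot, size = 4, endian = "little")
      } else if (fmt_code == 1L && bits == 16L) {
        readBin(con, integer(), n = n_tot, size = 2, endian = "little",
          signed = TRUE) / 32767
      } else {
        stop("unsupported WAV format code ", fmt_code, " / ", bits, " bits")
      }
      return(list(
        samples = matrix(x, ncol = nch, byrow = TRUE),
        rate = rate
      ))
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2))
    }
  }
}
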