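#' Write a mono WAV file
#'
#' Writes a RIFF/WAVE file, 16-bit PCM (`format = "pcm16"`) or 32-bit IEEE
#' float (`format = "float32"`), single channel.
#'
#' @param clip an [audio_clip].
#' @param path output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  rate <- clip$rate_hz
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bits <- 16L; fmt_code <- 1L
    data <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  } else {
    bits <- 32L; fmt_code <- 3L
    data <- x
  }
  bytes_per_sample <- bits %/% 8L
  data_size <- length(x) * bytes_per_sample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per_sample), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(data, con, size = 2, endian = "little")
  } else {
    writeBin(data, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' Supports single-channel 16-bit PCM and 32-bit float RIFF files.
#'
#' @param path input path.
#' @param clip_id identifier for the returned clip (default: file stem).
#' @return An [audio_clip].
#' @export
read_wav <- function(path, clip_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt_code <- NA_integer_; rate <- NA_integer_; bits <- NA_integer_
  channels <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (id == "data") {
      if (is.na(fmt_code)) stop("malformed WAV: data before fmt")
      n <- size %/% (bits %/% 8L)
      samples <- if (fmt_code == 1L && bits == 16L) {
        readBin(con, integer(), n = n, size = 2, signed = TRUE,
                endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else stop("unsupported WAV encoding: format ", fmt_code, ", ", bits, " bits")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (channels != 1L) stop("only mono WAV supported")
  if (is.null(clip_id)) clip_id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  audio_clip(pmax(pmin(samples, 1), -1), rate, clip_id = clip_id)
}
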