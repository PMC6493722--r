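#' Read a mono PCM WAV file
#'
#' Reads 16- or 24-bit integer PCM WAV. Samples are normalised to
#' `[-1, 1]`. Only mono files are accepted (the analysis assumes a single
#' focal microphone channel). Files whose rate differs from `target_rate`
#' are resampled on read with a warning so that all downstream spectral
#' settings refer to one rate.
#'
#' @param path Path to a `.wav` file.
#' @param target_rate Rate (Hz) the pipeline works at; `NULL` disables
#'   resampling.
#' @return An [audio_clip()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, target_rate = 44100) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF/WAVE file (bad magic): ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file (no WAVE tag): ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, "integer", 1L, 2L, endian = "little"),
        channels = readBin(con, "integer", 1L, 2L, endian = "little"),
        rate     = readBin(con, "integer", 1L, 4L, endian = "little"),
        byterate = readBin(con, "integer", 1L, 4L, endian = "little"),
        align    = readBin(con, "integer", 1L, 2L, endian = "little"),
        bits     = readBin(con, "integer", 1L, 2L, endian = "little")
      )
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      break
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path)
  if (fmt$format != 1L)
    stop("unsupported WAV encoding (only integer PCM, got format tag ",
         fmt$format, ")")
  if (fmt$channels != 1L)
    stop("only mono WAV is supported (file has ", fmt$channels, " channels)")

  if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
                 signed = TRUE, endian = "little") / 32767
  } else if (fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388607
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits, " (16 or 24 expected)")
  }
  x <- pmin(1, pmax(-1, x))
  clip <- audio_clip(x, fmt$rate)
  if (!is.null(target_rate) && fmt$rate != target_rate) {
    warning(sprintf("resampling %s from %d Hz to %d Hz", basename(path),
                    fmt$rate, as.integer(target_rate)))
    clip <- resample_clip(clip, target_rate)
  }
  clip
}

#' Write a mono PCM WAV file
#'
#' @param clip An [audio_clip()]; samples are clamped to `[-1, 1]` and
#'   quantised.
#' @param path Output path.
#' @param bits Bit depth, 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bits = 16L) {
  stopifnot(is_audio_clip(clip))
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 24L)) stop("`bits` must be 16 or 24")
  x <- pmin(1, pmax(-1, clip$samples))
  n <- length(x)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")            # PCM
  writeBin(1L, con, 2L, endian = "little")            # mono
  writeBin(as.integer(clip$rate), con, 4L, endian = "little")
  writeBin(as.integer(clip$rate * bytes_per), con, 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")
  writeBin(bits, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(x * 32767)), con, 2L, endian = "little")
  } else {
    v <- as.integer(round(x * 8388607))
    v <- ifelse(v < 0L, v + 16777216L, v)
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

# Polyphase resampling via signal::resample; rational approximation of the
# rate ratio keeps the result exact for common rate pairs (48k -> 44.1k etc.).
resample_clip <- function(clip, target_rate) {
  r <- target_rate / clip$rate
  fr <- as.integer(c(target_rate, clip$rate)) %/%
    gcd_int(as.integer(target_rate), as.integer(clip$rate))
  y <- signal::resample(clip$samples, fr[1L], fr[2L])
  want <- round(length(clip$samples) * r)
  if (length(y) > want) y <- y[seq_len(want)]
  if (length(y) < want) y <- c(y, numeric(want - length(y)))
  audio_clip(pmin(1, pmax(-1, y)), target_rate)
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}
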