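#' Construct an audio clip
#'
#' An `audio_clip` is the package's in-memory representation of a mono
#' recording: a numeric vector of amplitudes in `[-1, 1]` plus a sampling
#' rate in Hz.
#'
#' @param samples Numeric vector of amplitudes; must be finite.
#' @param rate Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_clip` with elements `samples` and
#'   `rate`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration(clip)
#' @export
audio_clip <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite (no NA/NaN/Inf)")
  structure(list(samples = samples, rate = rate), class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %.3f s at %g Hz, %d samples, peak %.3f>\n",
              duration(x), x$rate, length(x$samples),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip An [audio_clip()].
#' @return Length in seconds.
#' @export
duration <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples) / clip$rate
}

is_audio_clip <- function(x) inherits(x, "audio_clip")
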