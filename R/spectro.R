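#' Spectrogram analysis settings
#'
#' Defaults follow the study's spectral-analysis convention: 512-sample
#' FFT, Hann window, 90% overlap at 44.1 kHz (bin spacing ~86.1 Hz, hop
#' 51 samples). A Praat-style parameterisation is accepted through
#' `window_length`: the window length in seconds is converted to the
#' next power-of-two FFT size for the clip rate.
#'
#' @param fft_size FFT length in samples; must be a power of two.
#' @param overlap Window overlap fraction in `[0, 1)`.
#' @param window Window shape; only `"hanning"` is implemented.
#' @param dynamic_range Displayed/considered dynamic range in dB (used by
#'   peak picking in the non-linear phenomena detector).
#' @param window_length Optional window length in seconds; overrides
#'   `fft_size` given `rate`.
#' @param rate Rate used to resolve `window_length`.
#' @return A `spectrogram_settings` list.
#' @export
spectrogram_settings <- function(fft_size = 512L, overlap = 0.9,
                                 window = "hanning", dynamic_range = 40,
                                 window_length = NULL, rate = 44100) {
  if (!is.null(window_length)) {
    fft_size <- 2^ceiling(log2(window_length * rate))
  }
  fft_size <- as.integer(fft_size)
  if (fft_size < 2L || bitwAnd(fft_size, fft_size - 1L) != 0L)
    stop("`fft_size` must be a power of two")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  if (!identical(window, "hanning"))
    stop("only the Hann window is implemented")
  structure(list(fft_size = fft_size, overlap = overlap, window = window,
                 dynamic_range = dynamic_range),
            class = "spectrogram_settings")
}

#' Compute a linear-power spectrogram
#'
#' Short-time Fourier transform with a Hann window. Power is one-sided
#' (`fft_size / 2 + 1` bins); frame times are window centres in seconds;
#' bin spacing is `rate / fft_size`.
#'
#' @param clip An [audio_clip()] of length at least one window.
#' @param settings A [spectrogram_settings()].
#' @return A `spectrogram`: list with `power` (frames x bins matrix),
#'   `times` (s), `freq` (Hz), `rate`, `settings`.
#' @export
compute_spectrogram <- function(clip, settings = spectrogram_settings()) {
  stopifnot(is_audio_clip(clip), inherits(settings, "spectrogram_settings"))
  nfft <- settings$fft_size
  if (length(clip$samples) < nfft)
    stop("clip shorter than one analysis window (", nfft,
         " samples); zero-pad the clip before analysis")
  hop <- max(1L, as.integer(round(nfft * (1 - settings$overlap))))
  n <- length(clip$samples)
  nframes <- (n - nfft) %/% hop + 1L
  starts <- (seq_len(nframes) - 1L) * hop
  idx <- outer(seq_len(nfft), starts, "+")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1L)) / nfft)
  frames <- matrix(clip$samples[idx], nrow = nfft) * w
  spec <- stats::mvfft(frames)
  pow <- t(abs(spec[seq_len(nfft %/% 2L + 1L), , drop = FALSE])^2)
  structure(list(power = pow,
                 times = (starts + nfft / 2) / clip$rate,
                 freq = (0:(nfft %/% 2L)) * clip$rate / nfft,
                 rate = clip$rate, hop = hop, settings = settings),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d frames x %d bins, %.1f Hz bins, hop %d samples>\n",
              nrow(x$power), ncol(x$power), x$freq[2L], x$hop))
  invisible(x)
}

frames_in_segment <- function(spg, segment) {
  if (is.null(segment)) return(seq_along(spg$times))
  half_win <- spg$settings$fft_size / (2 * spg$rate)
  if (segment[2L] <= spg$times[1L] - half_win ||
      segment[1L] >= spg$times[length(spg$times)] + half_win)
    stop("segment [", segment[1L], ", ", segment[2L],
         ") lies outside the spectrogram extent")
  which(spg$times >= segment[1L] & spg$times <= segment[2L])
}

#' Mean power spectrum over a segment
#'
#' Averages the spectrogram's linear power over the frames whose centres
#' fall in `[onset, offset]` and normalises the result to sum to one, so
#' the slice can be read as a probability mass over frequency bins.
#'
#' @param spg A [compute_spectrogram()] result.
#' @param segment `c(onset, offset)` in seconds, or `NULL` for the whole
#'   clip.
#' @return A `spectral_slice`: list with `freq` (Hz) and `p` (normalised
#'   power, sums to 1).
#' @export
spectral_slice <- function(spg, segment = NULL) {
  stopifnot(inherits(spg, "spectrogram"))
  fr <- frames_in_segment(spg, segment)
  if (!length(fr)) stop("segment contains no analysis frames")
  s <- colMeans(spg$power[fr, , drop = FALSE])
  tot <- sum(s)
  structure(list(freq = spg$freq, p = if (tot > 0) s / tot else s),
            class = "spectral_slice")
}
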