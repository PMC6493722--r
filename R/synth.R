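#' Specification of a synthetic scream
#'
#' The generative model is a harmonic stack with `1/k` amplitude roll-off
#' on a (possibly drifting) pseudo-fundamental, mixed with Gaussian
#' broadband noise, under an attack/decay amplitude envelope. Four
#' non-linear phenomena (NLP) can be injected: a frequency jump (step in
#' the fundamental), a subharmonic (component at half the fundamental),
#' biphonation (an independent second voice at an inharmonic frequency),
#' and a chaotic segment (a stretch replaced by band-passed noise at full
#' depth).
#'
#' @param duration Call duration in seconds (> 0).
#' @param base_freq Pseudo-fundamental at call onset, Hz.
#' @param freq_slope Linear drift of the fundamental, Hz/s.
#' @param n_harmonics Number of stack harmonics; harmonics above Nyquist
#'   are dropped at synthesis time.
#' @param noise_mix Fraction (0-1) of total energy that is broadband
#'   noise; drives spectral entropy.
#' @param nlp Named list of NLP injections; any of
#'   `jump = list(frac, at)` (relative step size, position as fraction of
#'   duration), `subharmonic = list(level_db)` (level relative to the
#'   fundamental), `biphonation = list(freq, level_db)` (second-voice
#'   frequency in Hz), `chaos = list(frac, at)` (segment length and start
#'   as fractions of duration).
#' @param attack,decay Envelope ramp times in seconds.
#' @param amplitude Peak amplitude in (0, 1]; no clipping.
#' @return An object of class `scream_spec`.
#' @export
scream_spec <- function(duration, base_freq, freq_slope = 0,
                        n_harmonics = 8L, noise_mix = 0, nlp = list(),
                        attack = 0.02, decay = 0.05, amplitude = 0.9) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("invalid scream_spec: `duration` must be > 0")
  if (!is.numeric(base_freq) || base_freq <= 0)
    stop("invalid scream_spec: `base_freq` must be > 0")
  if (!is.numeric(noise_mix) || noise_mix < 0 || noise_mix > 1)
    stop("invalid scream_spec: `noise_mix` must be in [0, 1]")
  if (!is.numeric(amplitude) || amplitude <= 0 || amplitude > 1)
    stop("invalid scream_spec: `amplitude` must be in (0, 1]")
  if (n_harmonics < 1L)
    stop("invalid scream_spec: `n_harmonics` must be >= 1")
  bad <- setdiff(names(nlp), c("jump", "subharmonic", "biphonation", "chaos"))
  if (length(bad))
    stop("invalid scream_spec: unknown nlp form(s): ",
         paste(bad, collapse = ", "))
  structure(list(duration = duration, base_freq = base_freq,
                 freq_slope = freq_slope, n_harmonics = as.integer(n_harmonics),
                 noise_mix = noise_mix, nlp = nlp, attack = attack,
                 decay = decay, amplitude = amplitude),
            class = "scream_spec")
}

# run `expr` under a seeded, isolated RNG stream; the caller's RNG state is
# untouched, and the same seed always reproduces the same draws
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesise one scream
#'
#' @param spec A [scream_spec()].
#' @param rate Sampling rate, Hz. `base_freq` must be below Nyquist;
#'   harmonics above Nyquist are silently dropped.
#' @param seed Integer seed; the same seed gives a bit-identical waveform.
#' @return An [audio_clip()] of exactly `spec$duration * rate` (rounded)
#'   samples.
#' @examples
#' clip <- synth_scream(scream_spec(0.4, 1500), 44100, seed = 1)
#' duration(clip)
#' @export
synth_scream <- function(spec, rate = 44100, seed = 1L) {
  stopifnot(inherits(spec, "scream_spec"))
  if (spec$base_freq >= rate / 2)
    stop("invalid scream_spec: `base_freq` at or above Nyquist for rate ",
         rate)
  with_seed(seed, synth_scream_impl(spec, rate))
}

synth_scream_impl <- function(spec, rate) {
  n <- max(1L, round(spec$duration * rate))
  tt <- (seq_len(n) - 1L) / rate
  f0 <- spec$base_freq + spec$freq_slope * tt

  if (!is.null(spec$nlp$jump)) {
    j <- spec$nlp$jump
    frac <- if (is.null(j$frac)) 0.3 else j$frac
    at <- if (is.null(j$at)) 0.5 else j$at
    f0[tt >= at * spec$duration] <- f0[tt >= at * spec$duration] * (1 + frac)
  }
  f0 <- pmax(50, pmin(f0, rate / 2 - 50))
  phase <- 2 * pi * cumsum(f0) / rate

  tonal <- numeric(n)
  for (k in seq_len(spec$n_harmonics)) {
    if (k * max(f0) >= 0.98 * rate / 2) break
    tonal <- tonal + sin(k * phase + stats::runif(1, 0, 2 * pi)) / k
  }
  if (!is.null(spec$nlp$subharmonic)) {
    db <- if (is.null(spec$nlp$subharmonic$level_db)) -6 else
      spec$nlp$subharmonic$level_db
    tonal <- tonal + 10^(db / 20) * sin(phase / 2 + stats::runif(1, 0, 2 * pi))
  }
  if (!is.null(spec$nlp$biphonation)) {
    b <- spec$nlp$biphonation
    g <- if (is.null(b$freq)) 1.42 * spec$base_freq else b$freq
    db <- if (is.null(b$level_db)) -6 else b$level_db
    tonal <- tonal + 10^(db / 20) *
      sin(2 * pi * g * tt + stats::runif(1, 0, 2 * pi))
  }

  rms <- function(x) sqrt(mean(x^2))
  if (rms(tonal) > 0) tonal <- tonal / rms(tonal)
  noise <- stats::rnorm(n)
  noise <- noise / rms(noise)
  x <- sqrt(1 - spec$noise_mix) * tonal + sqrt(spec$noise_mix) * noise

  if (!is.null(spec$nlp$chaos)) {
    ch <- spec$nlp$chaos
    frac <- if (is.null(ch$frac)) 0.3 else ch$frac
    at <- if (is.null(ch$at)) 0.35 else ch$at
    i0 <- max(1L, round(at * n))
    i1 <- min(n, i0 + round(frac * n))
    if (i1 - i0 > 8L) {
      lo <- 500 / (rate / 2)
      hi <- min(0.95, (spec$n_harmonics * spec$base_freq * 1.2) / (rate / 2))
      bp <- signal::butter(4, c(lo, hi), type = "pass")
      seg <- signal::filtfilt(bp, stats::rnorm(i1 - i0 + 1L))
      seg <- seg / rms(seg) * max(rms(x[i0:i1]), rms(x))
      x[i0:i1] <- seg
    }
  }

  env <- rep(1, n)
  na <- min(n, round(spec$attack * rate))
  nd <- min(n - 1L, round(spec$decay * rate))
  if (na > 0L) env[seq_len(na)] <- seq(0, 1, length.out = na)
  if (nd > 0L) env[(n - nd):n] <- seq(1, 0, length.out = nd + 1L)
  x <- x * env
  peak <- max(abs(x))
  if (peak > 0) x <- x * (spec$amplitude / peak)
  audio_clip(x, rate)
}
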