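#' Peak frequency of a spectral slice
#'
#' Frequency of the maximum-power bin, in kHz. Ties are broken towards
#' the lowest frequency. When the spectrum is nearly flat
#' (peak-to-mean power ratio below `flatness_ratio`), the value is
#' returned with attribute `low_confidence = TRUE`.
#'
#' @param slice A [spectral_slice()].
#' @param flatness_ratio Peak/mean power ratio below which the peak is
#'   flagged low-confidence.
#' @return Peak frequency in kHz (`NA` for an all-zero slice, reported as
#'   missing rather than an error).
#' @export
peak_frequency <- function(slice, flatness_ratio = 3) {
  stopifnot(inherits(slice, "spectral_slice"))
  if (all(slice$p == 0)) return(NA_real_)
  i <- which.max(slice$p)   # which.max returns the first (lowest) maximum
  out <- slice$freq[i] / 1000
  if (slice$p[i] / mean(slice$p) < flatness_ratio)
    attr(out, "low_confidence") <- TRUE
  out
}

#' Normalised Shannon spectral entropy
#'
#' `-sum(p log p) / log(N)` over the `N` bins of the normalised slice:
#' 1 for white noise (flat spectrum), approaching 0 for a spectrum
#' concentrated in a single bin. Note that a windowed sinusoid cannot
#' reach 0 exactly: the analysis window's main lobe spreads a pure tone
#' over a few bins (about 0.16 for a Hann window at 512-point FFT).
#'
#' @param slice A [spectral_slice()].
#' @return Entropy in `[0, 1]`, or `NA` for a zero-energy slice.
#' @export
shannon_entropy <- function(slice) {
  stopifnot(inherits(slice, "spectral_slice"))
  p <- slice$p
  if (sum(p) <= 0) return(NA_real_)
  p <- p / sum(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(length(p))
}

#' Energy quartile frequencies of a spectral slice
#'
#' The frequency below which a given fraction of the total spectral
#' energy lies: `q50` splits the spectrum into two equal-energy halves;
#' `iqr = q75 - q25`.
#'
#' @param slice A [spectral_slice()].
#' @return List with `q25`, `q50`, `q75`, `iqr` (Hz), all `NA` if the
#'   slice has no energy.
#' @export
spectral_quartiles <- function(slice) {
  stopifnot(inherits(slice, "spectral_slice"))
  if (sum(slice$p) <= 0)
    return(list(q25 = NA_real_, q50 = NA_real_, q75 = NA_real_,
                iqr = NA_real_))
  cs <- cumsum(slice$p) / sum(slice$p)
  qf <- function(q) slice$freq[which(cs >= q)[1L]]
  q25 <- qf(0.25); q50 <- qf(0.5); q75 <- qf(0.75)
  list(q25 = q25, q50 = q50, q75 = q75, iqr = q75 - q25)
}

#' Dominant-frequency track over a segment
#'
#' Per-frame argmax frequency within an analysis band (default 100 Hz to
#' Nyquist, excluding DC). Frames with no energy in the band are
#' interpolated linearly from their neighbours.
#'
#' @param spg A [compute_spectrogram()] result.
#' @param segment `c(onset, offset)` seconds or `NULL`.
#' @param band `c(low, high)` Hz analysis band.
#' @return Numeric vector of dominant frequencies (Hz), one per frame;
#'   `NULL` when the segment holds fewer than 2 frames (coefficients are
#'   then missing).
#' @export
frequency_track <- function(spg, segment = NULL, band = c(100, Inf)) {
  stopifnot(inherits(spg, "spectrogram"))
  fr <- frames_in_segment(spg, segment)
  if (length(fr) < 2L) return(NULL)
  bins <- which(spg$freq >= band[1L] & spg$freq <= band[2L])
  P <- spg$power[fr, bins, drop = FALSE]
  tot <- rowSums(P)
  f <- spg$freq[bins][max.col(P, ties.method = "first")]
  # frames more than 30 dB below the loudest frame carry no reliable
  # dominant frequency; treat them as silent and interpolate
  silent <- tot <= max(tot) * 1e-3
  if (any(silent)) {
    if (all(silent)) return(rep(NA_real_, length(fr)))
    f[silent] <- NA_real_
    f <- stats::approx(seq_along(f)[!silent], f[!silent],
                       xout = seq_along(f), rule = 2)$y
  }
  f
}

#' Coefficient of frequency variation
#'
#' `sd(track) / mean(track)`: the spread of the dominant frequency
#' around its mean, scale-invariant.
#' @param track Output of [frequency_track()].
#' @return Dimensionless coefficient, `NA` for missing tracks.
#' @export
coef_variation <- function(track) {
  if (is.null(track) || length(track) < 2L || anyNA(track)) return(NA_real_)
  stats::sd(track) / mean(track)
}

#' Coefficient of frequency modulation
#'
#' `mean(|diff(track)|) / mean(track)`: frame-to-frame frequency change
#' relative to the mean frequency, scale-invariant.
#' @param track Output of [frequency_track()].
#' @return Dimensionless coefficient, `NA` for missing tracks.
#' @export
coef_modulation <- function(track) {
  if (is.null(track) || length(track) < 2L || anyNA(track)) return(NA_real_)
  mean(abs(diff(track))) / mean(track)
}

#' Frequency transitions across a scream
#'
#' Signed differences of the peak frequency between the beginning,
#' middle and end of the segment: `onset` is middle minus beginning,
#' `offset` is end minus middle. The beginning/middle/end windows are
#' the first, central and last `window_frac` of frames.
#'
#' @param spg A [compute_spectrogram()] result.
#' @param segment `c(onset, offset)` seconds or `NULL`.
#' @param window_frac Fraction of frames in each window (default 0.2).
#' @param band Analysis band in Hz, as in [frequency_track()].
#' @return List with `onset` and `offset` (Hz, signed); both `NA` when
#'   the segment holds fewer than 3 windows' worth of frames.
#' @export
transitions <- function(spg, segment = NULL, window_frac = 0.2,
                        band = c(100, Inf)) {
  stopifnot(inherits(spg, "spectrogram"))
  fr <- frames_in_segment(spg, segment)
  nw <- max(1L, round(window_frac * length(fr)))
  if (length(fr) < 3L)
    return(list(onset = NA_real_, offset = NA_real_))
  bins <- which(spg$freq >= band[1L] & spg$freq <= band[2L])
  pk <- function(sub) {
    s <- colMeans(spg$power[sub, bins, drop = FALSE])
    spg$freq[bins][which.max(s)]
  }
  beg <- pk(fr[seq_len(nw)])
  mid0 <- floor((length(fr) - nw) / 2)
  mid <- pk(fr[(mid0 + 1L):(mid0 + nw)])
  end <- pk(fr[(length(fr) - nw + 1L):length(fr)])
  list(onset = mid - beg, offset = end - mid)
}

# parabolic interpolation of a spectral peak position (in bins) from log
# power; gives sub-bin frequency estimates for the harmonicity test
interp_peak <- function(p, i) {
  if (i <= 1L || i >= length(p) || p[i] <= 0) return(i)
  lp <- log(pmax(p[(i - 1L):(i + 1L)], .Machine$double.xmin))
  den <- lp[1L] - 2 * lp[2L] + lp[3L]
  if (den >= 0) return(i)
  i + 0.5 * (lp[1L] - lp[3L]) / den
}

#' Default thresholds for the non-linear phenomena detector
#'
#' @param jump_frac Minimum relative step of the dominant-frequency
#'   track counted as a frequency jump.
#' @param sub_rel_db Minimum level of the half-fundamental component
#'   relative to the fundamental (dB) for a subharmonic.
#' @param sub_min_frac Minimum fraction of frames with subharmonic
#'   energy ("sustained").
#' @param biph_rel_db Minimum level of a second, non-harmonic peak
#'   relative to the dominant peak (dB).
#' @param biph_min_frac Minimum fraction of frames showing the second
#'   peak.
#' @param ratio_tol Relative tolerance around small-integer frequency
#'   ratios within which a second peak counts as harmonically related.
#' @param chaos_entropy Per-frame normalised entropy above which a frame
#'   counts as chaotic.
#' @param chaos_peakiness Peak-to-mean power ratio below which a frame
#'   counts as untonal (chaotic frames must satisfy both criteria).
#' @param chaos_min_frac Minimum fraction of chaotic frames.
#' @return A list of thresholds.
#' @export
nlp_params <- function(jump_frac = 0.2, sub_rel_db = -15,
                       sub_min_frac = 0.4, biph_rel_db = -15,
                       biph_min_frac = 0.4, ratio_tol = 0.025,
                       chaos_entropy = 0.75, chaos_peakiness = 20,
                       chaos_min_frac = 0.2) {
  as.list(environment())
}

#' Detect non-linear phenomena in a scream
#'
#' Flags the four classical non-linear phenomena of the mammalian vocal
#' source from the spectrogram of one scream:
#'
#' * `jump` — an abrupt step of the dominant-frequency track (relative
#'   change above `jump_frac` within one hop, after 3-point median
#'   smoothing).
#' * `subharmonic` — sustained energy at half the dominant frequency,
#'   above `sub_rel_db` relative to the dominant peak and well above the
#'   local spectral background.
#' * `biphonation` — a second spectral peak whose frequency ratio to the
#'   dominant peak is not within `ratio_tol` of any small-integer ratio
#'   (a subharmonic at exactly 1:2 is therefore not biphonation).
#' * `chaos` — a sustained stretch of frames whose per-frame normalised
#'   spectral entropy exceeds `chaos_entropy`.
#'
#' @param spg A [compute_spectrogram()] result.
#' @param segment `c(onset, offset)` seconds or `NULL`.
#' @param params Thresholds from [nlp_params()].
#' @param band Analysis band, Hz.
#' @param track Optional precomputed [frequency_track()] for the same
#'   segment (recomputed when `NULL`).
#' @return Named logical vector `c(jump, subharmonic, biphonation,
#'   chaos)`; all `FALSE` on degenerate input.
#' @export
detect_nlp <- function(spg, segment = NULL, params = nlp_params(),
                       band = c(100, Inf), track = NULL) {
  stopifnot(inherits(spg, "spectrogram"))
  out <- c(jump = FALSE, subharmonic = FALSE, biphonation = FALSE,
           chaos = FALSE)
  fr <- frames_in_segment(spg, segment)
  if (length(fr) < 3L) return(out)
  bins <- which(spg$freq >= band[1L] &
                  spg$freq <= min(band[2L], max(spg$freq)))
  P <- spg$power[fr, , drop = FALSE]
  binw <- spg$freq[2L]

  # --- frequency jump: step in the smoothed dominant-frequency track.
  # With overlapping windows an instantaneous step resolves over one
  # window length, so the step is measured over lags up to
  # fft_size / hop frames (slow modulation contributes only Hz over
  # that span and cannot trigger it).
  if (is.null(track)) track <- frequency_track(spg, segment, band)
  if (!is.null(track) && !anyNA(track) && length(track) >= 5L) {
    sm <- stats::runmed(track, 3L)
    thr <- max(params$jump_frac * stats::median(sm), 2.5 * binw)
    max_lag <- min(length(sm) - 1L,
                   as.integer(ceiling(spg$settings$fft_size / spg$hop)))
    for (lag in seq_len(max_lag)) {
      if (any(abs(diff(sm, lag = lag)) > thr)) {
        out["jump"] <- TRUE
        break
      }
    }
  }

  # --- subharmonic: sustained energy at half the dominant frequency
  if (!is.null(track) && !anyNA(track)) {
    nfr <- length(fr)
    nb <- ncol(P)
    b0 <- round(track / binw) + 1L
    bh <- round(track / 2 / binw) + 1L
    ok <- bh > 3L & bh + 6L <= nb & b0 + 1L <= nb
    rows <- seq_len(nfr)
    col <- function(bin, off) P[cbind(rows, pmin(nb, pmax(1L, bin + off)))]
    p_half <- pmax(col(bh, -1L), col(bh, 0L), col(bh, 1L))
    p_dom <- pmax(col(b0, -1L), col(b0, 0L), col(b0, 1L))
    # local background from bins flanking the half-frequency band
    bg <- numeric(nfr)
    for (off in c(-6:-2, 2:6)) bg <- bg + col(bh, off)
    bg <- bg / 10
    hit <- ok & p_half >= p_dom * 10^(params$sub_rel_db / 10) &
      p_half > 4 * pmax(bg, .Machine$double.xmin)
    out["subharmonic"] <- mean(hit) >= params$sub_min_frac
  }

  # --- biphonation: sustained second per-frame peak at a non-harmonic
  # frequency ratio. Assessed frame-by-frame (per-frame spectra are not
  # smeared by frequency drift, unlike the mean slice) on up to 40
  # evenly spaced frames.
  if (!is.null(track) && !anyNA(track)) {
    ratios <- unique(c(outer(1:8, 1:4, "/")))
    ratios <- ratios[ratios >= 0.2 & ratios <= 8]
    nfr <- length(fr)
    sel <- if (nfr > 40L) unique(round(seq(1L, nfr, length.out = 40L)))
    else seq_len(nfr)
    nb <- ncol(P)
    # a genuine second voice recurs at a stable absolute frequency;
    # broadband-noise spikes are scattered across bins and frames, so
    # candidates are accumulated per bin and only a band that recurs in
    # enough frames counts
    votes <- numeric(nb)
    for (j in sel) {
      p <- P[j, ]
      b0 <- round(track[j] / binw) + 1L
      if (b0 < 1L || b0 > nb) next
      dom <- max(p[max(1L, b0 - 1L):min(nb, b0 + 1L)])
      lvl <- max(dom * 10^(params$biph_rel_db / 10),
                 max(p) * 10^(-spg$settings$dynamic_range / 10))
      pk <- which(p >= lvl & p >= c(-Inf, p[-nb]) & p > c(p[-1L], -Inf) &
                    spg$freq >= band[1L])
      pk <- pk[abs(pk - b0) > 2L]
      if (!length(pk)) next
      f0 <- (interp_peak(p, b0) - 1) * binw
      hit_bins <- integer(0)
      for (ci in pk) {
        r <- (interp_peak(p, ci) - 1) * binw / f0
        if (all(abs(r / ratios - 1) > params$ratio_tol))
          hit_bins <- c(hit_bins, (ci - 1L):(ci + 1L))
      }
      hit_bins <- unique(hit_bins[hit_bins >= 1L & hit_bins <= nb])
      votes[hit_bins] <- votes[hit_bins] + 1
    }
    out["biphonation"] <- max(votes) / length(sel) >= params$biph_min_frac
  }

  # --- deterministic chaos: a sustained stretch of frames that are both
  # high-entropy and untonal (no dominant spectral peak); the peakiness
  # criterion keeps heavy but stationary broadband noise around a strong
  # harmonic stack from counting as chaos
  Pb <- P[, bins, drop = FALSE]
  tot <- rowSums(Pb)
  ok <- tot > 0
  if (any(ok)) {
    pp <- Pb[ok, , drop = FALSE] / tot[ok]
    hh <- -rowSums(pp * log(pmax(pp, 1e-300))) / log(ncol(pp))
    peakiness <- apply(pp, 1L, max) * ncol(pp)   # peak / mean power
    chaotic <- hh > params$chaos_entropy & peakiness < params$chaos_peakiness
    out["chaos"] <- mean(chaotic) >= params$chaos_min_frac
  }
  out
}

#' Call-level features of one scream
#'
#' Computes the nine call-level parameters (duration, peak frequency,
#' coefficients of frequency variation and modulation, transition onset
#' and offset, Q50, inter-quartile range, Shannon entropy) plus the four
#' non-linear phenomena flags from one scream's portion of a
#' spectrogram.
#'
#' @param spg A [compute_spectrogram()] result for the recording.
#' @param onset,offset Scream boundaries in seconds.
#' @param params [nlp_params()] thresholds.
#' @return One-row `data.frame` of features; failed measures are `NA`.
#' @export
call_features <- function(spg, onset, offset, params = nlp_params()) {
  stopifnot(inherits(spg, "spectrogram"), offset > onset)
  seg <- c(onset, offset)
  slice <- spectral_slice(spg, seg)
  qs <- spectral_quartiles(slice)
  track <- frequency_track(spg, seg)
  tr <- transitions(spg, seg)
  nlp <- detect_nlp(spg, seg, params, track = track)
  pf <- peak_frequency(slice)
  data.frame(
    duration = offset - onset,
    peak_frequency = as.numeric(pf),
    coef_freq_variation = coef_variation(track),
    coef_freq_modulation = coef_modulation(track),
    transition_onset = tr$onset,
    transition_offset = tr$offset,
    q50 = qs$q50, iqr = qs$iqr,
    entropy = shannon_entropy(slice),
    nlp_jump = unname(nlp["jump"]),
    nlp_subharmonic = unname(nlp["subharmonic"]),
    nlp_biphonation = unname(nlp["biphonation"]),
    nlp_any = any(nlp),
    nlp_chaos = unname(nlp["chaos"]))[, c(
      "duration", "peak_frequency", "coef_freq_variation",
      "coef_freq_modulation", "transition_onset", "transition_offset",
      "q50", "iqr", "entropy", "nlp_jump", "nlp_subharmonic",
      "nlp_biphonation", "nlp_chaos", "nlp_any")]
}

.call_feature_cols <- c("duration", "peak_frequency", "coef_freq_variation",
                        "coef_freq_modulation", "transition_onset",
                        "transition_offset", "q50", "iqr", "entropy")
.bout_feature_cols <- c("bout_duration", "n_screams", "avg_scream_duration",
                        "scream_intervals", "scream_rate", "pct_nlp")

#' Extract call- and bout-level feature tables from a study
#'
#' Runs the full extraction over an annotated dataset: for every event
#' recording, computes a spectrogram and measures each annotated
#' good-quality scream (annotation-trusting mode: the recorded
#' onsets/offsets are used); then aggregates bout-level features. Feature
#' failures are kept as `NA`, never dropped.
#'
#' @param study A `scream_study` from [simulate_study()] (with audio), or
#'   a list with `clips` (named [audio_clip()] list by `event_id`) and
#'   `annotations` (validated table with `onset`/`offset`).
#' @param settings [spectrogram_settings()].
#' @param params [nlp_params()].
#' @return List with `call` (one row per scream: 9 features + flags +
#'   labels) and `bout` (one row per bout: 6 features + labels).
#' @export
extract_features <- function(study, settings = spectrogram_settings(),
                             params = nlp_params()) {
  ann <- study$annotations
  if (!nrow(ann)) {
    call <- cbind(ann[0, , drop = FALSE],
                  stats::setNames(as.data.frame(
                    matrix(numeric(0), 0, length(.call_feature_cols))),
                    .call_feature_cols))
    bout <- stats::setNames(as.data.frame(
      matrix(numeric(0), 0, length(.bout_feature_cols))),
      .bout_feature_cols)
    return(list(call = call, bout = bout))
  }
  stopifnot(all(c("onset", "offset") %in% names(ann)))
  ann <- ann[ann$quality == "good", , drop = FALSE]
  feats <- vector("list", nrow(ann))
  for (ev in unique(ann$event_id)) {
    clip <- study$clips[[ev]]
    if (is.null(clip)) stop("no audio clip for event ", ev)
    for (i in which(ann$event_id == ev)) {
      # analyse only this scream's samples: one short spectrogram per
      # scream rather than one over the whole (mostly silent) event
      feats[[i]] <- tryCatch({
        i0 <- max(1L, floor(ann$onset[i] * clip$rate) + 1L)
        i1 <- min(length(clip$samples), ceiling(ann$offset[i] * clip$rate))
        sub <- audio_clip(clip$samples[i0:i1], clip$rate)
        spg <- compute_spectrogram(sub, settings)
        fe <- call_features(spg, 0, duration(sub), params)
        fe$duration <- ann$offset[i] - ann$onset[i]
        fe
      },
        error = function(e) {
          fe <- as.data.frame(as.list(stats::setNames(
            rep(NA_real_, length(.call_feature_cols)), .call_feature_cols)))
          fe$nlp_jump <- fe$nlp_subharmonic <- fe$nlp_biphonation <-
            fe$nlp_chaos <- fe$nlp_any <- NA
          fe
        })
    }
  }
  call_tab <- cbind(ann, do.call(rbind, feats))
  rownames(call_tab) <- NULL
  bout_tab <- bout_features_table(call_tab)
  list(call = call_tab, bout = bout_tab)
}

# aggregate call rows into the six bout-level features, preserving labels
bout_features_table <- function(call_tab) {
  rows <- lapply(split(call_tab, call_tab$bout_id), function(b) {
    b <- b[order(b$onset), , drop = FALSE]
    bf <- bout_features(
      data.frame(onset = b$onset, offset = b$offset),
      nlp_flags = b$nlp_any)
    lab <- b[1L, intersect(c("event_id", "bout_id", "caller_id", "role",
                             "severity", "context", "support_context",
                             "support"), names(b)), drop = FALSE]
    cbind(lab, as.data.frame(bf))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
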