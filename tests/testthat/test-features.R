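slice_of <- function(freq, p) {
  if (sum(p) > 0) p <- p / sum(p)
  structure(list(freq = freq, p = p), class = "spectral_slice")
}

test_that("spectrogram geometry follows from the settings arithmetic", {
  clip <- tone_clip(0.5, 1000)
  spg <- compute_spectrogram(clip)
  expect_equal(spg$freq[2], RATE / 512)         # ~86.13 Hz bins
  expect_identical(spg$hop, 51L)                # 512 * (1 - 0.9)
  expect_identical(ncol(spg$power), 257L)
  expect_true(all(diff(spg$times) > 0))
  expect_true(all(spg$power >= 0))

  short <- audio_clip(numeric(100), RATE)
  expect_error(compute_spectrogram(short), "pad")
  expect_error(spectrogram_settings(fft_size = 500), "power of two")
  expect_error(spectrogram_settings(overlap = 1), "overlap")
  # Praat-style parameterisation: 10 ms window -> next power of two
  expect_identical(spectrogram_settings(window_length = 0.01,
                                        rate = RATE)$fft_size, 512L)
})

test_that("an all-zero padded clip yields zero power and a sine peaks at its bin", {
  spg0 <- compute_spectrogram(audio_clip(numeric(2048), RATE))
  expect_true(all(spg0$power == 0))

  spg <- compute_spectrogram(tone_clip(0.5, 1000))
  argmax <- spg$freq[apply(spg$power, 1L, which.max)]
  expect_true(all(abs(argmax - 1000) <= RATE / 512))
})

test_that("spectral slices are normalised means of the frame spectra", {
  spg <- compute_spectrogram(tone_clip(0.5, 1000))
  slice <- spectral_slice(spg)
  expect_equal(sum(slice$p), 1)
  # stationary signal: every frame's normalised spectrum matches the slice
  frame17 <- spg$power[17, ] / sum(spg$power[17, ])
  expect_lt(max(abs(slice$p - frame17)), 0.02)

  # two tones -> local maxima at both bins
  clip2 <- audio_clip(tone_samples(0.5, 1000) + tone_samples(0.5, 4000), RATE)
  s2 <- spectral_slice(compute_spectrogram(clip2))
  top2 <- s2$freq[order(s2$p, decreasing = TRUE)[1:4]]
  expect_true(any(abs(top2 - 1000) <= RATE / 512))
  expect_true(any(abs(top2 - 4000) <= RATE / 512))

  expect_error(spectral_slice(spg, c(10, 11)), "outside")
})

test_that("peak frequency reports the lowest max bin and flags flat spectra", {
  pf <- peak_frequency(spectral_slice(compute_spectrogram(tone_clip(0.5, 2000))))
  expect_lt(abs(pf - 2), RATE / 512 / 1000)

  tie <- slice_of(c(100, 200, 300), c(1, 3, 3))
  expect_equal(as.numeric(peak_frequency(tie)), 0.2)  # lower of the tied bins

  expect_true(is.na(peak_frequency(slice_of(1:5, rep(0, 5)))))

  set.seed(4)
  flat <- slice_of(seq(0, 22050, length.out = 257),
                   rexp(257) + 5)
  expect_true(isTRUE(attr(peak_frequency(flat), "low_confidence")))
})

test_that("energy quartiles match a brute-force cumulative scan on random spectra", {
  brute <- function(freq, p, q) {
    cs <- cumsum(p) / sum(p)
    freq[which(cs >= q)[1]]
  }
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(16:257, 1)
    freq <- seq(0, 22050, length.out = n)
    p <- rexp(n) * rbinom(n, 1, 0.8)
    if (sum(p) == 0) p[1] <- 1
    qs <- spectral_quartiles(slice_of(freq, p))
    expect_identical(qs$q25, brute(freq, p, 0.25))
    expect_identical(qs$q50, brute(freq, p, 0.50))
    expect_identical(qs$q75, brute(freq, p, 0.75))
    expect_equal(qs$iqr, qs$q75 - qs$q25)
  }

  flat <- slice_of(seq(0, 1000, length.out = 101), rep(1, 101))
  qs <- spectral_quartiles(flat)
  expect_lt(abs(qs$q50 - 500), 10)
  expect_lt(abs(qs$iqr - 500), 10)

  one <- slice_of(c(100, 200, 300), c(0, 1, 0))
  qs1 <- spectral_quartiles(one)
  expect_equal(qs1$q25, 200); expect_equal(qs1$q75, 200)
  expect_equal(qs1$iqr, 0)
})

test_that("normalised entropy hits its closed-form anchors", {
  n <- 257
  freq <- seq(0, 22050, length.out = n)
  expect_equal(shannon_entropy(slice_of(freq, rep(1, n))), 1)
  half <- c(rep(1, n %/% 2), rep(0, n - n %/% 2))
  expect_equal(shannon_entropy(slice_of(freq, half)),
               log(n %/% 2) / log(n))
  single <- c(1, rep(0, n - 1))
  expect_equal(shannon_entropy(slice_of(freq, single)), 0)
  expect_true(is.na(shannon_entropy(slice_of(freq, rep(0, n)))))
})

test_that("entropy increases monotonically with the generator noise mix", {
  hs <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(m) {
    clip <- synth_scream(scream_spec(0.5, 1400, noise_mix = m), RATE,
                         seed = 50 + round(10 * m))
    shannon_entropy(spectral_slice(compute_spectrogram(clip)))
  }, numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("the dominant-frequency track follows tones, chirps and silent frames", {
  spg <- compute_spectrogram(tone_clip(0.5, 1500))
  tr <- frequency_track(spg)
  expect_lt(max(abs(tr - 1500)), RATE / 512)

  # linear chirp 1 -> 2 kHz: monotone within bin resolution
  t <- (0:(RATE / 2 - 1)) / RATE
  chirp <- audio_clip(0.8 * sin(2 * pi * (1000 * t + 1000 * t^2)), RATE)
  trc <- frequency_track(compute_spectrogram(chirp))
  expect_true(all(diff(trc) >= -RATE / 512))
  expect_lt(abs(trc[1] - 1000), 3 * RATE / 512)
  expect_lt(abs(trc[length(trc)] - 2000), 3 * RATE / 512)

  # a silent stretch inside the call is interpolated from its neighbours
  gap <- audio_clip(c(tone_samples(0.2, 1000), silence(0.1),
                      tone_samples(0.2, 1000)), RATE)
  trg <- frequency_track(compute_spectrogram(gap))
  expect_false(anyNA(trg))
  expect_lt(max(abs(trg - 1000)), 2 * RATE / 512)

  expect_null(frequency_track(spg, c(0.01, 0.011)))
})

test_that("variation and modulation coefficients follow their formulas", {
  expect_equal(coef_variation(rep(1200, 10)), 0)
  expect_equal(coef_modulation(rep(1200, 10)), 0)

  tr <- c(1000, 1200, 1000, 1200)
  expect_equal(coef_modulation(tr), 200 / 1100)
  expect_equal(coef_variation(tr), stats::sd(tr) / 1100)

  # scale invariance
  expect_equal(coef_variation(2 * tr), coef_variation(tr))
  expect_equal(coef_modulation(2 * tr), coef_modulation(tr))

  expect_true(is.na(coef_variation(NULL)))
  expect_true(is.na(coef_modulation(1500)))
})

test_that("transitions measure peak-frequency differences between call thirds", {
  # constant tone: no transitions
  tr0 <- transitions(compute_spectrogram(tone_clip(0.5, 1500)))
  expect_equal(tr0$onset, 0)
  expect_equal(tr0$offset, 0)

  # linear up-sweep 1 -> 2 kHz; windows are the first/central/last 20%
  # of frames, so the expected differences are f(50%) - f(10%) and
  # f(90%) - f(50%) = 400 Hz each
  t <- (0:(RATE / 2 - 1)) / RATE
  up <- audio_clip(0.8 * sin(2 * pi * (1000 * t + 1000 * t^2)), RATE)
  tru <- transitions(compute_spectrogram(up))
  expect_lt(abs(tru$onset - 400), 2.5 * RATE / 512)
  expect_lt(abs(tru$offset - 400), 2.5 * RATE / 512)

  # symmetric up-down sweep 1 -> 2 -> 1 kHz: antisymmetric transitions,
  # f(50%) - f(10%) = 2000 - 1400 = +600 and mirror-image offset
  half <- RATE / 4
  f_inst <- c(seq(1000, 2000, length.out = half),
              seq(2000, 1000, length.out = half))
  sweep <- audio_clip(0.8 * sin(2 * pi * cumsum(f_inst) / RATE), RATE)
  trs <- transitions(compute_spectrogram(sweep))
  expect_lt(abs(trs$onset - 600), 3 * RATE / 512)
  expect_lt(abs(trs$offset + 600), 3 * RATE / 512)

  short <- transitions(compute_spectrogram(tone_clip(0.5, 1500)),
                       c(0.01, 0.012))
  expect_true(is.na(short$onset) && is.na(short$offset))
})

test_that("non-linear phenomena flags fire on their injected forms only", {
  spg_of <- function(nlp, seed, noise = 0.1)
    compute_spectrogram(synth_scream(
      scream_spec(0.5, 1400, noise_mix = noise, nlp = nlp), RATE, seed))

  clean <- detect_nlp(spg_of(list(), 1))
  expect_false(any(clean))

  jump <- detect_nlp(spg_of(list(jump = list(frac = 0.3)), 2))
  expect_true(jump[["jump"]])

  sub <- detect_nlp(spg_of(list(subharmonic = list(level_db = -6)), 3))
  expect_true(sub[["subharmonic"]])
  expect_false(sub[["biphonation"]])   # a 1:2 ratio is harmonically related

  biph <- detect_nlp(spg_of(list(biphonation = list(level_db = -6)), 4))
  expect_true(biph[["biphonation"]])

  chaos <- detect_nlp(spg_of(list(chaos = list(frac = 0.35)), 5))
  expect_true(chaos[["chaos"]])
})

test_that("NLP detection is sensitive and specific at default injection strengths", {
  forms <- c("jump", "subharmonic", "biphonation", "chaos")
  n_per <- 25L
  hits <- matrix(NA, n_per, length(forms), dimnames = list(NULL, forms))
  fp <- logical(2 * n_per)
  k <- 0L
  for (i in seq_len(n_per)) {
    noise <- if (i %% 2 == 0) 0.15 else 0.3   # mild and severe regimes
    f0 <- 1100 + 60 * (i %% 7)
    for (f in forms) {
      spec <- scream_spec(0.45, f0, freq_slope = 200 * (i %% 3 - 1),
                          noise_mix = noise,
                          nlp = stats::setNames(list(list()), f))
      spg <- compute_spectrogram(synth_scream(spec, RATE, seed = 700 + i))
      hits[i, f] <- detect_nlp(spg)[[f]]
    }
    for (j in 1:2) {
      k <- k + 1L
      spec <- scream_spec(0.45, f0, freq_slope = 200 * (i %% 3 - 1),
                          noise_mix = noise)
      spg <- compute_spectrogram(synth_scream(spec, RATE, seed = 900 + k))
      fp[k] <- any(detect_nlp(spg))
    }
  }
  expect_true(all(colMeans(hits) >= 0.9))   # sensitivity per form
  expect_lte(mean(fp), 0.1)                 # false-positive rate, clean calls
})

test_that("all features are invariant to overall amplitude scaling", {
  spec <- scream_spec(0.5, 1400, noise_mix = 0.25,
                      nlp = list(subharmonic = list(level_db = -6)))
  clip <- synth_scream(spec, RATE, seed = 8)
  soft <- audio_clip(clip$samples * 0.1, RATE)
  f_loud <- call_features(compute_spectrogram(clip), 0, duration(clip))
  f_soft <- call_features(compute_spectrogram(soft), 0, duration(soft))
  expect_equal(f_loud, f_soft, tolerance = 1e-10)
})

test_that("the full extraction yields the 15 features and is pure per scream", {
  cfg <- study_config(n_callers = 3, n_events = 6, n_bouts = 8,
                      n_screams = 20, seed = 23)
  st <- simulate_study(cfg)
  fx <- extract_features(st)
  call_cols <- c("duration", "peak_frequency", "coef_freq_variation",
                 "coef_freq_modulation", "transition_onset",
                 "transition_offset", "q50", "iqr", "entropy")
  bout_cols <- c("bout_duration", "n_screams", "avg_scream_duration",
                 "scream_intervals", "scream_rate", "pct_nlp")
  expect_true(all(call_cols %in% names(fx$call)))
  expect_true(all(bout_cols %in% names(fx$bout)))
  expect_identical(nrow(fx$call), 20L)
  expect_identical(nrow(fx$bout), 8L)
  # every scream in exactly one bout, every bout in exactly one event
  expect_identical(sum(fx$bout$n_screams), 20L)
  expect_identical(length(unique(paste(fx$bout$bout_id, fx$bout$event_id))),
                   length(unique(fx$bout$bout_id)))

  # purity: one scream recomputed in isolation equals its pipeline row
  row <- fx$call[7, ]
  clip <- st$clips[[row$event_id]]
  i0 <- max(1L, floor(row$onset * clip$rate) + 1L)
  i1 <- min(length(clip$samples), ceiling(row$offset * clip$rate))
  sub <- audio_clip(clip$samples[i0:i1], clip$rate)
  alone <- call_features(compute_spectrogram(sub), 0, duration(sub))
  expect_equal(alone$entropy, row$entropy)
  expect_equal(alone$q50, row$q50)
  expect_identical(alone$nlp_any, row$nlp_any)

  # empty dataset: empty tables with full headers
  empty <- suppressWarnings(simulate_study(study_config(n_screams = 0),
                                           audio = FALSE))
  fe <- extract_features(empty)
  expect_identical(nrow(fe$call), 0L)
  expect_true(all(bout_cols %in% names(fe$bout)))
})
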