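# shared fixtures: tones, silences and study configurations used across
# the test files; everything is generated in code at test time

RATE <- 44100

tone_samples <- function(dur, freq = 1500, rate = RATE, amp = 0.8) {
  amp * sin(2 * pi * freq * (seq_len(round(dur * rate)) - 1) / rate)
}

silence <- function(dur, rate = RATE) numeric(round(dur * rate))

tone_clip <- function(dur, freq = 1500, rate = RATE) {
  audio_clip(tone_samples(dur, freq, rate), rate)
}

call_feature_set <- c("duration", "peak_frequency", "coef_freq_modulation",
                      "transition_onset", "transition_offset", "q50",
                      "iqr", "entropy")

# study with every identity and effect channel switched off: features are
# exchangeable across callers within role x severity cells
null_identity_config <- function(seed, n_callers = 4L, n_events = 48L,
                                 n_bouts = 64L, n_screams = 200L) {
  study_config(n_callers = n_callers, n_events = n_events,
               n_bouts = n_bouts, n_screams = n_screams,
               between_sd = 0, caller_duration_sd = 0, caller_noise_sd = 0,
               victim_duration_factor = 1, victim_q50_shift = 0,
               severe_entropy_shift = 0, severe_nlp_prob = 0.15,
               severe_rate_factor = 1, p_severe = 0.5, seed = seed)
}

# a tiny annotated table satisfying the schema
tiny_annotations <- function() {
  data.frame(
    event_id = c("E1", "E1", "E1", "E2"),
    bout_id = c("B1", "B1", "B2", "B3"),
    caller_id = c("C1", "C1", "C1", "C2"),
    role = c("victim", "victim", "aggressor", "victim"),
    severity = c("mild", "mild", "mild", "severe"),
    quality = c("good", "good", "good", "poor"),
    onset = c(0.2, 1.0, 2.5, 0.3),
    offset = c(0.6, 1.5, 2.9, 0.8),
    stringsAsFactors = FALSE)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}

# direct simulation of the mixed-model data-generating process: random
# caller and event intercepts plus fixed role/severity effects
make_lmm_data <- function(n_callers = 10, obs_per = 8, beta_role = 0,
                          beta_sev = 0, sd_caller = 0.5, sd_event = 0.3,
                          sd_res = 1, seed = 1) {
  set.seed(seed)
  n <- n_callers * obs_per
  caller <- rep(sprintf("C%02d", seq_len(n_callers)), each = obs_per)
  event <- sprintf("E%03d", sample.int(n %/% 2, n, replace = TRUE))
  role <- sample(c("aggressor", "victim"), n, replace = TRUE)
  severity <- sample(c("mild", "severe"), n, replace = TRUE)
  u_c <- rnorm(n_callers, 0, sd_caller)[as.integer(factor(caller))]
  u_e <- rnorm(n %/% 2, 0, sd_event)[as.integer(factor(event))]
  y <- u_c + u_e + beta_role * (role == "victim") +
    beta_sev * (severity == "severe") + rnorm(n, 0, sd_res)
  data.frame(y = y, caller_id = caller, event_id = event,
             role = role, severity = severity)
}
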