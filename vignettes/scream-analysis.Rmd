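---
title: "Methods: simulating and analysing agonistic screams"
author: "screamr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing agonistic screams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During agonistic encounters, many group-living primates produce screams:
high-pitched, high-amplitude calls whose acoustic structure may encode who
is calling, what role they hold in the conflict (aggressor or victim), and
how severe the conflict is. Testing those hypotheses requires a pipeline
that (i) segments screams from field recordings into biologically defined
units, (ii) measures a standard set of spectro-temporal parameters,
(iii) asks whether calls can be assigned to callers or contexts better
than chance under a permutation-calibrated discriminant analysis, and
(iv) models role/severity effects on each parameter with mixed models and
joint false-discovery-rate control. `screamr` implements that pipeline
end to end, together with a synthetic study generator with known ground
truth so every stage is testable without any field data.

## Units of analysis

Three nested units follow the field definitions:

* **scream** — one utterance; voiced units separated by gaps of at most
  0.03 s belong to the same continuous unit, and units closer than 0.3 s
  belong to the same scream. Gaps of 0.3 s or more separate screams.
* **bout** — a conflict stage in which the signaller's social role and
  the conflict severity are both constant; a change in either starts a
  new bout.
* **event** — an agonistic interaction; a new event starts when at least
  30 s pass without agonistic behaviour or when the pair of interacting
  individuals changes.

The band between the two silence thresholds (0.03–0.3 s) is read as
separating units *within* one scream, so a scream's duration spans its
first unit's onset to its last unit's offset; this keeps both printed
thresholds operative. The 0.3 s rule is applied per caller. The detector
(`detect_screams()`) gates short-window RMS energy at −25 dB relative to
the loudest frame with a 5 ms frame and 2.5 ms hop and drops raw regions
shorter than 50 ms; these are detector conventions (manual segmentation
needs none) and all are configurable. When annotations provide onsets
and offsets, detection is skipped ("annotation-trusting" mode), which
mirrors a manual Praat workflow; `read_textgrid()` ingests such
annotations directly.

## Acoustic features

All spectral measures derive from a Hann-windowed short-time Fourier
transform with a 512-sample FFT and 90% overlap at 44.1 kHz (bin width
≈ 86.1 Hz, hop 51 samples). A Praat-style `window_length` in seconds is
accepted and converted to the next power-of-two FFT size. Recordings at
other rates are resampled on read with a warning so that one set of
spectral settings applies throughout.

Nine call-level parameters are measured per scream: duration; peak
frequency (argmax of the normalised mean power spectrum, ties to the
lowest bin, flagged low-confidence when the spectrum is nearly flat);
coefficients of frequency variation (`sd/mean` of the dominant-frequency
track) and modulation (`mean|Δ|/mean`); signed transition onset/offset
(peak frequency of the middle 20% of frames minus the first 20%, and
last minus middle — the name "absolute transition" is kept for the
field's terminology but the subtraction is signed); the 50% energy
quartile Q50 and the inter-quartile range Q25–Q75 (cumulative-energy
crossing frequencies); and normalised Shannon entropy. Six bout-level
parameters aggregate screams within a bout: bout duration, scream count,
mean scream duration, mean inter-scream interval, scream rate, and the
percentage of screams carrying at least one non-linear phenomenon.

Entropy is `-Σ p log p / log N` over the `N` one-sided bins of the mean
power spectrum, so a flat spectrum scores 1 at any FFT size. A windowed
sinusoid cannot reach 0: the Hann main lobe spreads a tone over at least
three bins, which bounds its entropy below by about 0.156 at a 512-point
FFT (`-Σ p log p = (2/3)log(3/2) + (1/3)log 6 ≈ 0.868` nats over
`log 257 ≈ 5.55`). This leakage floor is an analysis-window property,
not noise; it is far below the entropy of any natural scream, so the
white-noise/pure-tone anchors remain ordered as intended but the
pure-tone value should be expected near 0.16 rather than 0.

The dominant-frequency track is the per-frame argmax in a 100 Hz–Nyquist
band (DC excluded); frames more than 30 dB below the loudest frame are
treated as silent and linearly interpolated from their neighbours. All
features are invariant to overall amplitude scaling because every
spectrum is normalised before use.

### Non-linear phenomena

Field studies typically code non-linear phenomena (NLP) by eye and ear
from spectrograms; `screamr` provides an algorithmic surrogate whose
thresholds (`nlp_params()`) were calibrated on the synthetic generator —
passing its detection tests therefore shows the detectors work on calls
matching the generator's physics, not that they match a human coder on
field recordings.

* **Frequency jump**: a step of the 3-point-median-smoothed track
  exceeding 20% of the track median (and at least 2.5 bins). Because a
  step resolves over one full analysis window under 90% overlap, the
  step is evaluated over lags up to `fft_size/hop` frames; slow
  modulation contributes only a few Hz over that span.
* **Subharmonic**: sustained (≥40% of frames) energy within one bin of
  half the dominant frequency, above −15 dB relative to the dominant
  peak and at least 4× the local spectral background.
* **Biphonation**: a second per-frame peak above −15 dB whose frequency
  ratio to the dominant peak is not within 2.5% of any small-integer
  ratio (m/n, m ≤ 8, n ≤ 4); a subharmonic at exactly 1:2 therefore does
  not count. Candidates are accumulated per frequency bin across frames
  and only a band recurring in ≥40% of frames fires — a genuine second
  voice is spectrally stable, whereas broadband-noise peaks scatter.
  Per-frame (rather than mean-slice) analysis avoids the smearing of
  high harmonics by frequency drift.
* **Deterministic chaos**: ≥20% of frames that are simultaneously
  high-entropy (per-frame normalised entropy > 0.75) and untonal
  (peak-to-mean power < 20). The tonality criterion stops heavy but
  stationary broadband noise around an intact harmonic stack from
  counting as chaos.

## The synthetic study generator

`synth_scream()` renders a harmonic stack with `1/k` amplitude roll-off
on a linearly drifting pseudo-fundamental, mixed with Gaussian broadband
noise so that `noise_mix` is the broadband energy fraction (the direct
driver of spectral entropy), under an attack/decay envelope. The four
NLP forms are physically injected: a fundamental step (default +30% at
mid-call), an added component at half the fundamental (−6 dB), an
independent second voice (default 1.42× the fundamental, chosen away
from small-integer ratios so the harmonicity test is meaningful), and a
segment replaced by band-passed noise at full depth (chaos is emulated
spectrally; no nonlinear dynamical system is simulated).

`simulate_study()` draws a complete annotated study. The default
configuration *is* the study design the package emulates: 26 callers,
374 analysable screams in 119 bouts across 95 events; one recording per
event (so segmentation is genuinely exercised); victims scream 1.5×
longer and 200 Hz higher; severe conflicts add 0.2 of broadband noise
share, triple the NLP probability (0.45 vs 0.15) and lower the calling
rate (rate factor 0.7 on a 0.5 s mean inter-scream interval, floored at
0.3 s); third-party support occurs in 39.6% of aggressor bouts and 4.8%
of victim bouts, with 1.9× the odds-scale weight under severe conflict.
Where the field literature gives no value, defaults were chosen once as
plausible for a medium-sized cercopithecine: population fundamental
1400 ± 250 Hz between callers and ±100 Hz within, log-normal scream
durations (median 0.35 s, σ = 0.3 on the log scale), ±400 Hz/s frequency
drift, 8 harmonics. Caller identity enters through the frequency
signature and through smaller caller-specific duration and noise
intercepts; setting `between_sd`, `caller_duration_sd` and
`caller_noise_sd` to zero produces a dataset carrying no identity
information, which is how the null-calibration studies are built.

`simulate_call_features()` is a statistical twin: the same latent
per-scream draws mapped to feature values by smooth monotone proxies
instead of waveform synthesis. It exists for calibration studies that
need thousands of datasets (permutation-null uniformity, type-I error,
parameter recovery); every scientific claim about the extractor itself
is tested on the waveform path.

The generator does not emulate reverberation, background fauna,
overlapping callers, microphone directionality or vocal-tract filtering,
so passing tests demonstrate correctness of the analysis machinery on
clean, single-caller audio — not robustness to field conditions.

## Discriminant analyses

`pdfa()` implements a permuted discriminant function analysis. The
classifier is a Fisher discriminant: class centroids with the pooled
within-class covariance; classification is nearest centroid in the
whitened space, which equals the Fisher rule with equal priors (the
within-class covariance is ridge-regularised, and flagged, only if
numerically singular). Jack-knifed rates follow the field convention:
classification success on the training subset, cross-validation success
on the held-out calls.

Crossed designs control a nuisance factor (e.g. role × severity when
testing caller identity). In the fully balanced mode only individuals
present in every control cell are retained and an equal per-cell number
of training calls — the minimum cell count times the training fraction,
at least 1 and leaving at least one holdout — is drawn per individual;
the achieved training share is reported rather than forced to a
constant. The unbalanced crossed mode keeps all individuals with at
least `min_samples` calls and stratifies draws by cell.

Significance is empirical: test-factor labels are shuffled within
control cells, preserving the design; each permuted dataset is evaluated
by exactly the same procedure as the observed data, i.e. averaged over
the same number of fresh training draws. This matched averaging makes
observed and permuted statistics exchangeable under the null, so the
add-one p-value `(b + 1)/(m + 1)` is uniform when there is no signal —
a single training draw per permutation would be cheaper but leaves the
p-value's null distribution concentrated around ½. Subsets are re-drawn
per permutation (the more conservative reading); features are
symmetrised (log/sqrt chosen by skewness, offsets logged), standardised,
and screened for pairwise |r| > 0.80 before entering any discriminant.
Ties in centroid assignment go to the lowest class label. Everything is
deterministic given the `seed`.

## Mixed-effects inference

Each retained acoustic parameter — eight call-level (the coefficient of
frequency variation is excluded as collinear with Q50) and four
bout-level (bout duration and scream intervals excluded as collinear
with scream count and rate) — is modelled by REML with social role,
conflict severity and their interaction as fixed effects and random
intercepts for caller and event. Responses pass through the same
symmetrise-and-scale policy, logged per response. p-values use the
Satterthwaite approximation; confidence intervals are Wald (±1.96 SE) —
profile intervals are out of scope. The 36 p-values (12 models × 3
effects) are adjusted jointly by Benjamini–Hochberg. Marginal and
conditional R² follow the variance-partition formula (fixed-effect
variance over total, plus random components for the conditional value;
π²/3 as the residual variance on the logit scale). Singular fits and
convergence messages are carried in the ledger, never hidden.

Support is modelled per bout by a binomial-logit GLMM (Laplace
approximation) on role, severity and their interaction, with caller and
a four-level production context as random intercepts. With realistic
bout counts (~111) and a 4.8% victim support rate, quasi-separation can
inflate the victim coefficient; its sign remains stable and that is what
the recovery study checks.

Diagnostics are explicit and policy-gated: observations with |scaled
residual| > 3 are flagged as outliers and callers whose removal shifts
any fixed effect by more than one standard error are flagged as
influential; nothing is removed unless the policy requests it, and every
removal is logged with before/after estimates. Cohen's kappa
(`cohen_kappa()`) supports inter-observer reliability checks, with the
continuous-measure agreement tolerances applied upstream as
categorisation rules by the caller.

## Study sizes used by the test-suite

The package's own validation studies use sizes chosen to give stable
Monte-Carlo answers on a single CPU: 1000 random spectra and p-vectors
and 100 discriminant instances for the oracle-equivalence checks; 200
replicate pipelines at 200 permutations (5 training draws each) for
null-calibration of the pDFA; one full-audio study at 1000 permutations
for signal recovery; 50 full-pipeline replicates at 26 callers / 300
screams / 120 bouts for effect recovery; 100 replicates of ~111 bouts
for the support model; 500 small-sample replicates for mixed-model
type-I error and 150 for CI coverage. Type-I error for the effect
recovery study is assessed over the contrasts that the generator leaves
null *and* that are acoustically decoupled from the two injected
effects — the broadband-noise shift genuinely moves quartiles,
modulation and NLP rates of severe screams, and the victim duration
factor genuinely moves victims' bout timing, so those contrasts are
true effects of the data-generating process rather than false
positives.

## Known limitations

* Fundamental-frequency and formant tracking are deliberately absent;
  noisy screams defeat them and the parameter set does not use them.
* The NLP detectors are validated only against the generator's physics;
  agreement with human auditory-visual coding of field recordings is
  untested.
* Entropy is computed on the whole-call mean spectrum (the per-frame
  average is used only inside the chaos detector); a tone's entropy has
  a leakage floor of ≈ 0.156 at the default settings.
* The support model's coefficient magnitudes are unstable under
  quasi-separation at realistic sample sizes; only signs and
  significance are interpreted.
* Overlapping simultaneous screamers are not resolved; callers are an
  annotation, never inferred from audio.
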