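# screamr

Acoustic and statistical analysis of primate agonistic screams.

During conflicts, vervet monkeys and other group-living primates produce
screams — high-pitched, high-amplitude calls whose structure may encode
the caller's identity, their social role in the conflict (aggressor vs.
victim) and the conflict's severity (mild vs. severe), and which may
recruit third-party support. `screamr` implements the full analysis
pipeline for such studies:

* **Synthetic study generator** — a harmonic-stack scream synthesiser
  (with injectable non-linear phenomena: frequency jumps, subharmonics,
  biphonation, deterministic chaos) and a whole-study simulator with
  known ground-truth effects, so the entire pipeline is testable without
  field recordings.
* **IO** — mono PCM WAV (16/24-bit), a documented annotation CSV schema
  with a strict validator, and Praat TextGrid interval tiers.
* **Segmentation** — amplitude-gated scream detection with the field's
  two silence thresholds (gaps ≤ 0.03 s join vocal units, gaps ≥ 0.3 s
  separate screams), bout grouping on role/severity constancy, and event
  grouping on the 30 s / partner-change rule.
* **Features** — nine call-level parameters per scream (duration, peak
  frequency, coefficients of frequency variation and modulation,
  transition onset/offset, Q50, inter-quartile range, normalised Shannon
  entropy) plus algorithmic detectors for the four non-linear phenomena,
  and six bout-level parameters.
* **Permuted discriminant function analysis (pDFA)** — Fisher
  discriminants with jack-knifed classification/cross-validation,
  balanced and unbalanced crossed subset designs controlling a nuisance
  factor, and empirical p-values `p = (b + 1)/(m + 1)` from label
  permutations within control cells.
* **Mixed-effects inference** — REML models of each retained parameter
  on `role * severity` with caller and event random intercepts,
  Satterthwaite p-values, Wald 95% CIs, marginal/conditional R² by
  variance partition, joint Benjamini–Hochberg adjustment of the 36
  p-values, a binomial-logit GLMM for third-party support, outlier and
  influential-caller diagnostics, and Cohen's kappa for inter-observer
  reliability.

The core statistics in standard notation: the spectral entropy of a
normalised mean power spectrum `p` over `N` bins is
`H = −Σ pᵢ log pᵢ / log N` (white noise → 1, a pure tone → the leakage
floor of the analysis window, ≈ 0.16 at a 512-point Hann FFT); the pDFA
compares observed jack-knifed success to its permutation expectation;
BH adjusts `p₍ᵢ₎ → min over j ≥ i of m·p₍ⱼ₎/j`; kappa is
`(p_o − p_e)/(1 − p_e)`.

## Worked example

```r
library(screamr)

study <- simulate_study(study_config(seed = 1))
study
#> <scream_study: 374 screams, 119 bouts, 95 events, 26 callers, 95 event clips>

feats <- extract_features(study)

id_dfa <- pdfa(feats$call, test = "caller_id",
               features = c("duration", "peak_frequency",
                            "coef_freq_modulation", "transition_onset",
                            "transition_offset", "q50", "iqr", "entropy"),
               control = c("role", "severity"), mode = "unbalanced_crossed",
               n_resamples = 20, n_permutations = 200, seed = 2)
id_dfa
#> Permuted DFA of `caller_id` controlling role x severity (unbalanced_crossed design)
#>   26 classes, 374 samples; features: duration, peak_frequency, coef_freq_modulation, transition_onset, iqr
#>   classification:    observed  27.2%  expected  14.8%  p = 0.004975
#>   cross-validation:  observed  17.2%  expected   5.7%  p = 0.004975
#>   (20 resamples, 200 permutations, mean training share 48.9%)
```

Calls are individually distinctive: observed cross-validated assignment
of calls to their 26 callers (17.2%) is three times its permutation
expectation (5.7%), with an empirical p at the resolution limit of 200
permutations. The feature screen dropped Q50, entropy and
transition-offset as collinear (|r| > 0.80) with retained features.

```r
ledger <- run_all_models(feats$call, feats$bout)
subset(as.data.frame(ledger), p_adj < 0.05,
       select = c(response, level, effect, estimate, p_adj))
#>                response level   effect   estimate        p_adj
#>                duration  call     role  0.9222353 2.144942e-11
#>          peak_frequency  call     role  0.7649556 6.015765e-17
#>    coef_freq_modulation  call severity  0.3947651 1.694216e-02
#>                     q50  call     role  0.4373739 9.983103e-09
#>                     q50  call severity  1.5733575 1.460660e-65
#>                     iqr  call     role  0.1873952 1.749603e-02
#>                     iqr  call severity  1.8669591 1.850329e-64
#>                 entropy  call severity  1.5969572 2.228746e-52
#>               n_screams  bout     role -0.8153317 2.180678e-03
#>     avg_scream_duration  bout     role  1.1676736 7.115930e-08
#>                 pct_nlp  bout severity  0.8406600 1.694891e-03
```

The ground-truth effects built into the simulator come back with the
right signs after FDR control: victims scream longer (positive
duration × role estimate, on the transformed and scaled response) and at
higher frequency (Q50 × role), while severe conflicts are noisier
(entropy × severity) with more non-linear phenomena (pct_nlp ×
severity). The additional quartile/IQR × severity effects are the
acoustic consequence of the broadband-noise shift, not false positives.

```r
support <- fit_support_model(feats$bout[!duplicated(feats$bout$bout_id), ])
support
#> Mixed model (binomial) for `support` [transform: identity]
#>   N = 119 bouts from 26 individuals; R2m = 0.45, R2c = 0.47
#>         effect estimate    se   stat ci_lo   ci_hi        p
#>           role   -2.224 1.092 -2.038 -4.36 -0.0847 0.041594
#>       severity    2.665 0.802  3.322  1.09  4.2378 0.000895
#>  role:severity   -0.639 1.376 -0.464 -3.33  2.0577 0.642526
```

Victims are less likely than aggressors to receive third-party support
(negative role coefficient on the logit scale) and severe conflicts
attract more support — the simulator's configured 39.6% vs. 4.8% role
gap, recovered through the GLMM.

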