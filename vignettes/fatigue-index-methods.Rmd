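---
title: "Band-power ratio indices for driving fatigue: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power ratio indices for driving fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfatigue)
```

## The problem and the model

Sustained, monotonous driving produces a well-known drift in the scalp
EEG: slow-wave (theta, 4–8 Hz) activity rises while fast-wave activity
falls, with the beta band (12–25 Hz) declining most steeply. Ratio
indices built on band power amplify this signature. `eegfatigue`
implements the three standard ones on temporal-lobe EEG:

* `R_ab` = G&alpha; / G&beta;
* `R_t_ab` = G&theta; / (G&alpha; + G&beta;)
* `R_at_ab` = (G&alpha; + G&theta;) / (G&alpha; + G&beta;)

where G<sub>band</sub> is the *band-average power spectral density*:
the integral of the one-sided PSD over the band divided by its
bandwidth,

$$G_{band} = \frac{1}{b - a}\int_a^b P(f)\,df .$$

Because the bands have different widths (4, 4, 13 and 20 Hz), the
bandwidth division matters: a signal carrying *equal total power* in
the alpha and beta bands has `R_ab` = 13/4 = 3.25, not 1. This
closed-form value doubles as a test oracle for the whole spectral
stack.

All three indices rise as drivers tire; `R_ab` is the most sensitive of
the three and is the quantity tracked per minute in the scent
intervention analysis. For positive band powers the two theta-based
indices always differ by G&alpha;/(G&alpha;+G&beta;) &isin; (0, 1),
an identity the tests enforce.

## The analysis pipeline

`compute_index_series()` chains four stages, each exported on its own:

1. **High-pass filtering** (`highpass()`). A first-order digital IIR
   high-pass (bilinear-transformed RC stage, frequency-prewarped so the
   −3 dB point sits exactly at the 0.16 Hz cutoff) removes DC and slow
   drift. The filter is applied *forward only*: it models a causal
   analog front-end, so we deliberately do not use zero-phase two-pass
   filtering. At 10 Hz its gain is within 0.05% of unity, so the 4–45 Hz
   analysis bands are untouched.
2. **Temporal-channel aggregation** (`aggregate_temporal()`). The two
   temporal electrodes (default labels T7/T8) are averaged
   sample-by-sample into one derived channel. Averaging before or after
   the linear filter is mathematically identical; whether published
   band-activity figures are single-channel or channel-averaged is
   generally unstated, so the channel set is configurable and averaged
   by default.
3. **Epoching** (`epoch_recording()`). Non-overlapping, left-aligned
   60 s windows; a trailing partial window is dropped. The 2-min series
   reported by the identification study are means of two consecutive
   1-min values, not a re-epoching.
4. **Spectral estimation** (`periodogram()`, `band_average()`). The
   classical *direct method*: a single-segment, rectangular-window
   periodogram, scaled so that the rectangle-rule integral of the PSD
   over frequency equals the epoch's mean squared amplitude (Parseval,
   enforced to 10⁻⁶ in tests). No Welch averaging, no multitaper —
   deliberately, because the direct method is the procedure the
   analysis is defined on. A 60 s epoch gives a grid resolution of
   1/60 Hz, i.e. ≥ 200 grid points in even the narrowest band, so the
   rectangle rule is ample.

Band intervals are treated as half-open `[a, b)` so the shared edges
(8 Hz, 12 Hz) belong to exactly one band and the four bands partition
4–45 Hz without double counting.

## Statistical machinery

* `paired_t()` — classical paired t, df = n−1, two-sided; differences
  are reported **pre minus post**, so a score that rises over the drive
  yields a negative difference. Zero-variance differences are a
  degenerate-input error, not a silent NaN.
* `normality_p()` — Shapiro–Wilk on the paired differences, the
  standard small-sample screen.
* `one_way_anova()` — classical equal-variance between-groups F.
* `rm_anova()` — fully within-subjects two-way ANOVA
  (`aov` with `Error(subject/(treatment*time))`), requiring a complete
  balanced table (missing cells are an error; nothing is imputed). The
  headline F/p values are uncorrected; a Greenhouse–Geisser epsilon
  (computed from orthonormal effect contrasts) and the corrected
  p-value are reported as auxiliary columns, since sphericity is rarely
  credible for trajectories sampled minutes apart.

All tests are two-sided at &alpha; = 0.05. No multiplicity correction
is applied across the five post-release minutes, matching the study
design this package mirrors.

## The synthetic cohort generator

Real recordings of this kind are typically unavailable (participant
data are restricted), so the package ships a generator whose *defaults
are the study conditions* the analyses assume. Each channel is

$$x_c(t) = \sum_b a_b(t)\, m_b(t)\, s_b(t) + \varepsilon_c(t)$$

* `s_b` — zero-mean, unit-variance process exactly confined to band
  *b*: a sum of equal-amplitude, random-phase sinusoids on the DFT
  frequency grid of the record (spacing 1/duration ≈ 0.0006 Hz),
  synthesized by one inverse FFT. The DFT grid is used instead of a
  coarser fixed grid because it is denser, exactly orthogonal over the
  record (variance is exactly 1), and O(N log N).
* `a_b(t)` — the fatigue envelope, piecewise linear in minutes
  (`default_fatigue_envelopes()`): over 30 min theta rises ~10%, alpha
  falls ~5%, beta falls ~18% (the largest relative change), gamma falls
  ~15%, with a slower continuation to 45 min. Band power scales as the
  squared amplitude, so these slopes make the noise-free `R_ab` move
  from ≈1.13 at minute 5 to ≈1.43 at minute 29 — the published range
  for this kind of cohort.
* `m_b(t)` — the scent multiplier (`intervention_multiplier()`),
  identity before release and in the control condition. Scent effects
  are parameterized as a factor &rho;(u) on the `R_ab` scale (u =
  minutes since release) and realized as a beta boost with a mild alpha
  suppression (`a_alpha ∝ ρ^{1/8}`, `a_beta ∝ ρ^{−3/8}`), so the induced
  index trajectory equals &rho; exactly. Defaults: nadir at +2 min
  (grapefruit, ρ=0.68), +3 min (peppermint, ρ=0.65), +4 min (lavender,
  ρ=0.62); peppermint recovers fully by +7 min, grapefruit nearly by
  +12, lavender only to 0.72 by +15 — encoding "grapefruit acts
  fastest, lavender lasts longest".
* `ε` — white sensor noise, sd 0.2 by default, independent per channel
  (the two channels share the latent band processes).

Between-subject heterogeneity makes cohort statistics realistic: each
subject carries a fatigue-progression rate multiplier (sd 0.4) and,
per condition, a scent-response depth multiplier (sd 0.3), both
truncated to [0.2, 1.8] to keep amplitudes positive.

**KSS scores** follow a latent linear model: baseline + drift·(t −
ref) − drop·1[post-release, scented] + subject trait (sd 1.1) +
Gaussian noise (sd 0.8), rounded half-up and clipped to the ordinal
1–9 range. Per-condition baselines and drops reproduce the published
questionnaire means, including the anomalously low control baseline at
28 min (≈3 vs ≈5 in the scent conditions) — that asymmetry is in the
published table, and the generator mirrors it rather than explaining
it.

**What the generator does not emulate**: 1/f background, spectral
morphology, eye-blink or movement artifacts, inter-channel asymmetry,
non-Gaussian sensor noise, or any circadian structure. Passing tests
therefore demonstrate that the *analysis machinery* behaves correctly
on signals with the assumed band-power structure — not that the
pipeline is robust to real-world EEG artifacts.

Sampling defaults: 128 Hz (the nominal delivery rate of the consumer
14-channel headset class used for such studies; at least 90 Hz is
required to resolve the 45 Hz gamma edge), two channels labelled
T7/T8. Absolute amplitude units are arbitrary — only ratios are
calibrated — since published band activities come without units.

## Study pipelines

`run_identification_study()` (default cohort: 14 subjects, one 30-min
drive) compares each index at the epoch starting at minute 5 against
the final complete epoch (start minute 29; a 30-min recording has no
epoch *starting* at 30, so "the value at 30 min" is the last full
minute of the task). Both minutes are arguments. KSS is compared at
its two questionnaire times. Recordings too short for the comparison
are excluded with a warning; fewer than two usable subjects is an
error.

`run_intervention_study()` (default cohort: 11 subjects × 4
conditions, 45-min drives, release at minute 30, analysis window
capped at 40 min) produces the within-condition KSS tests (28 vs
40 min), the scent-vs-control 40-min contrasts — paired across
subjects, because every subject experienced every condition — the
one-way ANOVA across the scents' KSS improvements, the per-scent
`R_ab` baseline contrasts at minutes 32–40 against the single epoch
starting at minute 28, and the 3-treatment × 5-time repeated-measures
ANOVA.

`render_report()` writes the tables as CSV with 3-decimal floats;
printed difference cells are recomputed from the *printed* (rounded)
means, so every file is internally consistent after rounding.

```{r example}
cohort <- simulate_cohort("identification", n_subjects = 4, seed = 1,
                          duration_min = 8)
res <- run_identification_study(cohort, pre_min = 1, post_min = 7)
res$tests[, c("variable", "mean_pre", "mean_post", "diff", "t", "p")]
```

## Numerical choices and degenerate inputs

* Half-open band edges; rectangle-rule integration (matches the
  Parseval scaling exactly).
* Forward-only first-order IIR; zero initial state (the DC step
  transient decays with &tau; ≈ 1 s, negligible against 60 s epochs of
  ≥4 Hz content).
* `paired_t` on identical vectors returns t = 0, p = 1; any other
  zero-variance difference vector is an explicit error, as are
  constant inputs to the normality screen, empty bands after
  discretization, non-finite samples, sub-Nyquist sampling rates and
  incomplete RM-ANOVA tables.
* KSS rounding is half-up (floor(x + 0.5)), the questionnaire
  convention, not banker's rounding.
* All randomness flows through explicit integer seeds; identical
  (config, seed) pairs are bit-for-bit reproducible, and cohort
  generation derives per-subject sub-seeds from the master seed.

## Problem sizes used by the shipped checks

The package's own calibration checks run the identification design at
its full size (100 replicate cohorts of 14 subjects) and the
intervention design on 11 replicate cohorts of 11 subjects × 4
conditions, plus 2000-replicate null calibrations of the paired t —
together a few minutes on one CPU. Unit tests use reduced scenarios
(1–8 min records, 3–8 subjects) with the same code paths.

## Known limitations

* The generator's spectral world is four band-limited processes plus
  white noise; conclusions about artifact-laden field EEG require real
  data.
* The RM-ANOVA reports its own degrees of freedom; published F values
  from other software may use different (e.g. sphericity-corrected or
  between-within) layouts, so F/p values are comparable in pattern,
  not digit-for-digit.
* EDF import/export is out of scope here; recordings interchange as
  the documented CSV dialect (a time column plus one column per
  channel), and datasets as a YAML manifest.
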