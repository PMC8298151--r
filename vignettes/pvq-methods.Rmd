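---
title: "Methods: acoustic features, synthesis model, and design choices in pvq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic features, synthesis model, and design choices in pvq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pvq` estimates the perceived quality of sustained vowels — the
auditory-perceptual construct clinicians rate on a 0–100 visual-analogue
scale (VAS) — from acoustic measurements. This vignette documents the
science and the engineering choices: what each stage computes, which
constants matter and why they hold their default values, what the
synthetic data generator does and does not emulate, and where the design
was genuinely open.

## 1. Front end

Recordings are analysed as 2-second segments taken from the middle of the
vowel (`extract_central_segment`; the start index is `floor((N - L)/2)`,
biasing one sample left on odd remainders) and decimated to 16 kHz.
Extraction precedes decimation; for a steady vowel the order is
immaterial, and extracting first avoids resampling audio that is then
discarded.

Decimation (`decimate_to_16k`) is exact FFT-domain band-limited
resampling: the spectrum is truncated at 0.45 × 16 kHz = 7.2 kHz and
inverse-transformed at the new length, after trimming the input to a whole
number of `fs/gcd(fs, 16000)`-sample blocks (10 ms maximum loss at
44.1 kHz) so the rational rate ratio is exact. We first tried
`signal::resample`, whose polyphase FIR showed ≈0.7 dB passband ripple at
1 kHz — enough to perturb filterbank energies — whereas the FFT route is
transparent below 7 kHz to machine precision. Its trade-off, periodic edge
effects, is negligible for steady vowels.

## 2. Traditional perturbation measures

**Cycle tracking.** Frame-wise f0 (40 ms frames, 10 ms hop) comes from a
normalized cross-correlation of each frame against its own future, maximum
sought over lags `[fs/400, fs/60]` (the 60–400 Hz range covers both male
and female Parkinsonian voices). Two numerical points deserve emphasis:

* The correlation uses *full-frame overlap* — the second segment extends
  past the frame — rather than the truncated overlap of a within-frame
  autocorrelation. For pulse-train-like voice signals the truncated
  estimator is biased low, which propagates directly into HNR.
* Vowels are broadband, so the correlation peak is sharp on the sample
  grid and a 3-point parabola misplaces it. The raw correlation is
  band-limited in the lag, so we interpolate it *exactly* to 1/8-sample
  resolution by FFT zero-padding before refining the peak. A small octave
  penalty (0.02 per doubling of lag) breaks near-ties between the period
  and its subharmonics.
* DC is removed once, globally. Per-frame demeaning subtracts a quantity
  that depends on the partial glottal cycle inside the window, which
  decorrelates period-shifted segments and biases HNR several dB low.

Cycle anchors are then one waveform peak per estimated period; each
cycle-to-cycle period is refined to sub-sample precision by sinc
interpolation of the local waveform cross-correlation (±24 integer lags of
support — narrower support leaves visible truncation bias). Edge cycles
whose analysis windows would be clipped are dropped. Per-cycle amplitude
is the energy-equivalent peak `sqrt(2) ×` cycle RMS, with the energy
window starting 0.2 periods before the anchor so one whole glottal event
falls inside: raw waveform peaks of formant-filtered voices carry ringing
from neighbouring cycles, which we measured to inflate shimmer by ≈30%,
while the energy-based amplitude tracks the true per-cycle amplitude to a
few percent.

**Definitions.** Percent jitter is `100·mean(|T_i − T_{i−1}|)/mean(T)`;
shimmer is `mean(|20·log10(A_{i+1}/A_i)|)` in dB. HNR per frame is
`10·log10(r/(1 − r))` with `r` the refined correlation maximum, averaged
over voiced frames (threshold r > 0.45) and clamped to [−10, 40] dB — the
upper clamp keeps noiseless synthetic input finite. CPPS uses the power
cepstrum of the dB log-magnitude spectrum on 1024-sample frames at 2 ms
hop, moving-average smoothed over 10 frames then 10 quefrency bins (the
common smoothed-CPP convention), with the cepstral peak in the
`[1/400, 1/60]` s quefrency band measured against a least-squares line fit
from 1 ms to the top of the band. Smoothing happens in the linear
power-cepstrum domain; the peak-minus-trend difference is in dB, making
CPPS exactly invariant to amplitude scaling.

## 3. Filterbank, LP, modulation, and nonlinear features

**GFCC.** 256-sample Hamming frames with 100-sample overlap (hop 156 —
"overlap" read in its standard sense, recorded as a config constant so the
alternative reading, hop 100, is one edit). Frame power spectra are
weighted by 128 Gammatone magnitude responses (4th-order approximation
evaluated on the FFT grid, peak-normalized, ERB-spaced centers
50 Hz–8 kHz), log-compressed (floor 1e-10), and decorrelated by an
orthonormal DCT-II. Thirty coefficients (excluding c0, the frame energy,
per standard cepstral practice) plus thirty first-order frame differences,
averaged over frames, give the 60-feature vector; 30 statics + 30 deltas
is the unique symmetric split consistent with that total.

**LCQA.** 20 ms non-overlapping rectangular frames; an 18th-order LP model
per frame by the autocorrelation method and Levinson–Durbin. From the LP
spectrum on a 512-bin grid: spectral flatness (geometric/arithmetic mean
ratio), excitation variance (LP residual power), signal variance, spectral
centroid, and spectral dynamics (mean squared difference of consecutive
log LP spectra, assigned to the later frame), plus each descriptor's first
difference. Across frames we take mean, population variance, Fisher skew
and excess kurtosis → 40 features. Population moments were chosen because
the descriptor summaries feed a regression, not an inferential test; at
~100 frames the 1/n vs 1/(n−1) distinction is immaterial.

**SRMR.** 23 Gammatone channels, ERB-spaced 125 Hz to half the sampling
rate; per-channel temporal envelope as the analytic-signal magnitude
(frequency-domain Hilbert), resampled to 256 Hz so envelope content up to
128 Hz survives; eight overlapping 2nd-order modulation bandpasses (Q = 2)
with centers log-spaced 4–128 Hz; SRMR = energy in modulation bands 1–4
over bands 5–8 (denominator floored at 1e-10). **ModA.** Four octave
bands, 300–4800 Hz; envelopes normalized by band RMS — so the metric
reflects modulation *shape*, not loudness — lowpassed and downsampled to
20 Hz; 1/3-octave modulation centers `0.5·2^(k/3)` Hz up to 8 Hz (13
centers — the count follows from the stated spacing and range); area by
trapezoidal integration over log-frequency, averaged over bands. The
envelope spectrum is zero-padded to a fine grid before the band sums
because a 2-s envelope at 20 Hz has only 0.5 Hz native resolution.

**RPDE.** The unit-SD-normalized signal is embedded with dimension 4 and
delay 35 samples (2.2 ms at 16 kHz); for each reference point the first
return into a ball of radius 0.12 SD *after first leaving it*
(close-returns semantics — plain returns would pile trivial mass at T = 1)
is histogrammed over T = 1..1000; `H_norm` is the normalized Shannon
entropy of that distribution. The four parameters follow common RPDE
practice for voice and are config keys. Reference points are subsampled
(stride 2) only beyond 2 s of audio; this moves `H_norm` by well under
0.02 on test vowels. No recurrences yields `H_norm = 1` by convention. The
search loop is the package's only compiled code (Rcpp).

## 4. Synthetic vowels and the simulated rater panel

The generator (`synth_vowel`) drives a band-limited glottal pulse train —
windowed-sinc impulses at fractional sample positions, so sub-sample
period perturbations survive sampling — through two one-pole lowpasses at
f0 (−12 dB/octave source rolloff) and a cascade of three two-pole formant
resonators, default (700, 130), (1220, 170), (2600, 250) Hz: standard
male /a/ values. Per-cycle periods are `T0(1 + e_i)` with Gaussian `e_i`
*rescaled so the realized percent jitter equals the requested value*;
amplitudes are perturbed in dB the same way. Gaussian noise is passed
through the same formant filters and scaled so the realized
periodic-to-aperiodic power ratio equals the requested HNR exactly. Both
components are band-limited to 7.2 kHz and demeaned before mixing, so the
subsequent decimation changes neither the ratio nor the DC-free property
(real microphones are AC-coupled; a DC pedestal would masquerade as
harmonic power).

A cohort (`synth_cohort`) draws f0 from 100–220 Hz, jitter 0.1–2%, shimmer
0.1–1.5 dB, and HNR 5–30 dB, uniformly — spanning mild to severe
dysphonia. The rater panel (`synth_ratings`) maps ground-truth parameters
to a mean VAS via a monotone logistic,
`100·plogis(0.09·(HNR − 1.5) − 0.675·jitter − 0.5625·shimmer)`, then adds
per-rater bias (default −5, 0, +5 VAS) and Gaussian noise (SD 8 VAS) and
clips to [0, 100]. The map's coefficients were calibrated once so the
default cohort's consensus ratings have mean ≈ 55 and SD ≈ 18 VAS with a
span above 60 — the magnitudes a clinical VAS panel produces — and the
noise level yields an interrater consistency ICC near 0.93, i.e. "good"
reliability. The quality map is an explicit artifact of the generator: it
claims nothing about human listeners, and passing tests on synthetic data
shows the *pipeline* recovers known structure, not that the features
capture everything listeners hear. Real dysphonia also includes
subharmonics, diplophonia, tremor, onset/offset dynamics, and
room/microphone effects that the generator deliberately omits.

## 5. Modelling and evaluation

Splits are seeded permutations with `floor(0.2·m)` test rows (113 → 91/22).
Feature ranking uses |Pearson r| with ties broken by column order;
zero-variance columns rank last with r = 0. Monte Carlo selection draws a
subset per iteration (size uniform on 1..n; members sampled without
replacement with weight `n − rank + 1`) and scores it by OLS validation
MSE averaged over a *fixed, seeded pool of 40 inner splits* of the
training rows (validation fraction 0.25). The shared pool makes subset
scores directly comparable — with per-iteration splits the winner is
mostly sampling noise — and the pool size was set so that selection
agrees with exhaustive subset search on every tractable (n ≤ 6) test
instance. Selection, standardization, and PCA constants are always
estimated on training rows only and stored in the model; an assertion in
the repeated-split driver verifies no held-out id ever enters a fit. The
alternative reading of the selection procedure — scoring subsets on the
test partition — is classic leakage and was rejected; generalization is
the stated point of the repeated-split check.

PCA standardizes columns before the eigendecomposition (the feature
families differ by orders of magnitude in scale) and keeps the smallest
component count reaching 95% cumulative variance. LR is OLS with
intercept, with a tiny-ridge fallback (λ = 1e-6·n, warned) when m ≤ n.
SVR is ε-insensitive RBF regression via `e1071::svm` with C = 10, ε = 1
VAS unit, γ = 1/n — fixed constants, no tuning loop; predictions are
evaluated from the stored support vectors so a JSON-serialized model
reproduces them without refitting. Predicted scores are clipped to
[0, 100] only for reporting; correlations use unclipped values.

SDPE is σ̂ₛ·√(1 − ρ²) with σ̂ₛ the population (1/n) SD — at n = 91 the
1/n vs 1/(n−1) difference (<0.6%) is below the 2-decimal reporting grain.
Steiger's Z uses the Fisher-transform Z̄₁* form with the Pearson–Filon
covariance evaluated at the mean correlation — the most-cited variant.
ICC follows the McGraw–Wong two-way conventions: average-measures
consistency `(MS_R − MS_E)/MS_R` and average-measures agreement
`(MS_R − MS_E)/(MS_R + (MS_C − MS_E)/m)`, hand-coded on the ANOVA
decomposition.

## 6. Validation problem sizes

The test suite validates ground-truth recovery on single 2-s vowels (HNR
ladder {5, 10, 20, 30} dB with a clean source; jitter ladder
{0.25, 0.5, 1, 2}% at 35 dB HNR — studio-clean conditions chosen to
isolate the period-perturbation axis, since correlation-lag noise imposes
a jitter floor that scales with the noise amplitude; shimmer at 1 dB under
25 dB HNR), and the end-to-end ordering property on one 113-vowel cohort
with 20 repeated 80/20 splits. Selection-vs-exhaustive equivalence is
checked on 60-row instances with 4–6 features over 5 seeds. These sizes
were chosen as the smallest that exercise every code path with stable
statistics.

## 7. Known limitations

* The feature extractors are validated against the package's own synthetic
  ground truth, not against Praat or other toolboxes; absolute values of
  CPPS and RPDE depend on convention (window, smoothing, embedding
  parameters) and should be compared only within-pipeline.
* The jitter estimator has a noise floor (≈0.2% at 25 dB HNR) inherent to
  correlation-based period measurement; very mild jitter in noisy
  recordings is overestimated.
* The rater panel is a convenience model (logistic mean, additive Gaussian
  raters); it cannot test rater nonlinearities such as end-of-scale
  compression beyond clipping.
* SRMR and ModA are included for completeness of the feature inventory;
  on steady sustained vowels their informative variance is low, which the
  study grid makes visible rather than hides.
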