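---
title: "Camera-based respiration monitoring: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based respiration monitoring: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratresp)
```

## The measurement model

A rat's breathing expands and contracts its thorax and abdomen. In an
overhead video, the projected (top-down) area of the animal's body
therefore oscillates at the respiratory frequency. `ratresp` turns a
sequence of per-frame segmentation masks of the thorax/abdominal region
into an instantaneous respiratory rate (RR):

1. **Gate** frames on segmentation certainty: frames with score
   below `score_threshold` (default 0.99) are marked invalid.
2. **Track** the region per frame: pixel count (area), center of mass
   (COM), and tight bounding box.
3. **Fill gaps**: invalid runs no longer than `gap_max_s` (default 0.5 s)
   are linearly interpolated; longer dropouts split the recording into
   independently analysed segments, because interpolating across more
   than a breath cycle would fabricate breaths.
4. **Denoise** the area signal by projecting out a noise subspace built
   from body motion.
5. **Band-pass** with a second-order Butterworth filter over the
   physiological band 1–3.3 Hz (60–198 breaths/min), applied zero-phase.
6. **Clip gradients** of the variance-normalized signal at 1.5 units
   per sample to suppress residual step artifacts.
7. **Detect breath peaks** with a zero-crossing scheme and convert each
   peak-to-peak interval $d_\mathrm{peak}$ to an instantaneous rate
   $f_\mathrm{RR} = 60 / d_\mathrm{peak}$ breaths/min.

An ECG-derived respiration (EDR) branch provides a reference: R-peak
amplitudes are modulated by breathing, so the series of R-peak heights,
resampled and band-passed over the same respiratory band, yields an
independent RR estimate from a simultaneously recorded ECG.

## Noise-subspace projection

Locomotion moves the animal across the lens's field, and perspective or
illumination changes then perturb the measured area at frequencies that
can overlap the breathing band, so a band-pass alone cannot remove them.
The key observation is that these disturbances are *correlated with
body motion*, which we can measure directly from the same masks.

Let $r \in \mathbb{R}^n$ be the linearly detrended area signal of one
segment and $Q \in \mathbb{R}^{n\times 4}$ the noise-regressor matrix
whose columns are the detrended COM $x$ and $y$ trajectories and their
first differences (velocities). The denoised signal is the residual of
the least-squares projection onto the column space of $Q$:

$$ z = r - Q\,(Q^\top Q)^{-1} Q^\top r . $$

`denoise_projection()` computes this via the SVD of $Q$
($z = r - U_r U_r^\top r$ with $U_r$ the left singular vectors of
numerically nonzero singular value), which tolerates rank-deficient
regressors — e.g. a perfectly stationary animal, where COM columns are
constant and detrend to zero. The residual is exactly orthogonal to the
regressors (verified to ~1e-16 relative in the tests), so any area
fluctuation expressible as a linear function of body position or
velocity is removed, while breathing — which moves area without moving
the COM in the synthetic model, and is only weakly COM-correlated in
practice — passes through.

Columns of $Q$ are detrended for the same reason $r$ is: a linear trend
in position would otherwise make the projection absorb slow area drift
into the position coefficients, and the subsequent band-pass already
owns everything below 1 Hz.

## Parameter choices

| Parameter | Default | Rationale |
|---|---|---|
| `score_threshold` | 0.99 | Segmentation certainty gate; strict `>` comparison, so exactly-0.99 frames are rejected. Resting RR extraction needs near-perfect masks; discarding frames is cheap at 60 FPS. |
| `band_low_hz`, `band_high_hz` | 1, 3.3 | 60–198 breaths/min covers resting-to-elevated rat RR; anything slower is drift/posture, anything faster is sniffing or noise. |
| `butter_order` | 2 | Second-order Butterworth per pass; `filtfilt` squares the magnitude response, giving gain exactly 0.5 at each band edge ($1/\sqrt 2$ per pass) and zero phase distortion, which matters because peak *timing* is the measurand. |
| `clip_limit` | 1.5 | Gradient clip threshold in units/sample, applied to the variance-normalized signal (see below). |
| `gap_max_s` | 0.5 | Interpolation limit: half a second is at most ~1.6 breath cycles at the band's low edge, short enough that linear interpolation cannot invent a breath. |
| `outlier_frac` | 0.3 | A peak interval shorter than 0.3× the median interval indicates a double-detected breath; the lower-amplitude member of the pair is dropped, iteratively. |
| `ecg_smoothwindow_s` | 0.05 | Moving-average width over the absolute ECG gradient; roughly the rat QRS footprint, so one QRS produces one smooth bump. |
| `ecg_avgwindow_s` | 0.1875 | Window for the adaptive threshold baseline; ~1.1 inter-beat intervals at 360 bpm, so the baseline tracks local signal level without following individual beats. |
| `ecg_gradthresh_weight` | 1.5 | A gradient region counts as QRS when the smoothed gradient exceeds 1.5× its local moving average. |
| `ecg_min_delay_s` | 0.1 | Peaks closer than 0.1 s are merged (larger amplitude kept); at ≤420 bpm true beats are ≥0.14 s apart. |
| `ecg_min_qrs` | 0.1 | *Relative* minimum region length: regions shorter than 0.1× the mean detected region length are discarded as noise spikes (see design decisions). |
| `edr_rate_out` | 20 Hz | Resampling rate for the R-peak amplitude series; ≥6× the 3.3 Hz band ceiling. |
| `edr_lowpass_hz` | 4 | Anti-alias/smoothing low-pass on the EDR series, just above the respiratory band. |

## The synthetic generator: realism and limits

`generate_breathing_masks()` rasterizes an ellipse (aspect ratio 2,
mimicking an elongated rodent body seen from above) whose area follows

$$ A(t) = \bar A\,\bigl(1 + a \sin(2\pi f_\mathrm{RR} t)\bigr) + \varepsilon_t, $$

with default modulation depth $a = 0.05$ (a few percent of projected
area per breath, the right order for a resting rat) and Gaussian area
noise. The center drifts sinusoidally at 0.1 Hz (slow locomotion) and
optional step artifacts displace the center by `artifact_shift` pixels
with alternating sign at chosen times (abrupt posture shifts). Pixel
rasterization uses the pixel-center convention, so the realized mask
area quantizes the analytic target; the returned truth table carries
both the analytic series and per-frame realized values.

What the generator deliberately does **not** model: non-elliptical
body shapes, occlusion, fur texture, illumination changes, or
respiration-locked COM motion. Its purpose is to provide *exact ground
truth* for the signal chain — area modulation in, RR out — not to fool
a segmenter. Consequently segmentation quality is exercised separately,
via `segment_threshold()` on synthetic intensity frames and IoU
evaluation against polygon annotations.

`generate_rat_ecg()` places biphasic QRS complexes (Gaussian R wave,
σ = 4 ms, plus an inverted 0.3-scaled S deflection 8 ms later) at beat
times $(k + 1/2)\,60/\mathrm{HR}$ with amplitudes modulated as
$1 + d\,\sin(2\pi f_\mathrm{resp} t_k)$, and adds 50 Hz powerline and
white noise. Beat times are kept continuous (not snapped to the sample
grid) so truth timestamps are unbiased; the waveform therefore repeats
exactly only when the inter-beat interval times the sampling rate is
rational (e.g. every 3 beats at 360 bpm / 1 kHz). P and T waves are
omitted: the R-peak detector keys on gradient steepness, for which the
narrow QRS dominates, and the EDR branch uses only R amplitudes.

## Numerical and design decisions

**Gradient clipping operates on the variance-normalized signal.** The
clip threshold (1.5 units/sample) is meaningful only on a signal of
unit scale: a raw band-passed area signal has slopes of tens of
pixels²/frame even for perfect breathing, and clipping it raw destroys
the waveform. The pipeline therefore divides the band-passed segment by
its standard deviation before clipping. Peak detection is
scale-invariant, so this changes nothing downstream except restoring
the clip's intended role: flattening residual step transients whose
normalized slope far exceeds that of any sinusoid in the 1–3.3 Hz band
(a unit-variance 3.3 Hz sine at 60 FPS has maximum slope
$\sqrt 2\,2\pi\,3.3/60 \approx 0.49$ per sample, comfortably below 1.5).
Clipped samples are replaced by linear interpolation across the flagged
region (both endpoints of an offending difference are flagged).

**`ecg_min_qrs` is a fraction, not seconds.** An absolute minimum QRS
region length of 0.1 s would discard *every* rat beat: at 300–420 bpm
the whole cardiac cycle is 0.14–0.2 s and the gradient region of one
QRS lasts ~0.03 s. Interpreting the parameter as a fraction of the mean
detected region length preserves its purpose — rejecting isolated noise
spikes much narrower than real QRS regions — at any heart rate.

**QRS-path band-limiting at 150 Hz.** Differentiation amplifies noise
power as $f^2$, so broadband noise can lift the adaptive threshold
above the gradient bumps of low-amplitude (respiration-attenuated)
beats. `preprocess_ecg()` therefore applies a zero-phase second-order
low-pass at 150 Hz — well above the ~40 Hz bandwidth of the σ = 4 ms
rat R wave, so QRS morphology and timing are preserved — before the
gradient is computed. This is standard practice in gradient-based QRS
detection and is skipped automatically when the sampling rate cannot
support it.

**The 4 Hz low-pass belongs on the EDR path, not before R-peak
detection.** A 4 Hz low-pass ahead of peak detection would erase the
rat QRS entirely (the cardiac fundamental alone is 5–7 Hz at 300–420
bpm). It is applied to the *resampled R-amplitude series*, where it is
coherent with the 3.3 Hz respiratory ceiling, before the final 1–3.3 Hz
band-pass.

**EDR sampling-rate guard.** The R-peak series samples respiration at
the heart rate, so extraction errors out when the beat rate falls below
twice the band's *lower* edge (the signal is then unobservable in the
band at all) and warns below twice the *upper* edge (rates near the
ceiling are aliased). At typical rat rates (≥300 bpm = 5 Hz vs. a 3.3 Hz
ceiling) the warning fires but the dominant resting RR (~1.5 Hz) is
well sampled.

**Empty-mask IoU is 0, not NaN.** `iou()` returns 0 when the union is
empty. For evaluation against annotations, a frame where prediction and
truth are both empty carries no evidence of agreement on the object of
interest; scoring it 1 would inflate averages on sparse recordings.

**Standard deviation convention.** All SDs use R's `sd()`, i.e. the
$n-1$ (sample) denominator, including the variance normalization before
clipping and the study-level EDR spread.

**Study aggregation.** Per-recording relative error is
$100\,|\mathrm{RR}_\mathrm{cam} - \mathrm{RR}_\mathrm{EDR}| /
\mathrm{RR}_\mathrm{EDR}$ (EDR is the reference and must be positive);
study means are unweighted across recordings. IoU aggregation across
animals is weighted by annotation count (`weighted_mean_by_count()`),
so animals with more annotated frames contribute proportionally.

## Problem sizes used in validation

The test suite and the acceptance script run the camera branch on
30-second, 60 FPS recordings (1800 frames, 120×160 px) at 70, 96, 150
and 190 breaths/min with area noise, drift and two step artifacts; all
four rates are recovered within 0.25 breaths/min. Frame bookkeeping is
checked on a 5-minute recording (18,000 frames at reduced resolution).
The ECG branch runs 60 s at 1 kHz, 360 bpm, 30 % amplitude modulation,
powerline and white noise: R-peak recall is 1.0 against ground-truth
beat times (20 ms tolerance) and the EDR rate lands within 0.2
breaths/min of the true 96.

```{r example}
gen <- generate_breathing_masks(blob_spec(
  duration_s = 30, fps = 60, rr_true = 96, noise_sd = 20,
  artifact_times = c(10, 20), seed = 42L))
out <- extract_rr_from_masks(gen$masks)
c(mean_rr = out$mean_rr, n_breaths = out$n_breaths,
  coverage = out$coverage_fraction)
```
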