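---
title: "Non-contact SCG and HRV from FMCW radar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-contact SCG and HRV from FMCW radar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarscg)
```

## The measurement problem

A frequency-modulated continuous-wave (FMCW) radar watching a supine subject
receives echoes whose beat (intermediate-frequency, IF) tone encodes the
target's range and whose phase encodes sub-wavelength motion of the chest
wall. At a 77 GHz carrier the wavelength is about 4 mm, so the phase of the
IF signal changes by

$$\Delta\varphi = \frac{4\pi}{\lambda}\,\Delta R$$

per chest displacement $\Delta R$ — about 0.314 rad for 0.1 mm. Respiration
moves the chest by 3–12 mm at 0.1–0.5 Hz; the mechanical recoil of the
heart (the seismocardiogram, SCG) moves it by only 0.1–0.5 mm per beat.
`radarscg` recovers the SCG from multi-antenna IF data, detects the
aortic-opening (AO) fiducial on every beat, and computes time-domain heart
rate variability (HRV) from the resulting inter-beat intervals (IBIs).

Because no public raw-data accession exists for this kind of recording, the
package ships a physics-based scene simulator whose ground truth (per-beat
AO times, the exact displacement trace, the heart azimuth) makes every stage
testable end to end.

## The simulator and what it does (and does not) emulate

`scene_config()` describes two moving scatterers at the same range
(default 0.6 m, the usual mounting height above a bed): a torso scatterer
dominated by respiration, and a heart scatterer at its own azimuth carrying
the cardiac micro-motion plus an attenuated respiration share (default 20%).
Respiration is a sinusoid with 10% second- and 5% third-harmonic content, so
the third harmonic genuinely overlaps the conventional 0.7–3 Hz heartbeat
band — the separation problem the wavelet-packet stage exists to solve.
Static clutter scatterers and complex white noise (SNR defined at the
target's range bin after the range FFT, relative to the heart scatterer)
complete the scene.

The cardiac kernel is a fixed analytic SCG morphology: a sum of Gaussian
lobes placing the canonical fiducials in order (AS, MC, the deep IM trough,
the dominant AO peak, the IC trough, the RE rebound, a shallow tail) over a
0.32 s support. The AO lobe peaks 115 ms after kernel onset; that instant is
the recorded ground truth. Inter-beat intervals are drawn from a Gaussian
model (default mean 1.0 s, SD 50 ms, optional lag-1 autocorrelation),
clamped to the physiological 0.4–2 s range.

The IF cube renderer implements the narrowband FMCW model: each scatterer
contributes a fast-time tone at $f_{IF} = 2\,\mathrm{slope}\,R_t/c$ with
phase $4\pi R_t/\lambda$, and virtual antenna $m$ adds
$\exp(-j 2\pi m (d/\lambda)\sin\theta)$. Chirp defaults follow a 77 GHz
radar configured for vital signs (60 MHz/µs slope, 60 µs ramp, 5 Msps ADC,
5 ms frame period — a 200 Hz slow-time rate — and a TDM 2T4R pair acting as
an ideal 8-element virtual array at $\lambda/2$).

Deliberately not modeled: electromagnetic scattering realism (RCS,
multipath), TDM phase migration, antenna coupling, body-surface extension,
posture changes, and multiple subjects. Passing tests therefore demonstrate
the correctness of the processing chain under the stated displacement
physics, not robustness to every artifact of real recordings.

## Range processing

`range_fft()` applies a windowless fast-time DFT (Hann optional) and keeps
the unambiguous positive-range half of the spectrum. `remove_static_clutter()`
subtracts each range bin's slow-time mean. `select_target_bin()` picks one
global bin maximizing total post-clutter-removal energy over frames and
antennas — a deliberate replacement for a per-frame argmax, which can
jitter between bins and corrupt the spatial covariance; a single range gate
is what the snapshot model requires.

One subtlety matters downstream: the mean subtracted from a bin whose phasor
swings over only part of a cycle is the chord centroid of an arc, not the
arc's centre. Removing it is right for clutter suppression and covariance
estimation but wrong for phase demodulation, which needs the true rotation
centre — in experiments, demodulating mean-removed sequences produced
36–42% displacement error versus 0.5% with the mean restored. The snapshot
object therefore carries both versions: the clutter-removed `X` feeds the
beamformer and its covariance, while the mean-restored `X_raw` at the same
gate feeds demodulation. Static returns from other azimuths are rejected
spatially by the beamformer; `dc_compensate()` (sliding 5 s complex mean)
remains for clutter co-located in both range and angle.

## Capon beamforming and the SQI azimuth search

The spatial covariance is the snapshot average
$R = \frac{1}{N}\sum_i X_i X_i^H$ plus diagonal loading
$\delta \cdot \mathrm{tr}(R)/M \cdot I$. The loading default is
$\delta = 0.1$ — robust-Capon territory rather than the numerical token
(1e-3) often quoted. The reason is specific to this application: the source
of interest is itself the strongest component of the training data, and its
true azimuth almost never falls exactly on the 1° search grid. Lightly
loaded MVDR treats a slightly mismatched strong source as interference and
cancels it (textbook self-nulling), which turns the search profile into
noise: in 12-draw experiments the ±2° recovery rate was 7/12 at
$\delta=10^{-3}$, 9/12 at $10^{-2}$, and 12/12 at $\delta \ge 0.1$, with no
loss of interferer rejection at the power ratios of this problem (a torso
9× stronger in power is still suppressed well below the heart signal).

The cardiac direction is found not at the spatial-spectrum peak (which
follows the strongest reflector — usually the torso) but by the
signal-quality search: for each of 121 angles in $[-60°, 60°]$, Capon
weights are computed from one covariance estimated on the first 20 s,
beamformed output is demodulated, SCG-band reconstructed, z-normalized, and
scored against a template with $SQI = 1/(DTW + 10^{-12})$. The angle with
maximum SQI wins (ties broken toward broadside), and its weights are frozen
for the rest of the record.

Design choices in this stage:

* **DTW form.** Classic dynamic programming, absolute-difference local
  cost, symmetric steps, no global band; path-length normalization is
  available behind a flag. An exhaustive-table oracle pins the
  implementation in tests.
* **Template.** A 20 s clean kernel train at 60 bpm, passed through the same
  wavelet-packet band reconstruction as the candidates and z-normalized.
  Users can substitute a recorded template from CSV.
* **Decimation before DTW.** Candidates and template are decimated to 50 Hz
  before scoring. The SCG band ends at 18.75 Hz, so decimation from 200 Hz
  is alias-free, and it cuts the quadratic DTW cost 16-fold (the full
  121-angle search runs in a few seconds). `sqi_fs_hz` disables it.
* **z-normalization** uses the population standard deviation, fixing the
  printed convention `znormalize(c(1,2,3)) = (-1.2247, 0, 1.2247)`.

## Phase demodulation

`mdacm_demodulate()` accumulates differentiate-and-cross-multiply
increments recovered from the cross- and dot-products of consecutive
samples,

$$\Delta\varphi_k = \operatorname{atan2}\!\big(I_{k-1}Q_k - Q_{k-1}I_k,\;
I_{k-1}I_k + Q_{k-1}Q_k\big),
\qquad \varphi[n] = \sum_{k=1}^n \Delta\varphi_k,$$

which tracks total phase without explicit unwrapping and recovers each
step exactly for step sizes below $\pi$. The exactness matters: the
common first-order variant that divides the cross product by $|Y_k|^2$
approximates the increment by $\sin(\Delta\varphi_k)\,|Y_{k-1}|/|Y_k|$,
and on harmonic-rich respiration both the cubic $\sin$ bias and the
envelope-ratio factor have non-zero mean — they rectify into a slow phase
drift that was measured at ~0.9 rad over 60 s (2% of the displacement
RMS, enough to dominate the round-trip error budget). With the exact
form, the demodulated displacement of a noise-free single-scatterer cube
matches the ground-truth trace to ~0.5%, the residual being the
beat-phase gain term of the finite ADC window that the narrowband
$4\pi\Delta R/\lambda$ relation neglects. The first sample is defined as
zero phase; constant offsets are irrelevant downstream because the
wavelet-packet stage discards the DC leaf.

## Wavelet-packet SCG extraction

A full six-level wavelet packet tree with the db45 wavelet (45 vanishing
moments, 90 taps) splits the 0–100 Hz band into 64 uniform leaves of
1.5625 Hz; leaf $i$, in frequency (sequency) order, spans
$((i-1)\,f_s/2^7,\; i\,f_s/2^7)$ Hz. Respiration and its harmonics live in
leaf 1 (0–1.5625 Hz) and its neighbors; the SCG is reconstructed from
leaves 6–12 (7.8125–18.750 Hz). The long db45 filter makes the leaf edges
steep, which is exactly why it is worth its cost here; the filter
coefficients are the standard published constants, computed once by
200-digit spectral factorization of the Daubechies half-band polynomial and
frozen in source (the construction reproduces shorter published filters to
the last bit).

The transform uses periodized filtering, implemented as an explicitly
orthogonal map (synthesis is the transpose of analysis), so perfect
reconstruction and Parseval hold to round-off for any input length —
signals are zero-padded to a multiple of $2^6$ and truncated back after
inversion. Frequency ordering follows the Gray-code child rule (children of
an even-index node keep low→low ordering; children of an odd-index node
swap), and a property test verifies that each leaf's white-noise
reconstruction has its spectral centroid inside its mapped band.
Inputs shorter than 10 s at 200 Hz trigger a warning: with 90-tap filters
the circular wrap-around becomes material on very short windows.

`bpf_baseline()` provides the conventional alternative (order-4 zero-phase
Butterworth, default 0.7–3 Hz) for comparison studies.

## AO detection

The detector segments cardiac cycles with the Hilbert envelope pair
(signal mean ± magnitude of the analytic signal of the mean-removed SCG),
finds envelope peaks and troughs with a 0.6 s minimum spacing, pairs them
positionally, and discards pairs whose positions differ by at least
0.15 · fs samples. In a ±0.1 s window around each trough it locates the
deepest minimum (IM), masks its neighborhood, locates the second minimum
(IC), and returns the SCG maximum strictly between them as the AO point.

Two implementation decisions deserve explanation:

* **Mask radius.** Masking only the argmin sample cannot find the second
  *local* minimum of a band-limited signal sampled at 200 Hz: the immediate
  neighbor of the deepest sample is almost always the second-deepest value,
  which would make IM and IC adjacent in virtually every cycle. The default
  mask covers ±25 ms — below the physiological IM–IC separation (~70 ms)
  and above the sampling quantization — so the second search lands on the
  IC trough. `mask_radius_s = 0` restores literal single-sample masking.
* **Mirror envelopes.** With the analytic-envelope pair, upper-envelope
  peaks and lower-envelope troughs coincide exactly, so the
  misalignment-discard rule can fire only through count desynchronization
  or window clipping; the discard counter is exercised by edge-clipped
  cycles in tests. The detector is amplitude-invariant by construction,
  which also means it will report envelope structure in pure noise — a
  record with no cardiac content yields pseudo-events, not an empty set;
  quality gating is the SQI stage's job, not the detector's.

IBIs are successive AO-time differences with an inclusive 400–2000 ms
validity filter; the filter exists because every discarded cycle would
otherwise inject a double-length interval.

## HRV metrics and agreement

`hrv_metrics()` implements the printed estimator forms: SDNN with the
population (1/N) denominator, RMSSD with $1/(N-1)$ over the $N-1$
successive differences, and pNN50 as the percentage of successive
differences strictly exceeding 50 ms with denominator $N$. The sample-SDNN
and $N-1$ pNN50 conventions are options; the two SDNN forms differ by
exactly $\sqrt{N/(N-1)}$, which a regression test pins.
`compare_to_reference()` matches detected AO times to reference beats
(nearest-neighbor within 0.5 s, one-to-one), forms intervals only between
consecutively matched beats (so a missed beat cannot fabricate a double
interval), and reports MAE, MRE, RMSE, Bland–Altman bias with 1.96·SD
limits of agreement, and absolute metric errors.

## Numerical and testing choices

* Problem sizes: tests and the acceptance study use 32–64 fast-time samples
  per chirp (the chirp table of the emulated device does not pin the ADC
  count; the package default is 128). This coarsens range bins but leaves
  slow-time phase — the quantity of interest — untouched.
* The azimuth-recovery study draws 50 scenes with the heart azimuth uniform
  in ±40° and bin SNR uniform in 10–20 dB; the end-to-end HRV study uses
  five 600 s scenes at 20 dB with SD-50 ms Gaussian IBIs. On one CPU the
  full suite runs in roughly a quarter hour.
* The displacement round-trip check uses a single-scatterer scene. With a
  separate torso scatterer the torso and heart motions are *coherent* (both
  driven by the same respiration), and no linear beamformer can null a
  source coherent with the signal perfectly; about 4% amplitude leakage
  (≈15% displacement RMSE) remains. This is a physical property of
  coherent-source MVDR, and it does not propagate to the SCG/HRV chain,
  whose band excludes respiration (measured SDNN error under 0.5 ms on
  torso-present scenes).
* Determinism: a master scene seed feeds separate sub-streams for beat
  times and noise; identical (scene, chirp, seed) triples produce
  bit-identical cubes.

## Known limitations

The simulator's beat kernel is one fixed morphology; detector performance
on pathological or highly variable SCG shapes is untested. The azimuth
search assumes the subject's heart lies within ±60° of boresight on the
scan axis. Real TDM arrays add phase-migration errors that the ideal
virtual array omits. The 2.4% displacement bias of very coarse range
binning (beat-phase term of the finite ADC window) is visible in the
phase-linearity checks but negligible against the SCG band content.
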