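# radarscg

Non-contact seismocardiography and heart-rate-variability analysis from
frequency-modulated continuous-wave (FMCW) radar, for researchers in
radar-based vital-sign sensing who need a fully testable processing chain
without access to radar hardware or clinical recordings.

A 77 GHz FMCW radar pointed at a supine subject measures chest-wall motion
through the phase of its intermediate-frequency (IF) signal:
`delta_phi = (4 * pi / lambda) * delta_R`, about 0.314 rad per 0.1 mm at a
4 mm wavelength. Respiration (3–12 mm) dominates the raw phase; the
seismocardiogram (SCG) — the 0.1–0.5 mm mechanical recoil of each heartbeat
— must be isolated from it. The package implements the full chain:

1. **Scene simulation** — torso + heart scatterers with configurable
   respiration, an analytic multi-lobe SCG beat kernel with known
   aortic-opening (AO) times, Gaussian inter-beat-interval (IBI) models,
   clutter, and noise, rendered into multi-antenna IF data cubes under the
   narrowband FMCW model.
2. **Range processing** — fast-time FFT, static clutter removal (slow-time
   mean subtraction), selection of the target range gate.
3. **Cardiac beamforming** — Capon/MVDR weights over the 8-element virtual
   uniform linear array, with the heart azimuth found by exhaustively
   scanning [−60°, 60°] in 1° steps and maximizing a signal-quality index
   `SQI = 1 / DTW(SCG, template)` (dynamic time warping against a clean SCG
   template), rather than the classical spatial-spectrum peak, which tracks
   the strongest reflector instead of the heart.
4. **Phase demodulation** — differentiate-and-cross-multiply (DACM)
   accumulation, unwrapping-free.
5. **SCG extraction** — six-level db45 wavelet-packet decomposition;
   frequency-ordered leaves 6–12 (7.8125–18.750 Hz at 200 Hz sampling) are
   reconstructed as the SCG. A 0.7–3 Hz Butterworth band-pass baseline is
   included for comparison.
6. **AO detection and HRV** — Hilbert-envelope cycle segmentation, an
   IM/IC neighborhood search for the AO peak of every beat, IBI validity
   filtering (400–2000 ms), and SDNN / RMSSD / pNN50 with Bland–Altman
   agreement reports against reference beat times.

## Worked example

Simulate two minutes of a subject whose heart sits 10° off boresight with a
stronger respiring torso at +15°, then run the full pipeline:

```r
library(radarscg)

chirp <- chirp_config(n_fast_samples = 32L)   # 77 GHz, 200 Hz slow time
scene <- scene_config(duration_s = 120, snr_db = 20, seed = 3)

res <- run_pipeline(scene, pipeline_config(chirp = chirp))
print(res)
#> Radar SCG/HRV pipeline result
#>   frozen azimuth -10 deg at range 0.78 m (bin 3)
#>   120 AO events, 119/119 valid IBIs
#> HRV (n = 119): SDNN 50.62 ms, RMSSD 68.67 ms, pNN50 40.34%
#>   vs ground truth: IBI MAE 1.87 ms, MRE 0.186%

hrv_metrics(ibi_from_events(res$truth$ao_times_s))   # simulated reference
#> HRV (n = 119): SDNN 50.31 ms, RMSSD 68.29 ms, pNN50 41.18%
```

The search froze the beamformer at the true −10° azimuth; all 120
simulated beats were detected, beat timing is accurate to ~2 ms on average,
and the three HRV metrics agree with the simulated IBI sequence's own
values to 0.3 ms (SDNN), 0.4 ms (RMSSD) and 0.8 percentage points (pNN50).

Every stage is also callable on its own (`range_fft()`,
`select_target_bin()`, `search_heart_azimuth()`, `mdacm_demodulate()`,
`wpt_decompose()` / `reconstruct_scg()`, `detect_ao()`, `hrv_metrics()`,
`compare_to_reference()`), and a thin command-line front end lives at
`inst/cli/radarscg.R` (`simulate`, `run`, `extract-scg`, `detect-ao`,
`hrv`, `compare`). IF cubes interchange as little-endian complex64 binaries
with a JSON sidecar; signals and events as CSV; reports as JSON.

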