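Package: radarscg
Title: Non-Contact Seismocardiography and Heart Rate Variability from FMCW Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-antenna frequency-modulated continuous-wave (FMCW)
    radar returns from a breathing, beating chest and recovers the
    seismocardiogram (SCG) and time-domain heart rate variability (HRV) from
    them. The processing chain covers range FFT and static clutter removal,
    Capon (MVDR) beamforming over an 8-element virtual uniform linear array
    with a cardiac azimuth search driven by a dynamic-time-warping signal
    quality index, differentiate-and-cross-multiply (DACM) phase demodulation,
    wavelet packet band reconstruction of the SCG, aortic-opening (AO)
    fiducial detection, and SDNN/RMSSD/pNN50 inter-beat-interval statistics.
    A physics-based scene simulator with known per-beat ground truth stands in
    for radar hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
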