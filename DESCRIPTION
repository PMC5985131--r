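Package: fetalica
Title: Fetal ECG Extraction from Abdominal Recordings by Overrelaxed FastICA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Noninvasive fetal electrocardiogram extraction from multichannel
    maternal abdominal recordings. Implements deflationary fixed-point
    independent component analysis with a cubic negentropy contrast, both in
    its conventional form and with an overrelaxation factor incorporated into
    the approximated Newton iteration to reduce sensitivity to the random
    initial weight vector. The surrounding pipeline covers Butterworth
    baseline-wander removal, PCA whitening, maternal component selection,
    Pan-Tompkins QRS detection, and SVD template cancellation of maternal
    beats, together with eigenvalue- and cross-correlation-based
    signal-to-noise ratios, beat-detection statistics (sensitivity, positive
    predictive accuracy, F1), the Amari separation index, a seeded synthetic
    abdominal-ECG simulator with ground truth, and CSV/EDF/WFDB readers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
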