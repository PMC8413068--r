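Package: StressVMD
Title: Stress Classification from Multichannel EEG/ECG via Variational
    Mode Decomposition and Poincare Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decomposes multichannel physiological recordings (EEG plus
    ECG, European Data Format) into band-limited intrinsic modes by
    variational mode decomposition, derives second-order difference
    Poincare plots per mode, extracts three dispersion descriptors
    (fitted-ellipse area, mean radial distance, central tendency
    measure), screens them with the Wilcoxon signed-rank test, and
    classifies stressed versus non-stressed task performers per
    brain-region channel group with a multilayer perceptron and a
    support vector machine under percentage-split and k-fold protocols.
    Includes a synthetic-data generator emulating the layout of public
    mental-arithmetic recordings so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
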