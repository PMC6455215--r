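Package: gssemg
Title: Guided Source Separation for High-Density Surface EMG Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Non-invasive decoding of motoneuron firing trains from
    high-density surface electromyograms (HD-sEMG) by guided source
    separation: density-based (OPTICS) clustering of active sEMG segments
    provides deterministic initial points for a gradient Convolution
    Kernel Compensation (gCKC) decomposition, accelerated by an
    expectation-maximization Kalman filter and refined with adaptive
    soft-thresholding of the estimated spike trains. Includes a
    parametric HD-sEMG simulator with known motor-unit firing patterns,
    physiological exclusion rules, duplicate-unit removal, and the
    standard validation metrics (rate of agreement, sensitivity,
    precision, pulse-to-noise ratio, signal-to-interference ratio,
    decomposability index) together with a benchmark harness over
    excitation level and signal-to-noise ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
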