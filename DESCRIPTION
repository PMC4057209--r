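Package: dcar
Title: Transfer Function Analysis of Dynamic Cerebral Autoregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying dynamic cerebral autoregulation from paired
    recordings of mean arterial blood pressure (MAP) and transcranial Doppler
    middle cerebral artery blood flow velocity (MCAv). Implements Welch
    cross-spectral estimation with Hanning tapering, transfer gain, normalised
    gain, MAP-to-MCAv phase and squared coherence in the very-low, low and
    high frequency bands with a coherence validity criterion; arterial oxygen
    content and cerebral oxygen vasoreactivity; exact Wilcoxon signed-rank
    paired tests with Holm step-down adjustment and median-IQR summaries; and
    a synthetic hemodynamic-signal generator with known linear transfer
    characteristics for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
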