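Package: emdecg
Title: Adaptive ECG Denoising by Empirical Mode Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Removes broadband noise, powerline interference and baseline
    wander from single-channel electrocardiogram (ECG) recordings by
    empirical mode decomposition (EMD). The signal is sifted into intrinsic
    mode functions (IMFs) with a normalised-standard-difference stopping
    rule; low-order noise IMFs are identified adaptively from the cumulative
    mean of the partial reconstructions, confirmed by an IMF-power test, and
    removed or attenuated before selective reconstruction; baseline wander is
    stripped by detaching high-order IMFs and the residue while a piecewise
    slope metric decreases. Includes a synthetic ECG-plus-noise generator, the
    standard SNR-improvement/MSE/PRD evaluation metrics, a seeded Monte-Carlo
    evaluation grid, CSV/JSON signal and report I/O, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
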