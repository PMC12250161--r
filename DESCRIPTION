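Package: evokedff
Title: Event-Locked Delta-F/F0 Analysis of Deep-Brain Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying stimulus-evoked fluorescence responses in
    implanted micro-CMOS calcium-imaging recordings. Provides a synthetic
    movie generator with ground truth (force-graded nociceptive depression,
    rebound excitation, chronic-pain and morphine condition effects), TIFF/CSV
    recording I/O, automatic 10x10-pixel region-of-interest selection,
    event-locked epoch segmentation with a per-stimulation dynamic baseline
    Delta-F/F0 normalization, four-window area-under-curve quantification,
    and normality-routed paired statistics (Shapiro-Wilk gated paired t /
    Wilcoxon signed-rank) with animal-level aggregation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
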